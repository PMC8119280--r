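#' Acquisition geometry of a BOLD run
#'
#' @param dim Integer grid size `c(nx, ny, nz)`.  The default is a
#'   desk-scale 24 x 24 x 18 grid at the acquisition's in-plane/slice
#'   resolution rather than the full scanner matrix.
#' @param voxel_mm Voxel extents in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes in the run.
#' @param mask Optional 3-D logical array; defaults to all-TRUE.
#' @return An object of class `bold_geometry`.
#' @export
bold_geometry <- function(dim = c(24L, 24L, 18L),
                          voxel_mm = c(3.75, 3.75, 4),
                          tr_s = 3, n_volumes = 304L, mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), length(voxel_mm) == 3L,
            all(voxel_mm > 0), tr_s > 0, n_volumes >= 1L)
  if (is.null(mask)) mask <- array(TRUE, dim)
  if (!identical(dim(mask), dim)) stop("mask shape must match `dim`")
  structure(list(dim = dim, voxel_mm = voxel_mm, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes), mask = mask),
            class = "bold_geometry")
}

#' Condition-locked activation effect
#'
#' Describes one planted activation: a set of voxels whose time courses
#' receive `amplitude` times the HRF-convolved onset train of one trial
#' category.  Negative amplitudes model deactivations.
#'
#' @param region Either an n x 3 integer matrix of voxel coordinates or a
#'   3-D logical array.
#' @param condition Trial category: `"ST"`, `"UT"`, `"SNT"`, `"UNT"`,
#'   `"OT"`.
#' @param amplitude Signal change in baseline units per unit regressor.
#' @param group Which simulated group carries the effect: `"both"`,
#'   `"HC"`, or `"SCZ"`.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region, condition, amplitude, group = "both") {
  stopifnot(condition %in% c("ST", "UT", "SNT", "UNT", "OT"),
            is.finite(amplitude))
  if (is.array(region) && is.logical(region)) {
    region <- which(region, arr.ind = TRUE)
  }
  region <- as.matrix(region)
  if (ncol(region) != 3L || nrow(region) < 1L) {
    stop("`region` must be an n x 3 coordinate matrix or logical array")
  }
  structure(list(region = region, condition = condition,
                 amplitude = amplitude, group = group),
            class = "effect_spec")
}

region_index <- function(region, dim) {
  if (any(region < 1L) || any(t(region) > dim)) {
    stop("effect region lies outside the volume")
  }
  (region[, 3] - 1L) * dim[1] * dim[2] + (region[, 2] - 1L) * dim[1] + region[, 1]
}

#' Simulate a 4-D BOLD series from a categorized timeline
#'
#' Generates `baseline + effects + drift + noise` voxel by voxel: each
#' [effect_spec()] contributes its amplitude times the HRF-convolved
#' impulse train of its condition within its region; drift is a shared
#' linear ramp plus a one-cycle sinusoid scaled by `drift_amp`; noise is
#' an AR(1) process driven by white innovations of sd `white_sd`.  With
#' all noise terms zero the series is exactly linear in the planted
#' effects.
#'
#' @param timeline Data frame with `onset_s` and `category` per trial
#'   (a classified session works directly).
#' @param effects List of [effect_spec()]s (possibly empty).
#' @param geometry A [bold_geometry()].
#' @param noise List with `white_sd`, `ar1`, `drift_amp` (any may be 0).
#' @param baseline Baseline signal level.
#' @param group Simulated subject's group label, used to filter effects by
#'   their `group` field.
#' @param hrf Hemodynamic response function of time in seconds, see
#'   [hrf_double_gamma()].
#' @param seed Optional integer seed.
#' @return A `bold_series`: list with 4-D `data` (x, y, z, t) and the
#'   `geometry`.
#' @export
simulate_bold <- function(timeline, effects = list(),
                          geometry = bold_geometry(),
                          noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 0),
                          baseline = 100, group = "both",
                          hrf = hrf_double_gamma, seed = NULL) {
  stopifnot(inherits(geometry, "bold_geometry"))
  noise <- utils::modifyList(list(white_sd = 0, ar1 = 0, drift_amp = 0),
                             as.list(noise))
  d <- geometry$dim; nt <- geometry$n_volumes
  nv <- prod(d)
  X <- NULL
  if (length(effects) > 0) {
    if (!all(c("onset_s", "category") %in% names(timeline))) {
      stop("timeline needs `onset_s` and `category` columns")
    }
    X <- build_design(timeline$onset_s, timeline$category,
                      tr_s = geometry$tr_s, n_volumes = nt, hrf = hrf)
  }

  with_seed(seed, {
    M <- matrix(baseline, nrow = nv, ncol = nt)  # voxels x time
    if (noise$drift_amp != 0) {
      tt <- seq_len(nt)
      w <- noise$drift_amp * (seq(-0.5, 0.5, length.out = nt) +
                                0.5 * sin(2 * pi * (tt - 1) / nt))
      M <- M + matrix(w, nrow = nv, ncol = nt, byrow = TRUE)
    }
    for (ef in effects) {
      stopifnot(inherits(ef, "effect_spec"))
      if (!(ef$group == "both" || ef$group == group)) next
      idx <- region_index(ef$region, d)
      if (!all(geometry$mask[idx])) stop("effect region lies outside the mask")
      reg <- X[, ef$condition]
      M[idx, ] <- M[idx, ] + ef$amplitude * matrix(reg, nrow = length(idx),
                                                   ncol = nt, byrow = TRUE)
    }
    if (noise$white_sd > 0) {
      W <- matrix(stats::rnorm(nv * nt, sd = noise$white_sd), nrow = nt)
      if (noise$ar1 != 0) {
        W <- stats::filter(W, noise$ar1, method = "recursive")
        W <- matrix(as.numeric(W), nrow = nt)
      }
      M <- M + t(W)
    }
    structure(list(data = array(M, c(d, nt)), geometry = geometry),
              class = "bold_series")
  })
}

#' Preprocess a BOLD series
#'
#' The two preprocessing steps with a synthetic counterpart: (1) discard
#' the first `n_dummy` volumes (T1-saturation dummies), (2) temporal
#' high-pass filtering by projecting out sine/cosine pairs at whole-run
#' frequencies strictly below `highpass_cycles` cycles/run (the run mean
#' is kept), and (3) isotropic Gaussian spatial smoothing of `fwhm_mm`
#' within the mask (kernel renormalised at mask edges, so spatially
#' constant signals are preserved).
#'
#' @param series A `bold_series`.
#' @param n_dummy Number of initial volumes to discard.
#' @param highpass_cycles Cutoff in cycles per run; frequencies below it
#'   are removed.  Use 0 to skip.
#' @param fwhm_mm Smoothing kernel FWHM in mm.  Use 0 to skip.
#' @return A `bold_series` with updated data and `n_volumes`.
#' @export
preprocess_bold <- function(series, n_dummy = 4L, highpass_cycles = 3,
                            fwhm_mm = 6) {
  stopifnot(inherits(series, "bold_series"))
  geom <- series$geometry
  nt <- geom$n_volumes
  if (n_dummy >= nt) stop("`n_dummy` must be smaller than the number of volumes")
  dat <- series$data
  if (n_dummy > 0) {
    dat <- dat[, , , -(seq_len(n_dummy)), drop = FALSE]
    nt <- nt - as.integer(n_dummy)
  }
  d <- geom$dim; nv <- prod(d)
  M <- matrix(dat, nrow = nv)  # voxels x time

  if (highpass_cycles > 0) {
    jmax <- ceiling(highpass_cycles) - 1L
    if (jmax >= 1L) {
      if (2L * jmax >= nt) stop("high-pass basis larger than the time dimension")
      tt <- (seq_len(nt) - 1L) / nt
      B <- do.call(cbind, lapply(seq_len(jmax), function(j) {
        cbind(sin(2 * pi * j * tt), cos(2 * pi * j * tt))
      }))
      Q <- qr.Q(qr(B))
      M <- M - (M %*% Q) %*% t(Q)
    }
  }

  if (fwhm_mm > 0) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / geom$voxel_mm
    maskn <- array(as.numeric(geom$mask), d)
    den <- gaussian_conv3(maskn, sigma)
    for (k in seq_len(nt)) {
      vol <- array(M[, k], d)
      vol[!geom$mask] <- 0
      sm <- gaussian_conv3(vol, sigma) / den
      sm[!geom$mask] <- NA_real_
      M[, k] <- as.numeric(sm)
    }
  }

  geom$n_volumes <- nt
  structure(list(data = array(M, c(d, nt)), geometry = geom),
            class = "bold_series")
}

# --- separable Gaussian convolution -----------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# zero-padded convolution along the first axis of a matrix
conv_first <- function(M, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  for (s in seq.int(-r, r)) {
    w <- k[s + r + 1L]
    if (s >= 0) {
      out[(1L + s):n, ] <- out[(1L + s):n, ] + w * M[1L:(n - s), , drop = FALSE]
    } else {
      out[1L:(n + s), ] <- out[1L:(n + s), ] + w * M[(1L - s):n, , drop = FALSE]
    }
  }
  out
}

# separable 3-D Gaussian convolution with zero padding; per-axis sigma in
# voxels (0 skips an axis)
gaussian_conv3 <- function(a, sigma_vox) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    k <- gauss_kernel(sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(a, perm)
    dp <- dim(p)
    m <- conv_first(matrix(p, dp[1], prod(dp[-1])), k)
    a <- aperm(array(m, dp), order(perm))
  }
  a
}

#' Gaussian-smooth a 3-D volume within a mask
#'
#' Separable Gaussian smoothing with the kernel renormalised by the
#' smoothed mask indicator, so constants are preserved everywhere inside
#' the mask.  Voxels outside the mask are returned as `NA`.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm.
#' @param voxel_mm Voxel extents in mm.
#' @param mask Optional 3-D logical array.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_mm = c(1, 1, 1), mask = NULL) {
  d <- dim(vol)
  if (is.null(mask)) mask <- array(TRUE, d)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  v <- vol
  v[!mask] <- 0
  num <- gaussian_conv3(v, sigma)
  den <- gaussian_conv3(array(as.numeric(mask), d), sigma)
  out <- num / den
  out[!mask] <- NA_real_
  out
}
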