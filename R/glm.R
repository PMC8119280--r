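CONDITIONS <- c("ST", "UT", "SNT", "UNT", "OT")

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with unit time constants: response
#' peak at `peak` seconds, undershoot peak at `undershoot` seconds,
#' peak-to-undershoot ratio `ratio`.  Normalised to a maximum of 1.
#'
#' @param t Time in seconds (vector).
#' @param peak Time to response peak (s).
#' @param undershoot Time to undershoot peak (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 5, undershoot = 15, ratio = 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h / max(h)
}

#' Build the event-related design matrix
#'
#' One predictor per trial category (impulse train at stimulus onsets
#' convolved with the HRF on a fine time grid, then sampled at volume
#' acquisition times) plus a constant column.  Categories with no events
#' yield all-zero columns, flagged in the `"empty"` attribute; [fit_glm()]
#' drops them before solving.
#'
#' @param onset_s Stimulus onsets in seconds from run start.
#' @param category Trial category per onset (`ST`, `UT`, `SNT`, `UNT`,
#'   `OT`).
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param hrf HRF function of time in seconds.
#' @param dt Microtime resolution (s) for the convolution grid.
#' @return A `design_matrix`: an `n_volumes` x 6 matrix with attributes
#'   `empty` (categories without events), `tr_s` and `conditions`.
#' @export
build_design <- function(onset_s, category, tr_s, n_volumes,
                         hrf = hrf_double_gamma, dt = 0.1) {
  stopifnot(length(onset_s) == length(category), tr_s > 0, n_volumes >= 1)
  run_end <- n_volumes * tr_s
  if (any(onset_s < 0)) stop("onsets must be non-negative")
  if (any(onset_s > run_end)) stop("onset beyond the end of the run")
  nt_fine <- as.integer(ceiling(run_end / dt)) + 1L
  h <- hrf(seq(0, 32, by = dt))
  vol_idx <- as.integer(round((seq_len(n_volumes) - 1L) * tr_s / dt)) + 1L

  X <- matrix(0, n_volumes, length(CONDITIONS) + 1L,
              dimnames = list(NULL, c(CONDITIONS, "constant")))
  X[, "constant"] <- 1
  empty <- character(0)
  for (cc in CONDITIONS) {
    ons <- onset_s[category == cc & !is.na(category)]
    if (length(ons) == 0L) { empty <- c(empty, cc); next }
    bins <- pmin(nt_fine, as.integer(floor(ons / dt)) + 1L)
    u <- as.numeric(tabulate(bins, nbins = nt_fine))
    x <- causal_conv(u, h)
    X[, cc] <- x[vol_idx]
  }
  structure(X, class = c("design_matrix", "matrix"), empty = empty,
            tr_s = tr_s, dt = dt, conditions = CONDITIONS)
}

# exact causal discrete convolution, truncated to length(u)
causal_conv <- function(u, h) {
  n <- length(u)
  out <- numeric(n)
  hits <- which(u != 0)
  for (i in hits) {
    j <- i:min(n, i + length(h) - 1L)
    out[j] <- out[j] + u[i] * h[seq_along(j)]
  }
  out
}

#' Voxelwise ordinary least squares GLM
#'
#' Fits the design to every voxel time course inside the mask.  Flagged
#' empty condition columns are dropped before solving; a rank-deficient
#' design is an error naming the collinear columns.  Voxels outside the
#' mask carry `NA`, never 0.
#'
#' @param series A `bold_series` (typically after [preprocess_bold()]).
#' @param design A `design_matrix` with rows matching the series' volumes.
#' @return A `beta_maps` object: list with `beta` (named list of 3-D
#'   arrays, one per retained predictor; dropped empty conditions are
#'   all-`NA`), `sigma2` (residual variance), `df_resid`, `mask`,
#'   `geometry`.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "bold_series"))
  geom <- series$geometry
  nt <- geom$n_volumes
  if (nrow(design) != nt) {
    stop(sprintf("design has %d rows but the series has %d volumes",
                 nrow(design), nt))
  }
  empty <- attr(design, "empty")
  keep <- setdiff(colnames(design), empty)
  X <- design[, keep, drop = FALSE]
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  d <- geom$dim
  midx <- which(geom$mask)
  Y <- matrix(series$data, nrow = prod(d))[midx, , drop = FALSE]
  coef <- qr.coef(q, t(Y))                       # predictors x voxels
  resid <- t(Y) - X %*% coef
  df_resid <- nt - q$rank
  sigma2 <- colSums(resid^2) / df_resid

  to_map <- function(v) {
    a <- array(NA_real_, d); a[midx] <- v; a
  }
  beta <- stats::setNames(
    lapply(seq_len(nrow(coef)), function(i) to_map(coef[i, ])),
    rownames(coef) %||% keep)
  for (cc in empty) beta[[cc]] <- array(NA_real_, d)
  structure(list(beta = beta, sigma2 = to_map(sigma2),
                 df_resid = df_resid, mask = geom$mask, geometry = geom,
                 empty = empty),
            class = "beta_maps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_stat_map <- function(values, df, kind, contrast, mask, geometry = NULL) {
  structure(list(values = values, df = df, kind = kind,
                 contrast = contrast, mask = mask, geometry = geometry),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s map '%s', df = %s, %s voxels in mask\n",
              x$kind, x$contrast, paste(x$df, collapse = ","),
              sum(x$mask)))
  invisible(x)
}

subject_contrast_matrix <- function(subjects, weights) {
  # subjects: list of beta_maps or of plain 3-D arrays (pre-computed
  # contrast maps); returns subjects x voxels matrix over the common mask
  first <- subjects[[1L]]
  if (inherits(first, "beta_maps")) {
    mask <- Reduce(`&`, lapply(subjects, `[[`, "mask"))
    midx <- which(mask)
    C <- t(vapply(subjects, function(s) {
      v <- numeric(length(midx))
      for (cc in names(weights)) {
        b <- s$beta[[cc]]
        if (is.null(b)) stop("subject lacks condition ", cc)
        v <- v + weights[[cc]] * b[midx]
      }
      v
    }, numeric(length(midx))))
    list(C = C, mask = mask, midx = midx, geometry = first$geometry)
  } else {
    mask <- !is.na(first)
    for (s in subjects) mask <- mask & !is.na(s)
    midx <- which(mask)
    C <- t(vapply(subjects, function(s) s[midx], numeric(length(midx))))
    list(C = C, mask = mask, midx = midx, geometry = NULL)
  }
}

#' Random-effects group map (one-sample t on subject contrasts)
#'
#' Treats subject-level contrast estimates as the sampling unit: per
#' voxel, a one-sample t of the subjects' contrast values against zero
#' with `n - 1` degrees of freedom.  Subjects with identical nonzero
#' values give an infinite t (flagged, not silently clipped).  Optional
#' second-level covariates are entered as additional regressors; their
#' per-covariate t maps are attached as the `covariate_maps` element.
#'
#' @param subjects List of `beta_maps` (one per subject) or of 3-D
#'   subject contrast arrays.
#' @param weights Named condition weights, e.g. `c(ST = 1, UT = -1)`;
#'   ignored when `subjects` are plain contrast arrays.
#' @param contrast Label for the resulting map.
#' @param covariates Optional numeric matrix/data frame (subjects x
#'   covariates), mean-centred internally.
#' @return A `stat_map` (kind `"t"`, df `n - 1 - n_covariates`).
#' @export
rfx_contrast <- function(subjects, weights = NULL, contrast = "contrast",
                         covariates = NULL) {
  if (length(subjects) < 2L) stop("random-effects analysis needs >= 2 subjects")
  if (inherits(subjects[[1L]], "beta_maps") && is.null(weights)) {
    stop("`weights` are required when subjects are beta maps")
  }
  sc <- subject_contrast_matrix(subjects, weights)
  C <- sc$C
  n <- nrow(C)
  if (is.null(covariates)) {
    m <- colMeans(C)
    s <- apply(C, 2L, stats::sd)
    t <- ifelse(s > 0, m / (s / sqrt(n)),
                ifelse(m == 0, 0, sign(m) * Inf))
    df <- n - 1L
    vals <- array(NA_real_, dim(sc$mask)); vals[sc$midx] <- t
    return(new_stat_map(vals, df, "t", contrast, sc$mask, sc$geometry))
  }
  Z <- as.matrix(covariates)
  if (nrow(Z) != n) stop("covariates must have one row per subject")
  Z <- scale(Z, center = TRUE, scale = FALSE)
  X <- cbind(intercept = 1, Z)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("covariate design is rank deficient")
  coef <- qr.coef(q, C)
  res <- C - X %*% coef
  df <- n - q$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(q))
  maps <- lapply(seq_len(ncol(X)), function(j) {
    se <- sqrt(sigma2 * xtx_inv[j, j])
    t <- ifelse(se > 0, coef[j, ] / se, 0)
    vals <- array(NA_real_, dim(sc$mask)); vals[sc$midx] <- t
    new_stat_map(vals, df, "t",
                 paste0(contrast, ":", colnames(X)[j]), sc$mask, sc$geometry)
  })
  out <- maps[[1L]]
  out$contrast <- contrast
  out$covariate_maps <- maps[-1L]
  out
}

#' Voxelwise two-factor mixed-design ANOVA
#'
#' Per voxel, a mixed ANOVA with trial category (k levels) as the
#' within-subject factor and group as the between-subject factor.  The
#' between-group F uses the subject-within-group mean square
#' (df `g - 1`, `n - g`); the condition and interaction Fs share the
#' subject-by-condition error term (df `k - 1`, `(n - g)(k - 1)`).  With
#' n = 34, g = 2, k = 5 these are (1, 32) and (4, 128).  No sphericity
#' correction is applied.
#'
#' @param subjects List of `beta_maps`, one per subject, each holding all
#'   five condition betas.
#' @param groups Character/factor group label per subject (two groups).
#' @param conditions Condition names used as the within factor.
#' @return List with `stat_map`s `F_between`, `F_within`,
#'   `F_interaction`, each with a two-element df.
#' @export
mixed_anova <- function(subjects, groups,
                        conditions = CONDITIONS) {
  n <- length(subjects)
  stopifnot(length(groups) == n, n >= 4L)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  if (g != 2L) stop("exactly two groups are expected")
  K <- length(conditions)

  mask <- Reduce(`&`, lapply(subjects, `[[`, "mask"))
  for (s in subjects) {
    for (cc in conditions) {
      b <- s$beta[[cc]]
      if (is.null(b)) stop("subject lacks condition ", cc)
      mask <- mask & !is.na(b)
    }
  }
  midx <- which(mask)
  V <- length(midx)
  # Y: voxels x subjects x conditions
  Y <- array(NA_real_, c(V, n, K))
  for (s in seq_len(n)) {
    for (k in seq_len(K)) {
      Y[, s, k] <- subjects[[s]]$beta[[conditions[k]]][midx]
    }
  }

  subj_mean <- apply(Y, c(1, 2), mean)              # V x n
  grand <- rowMeans(subj_mean)                      # V
  cond_mean <- apply(Y, c(1, 3), mean)              # V x K

  glev <- levels(groups)
  ng <- as.integer(table(groups))
  group_mean <- vapply(glev, function(gl)
    rowMeans(subj_mean[, groups == gl, drop = FALSE]), numeric(V))  # V x g

  SS_bs <- K * rowSums((subj_mean - grand)^2)
  SS_group <- K * (ng[1] * (group_mean[, 1] - grand)^2 +
                     ng[2] * (group_mean[, 2] - grand)^2)
  SS_subj_wg <- SS_bs - SS_group

  SS_cond <- n * rowSums((cond_mean - grand)^2)
  SS_inter <- numeric(V)
  for (gi in seq_len(g)) {
    sel <- groups == glev[gi]
    cell <- apply(Y[, sel, , drop = FALSE], c(1, 3), mean)     # V x K
    cond_g <- cell - group_mean[, gi]                          # remove group mean
    SS_inter <- SS_inter + ng[gi] * rowSums((cond_g - (cond_mean - grand))^2)
  }
  SS_within_tot <- rowSums((Y - as.vector(subj_mean))^2)       # recycles over K
  SS_err <- SS_within_tot - SS_cond - SS_inter

  df_group <- c(g - 1L, n - g)
  df_cond <- c(K - 1L, (n - g) * (K - 1L))

  Fmap <- function(ss, df1, ss_err, df2) {
    ms <- ss / df1; mse <- ss_err / df2
    ifelse(mse > 0, ms / mse, ifelse(ms == 0, 0, Inf))
  }
  to_map <- function(v) { a <- array(NA_real_, dim(mask)); a[midx] <- v; a }

  list(
    F_between = new_stat_map(to_map(Fmap(SS_group, df_group[1], SS_subj_wg, df_group[2])),
                             df_group, "F", "group", mask),
    F_within = new_stat_map(to_map(Fmap(SS_cond, df_cond[1], SS_err, df_cond[2])),
                            df_cond, "F", "condition", mask),
    F_interaction = new_stat_map(to_map(Fmap(SS_inter, df_cond[1], SS_err, df_cond[2])),
                                 df_cond, "F", "group:condition", mask)
  )
}

#' Post-hoc between-group map
#'
#' Voxelwise pooled-variance two-sample t between the groups' subject
#' contrast values.  `df_mode` selects the degrees of freedom attached to
#' the map: `"anova_pooled"` uses the cell-level pooled-error convention
#' `(n - 1)(k - 1)` (132 for n = 34, k = 5), `"two_sample"` the plain
#' `n - 2`.  The mode used is recorded on the map.
#'
#' @param subjects List of `beta_maps` or 3-D subject contrast arrays.
#' @param groups Group label per subject (two groups); the statistic is
#'   first level minus second level.
#' @param weights Named condition weights when `subjects` are beta maps.
#' @param df_mode `"anova_pooled"` or `"two_sample"`.
#' @param n_conditions Number of within-subject conditions (k) used by
#'   the pooled-df convention.
#' @param contrast Label for the map.
#' @return A `stat_map` with attribute-like fields `df_mode`.
#' @export
posthoc_group_map <- function(subjects, groups, weights = NULL,
                              df_mode = c("anova_pooled", "two_sample"),
                              n_conditions = 5L, contrast = "group difference") {
  df_mode <- match.arg(df_mode)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are expected")
  sc <- subject_contrast_matrix(subjects, weights)
  C <- sc$C
  n <- nrow(C)
  i1 <- groups == levels(groups)[1L]
  n1 <- sum(i1); n2 <- n - n1
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 subjects")
  m1 <- colMeans(C[i1, , drop = FALSE]); m2 <- colMeans(C[!i1, , drop = FALSE])
  v1 <- apply(C[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(C[!i1, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se,
              ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- switch(df_mode,
               anova_pooled = (n - 1L) * (as.integer(n_conditions) - 1L),
               two_sample = n - 2L)
  vals <- array(NA_real_, dim(sc$mask)); vals[sc$midx] <- t
  out <- new_stat_map(vals, df, "t", contrast, sc$mask, sc$geometry)
  out$df_mode <- df_mode
  out
}
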