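#' Cluster-extent correction rule
#'
#' Bundles the parameters of Monte-Carlo cluster-extent thresholding: the
#' two-tailed voxel-level probability, the family-wise cluster alpha, the
#' number of null-map repetitions, the neighbourhood used for connected
#' components, and the spatial smoothness injected into the null maps.
#' `min_cluster_size` is filled by [estimate_min_cluster()].
#'
#' @param voxel_p Voxel-level two-tailed probability threshold.
#' @param alpha Family-wise cluster-level alpha.
#' @param n_iter Monte-Carlo repetitions.
#' @param connectivity Neighbourhood: 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+vertices).
#' @param fwhm_mm Smoothness injected into the null maps (mm FWHM);
#'   usually the analysis smoothing.
#' @param min_cluster_size Minimum cluster extent in voxels (output).
#' @return An object of class `cluster_rule`.
#' @export
cluster_rule <- function(voxel_p = 0.01, alpha = 0.05, n_iter = 1000L,
                         connectivity = 26L, fwhm_mm = 6,
                         min_cluster_size = NA_integer_) {
  stopifnot(voxel_p > 0, voxel_p < 1, alpha > 0, alpha <= 1,
            n_iter >= 1L, connectivity %in% c(6L, 18L, 26L), fwhm_mm >= 0)
  structure(list(voxel_p = voxel_p, alpha = alpha,
                 n_iter = as.integer(n_iter),
                 connectivity = as.integer(connectivity),
                 fwhm_mm = fwhm_mm,
                 min_cluster_size = min_cluster_size),
            class = "cluster_rule")
}

neighbour_offsets <- function(connectivity) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(o)) == 1,
                 "18" = rowSums(abs(o)) <= 2,
                 "26" = rep(TRUE, nrow(o)),
                 stop("connectivity must be 6, 18 or 26"))
  o[keep, , drop = FALSE]
}

#' Connected suprathreshold clusters of a 3-D field
#'
#' Labels the connected components of the suprathreshold voxels of a 3-D
#' statistic field (or of a logical array) under the stated neighbourhood,
#' returning clusters sorted by decreasing size.  For a two-tailed rule
#' pass `abs(values)` (signed maps form separate positive and negative
#' clusters only if they are spatially separate).
#'
#' @param x 3-D numeric or logical array (a `stat_map`'s `values` works).
#' @param threshold Numeric threshold (`x >= threshold`); ignored for
#'   logical input.  `NA` voxels never pass.
#' @param connectivity 6, 18 or 26.
#' @param mask Optional 3-D logical array restricting the search.
#' @return A list of clusters, each a list with `voxels` (linear
#'   indices), `coords` (n x 3 matrix) and `size`; sorted by size,
#'   largest first.
#' @export
find_clusters <- function(x, threshold = NULL, connectivity = 26L,
                          mask = NULL) {
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be a 3-D array")
  if (is.logical(x)) {
    bin <- x & !is.na(x)
  } else {
    if (is.null(threshold)) stop("`threshold` is required for numeric input")
    bin <- !is.na(x) & x >= threshold
  }
  if (!is.null(mask)) bin <- bin & mask
  off <- neighbour_offsets(connectivity)
  idx <- which(bin)
  if (length(idx) == 0L) return(list())
  lab <- integer(prod(d))
  lab[idx] <- -1L
  nx <- d[1]; nxy <- d[1] * d[2]
  clusters <- list()
  for (v0 in idx) {
    if (lab[v0] != -1L) next
    cl_id <- length(clusters) + 1L
    stack <- v0
    lab[v0] <- cl_id
    members <- integer(0)
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      v0i <- v - 1L
      z <- v0i %/% nxy
      r <- v0i %% nxy
      y <- r %/% nx
      xco <- r %% nx
      nb <- cbind(xco + 1L + off[, 1], y + 1L + off[, 2], z + 1L + off[, 3])
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1L) * nxy + (nb[, 2] - 1L) * nx + nb[, 1]
      new <- lin[lab[lin] == -1L]
      if (length(new) > 0L) {
        lab[new] <- cl_id
        stack <- c(stack, new)
      }
    }
    clusters[[cl_id]] <- members
  }
  sizes <- lengths(clusters)
  ord <- order(sizes, decreasing = TRUE)
  lapply(ord, function(i) {
    v <- clusters[[i]]
    list(voxels = v, coords = arrayInd(v, d), size = length(v))
  })
}

#' Monte-Carlo minimum cluster-extent threshold
#'
#' Estimates the smallest cluster size whose family-wise probability
#' under the null does not exceed `alpha`: for each repetition, white
#' Gaussian noise is drawn on the grid, smoothed by `fwhm_mm` (the
#' injected spatial correlation), re-standardised to unit variance within
#' the mask (skipped when `fwhm_mm = 0`, where the draw is already
#' standard normal — this keeps the independent-voxel case exact),
#' thresholded two-tailed at `voxel_p`, and the largest suprathreshold
#' cluster size recorded.  The returned rule's `min_cluster_size` is the
#' smallest k with `P(max cluster >= k) <= alpha`.
#'
#' @param geometry A [bold_geometry()] (only `dim`, `voxel_mm`, `mask`
#'   are used).
#' @param rule A [cluster_rule()].
#' @param mask Optional override of the geometry mask.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return The rule with `min_cluster_size`, `alpha_achieved` and the
#'   null `max_sizes` sample filled in.
#' @export
estimate_min_cluster <- function(geometry, rule = cluster_rule(),
                                 mask = NULL, seed = NULL) {
  stopifnot(inherits(geometry, "bold_geometry"), inherits(rule, "cluster_rule"))
  if (is.null(mask)) mask <- geometry$mask
  if (!any(mask)) stop("mask is empty")
  if (rule$alpha < 1 / rule$n_iter) {
    warning("alpha below 1/n_iter; the null quantile is unreliable")
  }
  d <- geometry$dim
  thr <- stats::qnorm(1 - rule$voxel_p / 2)
  sigma <- rule$fwhm_mm / (2 * sqrt(2 * log(2))) / geometry$voxel_mm
  smooth <- any(sigma > 0)
  if (smooth) {
    maskn <- array(as.numeric(mask), d)
    den <- gaussian_conv3(maskn, sigma)
  }
  max_sizes <- integer(rule$n_iter)
  with_seed(seed, {
    for (i in seq_len(rule$n_iter)) {
      z <- array(stats::rnorm(prod(d)), d)
      if (smooth) {
        z[!mask] <- 0
        z <- gaussian_conv3(z, sigma) / den
        zm <- z[mask]
        z <- (z - mean(zm)) / stats::sd(zm)
      }
      supra <- !is.na(z) & abs(z) >= thr & mask
      cl <- find_clusters(supra, connectivity = rule$connectivity)
      max_sizes[i] <- if (length(cl) > 0L) cl[[1L]]$size else 0L
    }
  })
  rule$min_cluster_size <- min_cluster_from_null(max_sizes, rule$alpha)
  rule$alpha_achieved <- mean(max_sizes >= rule$min_cluster_size)
  rule$max_sizes <- max_sizes
  rule
}

#' Minimum cluster size from a null max-cluster sample
#'
#' Given the Monte-Carlo sample of largest null cluster sizes, returns
#' the smallest extent k whose exceedance fraction is at most `alpha`.
#' Useful for re-reading one simulation at several alphas.
#'
#' @param max_sizes Integer vector of per-repetition largest cluster
#'   sizes.
#' @param alpha Family-wise alpha.
#' @return Minimum cluster size in voxels (>= 1).
#' @export
min_cluster_from_null <- function(max_sizes, alpha) {
  ks <- seq_len(max(max_sizes, 1L) + 1L)
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  ks[which(exceed <= alpha)[1L]]
}

#' Apply a filled cluster rule to a statistic map
#'
#' Two-tailed voxel thresholding at the rule's `voxel_p` (critical value
#' from the map's own t or z null) followed by the minimum-extent filter.
#'
#' @param map A `stat_map` (kind `"t"`) or a 3-D z-valued array.
#' @param rule A [cluster_rule()] with `min_cluster_size` filled.
#' @return Clusters (as in [find_clusters()]) of at least
#'   `min_cluster_size` voxels.
#' @export
apply_cluster_rule <- function(map, rule) {
  if (is.na(rule$min_cluster_size)) {
    stop("rule has no `min_cluster_size`; run estimate_min_cluster() first")
  }
  if (inherits(map, "stat_map")) {
    crit <- if (map$kind == "t") critical_t(rule$voxel_p, map$df[1]) else
      stats::qnorm(1 - rule$voxel_p / 2)
    vals <- map$values
    mask <- map$mask
  } else {
    crit <- stats::qnorm(1 - rule$voxel_p / 2)
    vals <- map
    mask <- NULL
  }
  cl <- find_clusters(abs(vals), threshold = crit,
                      connectivity = rule$connectivity, mask = mask)
  Filter(function(x) x$size >= rule$min_cluster_size, cl)
}
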