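#' Define ROIs from a group statistic map
#'
#' Applies a filled [cluster_rule()] to a group map: voxels exceeding the
#' two-tailed critical value at the rule's `voxel_p` (on the map's own
#' degrees of freedom) that form clusters of at least `min_cluster_size`
#' voxels become regions of interest.  Each ROI reports its size, its
#' unweighted centre of gravity (voxel coordinates and mm), and its
#' volume in mm^3.  A map with no surviving cluster yields an empty set.
#'
#' @param map A `stat_map`.
#' @param rule A [cluster_rule()] with `min_cluster_size` filled.
#' @param voxel_mm Voxel extents, taken from the map's geometry when
#'   available.
#' @return An object of class `roi_set`: a list of ROIs, each with
#'   `label`, `voxels`, `coords`, `size`, `cog_voxel`, `cog_mm`,
#'   `volume_mm3`, `peak_stat`.
#' @export
define_rois <- function(map, rule, voxel_mm = NULL) {
  stopifnot(inherits(map, "stat_map"), inherits(rule, "cluster_rule"))
  if (is.null(voxel_mm)) {
    voxel_mm <- if (!is.null(map$geometry)) map$geometry$voxel_mm else c(1, 1, 1)
  }
  clusters <- apply_cluster_rule(map, rule)
  rois <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    cog <- colMeans(cl$coords)
    peak <- cl$voxels[which.max(abs(map$values[cl$voxels]))]
    list(label = sprintf("roi_%02d", i), voxels = cl$voxels,
         coords = cl$coords, size = cl$size,
         cog_voxel = cog, cog_mm = cog * voxel_mm,
         volume_mm3 = cl$size * prod(voxel_mm),
         peak_stat = map$values[peak])
  })
  structure(rois, class = "roi_set", rule = rule)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s)\n", length(x)))
  if (length(x) > 0) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.roi_set <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(label = character(0), size = integer(0),
                      cog_x = numeric(0), cog_y = numeric(0),
                      cog_z = numeric(0), volume_mm3 = numeric(0),
                      peak_stat = numeric(0)))
  }
  do.call(rbind, lapply(x, function(r) {
    data.frame(label = r$label, size = r$size,
               cog_x = r$cog_mm[1], cog_y = r$cog_mm[2], cog_z = r$cog_mm[3],
               volume_mm3 = r$volume_mm3, peak_stat = r$peak_stat,
               stringsAsFactors = FALSE)
  }))
}

roi_subject_means <- function(roi, subjects, weights = NULL, condition = NULL) {
  vapply(subjects, function(s) {
    vals <- if (inherits(s, "beta_maps")) {
      if (!is.null(condition)) {
        b <- s$beta[[condition]]
        if (is.null(b)) stop("subject lacks condition ", condition)
        b[roi$voxels]
      } else {
        stopifnot(!is.null(weights))
        v <- 0
        for (cc in names(weights)) v <- v + weights[[cc]] * s$beta[[cc]][roi$voxels]
        v
      }
    } else {
      s[roi$voxels]
    }
    if (all(is.na(vals))) stop("ROI is empty after masking for a subject")
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Between-group comparison of ROI beta weights
#'
#' For each ROI, every subject's beta weights (for a condition or a
#' weighted contrast) are averaged over the ROI voxels and the two groups
#' are compared with the pooled two-sample Student t test ([pooled_t()]).
#'
#' @param rois An `roi_set` from [define_rois()].
#' @param subjects List of `beta_maps` (or plain 3-D arrays of subject
#'   contrast values).
#' @param groups Group label per subject (two levels; the statistic is
#'   first level minus second).
#' @param weights Named condition weights for a contrast, e.g.
#'   `c(ST = 1, UT = -1)`.
#' @param condition Alternatively, a single condition name.
#' @return A data frame with one row per ROI: centre of gravity, size,
#'   per-group means and sds, `t`, `df`, `p`.
#' @export
roi_group_test <- function(rois, subjects, groups, weights = NULL,
                           condition = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are expected")
  g1 <- levels(groups)[1L]; g2 <- levels(groups)[2L]
  out <- lapply(rois, function(roi) {
    vals <- roi_subject_means(roi, subjects, weights, condition)
    tt <- pooled_t(vals[groups == g1], vals[groups == g2])
    data.frame(label = roi$label, size = roi$size,
               cog_x = roi$cog_mm[1], cog_y = roi$cog_mm[2],
               cog_z = roi$cog_mm[3], volume_mm3 = roi$volume_mm3,
               mean_g1 = tt$a$mean, sd_g1 = tt$a$sd,
               mean_g2 = tt$b$mean, sd_g2 = tt$b$sd,
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame()
  } else {
    names(res)[names(res) == "mean_g1"] <- paste0("mean_", g1)
    names(res)[names(res) == "sd_g1"] <- paste0("sd_", g1)
    names(res)[names(res) == "mean_g2"] <- paste0("mean_", g2)
    names(res)[names(res) == "sd_g2"] <- paste0("sd_", g2)
    rownames(res) <- NULL
  }
  res
}

#' Per-condition decomposition of an ROI group difference
#'
#' Repeats [roi_group_test()] separately for each condition, the analysis
#' used to attribute a contrast-level group difference to its conscious
#' (ST) or unconscious (UT) component.
#'
#' @inheritParams roi_group_test
#' @param conditions Conditions to decompose over.
#' @return A data frame with a `condition` column stacked over
#'   conditions.
#' @export
roi_condition_tests <- function(rois, subjects, groups,
                                conditions = c("ST", "UT")) {
  out <- lapply(conditions, function(cc) {
    df <- roi_group_test(rois, subjects, groups, condition = cc)
    if (nrow(df) > 0) df$condition <- cc
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
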