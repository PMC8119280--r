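#' Group summary (n, mean, sd)
#'
#' A small container for per-group statistics, either computed from raw
#' per-subject values or entered directly from printed summaries.
#'
#' @param x Optional numeric vector of per-subject values.
#' @param label Group label (e.g. `"HC"`, `"SCZ"`).
#' @param n,mean,sd Summary statistics, given directly when `x` is NULL.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(x = NULL, label = NA_character_,
                          n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(n) || is.null(mean) || is.null(sd)) {
    stop("provide either raw values `x` or all of `n`, `mean`, `sd`")
  }
  if (n < 2) stop("a group needs at least 2 subjects")
  if (sd < 0) stop("`sd` must be non-negative")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(x, label = NA_character_) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) return(group_summary(x, label = label))
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
    return(group_summary(label = if (!is.null(x$label)) x$label else label,
                         n = x$n, mean = x$mean, sd = x$sd))
  }
  stop("cannot interpret group input; give a numeric vector or n/mean/sd")
}

#' Pooled-variance two-sample Student t test
#'
#' The classic equal-variance two-sample t test with
#' `df = n1 + n2 - 2`, computed either from raw per-subject vectors or
#' directly from printed group summaries (mean, sd, n) — which makes every
#' published t value recomputable from the reported descriptives.
#' The p value is two-tailed from the central t distribution.
#'
#' @param a,b Numeric vectors, `group_summary` objects, or lists with
#'   `n`, `mean`, `sd`.  The statistic is for `a - b`.
#' @return A list of class `pooled_t` with `t`, `df`, `p`, `mean_diff`,
#'   `se` and the two summaries.
#' @examples
#' # thresholds: SCZ (52.17 +/- 20.20, n 15) vs HC (35.08 +/- 8.16, n 19)
#' pooled_t(list(n = 15, mean = 52.17, sd = 20.20),
#'          list(n = 19, mean = 35.08, sd = 8.16))
#' @export
pooled_t <- function(a, b) {
  a <- as_group_summary(a, "a"); b <- as_group_summary(b, "b")
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  d <- a$mean - b$mean
  t <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_diff = d, se = se,
                 a = a, b = b),
            class = "pooled_t")
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("Pooled two-sample Student t: t(%d) = %.3f, p = %.4g (diff %.3f)\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Pearson correlation with two-tailed p
#'
#' Sample Pearson correlation with the usual t-transform p value on
#' `n - 2` degrees of freedom (delegates to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return A list with `r`, `p`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Catch-trial error summary per group
#'
#' Per participant, misses are positive-control trials not answered "yes"
#' (out of 6) and false alarms are negative-control trials answered "yes"
#' (out of 6); the summary reports group mean and sd of both.
#'
#' @param sessions List of classified (or at least generated) sessions.
#' @param groups Character vector of group labels, one per session.
#' @return A data frame with one row per group: `group`, `n`,
#'   `misses_mean`, `misses_sd`, `false_alarms_mean`, `false_alarms_sd`.
#' @export
catch_summary <- function(sessions, groups) {
  stopifnot(length(sessions) == length(groups))
  misses <- vapply(sessions, function(s)
    sum(s$kind == "positive_control" & s$response != "yes"), numeric(1))
  fas <- vapply(sessions, function(s)
    sum(s$kind == "negative_control" & s$response == "yes"), numeric(1))
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    i <- groups == g
    data.frame(group = g, n = sum(i),
               misses_mean = mean(misses[i]), misses_sd = stats::sd(misses[i]),
               false_alarms_mean = mean(fas[i]),
               false_alarms_sd = stats::sd(fas[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-tailed critical t value
#'
#' Critical value of the central t distribution for a two-tailed test at
#' probability `p` with `df` degrees of freedom (e.g. the voxel-level
#' thresholds used on statistical maps).
#'
#' @param p Two-tailed probability.
#' @param df Degrees of freedom.
#' @return The positive critical value.
#' @export
critical_t <- function(p, df) {
  stopifnot(p > 0, p < 1, df > 0)
  stats::qt(1 - p / 2, df)
}
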