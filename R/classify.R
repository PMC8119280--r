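#' Least-squares slope of a five-trial window
#'
#' Ordinary least-squares slope of stimulus duration against within-window
#' position (0..4) for a window of five consecutive staircase trials.
#'
#' @param durations Numeric vector of exactly five stimulus durations
#'   (refresh units or ms; the zero test is scale-free).
#' @return The OLS slope (duration units per trial).
#' @export
window_slope <- function(durations) {
  if (length(durations) != 5L || !is.numeric(durations)) {
    stop("`durations` must be a numeric vector of length 5")
  }
  x <- 0:4
  # closed-form OLS: sum((x - 2) * d) / sum((x - 2)^2), with sum((x-2)^2) = 10
  sum((x - 2) * durations) / 10
}

#' Classify trials of a session into the five categories
#'
#' Implements the at-threshold rule: for each staircase independently, a
#' regression line is fitted to every set of five consecutive staircase
#' trials and a trial counts as "at threshold" iff at least one window
#' covering it has zero slope.  Categories are then: at-threshold trials
#' answered yes/no are ST/UT; off-threshold trials answered yes/no are
#' SNT/UNT; positive controls answered yes are SNT; negative controls,
#' missed positive controls and trials without a response are OT.
#'
#' Durations are integer refresh units, so a zero slope is attainable
#' exactly; `slope_tol` only guards against floating-point dust.
#'
#' @param session A `staircase_session` (60 trials with responses).
#' @param window Window length (five consecutive trials).
#' @param mode `"sliding"` (stride-1 windows, default) or `"disjoint"`
#'   (non-overlapping tiling, for sensitivity analysis).
#' @param slope_tol Absolute slope below which a window counts as flat.
#' @return A `categorized_session`: the session with its `category` column
#'   filled, plus attributes `counts` (named ST/UT/SNT/UNT/OT counts),
#'   `mode`, and catch-trial error tallies `misses` and `false_alarms`.
#' @export
classify_trials <- function(session, window = 5L,
                            mode = c("sliding", "disjoint"),
                            slope_tol = 1e-9) {
  mode <- match.arg(mode)
  need <- c("kind", "staircase_id", "response")
  if (!all(need %in% names(session))) {
    stop("session lacks columns: ", paste(setdiff(need, names(session)), collapse = ", "))
  }
  dur <- if ("duration_units" %in% names(session) &&
             !all(is.na(session$duration_units))) {
    session$duration_units
  } else {
    session$duration_ms
  }

  at_threshold <- rep(FALSE, nrow(session))
  for (id in unique(stats::na.omit(session$staircase_id))) {
    idx <- which(session$kind == "staircase" & session$staircase_id == id)
    n <- length(idx)
    if (n < window) {
      stop(sprintf("staircase %s has %d trials; at least %d are needed", id, n, window))
    }
    starts <- if (mode == "sliding") {
      seq_len(n - window + 1L)
    } else {
      seq.int(1L, n - window + 1L, by = window)
    }
    for (s in starts) {
      win <- s:(s + window - 1L)
      if (abs(window_slope(dur[idx[win]])) < slope_tol) {
        at_threshold[idx[win]] <- TRUE
      }
    }
  }

  category <- character(nrow(session))
  for (i in seq_len(nrow(session))) {
    k <- session$kind[i]; r <- session$response[i]
    category[i] <-
      if (k == "negative_control") "OT"
      else if (r == "none") "OT"
      else if (k == "positive_control") { if (r == "yes") "SNT" else "OT" }
      else if (at_threshold[i]) { if (r == "yes") "ST" else "UT" }
      else { if (r == "yes") "SNT" else "UNT" }
  }
  session$category <- category

  counts <- vapply(c("ST", "UT", "SNT", "UNT", "OT"),
                   function(cc) sum(category == cc), integer(1L))
  attr(session, "counts") <- counts
  attr(session, "mode") <- mode
  attr(session, "at_threshold") <- at_threshold
  attr(session, "misses") <- sum(session$kind == "positive_control" &
                                   session$response != "yes")
  attr(session, "false_alarms") <- sum(session$kind == "negative_control" &
                                         session$response == "yes")
  class(session) <- unique(c("categorized_session", class(session)))
  session
}

#' Visual detection threshold of a classified session
#'
#' The threshold is the arithmetic mean stimulus duration (ms) over the
#' at-threshold trials (ST and UT).  A session with no at-threshold trial
#' has no defined threshold and returns `NA_real_` with a warning rather
#' than a silent zero.
#'
#' @param categorized A `categorized_session` from [classify_trials()].
#' @return Threshold in ms, or `NA_real_` when no trial is at threshold.
#' @export
estimate_threshold <- function(categorized) {
  if (!"category" %in% names(categorized) ||
      all(is.na(categorized$category))) {
    stop("session is not classified; run classify_trials() first")
  }
  at <- categorized$category %in% c("ST", "UT")
  if (!any(at)) {
    warning("no at-threshold trials; threshold is undefined (NA)")
    return(NA_real_)
  }
  mean(categorized$duration_ms[at])
}

#' Per-participant summary of a classified session
#'
#' @param categorized A `categorized_session`.
#' @return A list with `threshold_ms`, category `counts`, `misses` and
#'   `false_alarms`, suitable for JSON serialisation.
#' @export
session_summary <- function(categorized) {
  list(
    threshold_ms = suppressWarnings(estimate_threshold(categorized)),
    counts = as.list(attr(categorized, "counts")),
    misses = attr(categorized, "misses"),
    false_alarms = attr(categorized, "false_alarms"),
    classification_mode = attr(categorized, "mode")
  )
}
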