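#' Synthetic yes/no observer
#'
#' Constructs a parametric observer for a near-threshold visual detection
#' task.  The observer answers "yes"/"no" to gratings presented for a given
#' duration according to a psychometric function anchored at a 50%-detection
#' threshold, and makes occasional errors on catch trials.
#'
#' The detection probability for a grating of duration `d` (ms) is
#' \deqn{p(yes \mid d) = \gamma + (1 - \gamma - \lambda)\,F\!\left(\frac{d - \theta}{\sigma}\right)}
#' where `theta` is `threshold_ms`, `sigma` is `slope_ms`, `gamma` the guess
#' rate, `lambda` the lapse rate, and `F` a sigmoid with `F(0) = 0.5`
#' (logistic by default, cumulative normal as an alternative).  At
#' `d = threshold_ms` the probability is the exact midpoint of the two
#' asymptotes, `(gamma + 1 - lambda) / 2`.
#'
#' @param threshold_ms Stimulus duration (ms) at which the sigmoid term
#'   reaches 0.5; must be positive.
#' @param slope_ms Psychometric spread (ms); must be positive.  Smaller
#'   values give a steeper transition from unseen to seen.
#' @param lapse_rate Probability of answering "no" to an arbitrarily strong
#'   stimulus.
#' @param guess_rate Probability of answering "yes" to a blank.
#' @param catch_miss_rate Probability of answering "no" on the full-contrast
#'   positive control.
#' @param no_response_rate Probability of giving no answer at all on any
#'   trial (applied before the psychometric draw).
#' @param family Sigmoid family: `"logistic"` (default) or `"cnorm"`
#'   (cumulative normal).
#' @return An object of class `observer`.
#' @examples
#' obs <- observer(threshold_ms = 35, slope_ms = 6)
#' p_yes(obs, c(20, 35, 60))
#' @export
observer <- function(threshold_ms, slope_ms,
                     lapse_rate = 0.02, guess_rate = 0.05,
                     catch_miss_rate = 0.01, no_response_rate = 0.01,
                     family = c("logistic", "cnorm")) {
  family <- match.arg(family)
  if (!is.numeric(threshold_ms) || length(threshold_ms) != 1L || threshold_ms <= 0) {
    stop("`threshold_ms` must be a single positive number")
  }
  if (!is.numeric(slope_ms) || length(slope_ms) != 1L || slope_ms <= 0) {
    stop("`slope_ms` must be a single positive number")
  }
  rates <- c(lapse_rate = lapse_rate, guess_rate = guess_rate,
             catch_miss_rate = catch_miss_rate,
             no_response_rate = no_response_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  }
  if (guess_rate + lapse_rate >= 1) {
    stop("`guess_rate` + `lapse_rate` must be < 1 for a rising psychometric function")
  }
  structure(
    list(threshold_ms = threshold_ms, slope_ms = slope_ms,
         lapse_rate = lapse_rate, guess_rate = guess_rate,
         catch_miss_rate = catch_miss_rate,
         no_response_rate = no_response_rate, family = family),
    class = "observer"
  )
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf(
    "<observer> threshold %.2f ms, slope %.2f ms (%s)\n  guess %.3f, lapse %.3f, catch-miss %.3f, no-response %.3f\n",
    x$threshold_ms, x$slope_ms, x$family,
    x$guess_rate, x$lapse_rate, x$catch_miss_rate, x$no_response_rate))
  invisible(x)
}

#' Detection probability of an observer
#'
#' Evaluates the observer's psychometric function at one or more stimulus
#' durations.
#'
#' @param obs An [observer()].
#' @param duration_ms Numeric vector of non-negative stimulus durations (ms).
#' @return Numeric vector of detection probabilities in `[0, 1]`.
#' @export
p_yes <- function(obs, duration_ms) {
  stopifnot(inherits(obs, "observer"))
  if (!is.numeric(duration_ms) || any(!is.finite(duration_ms))) {
    stop("`duration_ms` must be finite numeric")
  }
  if (any(duration_ms < 0)) stop("`duration_ms` must be non-negative")
  F <- switch(obs$family, logistic = stats::plogis, cnorm = stats::pnorm)
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) *
    F((duration_ms - obs$threshold_ms) / obs$slope_ms)
}

#' Draw one response from an observer
#'
#' Simulates a single trial response.  A "none" (no button press) outcome is
#' drawn first with probability `no_response_rate`; otherwise the answer is
#' "yes" with probability [p_yes()] for a staircase grating, `guess_rate`
#' for a blank negative control, and `1 - catch_miss_rate` for the
#' full-contrast positive control.
#'
#' Uses the current RNG stream; seed at the session level (see
#' [generate_session()]) for reproducibility.
#'
#' @param obs An [observer()].
#' @param kind Trial kind: `"staircase"`, `"positive_control"` or
#'   `"negative_control"`.
#' @param duration_ms Stimulus duration (ms); required for staircase trials.
#' @return One of `"yes"`, `"no"`, `"none"`.
#' @export
respond <- function(obs, kind = c("staircase", "positive_control", "negative_control"),
                    duration_ms = NULL) {
  stopifnot(inherits(obs, "observer"))
  kind <- match.arg(kind)
  if (stats::runif(1L) < obs$no_response_rate) return("none")
  p <- switch(kind,
    staircase = {
      if (is.null(duration_ms)) stop("`duration_ms` is required for staircase trials")
      p_yes(obs, duration_ms)
    },
    negative_control = obs$guess_rate,
    positive_control = 1 - obs$catch_miss_rate
  )
  if (stats::runif(1L) < p) "yes" else "no"
}

#' Read/write observer parameters as JSON
#'
#' @param obs An [observer()].
#' @param path File path.
#' @return `write_observer_json` returns `path` invisibly;
#'   `read_observer_json` returns an [observer()].
#' @export
write_observer_json <- function(obs, path) {
  stopifnot(inherits(obs, "observer"))
  jsonlite::write_json(unclass(obs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_json
#' @export
read_observer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  observer(threshold_ms = x$threshold_ms, slope_ms = x$slope_ms,
           lapse_rate = x$lapse_rate, guess_rate = x$guess_rate,
           catch_miss_rate = x$catch_miss_rate,
           no_response_rate = x$no_response_rate, family = x$family)
}
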