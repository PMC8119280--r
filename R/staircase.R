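#' Session configuration for the adaptive detection task
#'
#' Holds the timing and counting constants of one 60-trial detection
#' session: two descending staircases (24 trials each) randomly interleaved
#' with 6 blank negative controls and 6 full-contrast positive controls.
#' Stimulus durations are quantised to the display refresh period; the
#' adaptive rule steps by one refresh period (~13 ms at 75 Hz) after the
#' first response inversion and by a large opening step (70 ms, rounded to
#' whole refresh periods) before it.
#'
#' The per-trial wall clock is fixed: a cue sound starts the trial, the
#' stimulus onsets `pre_stim_ms` plus a uniform jitter in
#' `jitter_range_ms` later, the response sound plays at a constant offset
#' (the post-stimulus interval absorbs jitter and duration so that total
#' trial time is constant), and an inter-stimulus fixation interval lets
#' the hemodynamic response return to baseline.
#'
#' @param refresh_ms Display refresh period in ms.  Defaults to 1000/75
#'   (75 Hz scanner projector); set 1000/85 for an 85 Hz training monitor.
#' @param n_trials Total trials per session.
#' @param n_staircase_trials Staircase trials per session (split evenly
#'   over staircases A and B).
#' @param n_positive,n_negative Numbers of positive (always-seen, 100%
#'   contrast, 400 ms) and negative (blank) catch trials.
#' @param start_ms Initial staircase duration (ms); rounded to refresh
#'   units.
#' @param big_step_ms Opening step size (ms) used until the first response
#'   inversion; rounded to a whole number of refresh periods.
#' @param jitter_range_ms Two-element range (ms) of the uniform pre-stimulus
#'   jitter.
#' @param pre_stim_ms Fixed pre-stimulus interval (ms) before the jitter.
#' @param cue_ms,response_sound_ms Durations (ms) of the cue and response
#'   sounds.
#' @param post_stim_min_ms Minimum post-stimulus interval (ms) at maximal
#'   jitter and stimulus duration.
#' @param isi_ms Inter-stimulus fixation interval (ms).
#' @param positive_ms Positive-control stimulus duration (ms).
#' @return An object of class `session_config`.
#' @export
session_config <- function(refresh_ms = 1000 / 75,
                           n_trials = 60L, n_staircase_trials = 48L,
                           n_positive = 6L, n_negative = 6L,
                           start_ms = 400, big_step_ms = 70,
                           jitter_range_ms = c(0, 1100),
                           pre_stim_ms = 550, cue_ms = 200,
                           response_sound_ms = 200, post_stim_min_ms = 200,
                           isi_ms = 13560, positive_ms = 400) {
  if (refresh_ms <= 0) stop("`refresh_ms` must be positive")
  counts <- c(n_trials, n_staircase_trials, n_positive, n_negative)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("trial counts must be positive integers")
  }
  if (n_staircase_trials %% 2L != 0L) {
    stop("`n_staircase_trials` must be even (two staircases)")
  }
  if (n_staircase_trials + n_positive + n_negative != n_trials) {
    stop("staircase + catch trials must equal `n_trials`")
  }
  if (length(jitter_range_ms) != 2L || jitter_range_ms[1] < 0 ||
      diff(jitter_range_ms) < 0) {
    stop("`jitter_range_ms` must be an increasing non-negative range")
  }
  start_units <- as.integer(round(start_ms / refresh_ms))
  big_step_units <- max(1L, as.integer(round(big_step_ms / refresh_ms)))
  if (start_units < 1L) stop("`start_ms` is below one refresh period")
  max_stim_ms <- max(start_ms, positive_ms)
  # response sound at a constant offset so the overall trial time is fixed
  response_offset_ms <- pre_stim_ms + jitter_range_ms[2] + max_stim_ms +
    post_stim_min_ms
  trial_ms <- response_offset_ms + response_sound_ms + isi_ms
  structure(
    list(refresh_ms = refresh_ms, n_trials = as.integer(n_trials),
         n_staircase_trials = as.integer(n_staircase_trials),
         n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         start_ms = start_ms, start_units = start_units,
         big_step_ms = big_step_ms, big_step_units = big_step_units,
         jitter_range_ms = jitter_range_ms, pre_stim_ms = pre_stim_ms,
         cue_ms = cue_ms, response_sound_ms = response_sound_ms,
         post_stim_min_ms = post_stim_min_ms, isi_ms = isi_ms,
         positive_ms = positive_ms,
         response_offset_ms = response_offset_ms, trial_ms = trial_ms),
    class = "session_config"
  )
}

staircase_init <- function(id, config) {
  list(id = id, units = config$start_units, inverted = FALSE,
       emitted = 0L)
}

#' Advance one staircase after a response
#'
#' Applies the adaptive rule: before the first inversion a "yes" lowers the
#' duration by the large opening step; the first "no" marks the inversion
#' and from then on "yes"/"no" step the duration down/up by one refresh
#' period.  Durations are floored at one refresh period, and "none"
#' responses leave the state untouched.
#'
#' @param state A staircase state as produced internally by
#'   [generate_session()] (fields `id`, `units`, `inverted`, `emitted`).
#' @param response `"yes"`, `"no"` or `"none"`.
#' @param config A [session_config()].
#' @return The updated state.
#' @export
staircase_step <- function(state, response, config) {
  stopifnot(response %in% c("yes", "no", "none"))
  if (response == "none") return(state)
  if (!state$inverted) {
    if (response == "yes") {
      state$units <- state$units - config$big_step_units
    } else {
      # first reversal of the descending run: switch to refresh-unit steps
      state$inverted <- TRUE
      state$units <- state$units + 1L
    }
  } else {
    state$units <- state$units + if (response == "yes") -1L else 1L
  }
  state$units <- max(1L, state$units)
  state
}

#' Generate one full detection session
#'
#' Simulates a complete 60-trial session for one observer: catch-trial
#' positions are drawn without replacement from the session slots, the two
#' staircases are interleaved by drawing uniformly among staircases with
#' trials remaining, each trial's response is drawn from the observer, and
#' each staircase state is updated only by its own trials.  Stimulus onsets
#' on the continuous session clock are filled in via [build_timeline()].
#'
#' @param obs An [observer()].
#' @param config A [session_config()].
#' @param seed Optional integer seed; with a fixed seed and observer the
#'   full trial-by-trial log is reproducible.
#' @return A `staircase_session` data frame with one row per trial and
#'   columns `index`, `kind`, `staircase_id`, `duration_units`,
#'   `duration_ms`, `onset_s`, `jitter_ms`, `response`, `post_inversion`,
#'   `category` (filled later by [classify_trials()]).
#' @export
generate_session <- function(obs, config = session_config(), seed = NULL) {
  stopifnot(inherits(obs, "observer"), inherits(config, "session_config"))
  with_seed(seed, {
    n <- config$n_trials
    kind <- rep("staircase", n)
    catch_idx <- sample.int(n, config$n_positive + config$n_negative)
    pos_idx <- catch_idx[seq_len(config$n_positive)]
    neg_idx <- catch_idx[config$n_positive + seq_len(config$n_negative)]
    kind[pos_idx] <- "positive_control"
    kind[neg_idx] <- "negative_control"

    states <- list(A = staircase_init("A", config),
                   B = staircase_init("B", config))
    per_stair <- config$n_staircase_trials %/% 2L
    remaining <- c(A = per_stair, B = per_stair)

    staircase_id <- rep(NA_character_, n)
    duration_units <- rep(NA_integer_, n)
    duration_ms <- numeric(n)
    response <- character(n)
    post_inversion <- rep(NA, n)
    jitter_ms <- stats::runif(n, config$jitter_range_ms[1],
                              config$jitter_range_ms[2])

    for (i in seq_len(n)) {
      if (kind[i] == "staircase") {
        avail <- names(remaining)[remaining > 0L]
        id <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
        st <- states[[id]]
        staircase_id[i] <- id
        duration_units[i] <- st$units
        duration_ms[i] <- st$units * config$refresh_ms
        post_inversion[i] <- st$inverted
        response[i] <- respond(obs, "staircase", duration_ms = duration_ms[i])
        st <- staircase_step(st, response[i], config)
        st$emitted <- st$emitted + 1L
        states[[id]] <- st
        remaining[id] <- remaining[id] - 1L
      } else if (kind[i] == "positive_control") {
        duration_ms[i] <- config$positive_ms
        response[i] <- respond(obs, "positive_control")
      } else {
        duration_ms[i] <- 0
        response[i] <- respond(obs, "negative_control")
      }
    }

    session <- data.frame(
      index = seq_len(n), kind = kind, staircase_id = staircase_id,
      duration_units = duration_units, duration_ms = duration_ms,
      onset_s = NA_real_, jitter_ms = jitter_ms, response = response,
      post_inversion = post_inversion, category = NA_character_,
      stringsAsFactors = FALSE
    )
    attr(session, "config") <- config
    attr(session, "observer") <- obs
    class(session) <- c("staircase_session", "data.frame")
    tl <- build_timeline(session, config)
    session$onset_s <- tl$stim_onset_s
    session
  })
}

#' Event-related timeline of a session
#'
#' Lays the trials of a session out on a continuous clock.  Each trial
#' occupies a constant wall-clock length; the stimulus onsets
#' `pre_stim_ms + jitter` after trial start and the response sound plays at
#' a fixed offset, so the post-stimulus interval shrinks exactly as jitter
#' and stimulus duration grow.
#'
#' @param session A `staircase_session` from [generate_session()].
#' @param config A [session_config()]; defaults to the one stored on the
#'   session.
#' @return A data frame with per-trial `index`, `trial_start_s`,
#'   `cue_onset_s`, `stim_onset_s`, `response_sound_s`, `post_stim_ms`.
#' @export
build_timeline <- function(session, config = NULL) {
  if (is.null(config)) config <- attr(session, "config")
  stopifnot(inherits(config, "session_config"))
  need <- c("index", "duration_ms", "jitter_ms")
  if (!all(need %in% names(session))) {
    stop("session lacks columns: ", paste(setdiff(need, names(session)), collapse = ", "))
  }
  start_s <- (session$index - 1L) * config$trial_ms / 1000
  onset_in_trial_ms <- config$pre_stim_ms + session$jitter_ms
  post_stim_ms <- config$response_offset_ms - onset_in_trial_ms -
    session$duration_ms
  if (any(post_stim_ms < 0)) {
    stop("stimulus duration exceeds the trial's timing budget")
  }
  data.frame(
    index = session$index,
    trial_start_s = start_s,
    cue_onset_s = start_s,
    stim_onset_s = start_s + onset_in_trial_ms / 1000,
    response_sound_s = start_s + config$response_offset_ms / 1000,
    post_stim_ms = post_stim_ms
  )
}

#' Read/write session logs as CSV
#'
#' One row per trial with the fixed columns `index`, `kind`,
#' `staircase_id`, `duration_ms`, `onset_s`, `jitter_ms`, `response`,
#' `category` (plus `duration_units` and `post_inversion` when available).
#' `read_session_csv` restores refresh units from `duration_ms` when the
#' unit column is missing, so externally recorded logs can be classified.
#'
#' @param session A session data frame.
#' @param path CSV file path.
#' @param refresh_ms Refresh period used to reconstruct integer duration
#'   units on read.
#' @return `write_session_csv` returns `path` invisibly;
#'   `read_session_csv` returns a `staircase_session` data frame.
#' @export
write_session_csv <- function(session, path) {
  cols <- c("index", "kind", "staircase_id", "duration_ms", "onset_s",
            "jitter_ms", "response", "category", "duration_units",
            "post_inversion")
  out <- session[, intersect(cols, names(session)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path, refresh_ms = 1000 / 75) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"duration_units" %in% names(x)) {
    x$duration_units <- ifelse(
      x$kind == "staircase",
      as.integer(round(x$duration_ms / refresh_ms)), NA_integer_)
  }
  if (!"category" %in% names(x)) x$category <- NA_character_
  class(x) <- c("staircase_session", "data.frame")
  x
}
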