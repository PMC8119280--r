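#' Pipeline configuration
#'
#' Nested configuration for the full simulate-and-analyse pipeline.  The
#' defaults reproduce the reference cohort conditions: a 19-subject HC-like cohort
#' with true 50% thresholds drawn from N(35.08, 8.16) ms and a 15-subject
#' SCZ-like cohort from N(52.17, 20.20) ms (truncated below at one
#' refresh period), 60-trial sessions, TR 3 s acquisitions with 4 dummy
#' volumes, high-pass at 3 cycles/run, 6 mm smoothing, and cluster
#' correction at voxel p < 0.01, alpha 0.05, 1000 Monte-Carlo
#' repetitions.  The planted BOLD effects put a shared visual-region ST
#' and UT activation in both groups and a group-dependent UT effect in an
#' anterior region (engaged in the HC-like group, disengaged in the
#' SCZ-like group), the ground truth the ROI decomposition is meant to
#' recover.
#'
#' @param n_hc,n_scz Group sizes.
#' @param bold_dim Simulation grid.
#' @param n_iter Monte-Carlo repetitions for the cluster threshold.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param ... Reserved.
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(n_hc = 19L, n_scz = 15L,
                            bold_dim = c(24L, 24L, 18L),
                            n_iter = 1000L, seed = 20200819L, ...) {
  cfg <- list(
    cohort = list(
      groups = list(
        HC = list(n = as.integer(n_hc), threshold_mean_ms = 35.08,
                  threshold_sd_ms = 8.16, slope_ms = 6),
        SCZ = list(n = as.integer(n_scz), threshold_mean_ms = 52.17,
                   threshold_sd_ms = 20.20, slope_ms = 6)
      ),
      lapse_rate = 0.02, guess_rate = 0.05,
      catch_miss_rate = 0.01, no_response_rate = 0.01
    ),
    session = session_config(),
    bold = list(
      dim = as.integer(bold_dim),
      voxel_mm = c(3.75, 3.75, 4),
      tr_s = 3, n_volumes = NULL,   # NULL: sized from the session timeline
      n_dummy = 4L, highpass_cycles = 3, fwhm_mm = 6,
      baseline = 100,
      noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 0.5),
      effects = list(
        list(box = list(x = c(4, 9), y = c(14, 19), z = c(3, 6)),
             condition = "ST", amplitude = 1.2, group = "both"),
        list(box = list(x = c(4, 9), y = c(14, 19), z = c(3, 6)),
             condition = "UT", amplitude = 0.8, group = "both"),
        list(box = list(x = c(15, 19), y = c(4, 8), z = c(11, 14)),
             condition = "UT", amplitude = 0.7, group = "HC"),
        list(box = list(x = c(15, 19), y = c(4, 8), z = c(11, 14)),
             condition = "UT", amplitude = -0.9, group = "SCZ")
      )
    ),
    stats = list(voxel_p = 0.01, alpha = 0.05, n_iter = as.integer(n_iter),
                 connectivity = 26L, df_mode = "anova_pooled"),
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  for (g in names(config$cohort$groups)) {
    gr <- config$cohort$groups[[g]]
    if (gr$n < 2L) stop("group ", g, " needs at least 2 subjects")
    if (gr$threshold_mean_ms <= 0 || gr$threshold_sd_ms < 0) {
      stop("invalid threshold distribution for group ", g)
    }
  }
  st <- config$stats
  if (st$n_iter < 1L) stop("stats$n_iter must be at least 1")
  if (st$voxel_p <= 0 || st$voxel_p >= 1) stop("stats$voxel_p must be in (0,1)")
  if (st$alpha <= 0 || st$alpha > 1) stop("stats$alpha must be in (0,1]")
  if (!st$connectivity %in% c(6L, 18L, 26L)) stop("bad connectivity")
  invisible(TRUE)
}

#' Simulate a two-group cohort of detection sessions
#'
#' Draws each subject's true 50% threshold from the group distribution
#' (normal, truncated below at one refresh period), builds the observer,
#' and generates one full session per subject.
#'
#' @param config A [pipeline_config()] (only the `cohort` and `session`
#'   blocks are used) — or a cohort block directly.
#' @param seed Integer seed.
#' @return A list with `sessions` (list of `staircase_session`),
#'   `observers`, `groups` (character vector), `true_threshold_ms`.
#' @export
simulate_cohort <- function(config = pipeline_config(), seed = NULL) {
  cohort <- if (inherits(config, "pipeline_config")) config$cohort else config
  session_cfg <- if (inherits(config, "pipeline_config")) config$session else session_config()
  with_seed(seed, {
    sessions <- list(); observers <- list()
    groups <- character(0); truth <- numeric(0)
    for (g in names(cohort$groups)) {
      gr <- cohort$groups[[g]]
      for (i in seq_len(gr$n)) {
        thr <- -Inf
        while (thr < session_cfg$refresh_ms) {
          thr <- stats::rnorm(1L, gr$threshold_mean_ms, gr$threshold_sd_ms)
        }
        obs <- observer(threshold_ms = thr, slope_ms = gr$slope_ms,
                        lapse_rate = cohort$lapse_rate,
                        guess_rate = cohort$guess_rate,
                        catch_miss_rate = cohort$catch_miss_rate,
                        no_response_rate = cohort$no_response_rate)
        sessions[[length(sessions) + 1L]] <- generate_session(obs, session_cfg)
        observers[[length(observers) + 1L]] <- obs
        groups <- c(groups, g)
        truth <- c(truth, thr)
      }
    }
    list(sessions = sessions, observers = observers, groups = groups,
         true_threshold_ms = truth)
  })
}

resolve_effects <- function(effect_cfgs) {
  lapply(effect_cfgs, function(e) {
    b <- e$box
    coords <- as.matrix(expand.grid(x = b$x[1]:b$x[2], y = b$y[1]:b$y[2],
                                    z = b$z[1]:b$z[2]))
    effect_spec(coords, condition = e$condition, amplitude = e$amplitude,
                group = e$group %||% "both")
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order — simulate cohort, classify and estimate
#' thresholds, group behavioral statistics, simulate and preprocess BOLD,
#' first-level GLMs, group RFX maps, mixed ANOVA with post-hoc maps,
#' Monte-Carlo cluster threshold, ROI analysis — and writes the
#' per-stage artifacts (CSV, JSON, NIfTI) plus a consolidated
#' `report.json` and a `run_log.yaml` recording seeds and the full
#' configuration.  Subjects without a defined threshold are excluded from
#' the group threshold test; subjects missing a trial category are
#' excluded from the imaging group stages; both exclusions are logged.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`.
#' @return The report, invisibly (a nested list mirroring
#'   `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         seed = config$seed) {
  validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("stairbold %s", as.character(utils::packageVersion("stairbold"))),
                 sprintf("master seed: %d", seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## ---- cohort ----
  cohort_seed <- stage_seed(seed, "cohort")
  note("stage cohort: seed %d", cohort_seed)
  cohort <- simulate_cohort(config, seed = cohort_seed)
  nsub <- length(cohort$sessions)

  ## ---- classify ----
  classified <- lapply(cohort$sessions, classify_trials)
  thresholds <- vapply(classified, function(s)
    suppressWarnings(estimate_threshold(s)), numeric(1))
  summaries <- lapply(classified, session_summary)
  all_trials <- do.call(rbind, lapply(seq_len(nsub), function(i) {
    s <- as.data.frame(classified[[i]])
    s$subject <- i; s$group <- cohort$groups[i]
    s
  }))
  utils::write.csv(all_trials, file.path(output_dir, "sessions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(subject = seq_len(nsub), group = cohort$groups,
         true_threshold_ms = cohort$true_threshold_ms,
         estimated_threshold_ms = thresholds,
         summaries = summaries),
    file.path(output_dir, "participants.json"), auto_unbox = TRUE,
    digits = NA, na = "null")

  ## ---- behavior ----
  ok <- is.finite(thresholds)
  if (any(!ok)) note("%d subject(s) without a defined threshold excluded from the group test",
                     sum(!ok))
  g <- cohort$groups
  tt <- pooled_t(thresholds[ok & g == "SCZ"], thresholds[ok & g == "HC"])
  catches <- catch_summary(classified, g)
  st_counts <- vapply(classified, function(s) attr(s, "counts")[["ST"]], numeric(1))
  ut_counts <- vapply(classified, function(s) attr(s, "counts")[["UT"]], numeric(1))
  behavior <- list(
    threshold_t = list(t = tt$t, df = tt$df, p = tt$p),
    group_thresholds = lapply(split(thresholds[ok], g[ok]), function(x)
      list(n = length(x), mean = mean(x), sd = stats::sd(x))),
    st_ut_counts = lapply(split(seq_len(nsub), g), function(i)
      list(ST_mean = mean(st_counts[i]), UT_mean = mean(ut_counts[i]))),
    catch_trials = catches
  )
  jsonlite::write_json(behavior, file.path(output_dir, "behavior.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  ## ---- bold simulation + first-level GLM ----
  bold_cfg <- config$bold
  session_end_s <- config$session$trial_ms * config$session$n_trials / 1000
  n_task_vols <- bold_cfg$n_volumes %||%
    (as.integer(ceiling((session_end_s + 20) / bold_cfg$tr_s)) + bold_cfg$n_dummy)
  geometry <- bold_geometry(dim = bold_cfg$dim, voxel_mm = bold_cfg$voxel_mm,
                            tr_s = bold_cfg$tr_s, n_volumes = n_task_vols)
  effects <- resolve_effects(bold_cfg$effects)
  note("bold geometry: %s, %d volumes (incl. %d dummies)",
       paste(geometry$dim, collapse = "x"), n_task_vols, bold_cfg$n_dummy)

  dummy_offset_s <- bold_cfg$n_dummy * bold_cfg$tr_s
  fits <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    tl <- data.frame(onset_s = classified[[i]]$onset_s + dummy_offset_s,
                     category = classified[[i]]$category)
    series <- simulate_bold(tl, effects = effects, geometry = geometry,
                            noise = bold_cfg$noise, baseline = bold_cfg$baseline,
                            group = g[i],
                            seed = stage_seed(seed, paste0("bold_subject_", i)))
    series <- preprocess_bold(series, n_dummy = bold_cfg$n_dummy,
                              highpass_cycles = bold_cfg$highpass_cycles,
                              fwhm_mm = bold_cfg$fwhm_mm)
    design <- build_design(classified[[i]]$onset_s, classified[[i]]$category,
                           tr_s = bold_cfg$tr_s,
                           n_volumes = series$geometry$n_volumes)
    fits[[i]] <- fit_glm(series, design)
  }

  complete <- vapply(fits, function(f) length(f$empty) == 0L, logical(1))
  if (any(!complete)) {
    note("%d subject(s) missing a trial category excluded from group imaging stages",
         sum(!complete))
  }
  fits_c <- fits[complete]; g_c <- g[complete]

  ## ---- group maps ----
  w_st_ut <- c(ST = 1, UT = -1)
  maps <- list()
  for (grp in c("HC", "SCZ")) {
    sel <- fits_c[g_c == grp]
    maps[[paste0(grp, "_ST")]] <- rfx_contrast(sel, c(ST = 1), paste0("[ST] ", grp))
    maps[[paste0(grp, "_UT")]] <- rfx_contrast(sel, c(UT = 1), paste0("[UT] ", grp))
    maps[[paste0(grp, "_ST_minus_UT")]] <- rfx_contrast(sel, w_st_ut,
                                                        paste0("[ST-UT] ", grp))
  }
  maps[["ALL_ST_minus_UT"]] <- rfx_contrast(fits_c, w_st_ut, "[ST-UT] all")
  anova_maps <- mixed_anova(fits_c, g_c)
  posthoc <- list(
    ST = posthoc_group_map(fits_c, g_c, weights = c(ST = 1),
                           df_mode = config$stats$df_mode, contrast = "[ST] HC-SCZ"),
    UT = posthoc_group_map(fits_c, g_c, weights = c(UT = 1),
                           df_mode = config$stats$df_mode, contrast = "[UT] HC-SCZ"),
    ST_minus_UT = posthoc_group_map(fits_c, g_c, weights = w_st_ut,
                                    df_mode = config$stats$df_mode,
                                    contrast = "[ST-UT] HC-SCZ")
  )
  map_dir <- file.path(output_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  for (nm in names(maps)) {
    write_volume(maps[[nm]], file.path(map_dir, paste0(nm, ".nii.gz")))
    jsonlite::write_json(list(kind = maps[[nm]]$kind, df = maps[[nm]]$df,
                              contrast = maps[[nm]]$contrast),
                         file.path(map_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- cluster threshold ----
  mc_seed <- stage_seed(seed, "clustermc")
  note("stage clustermc: seed %d", mc_seed)
  rule <- cluster_rule(voxel_p = config$stats$voxel_p,
                       alpha = config$stats$alpha,
                       n_iter = config$stats$n_iter,
                       connectivity = config$stats$connectivity,
                       fwhm_mm = bold_cfg$fwhm_mm)
  rule <- estimate_min_cluster(geometry, rule, seed = mc_seed)
  jsonlite::write_json(
    list(min_cluster_size = rule$min_cluster_size,
         alpha_achieved = rule$alpha_achieved, n_iter = rule$n_iter,
         voxel_p = rule$voxel_p, alpha = rule$alpha,
         connectivity = rule$connectivity, fwhm_mm = rule$fwhm_mm,
         seed = mc_seed),
    file.path(output_dir, "cluster_rule.json"), auto_unbox = TRUE, digits = NA)

  ## ---- ROI analysis ----
  rois <- define_rois(maps[["ALL_ST_minus_UT"]], rule)
  roi_table <- roi_group_test(rois, fits_c, g_c, weights = w_st_ut)
  roi_decomp <- if (length(rois) > 0) {
    roi_condition_tests(rois, fits_c, g_c, conditions = c("ST", "UT"))
  } else data.frame()
  utils::write.csv(roi_table, file.path(output_dir, "roi_table.csv"),
                   row.names = FALSE)
  utils::write.csv(roi_decomp, file.path(output_dir, "roi_condition_tests.csv"),
                   row.names = FALSE)

  ## ---- report ----
  report <- list(
    n_subjects = nsub,
    behavior = behavior,
    anova_df = list(between = anova_maps$F_between$df,
                    within = anova_maps$F_within$df,
                    interaction = anova_maps$F_interaction$df),
    cluster_rule = list(min_cluster_size = rule$min_cluster_size,
                        alpha_achieved = rule$alpha_achieved),
    n_rois = length(rois),
    roi_table = roi_table,
    roi_condition_tests = roi_decomp,
    seeds = list(master = seed, cohort = cohort_seed, clustermc = mc_seed)
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(list(log = log_lines, config = rapply(
    unclass(config), function(x) x, how = "replace")),
    file.path(output_dir, "run_log.yaml"))
  invisible(report)
}
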