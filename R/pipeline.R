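#' Run the full analysis pipeline on a session
#'
#' Executes, in order: running-trace smoothing and trial state labelling
#' (with the session-inclusion rule), CSD sink localization and laminar
#' depth assignment (when an LFP block is present), waveform cell-class
#' assignment, per-unit response summaries, the modulation-index /
#' additivity analysis (skipped with a note when the session has too few
#' running trials), the matched sitting-trial subsampling, the
#' distance-correlation sweep, and layer-group statistics on the running
#' effect. Every stage's parameters are echoed into the report so each
#' number is recomputable.
#'
#' @param s An `ephys_session` or a session directory path.
#' @param config Named list overriding defaults: `threshold_fraction`,
#'   `min_running_trials`, `csd_band`, `sink_window_s`, `sink_k_sd`,
#'   `width_threshold_ms`, `alpha_sig`, `min_trials_mi`,
#'   `subsample_repeats`, `dcor_ladder`, `dcor_shuffles`, `seed`.
#' @param out Optional path; when given, the report is written there as JSON
#'   (identical config + seed gives byte-identical output).
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(s, config = list(), out = NULL) {
  if (is.character(s)) s <- read_session(s)
  cfg <- utils::modifyList(list(
    threshold_fraction = 0.05, min_running_trials = 7,
    csd_band = c(1, 300), sink_window_s = c(0, 0.05), sink_k_sd = 3,
    width_threshold_ms = 0.5, alpha_sig = 0.01, min_trials_mi = 7,
    subsample_repeats = 100, dcor_ladder = bin_ladder(0.05, 12.8),
    dcor_shuffles = 50, seed = 1
  ), config)
  report <- list(session_id = s$session_id, config = cfg, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. behavioral state
  lab <- stage("classify-trials", {
    sm <- smooth_running(s$running)
    label_trials(s$trials, sm, cfg$threshold_fraction, cfg$min_running_trials)
  })
  s$trials <- lab$trials
  report$stages$behavior <- list(
    max_speed_cmps = lab$max_speed, n_running = lab$n_running,
    n_sitting = lab$n_sitting, included = lab$included)

  # 2. laminar assignment
  if (!is.null(s$lfp)) {
    sink <- stage("csd", {
      prof <- compute_csd(s$lfp, band = cfg$csd_band)
      locate_sink(prof, s$trials, window_s = cfg$sink_window_s,
                  k_sd = cfg$sink_k_sd)
    })
    s$units <- assign_depths(s$units, sink, spacing_um = s$lfp$spacing_um)
    report$stages$laminar <- list(
      sink_detected = sink$detected, sink_channel = sink$sink_channel,
      sink_latency_s = sink$sink_latency_s)
  } else {
    report$stages$laminar <- list(sink_detected = FALSE,
                                  note = "no LFP block; laminar analysis skipped")
  }

  # 3. cell classes
  s <- stage("classify-cells", classify_cells(s, cfg$width_threshold_ms))
  classes <- vapply(s$units, `[[`, "", "cell_class")
  report$stages$cell_class <- as.list(table(classes))

  # 4. responses + modulation
  resp <- stage("responses", response_summary(s, alpha = cfg$alpha_sig,
                                              min_trials = 2))
  report$stages$responses <- list(
    n_sig_increase = sum(resp$sig_increase[resp$state == "sitting" &
                                             resp$laser == "off"], na.rm = TRUE))
  mods <- stage("modulation", modulation_set(s, min_trials = cfg$min_trials_mi,
                                             alpha = cfg$alpha_sig))
  report$stages$modulation <- list(
    n_units = nrow(mods),
    mean_mi_sit_off = mean(mods$mi_sit_off, na.rm = TRUE),
    mean_mi_run_off = mean(mods$mi_run_off, na.rm = TRUE))
  if (lab$included && nrow(mods) >= 3 &&
      sum(stats::complete.cases(mods[, c("predicted_combined",
                                         "observed_combined")])) >= 3) {
    add <- stage("additivity", additivity_test(mods))
    report$stages$additivity <- unclass(add)[c("rho", "p", "slope",
                                               "intercept", "r2", "n",
                                               "mean_diff", "se_diff")]
    sub <- stage("subsample", matched_subsample_mi(
      s, n_repeats = cfg$subsample_repeats, seed = cfg$seed))
    report$stages$subsample <- list(
      mean_mi = sub$mean_mi, range_mi = sub$range_mi, mean_p = sub$mean_p,
      running_mean_mi = sub$running_mean_mi, n_running = sub$n_running)
  } else {
    report$stages$additivity <- list(
      skipped = TRUE,
      reason = if (!lab$included) "fewer running trials than the inclusion floor"
      else "too few units with defined combined effects")
  }

  # 5. population timescale
  report$stages$dcor <- stage("dcor", {
    sw <- dcor_sweep(s$units, s$running, duration_s = s$duration_s,
                     ladder = cfg$dcor_ladder, n_shuffles = cfg$dcor_shuffles,
                     seed = cfg$seed)
    ok <- !is.na(sw$dcor_corrected)
    list(sweep = as.data.frame(sw),
         peak_bin_s = if (any(ok)) sw$bin_s[ok][which.max(sw$dcor_corrected[ok])]
         else NA_real_)
  })

  # 6. layer-group statistics on the running effect
  if (lab$included && nrow(mods) > 0 &&
      length(unique(mods$layer[mods$layer != "unassigned"])) >= 2) {
    by_layer <- split(mods$running_effect, mods$layer)
    by_layer <- lapply(by_layer, function(v) v[!is.na(v)])
    report$stages$layer_stats <- stage("layer-stats", tryCatch({
      g <- layer_group_test(by_layer)
      list(chisq = g$statistic, df = g$df, p = g$p, n = g$n_cases,
           post_hoc = g$post_hoc)
    }, error = function(e) list(skipped = TRUE, reason = conditionMessage(e))))
  } else {
    report$stages$layer_stats <- list(skipped = TRUE,
                                      reason = "no laminar assignment or session excluded")
  }

  class(report) <- "pipeline_report"
  if (!is.null(out)) {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null", force = TRUE)
    writeLines(json, out, useBytes = TRUE)
  }
  report
}
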