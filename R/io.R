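# Native on-disk layout: a directory of delimited text files plus meta.json.
#   trials.tsv    onset_s stim laser duration_s mean_speed state
#   units.tsv     unit_id peak_channel depth_um layer cell_class waveform_rate_hz
#   spikes.tsv    unit_id spike_time_s
#   waveforms.tsv unit_id channel s0001 ... (one row per unit x channel)
#   running.tsv / pupil.tsv   t_s value
#   lfp.tsv       samples x channels matrix (header ch0001 ...)
#   meta.json     session id, duration, acquisition schedule, LFP attributes
# Numbers are written with %.17g so doubles round-trip exactly and a
# write/read/write cycle is byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_chr <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(NULL)
}

read_tsv_chr <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Write a session to a directory in the native tabular format
#'
#' All tables are tab-delimited text with header rows; the LFP matrix is a
#' TSV of samples x channels with its sampling rate, spacing and filter band
#' recorded in `meta.json`. Writing the result of [read_session()] again
#' produces byte-identical files.
#'
#' @param s An `ephys_session`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(s, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path)) stop("cannot create session directory: ", path)

  write_tsv_chr(as.data.frame(s$trials), file.path(path, "trials.tsv"))

  units_df <- data.frame(
    unit_id = vapply(s$units, `[[`, "", "unit_id"),
    peak_channel = vapply(s$units, function(u) as.integer(u$peak_channel), 0L),
    depth_um = vapply(s$units, function(u) as.numeric(u$depth_um), 0),
    layer = vapply(s$units, `[[`, "", "layer"),
    cell_class = vapply(s$units, `[[`, "", "cell_class"),
    waveform_rate_hz = vapply(s$units, function(u) as.numeric(u$waveform_rate_hz), 0),
    stringsAsFactors = FALSE
  )
  if (!length(s$units)) {
    units_df <- data.frame(unit_id = character(), peak_channel = integer(),
                           depth_um = numeric(), layer = character(),
                           cell_class = character(), waveform_rate_hz = numeric(),
                           stringsAsFactors = FALSE)
  }
  write_tsv_chr(units_df, file.path(path, "units.tsv"))

  spk <- data.frame(
    unit_id = rep(units_df$unit_id,
                  vapply(s$units, function(u) length(u$spike_times), 0L)),
    spike_time_s = unlist(lapply(s$units, `[[`, "spike_times"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!length(s$units)) spk <- data.frame(unit_id = character(), spike_time_s = numeric())
  write_tsv_chr(spk, file.path(path, "spikes.tsv"))

  wf_rows <- list()
  for (u in s$units) {
    if (is.null(u$waveforms)) next
    w <- u$waveforms
    df <- data.frame(unit_id = rep(u$unit_id, nrow(w)), channel = seq_len(nrow(w)),
                     stringsAsFactors = FALSE)
    samp <- as.data.frame(w)
    names(samp) <- sprintf("s%04d", seq_len(ncol(w)))
    wf_rows[[length(wf_rows) + 1L]] <- cbind(df, samp)
  }
  if (length(wf_rows)) {
    write_tsv_chr(do.call(rbind, wf_rows), file.path(path, "waveforms.tsv"))
  }

  write_tsv_chr(data.frame(t_s = s$running$t, value = s$running$v),
                file.path(path, "running.tsv"))
  if (!is.null(s$pupil)) {
    write_tsv_chr(data.frame(t_s = s$pupil$t, value = s$pupil$v),
                  file.path(path, "pupil.tsv"))
  }
  if (!is.null(s$lfp)) {
    lfp_df <- as.data.frame(t(s$lfp$data))
    names(lfp_df) <- sprintf("ch%04d", seq_len(nrow(s$lfp$data)))
    write_tsv_chr(lfp_df, file.path(path, "lfp.tsv"))
  }

  meta <- list(
    session_id = s$session_id,
    duration_s = s$duration_s,
    running_rate_hz = s$running$rate_hz,
    pupil_rate_hz = if (is.null(s$pupil)) NULL else s$pupil$rate_hz,
    acquisition = unclass(s$meta),
    lfp = if (is.null(s$lfp)) NULL else list(
      spacing_um = s$lfp$spacing_um, rate_hz = s$lfp$rate_hz,
      filtered_band = s$lfp$filtered_band
    )
  )
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, file.path(path, "meta.json"), useBytes = TRUE)
  invisible(path)
}

#' Read a session from a directory in the native tabular format
#'
#' @param path Session directory produced by [write_session()].
#' @param validate Run [validate_session()] and error on violations.
#' @return An `ephys_session`.
#' @export
read_session <- function(path, validate = TRUE) {
  need <- function(fname, what) {
    fp <- file.path(path, fname)
    if (!file.exists(fp)) {
      stop("session load error: missing ", what, " file '", fname, "' in ", path)
    }
    fp
  }
  meta_raw <- jsonlite::fromJSON(need("meta.json", "meta"))
  trials_df <- read_tsv_chr(need("trials.tsv", "trials"))
  units_df <- read_tsv_chr(need("units.tsv", "units"))
  spikes_df <- read_tsv_chr(need("spikes.tsv", "spikes"))

  acq <- meta_raw$acquisition
  meta <- acquisition_meta(stim_dur_s = acq$stim_dur_s, isi_s = acq$isi_s,
                           laser_pre_s = acq$laser_pre_s,
                           laser_post_s = acq$laser_post_s,
                           min_reps_per_combo = acq$min_reps_per_combo)

  wf_path <- file.path(path, "waveforms.tsv")
  wf_by_unit <- list()
  if (file.exists(wf_path)) {
    wf_df <- read_tsv_chr(wf_path)
    scols <- grep("^s\\d+$", names(wf_df))
    for (uid in unique(wf_df$unit_id)) {
      sub <- wf_df[wf_df$unit_id == uid, , drop = FALSE]
      sub <- sub[order(sub$channel), , drop = FALSE]
      wf_by_unit[[uid]] <- as.matrix(sub[, scols, drop = FALSE])
    }
  }

  units <- lapply(seq_len(nrow(units_df)), function(i) {
    uid <- units_df$unit_id[i]
    st <- spikes_df$spike_time_s[spikes_df$unit_id == uid]
    w <- wf_by_unit[[uid]]
    if (!is.null(w)) dimnames(w) <- NULL
    unit(uid, sort(st), waveforms = w,
         waveform_rate_hz = units_df$waveform_rate_hz[i],
         peak_channel = as.integer(units_df$peak_channel[i]),
         depth_um = as.numeric(units_df$depth_um[i]),
         layer = units_df$layer[i],
         cell_class = units_df$cell_class[i])
  })

  run_df <- read_tsv_chr(need("running.tsv", "running"))
  running <- behavior_trace(run_df$t_s, run_df$value, meta_raw$running_rate_hz)

  pupil <- NULL
  if (file.exists(file.path(path, "pupil.tsv"))) {
    pup_df <- read_tsv_chr(file.path(path, "pupil.tsv"))
    pupil <- behavior_trace(pup_df$t_s, pup_df$value, meta_raw$pupil_rate_hz)
  }

  lfp <- NULL
  if (file.exists(file.path(path, "lfp.tsv"))) {
    lfp_df <- read_tsv_chr(file.path(path, "lfp.tsv"))
    band <- meta_raw$lfp$filtered_band
    lfp <- lfp_block(t(as.matrix(lfp_df)), spacing_um = meta_raw$lfp$spacing_um,
                     rate_hz = meta_raw$lfp$rate_hz,
                     filtered_band = if (is.null(band)) NULL else as.numeric(band))
    dimnames(lfp$data) <- NULL
  }

  tt <- trial_table(trials_df$onset_s, trials_df$stim, trials_df$laser,
                    trials_df$duration_s)
  tt$mean_speed <- as.numeric(trials_df$mean_speed)
  tt$state <- trials_df$state

  s <- session(meta_raw$session_id, units, tt, running, pupil = pupil,
               lfp = lfp, meta = meta, duration_s = meta_raw$duration_s)
  if (validate) {
    viol <- validate_session(s)
    if (length(viol)) {
      stop("session validation error:\n  ", paste(viol, collapse = "\n  "))
    }
  }
  s
}
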