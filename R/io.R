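# Session serialization (flat binary + sidecar / CSV) and the pipeline
# driver.
#
# On-disk layout of a session directory:
#   lfp.bin          float32 little-endian samples
#   lfp.json         {fs, n_samples, units}
#   spikes.csv       unit_id, spike_time_s
#   waveforms.csv    unit_id, sample_index, amplitude  (+ fs in lfp.json)
#   trials.csv       onset_s, force_g, withdrawal, latency_s
#   ground_truth.json  generating configuration (simulated sessions only)

#' Write a recording session to a directory
#'
#' @param session A `recording_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lfp <- as.numeric(session$lfp)
  con <- file(file.path(dir, "lfp.bin"), "wb")
  writeBin(lfp, con, size = 4, endian = "little")
  close(con)
  fs_wave <- if (length(session$units)) session$units[[1]]$fs_wave else NA
  jsonlite::write_json(
    list(fs = attr(session$lfp, "fs"), n_samples = length(lfp),
         units = "volts", fs_wave = fs_wave, condition = session$condition,
         duration_s = session$duration),
    file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)
  spikes <- do.call(rbind, lapply(seq_along(session$units), function(j)
    if (length(session$units[[j]]$spike_times))
      data.frame(unit_id = j, spike_time_s = session$units[[j]]$spike_times)))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = integer(0), spike_time_s = numeric(0))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  waves <- do.call(rbind, lapply(seq_along(session$units), function(j) {
    w <- as.numeric(session$units[[j]]$waveform)
    data.frame(unit_id = j, sample_index = seq_along(w) - 1, amplitude = w)
  }))
  if (is.null(waves))
    waves <- data.frame(unit_id = integer(0), sample_index = integer(0),
                        amplitude = numeric(0))
  utils::write.csv(waves, file.path(dir, "waveforms.csv"), row.names = FALSE)
  utils::write.csv(
    session$trials[, c("onset_s", "force_g", "withdrawal", "latency_s")],
    file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(session$ground_truth)) {
    gt <- unclass(session$ground_truth)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Load a recording session from a directory
#'
#' Validates the sidecar against the binary length, spike-time ordering and
#' trial-window coverage; trials whose analysis window extends past the
#' trace are flagged (`in_range = FALSE`) with a warning.
#'
#' @param dir Session directory written by [write_session()] (or compatible).
#' @return A `recording_session`.
#' @export
load_session <- function(dir) {
  need <- c("lfp.bin", "lfp.json", "spikes.csv", "waveforms.csv", "trials.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    pe_stop("missing_file", "missing session file(s): %s",
            paste(missing, collapse = ", "))
  side <- jsonlite::read_json(file.path(dir, "lfp.json"), simplifyVector = TRUE)
  if (is.null(side$fs) || side$fs <= 0)
    pe_stop("badsidecar", "sidecar sampling rate must be > 0")
  sz <- file.size(file.path(dir, "lfp.bin"))
  if (sz != 4 * side$n_samples)
    pe_stop("length_mismatch",
            "lfp.bin length mismatch: sidecar says %d samples, file holds %g",
            side$n_samples, sz / 4)
  con <- file(file.path(dir, "lfp.bin"), "rb")
  lfp <- readBin(con, numeric(), n = side$n_samples, size = 4,
                 endian = "little")
  close(con)
  attr(lfp, "fs") <- side$fs
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  waves <- utils::read.csv(file.path(dir, "waveforms.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  duration <- side$duration_s %||% (side$n_samples / side$fs)
  unit_ids <- sort(unique(c(spikes$unit_id, waves$unit_id)))
  units <- lapply(unit_ids, function(j) {
    st <- spikes$spike_time_s[spikes$unit_id == j]
    if (is.unsorted(st))
      pe_stop("unsorted", "spike times of unit %s are not sorted", j)
    if (length(st) && (min(st) < 0 || max(st) > duration))
      pe_stop("badspikes", "unit %s has spike times outside [0, duration]", j)
    wv <- waves[waves$unit_id == j, ]
    list(spike_times = st,
         waveform = wv$amplitude[order(wv$sample_index)],
         fs_wave = side$fs_wave %||% side$fs)
  })
  if (is.unsorted(trials$onset_s))
    pe_stop("badtrials", "trial onsets must be ascending")
  trials$in_range <- TRUE
  bad <- trials$onset_s < 0 | trials$onset_s > duration
  if (any(bad)) {
    pe_warn("%d trial onset(s) beyond the trace; flagged out of range", sum(bad))
    trials$in_range[bad] <- FALSE
  }
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  structure(list(lfp = lfp, units = units, trials = trials,
                 condition = side$condition %||% "unknown",
                 duration = duration, ground_truth = gt),
            class = "recording_session")
}

#' Run the full analysis pipeline on a session directory
#'
#' simulate/ingest -> preprocess -> event-locked spectrogram -> band
#' summaries and time courses -> unit responses -> unit classes -> behavior
#' summary. Writes tidy CSV tables plus a machine-readable JSON summary, all
#' stamped with the package version, the configuration hash and the seed.
#'
#' @param session_dir Directory holding a session (see [load_session()]);
#'   alternatively a `recording_session` object.
#' @param out_dir Output directory.
#' @param params,pre_params,psth Analysis parameter objects.
#' @param seed Seed recorded in the outputs (clustering restarts use it).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(session_dir, out_dir,
                         params = spectrogram_params(),
                         pre_params = preprocess_params(),
                         psth = psth_params(), seed = 1L) {
  session <- if (inherits(session_dir, "recording_session")) session_dir
             else load_session(session_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      pe_stop("stage_failure", "stage '%s' failed: %s", name,
              conditionMessage(e)))
  }
  nspec <- stage("spectrogram",
                 session_normalized_spectrogram(session, params, pre_params))
  bands <- band_table()$band
  band_sum <- data.frame(band = bands,
                         pct_change = vapply(bands, function(b)
                           band_power_change(nspec, b), numeric(1)))
  tc <- do.call(rbind, lapply(bands, function(b) {
    d <- band_timecourse(nspec, b,
                         withdrawal_times = nspec$withdrawal_latencies)
    cbind(band = b, d)
  }))
  responses <- stage("units", session_unit_responses(session, psth))
  resp_tab <- do.call(rbind, lapply(responses, function(r)
    data.frame(unit_id = r$unit_id, label = r$label,
               z_max = r$z_max, z_min = r$z_min, included = r$included,
               mixed = r$mixed)))
  feats <- stage("waveforms", session_waveform_features(session))
  classes <- if (sum(!feats$unclassifiable) >= 2)
    stage("classify", cluster_unit_types(feats, mode = "final", seed = seed))
  else rep(NA_integer_, nrow(feats))
  class_tab <- data.frame(unit_id = feats$unit_id, class = classes)
  curve <- stage("behavior", response_curve(session$trials))
  # tidy normalized spectrogram (100-ms bins to keep the file small)
  nspec_tidy <- do.call(rbind, lapply(bands, function(b) {
    d <- band_timecourse(nspec, b)
    data.frame(band = b, time_s = d$bin_center, pct_change = d$pct)
  }))
  utils::write.csv(band_sum, file.path(out_dir, "band_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(tc, file.path(out_dir, "timecourse.csv"), row.names = FALSE)
  utils::write.csv(nspec_tidy, file.path(out_dir, "nspec_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(resp_tab, file.path(out_dir, "unit_responses.csv"),
                   row.names = FALSE)
  utils::write.csv(feats, file.path(out_dir, "unit_features.csv"),
                   row.names = FALSE)
  utils::write.csv(class_tab, file.path(out_dir, "unit_classes.csv"),
                   row.names = FALSE)
  utils::write.csv(curve, file.path(out_dir, "curves.csv"), row.names = FALSE)
  cfg <- list(params = unclass(params), pre_params = unclass(pre_params),
              psth = unclass(psth), seed = seed)
  cfg_file <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  summary <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("painephys")),
      error = function(e) "unknown"),
    config_hash = unname(tools::md5sum(cfg_file)), seed = seed,
    condition = session$condition,
    n_trials = nrow(session$trials),
    n_withdrawal = sum(session$trials$withdrawal),
    band_change = stats::setNames(band_sum$pct_change, band_sum$band),
    unit_labels = table(resp_tab$label),
    n_class1 = sum(classes == 1, na.rm = TRUE),
    n_class2 = sum(classes == 2, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}
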