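# End-to-end composition: track -> filter -> detect -> classify, batch
# execution over a manifest, and the synthetic benchmark dataset.

#' Process one frame stack through the full detection chain
#'
#' Tracks frame-to-frame displacement, integrates to the cumulative
#' position, isolates the respiratory band of the horizontal component,
#' detects breath peaks and classifies the recording.
#'
#' @param stack A [frame_stack()].
#' @param filter A [filter_spec()]; its `fs` is overridden by the stack's
#'   acquisition rate.
#' @param detection A [detection_config()].
#' @param n_background Frames used for the background reference.
#' @return List with `trace`, `position`, `signal`, `peaks`, `bpm` (NA with
#'   fewer than two peaks) and `classification`.
#' @export
process_recording <- function(stack, filter = filter_spec(),
                              detection = detection_config(),
                              n_background = 50) {
  stopifnot(inherits(stack, "frame_stack"))
  spec <- filter_spec(filter$order, filter$ripple, filter$band,
                      fs = stack$fs, pad = filter$pad)
  trace <- track(stack, n_background = n_background)
  position <- cumulative_position(trace)
  signal <- zero_phase_filter(position$x, spec = spec)
  peaks <- detect_breath_peaks(signal)
  bpm <- if (length(peaks$indices) >= 2) breathing_rate(peaks) else NA_real_
  list(trace = trace, position = position, signal = signal, peaks = peaks,
       bpm = bpm, classification = classify_signal(signal, detection))
}

#' Run the pipeline over a manifest of recordings
#'
#' Processes every recording of a manifest (frame-stack paths on disk, or
#' in-memory stacks) through [process_recording()]; failures are logged and
#' skipped so one bad file never aborts a batch. When at least five
#' recordings per class succeed, the nested cross-validated evaluation is
#' run on the results.
#'
#' @param manifest Data frame with columns `recording_id`, `subject_id`,
#'   `posture`, `true_class` and `path` (ignored when `stacks` is given).
#' @param config A [pipeline_config()].
#' @param stacks Optional named list of in-memory [frame_stack()]s keyed by
#'   recording id.
#' @param out_dir Optional directory; per-recording traces, signals and
#'   event JSONs are written there.
#' @param evaluate Run [run_nested_cv()] on the processed recordings when
#'   feasible.
#' @return List with `results` (per-recording outputs), `predictions`
#'   (data frame of true and predicted labels), `errors` (data frame of
#'   failed recordings) and optionally `cv`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         stacks = NULL, out_dir = NULL, evaluate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(manifest) == 0) {
    warning("empty manifest; nothing to do")
    return(list(results = list(),
                predictions = data.frame(), errors = data.frame()))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list(); errors <- NULL; rows <- NULL
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$recording_id[i]
    res <- tryCatch({
      stack <- if (!is.null(stacks)) stacks[[id]]
               else read_frame_stack(manifest$path[i])
      out <- process_recording(stack, config$filter, config$detection,
                               config$n_background)
      if (!is.null(out_dir)) {
        write_trace_csv(out$position,
                        file.path(out_dir, paste0(id, "_position.csv")))
        write_respiratory_csv(out$signal, out$peaks,
                              file.path(out_dir, paste0(id, "_resp.csv")))
        write_events_json(out$classification,
                          file.path(out_dir, paste0(id, "_events.json")))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors,
                      data.frame(recording_id = id,
                                 message = conditionMessage(res)))
      message(sprintf("[pipeline] %s FAILED: %s", id, conditionMessage(res)))
      next
    }
    results[[id]] <- res
    rows <- rbind(rows, data.frame(
      recording_id = id, subject_id = manifest$subject_id[i],
      true_class = manifest$true_class[i],
      predicted = res$classification$label, bpm = res$bpm))
  }
  bundle <- list(results = results,
                 predictions = if (is.null(rows)) data.frame() else rows,
                 errors = if (is.null(errors)) data.frame() else errors)
  if (evaluate && !is.null(rows) &&
      all(table(factor(rows$true_class, CLASS_LEVELS)) >= 5)) {
    recs <- lapply(rows$recording_id, function(id) {
      j <- match(id, manifest$recording_id)
      labeled_recording(id, manifest$subject_id[j], manifest$true_class[j],
                        results[[id]]$signal, manifest$posture[j])
    })
    bundle$cv <- run_nested_cv(recs, scheme = config$scheme,
                               grid = config$grid,
                               config = config$detection,
                               seed = config$seed)
  }
  bundle
}

# posture-dependent breathing amplitude: supine strongest, prone weakest
posture_factor <- c(supine = 1.0, lateral = 0.8, prone = 0.65)

#' Plan a synthetic benchmark cohort
#'
#' Draws the per-recording study conditions for `n_per_class` recordings in
#' each class (normal, short, long): breathing rate uniform in 12-20
#' breaths/min, breathing phase uniform, posture cycling through
#' supine/lateral/prone (modulating the tilt amplitude), cessation duration
#' uniform in [10, 20) s (short) or [20, 30] s (long) at an onset leaving
#' at least 10 s of breathing before and 5 s after the hold. Recording `i`
#' uses seed `seed + i - 1`, so a cohort is fully reproducible from its
#' base seed.
#'
#' @param n_per_class Recordings per class.
#' @param seed Base integer seed.
#' @param tilt_amplitude Supine breathing tilt amplitude in radians.
#' @param duration Recording length in seconds.
#' @param waveform_noise_sd Tilt noise SD in radians (default 1% of the
#'   supine amplitude).
#' @param n_subjects Number of synthetic subjects the recordings are dealt
#'   to.
#' @return Data frame with one row per recording: class, subject, posture,
#'   seed and the drawn schedule parameters.
#' @export
benchmark_plan <- function(n_per_class, seed = 0, tilt_amplitude = 1e-3,
                           duration = 60,
                           waveform_noise_sd = 0.01 * tilt_amplitude,
                           n_subjects = 10) {
  stopifnot(n_per_class >= 1)
  if (duration < 45)
    stop("'duration' must be at least 45 s to embed a 30 s hold with ",
         "breathing on both sides", call. = FALSE)
  classes <- rep(CLASS_LEVELS, each = n_per_class)
  n <- length(classes)
  plan <- data.frame(
    recording_id = sprintf("R%03d", seq_len(n)),
    subject_id = sprintf("B%02d", ((seq_len(n) - 1) %% n_subjects) + 1),
    posture = names(posture_factor)[((seq_len(n) - 1) %% 3) + 1],
    true_class = classes,
    seed = as.integer(seed) + seq_len(n) - 1L)
  draws <- lapply(plan$seed, function(s) with_seed(s, {
    rate <- stats::runif(1, 12, 20)
    phase <- stats::runif(1, 0, 2 * pi)
    dur <- c(stats::runif(1, 10, 20), stats::runif(1, 20, 30))
    onset <- stats::runif(1, 10, duration - max(dur) - 5)
    c(rate = rate, phase = phase, dur_short = dur[1], dur_long = dur[2],
      onset = onset)
  }))
  draws <- do.call(rbind, draws)
  plan$breathing_rate <- draws[, "rate"]
  plan$phase <- draws[, "phase"]
  plan$onset <- ifelse(plan$true_class == "normal", NA, draws[, "onset"])
  plan$cessation_duration <- ifelse(
    plan$true_class == "normal", NA,
    ifelse(plan$true_class == "short", draws[, "dur_short"],
           draws[, "dur_long"]))
  plan$tilt_amplitude <- tilt_amplitude *
    posture_factor[plan$posture]
  plan$waveform_noise_sd <- waveform_noise_sd
  plan$duration <- duration
  rownames(plan) <- NULL
  plan
}

plan_schedule <- function(row) {
  iv <- if (is.na(row$onset)) list() else
    list(c(row$onset, row$cessation_duration))
  respiration_schedule(
    breathing_rate = row$breathing_rate,
    tilt_amplitude = row$tilt_amplitude,
    cessation_intervals = iv,
    drift_amplitude = 0.1 * row$tilt_amplitude,
    noise_sd = row$waveform_noise_sd,
    duration = row$duration,
    phase = row$phase,
    seed = row$seed)
}

#' Simulate a benchmark cohort and write it to disk
#'
#' Simulates every recording of a [benchmark_plan()] and writes frame
#' stacks plus ground-truth JSONs to `out_dir`, returning the manifest
#' (also written as `manifest.csv`). Two calls with the same arguments
#' produce identical datasets.
#'
#' @param n_per_class Recordings per class.
#' @param seed Base seed.
#' @param optics An [optics_config()].
#' @param out_dir Output directory (created if needed).
#' @param duration Recording length in seconds.
#' @param ... Passed to [benchmark_plan()].
#' @return The manifest data frame, invisibly.
#' @export
make_benchmark_dataset <- function(n_per_class, seed = 0,
                                   optics = optics_config(),
                                   out_dir, duration = 60, ...) {
  plan <- benchmark_plan(n_per_class, seed, duration = duration, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  plan$path <- file.path(out_dir, paste0(plan$recording_id, ".bin"))
  for (i in seq_len(nrow(plan))) {
    rec <- simulate_recording(plan_schedule(plan[i, ]), optics,
                              seed = plan$seed[i],
                              subject_id = plan$subject_id[i],
                              posture = plan$posture[i])
    write_frame_stack(rec$stack, plan$path[i], format = "raw")
    write_events_json(rec$truth,
                      file.path(out_dir,
                                paste0(plan$recording_id[i], "_truth.json")))
  }
  write_manifest(plan, file.path(out_dir, "manifest.csv"))
  invisible(plan)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate and process a benchmark cohort in memory
#'
#' Runs every planned recording through simulation and the full detection
#' chain without keeping frame stacks, returning the filtered signals,
#' classifications and ground truth. This is the evaluation entry point for
#' synthetic experiments at realistic cohort sizes.
#'
#' @param plan A [benchmark_plan()] data frame.
#' @param optics An [optics_config()].
#' @param filter A [filter_spec()].
#' @param detection A [detection_config()].
#' @param n_background Tracker background frames.
#' @param progress Emit a message per recording.
#' @return List with `recordings` (list of [labeled_recording()]s),
#'   `truths` (list of [ground_truth()]s) and `predictions` (data frame
#'   with true and predicted labels and detected events).
#' @export
run_benchmark <- function(plan, optics = optics_config(),
                          filter = filter_spec(),
                          detection = detection_config(),
                          n_background = 50, progress = FALSE) {
  recordings <- vector("list", nrow(plan))
  truths <- vector("list", nrow(plan))
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sim <- simulate_recording(plan_schedule(plan[i, ]), optics,
                              seed = plan$seed[i],
                              subject_id = plan$subject_id[i],
                              posture = plan$posture[i])
    out <- process_recording(sim$stack, filter, detection, n_background)
    recordings[[i]] <- labeled_recording(
      plan$recording_id[i], plan$subject_id[i], plan$true_class[i],
      out$signal, plan$posture[i])
    truths[[i]] <- sim$truth
    ev <- out$classification$events
    rows[[i]] <- data.frame(
      recording_id = plan$recording_id[i],
      true_class = plan$true_class[i],
      predicted = out$classification$label,
      bpm = out$bpm,
      detected_onset = if (nrow(ev)) ev$onset[which.max(ev$duration)] else NA,
      detected_offset = if (nrow(ev)) ev$offset[which.max(ev$duration)] else NA,
      true_onset = if (is.na(plan$onset[i])) NA else plan$onset[i],
      true_offset = if (is.na(plan$onset[i])) NA else
        plan$onset[i] + plan$cessation_duration[i])
    if (progress)
      message(sprintf("[benchmark] %s: %s -> %s", plan$recording_id[i],
                      plan$true_class[i], out$classification$label))
  }
  list(recordings = recordings, truths = truths,
       predictions = do.call(rbind, rows))
}
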