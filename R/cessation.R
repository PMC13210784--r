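# Apnea-like cessation detection: normalized amplitude thresholding with a
# 10 s minimum-duration rule and duration-based recording classification.

#' Detection configuration
#'
#' The normalized threshold fraction `threshold` (THR) scales the maximum
#' breathing amplitude Amax to an absolute sub-threshold level. A continuous
#' run of `|signal| < THR * Amax` lasting at least `min_event` seconds is a
#' cessation event; events up to 20 s are `short`, events of 20 s up to
#' `max_long` are `long`, and longer runs are treated as invalid whole-window
#' artefacts and discarded during classification.
#'
#' @param threshold Normalized threshold fraction in `(0, 1]`; the
#'   cross-validated operating point of the method is 0.235.
#' @param min_event Minimum event duration in seconds; 10 s matches the
#'   clinical apnea rule and must not be lowered.
#' @param max_long Upper duration bound of the long class in seconds
#'   (default 30; configurable for open-ended monitoring).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold = 0.235, min_event = 10,
                             max_long = 30) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  if (min_event < 10)
    stop("'min_event' below 10 s breaks the clinical apnea rule",
         call. = FALSE)
  if (max_long <= min_event)
    stop("'max_long' must exceed 'min_event'", call. = FALSE)
  structure(list(threshold = as.numeric(threshold),
                 min_event = as.numeric(min_event),
                 max_long = as.numeric(max_long)),
            class = "detection_config")
}

#' Maximum breathing amplitude (Amax)
#'
#' The largest peak amplitude observed in the whole recording: the
#' normalization base for the detection threshold.
#'
#' @param signal A `respiratory_signal`.
#' @param peaks A [detect_breath_peaks()] result with at least one peak.
#' @return Amax in pixels.
#' @export
max_breathing_amplitude <- function(signal, peaks) {
  stopifnot(inherits(signal, "respiratory_signal"),
            inherits(peaks, "breath_peaks"))
  if (!length(peaks$indices))
    stop("no detected peaks; Amax undefined for a degenerate recording",
         call. = FALSE)
  max(signal$values[peaks$indices])
}

#' Detect sub-threshold (apnea-like) runs
#'
#' Finds maximal runs of consecutive samples with
#' `|signal| <= threshold * amax` (the filtered signal oscillates about
#' zero, so the magnitude is compared; equality matters only at the crest
#' that defines Amax, and including it lets the saturated `threshold = 1`
#' case form a single whole-window run) and keeps those lasting at least
#' `min_event` seconds. Shorter excursions are normal breathing
#' fluctuations. Runs longer than `max_long` are retained here; the
#' classifier discards them.
#'
#' @param signal A `respiratory_signal`.
#' @param amax Maximum breathing amplitude, > 0.
#' @param config A [detection_config()].
#' @return Data frame with columns `onset`, `offset`, `duration` (seconds),
#'   in time order. Run duration is `(last - first + 1) / fs`.
#' @export
detect_subthreshold_runs <- function(signal, amax,
                                     config = detection_config()) {
  stopifnot(inherits(signal, "respiratory_signal"),
            inherits(config, "detection_config"))
  if (!is.numeric(amax) || amax <= 0)
    stop("'amax' must be > 0", call. = FALSE)
  below <- abs(signal$values) <= config$threshold * amax
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / signal$fs >= config$min_event)
  data.frame(onset = (starts[keep] - 1) / signal$fs,
             offset = ends[keep] / signal$fs,
             duration = r$lengths[keep] / signal$fs)
}

#' Classify a recording from its detected events
#'
#' Events longer than `max_long` are discarded as invalid (at very
#' permissive thresholds the sub-threshold run spans nearly the whole
#' window; discarding it restores normal classification, which is what
#' keeps specificity high there while sensitivity collapses). If no valid
#' event remains the recording is `normal`; otherwise the longest valid
#' event decides: duration below 20 s is `short`, 20 s and above is `long`
#' (the boundary itself goes to the more severe class).
#'
#' @param events Data frame from [detect_subthreshold_runs()].
#' @param config A [detection_config()].
#' @param amax Optional Amax to carry in the result.
#' @return An object of class `recording_classification`: list with `label`
#'   (`"normal"`, `"short"` or `"long"`), the valid `events`, `amax` and
#'   `thr_used`.
#' @export
classify_recording <- function(events, config = detection_config(),
                               amax = NA_real_) {
  stopifnot(inherits(config, "detection_config"), is.data.frame(events))
  valid <- events[events$duration >= config$min_event &
                  events$duration <= config$max_long, , drop = FALSE]
  label <- if (nrow(valid) == 0) {
    "normal"
  } else if (max(valid$duration) < 20) "short" else "long"
  structure(list(label = label, events = valid, amax = amax,
                 thr_used = config$threshold),
            class = "recording_classification")
}

#' @export
print.recording_classification <- function(x, ...) {
  cat(sprintf("<recording_classification> %s (THR %g, Amax %.3g px, %d event%s)\n",
              x$label, x$thr_used, x$amax, nrow(x$events),
              if (nrow(x$events) == 1) "" else "s"))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  event %d: %.2f-%.2f s (%.2f s)\n", i,
                  x$events$onset[i], x$events$offset[i], x$events$duration[i]))
  }
  invisible(x)
}

#' Full per-recording detection from a filtered signal
#'
#' Convenience composition: breath peaks, Amax, sub-threshold runs,
#' classification. A recording with no detectable breath peaks is
#' degenerate and classified `normal` with a warning so that batch
#' evaluation never aborts.
#'
#' @param signal A `respiratory_signal`.
#' @param config A [detection_config()].
#' @param min_sep Minimum inter-peak interval in seconds for peak detection.
#' @return A `recording_classification`.
#' @export
classify_signal <- function(signal, config = detection_config(),
                            min_sep = 2) {
  peaks <- detect_breath_peaks(signal, min_sep = min_sep)
  if (!length(peaks$indices) || max(signal$values[peaks$indices]) <= 0) {
    warning("degenerate recording (no positive breath peaks); classified normal")
    return(classify_recording(
      data.frame(onset = numeric(0), offset = numeric(0),
                 duration = numeric(0)),
      config))
  }
  amax <- max_breathing_amplitude(signal, peaks)
  classify_recording(detect_subthreshold_runs(signal, amax, config),
                     config, amax = amax)
}
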