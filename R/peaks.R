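# Breath-peak detection and respiratory rate.

#' Detect breath peaks
#'
#' Finds local maxima of the filtered respiratory signal with a minimum
#' inter-peak interval: among candidate maxima closer than
#' `min_sep * fs` samples, the larger amplitude wins (ties go to the earlier
#' index). Maxima correspond to inhalation crests of the signed signal.
#'
#' @param signal A [zero_phase_filter()] result (class `respiratory_signal`).
#' @param min_sep Minimum inter-peak interval in seconds (default 2, i.e.
#'   400 samples at 200 Hz).
#' @param min_prominence Optional minimum peak height; `NULL` (default)
#'   applies no height criterion.
#' @return An object of class `breath_peaks`: list with sorted sample
#'   `indices`, `min_sep` and `fs`.
#' @export
detect_breath_peaks <- function(signal, min_sep = 2, min_prominence = NULL) {
  stopifnot(inherits(signal, "respiratory_signal"))
  v <- signal$values
  gap <- min_sep * signal$fs
  if (length(v) < gap)
    stop("signal shorter than one minimum inter-peak interval", call. = FALSE)
  # strict local maxima: rising before, falling after
  dv <- diff(v)
  cand <- which(dv[-length(dv)] > 0 & dv[-1] < 0) + 1L
  if (!is.null(min_prominence)) cand <- cand[v[cand] >= min_prominence]
  if (!length(cand))
    return(structure(list(indices = integer(0), min_sep = min_sep,
                          fs = signal$fs), class = "breath_peaks"))
  cand <- cand[order(-v[cand], cand)]        # height desc, then earlier
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= gap)) keep <- c(keep, i)
  structure(list(indices = sort(keep), min_sep = min_sep, fs = signal$fs),
            class = "breath_peaks")
}

#' @export
print.breath_peaks <- function(x, ...) {
  cat(sprintf("<breath_peaks> %d peaks (min separation %g s @ %g Hz)\n",
              length(x$indices), x$min_sep, x$fs))
  invisible(x)
}

#' Respiratory rate in breaths per minute
#'
#' `BPM = 60 / mean(inter-peak interval in seconds)`; requires at least two
#' peaks.
#'
#' @param peaks A [detect_breath_peaks()] result.
#' @param fs Sampling rate in Hz; defaults to the rate stored in `peaks`.
#' @return Breathing rate in breaths/min.
#' @export
breathing_rate <- function(peaks, fs = peaks$fs) {
  stopifnot(inherits(peaks, "breath_peaks"))
  if (length(peaks$indices) < 2)
    stop("breathing rate undefined with fewer than 2 peaks", call. = FALSE)
  60 / mean(diff(peaks$indices) / fs)
}
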