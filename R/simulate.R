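# Far-field speckle simulator: rough-surface phase screen, Fraunhofer
# propagation, tilt-driven lateral shifts, respiration-like tilt schedules.

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a rough-surface phase screen
#'
#' Draws the random surface phase of the optically rough scatterer: an
#' `H' x W'` grid of independent phases uniform on `[0, 2*pi)`. The screen is
#' the only stochastic ingredient of a speckle realization; regenerating with
#' the same seed reproduces it bit-exactly.
#'
#' @param shape Integer vector `c(H, W)`, both at least 8.
#' @param seed Integer seed.
#' @return An object of class `phase_screen`: the phase matrix with the seed
#'   stored as an attribute.
#' @export
generate_phase_screen <- function(shape, seed) {
  if (length(shape) != 2 || any(!is.finite(shape)) || any(shape < 8))
    stop("'shape' must be two values >= 8", call. = FALSE)
  shape <- as.integer(shape)
  ph <- with_seed(seed,
                  matrix(stats::runif(prod(shape), 0, 2 * pi),
                         shape[1], shape[2]))
  structure(ph, seed = as.integer(seed), class = c("phase_screen", "matrix"))
}

# complex field at the scatterer: circular aperture times exp(i*phase)
base_field <- function(screen, optics) {
  h <- nrow(screen); w <- ncol(screen)
  ry <- h / 2 * optics$aperture_fraction
  rx <- w / 2 * optics$aperture_fraction
  yy <- matrix(seq_len(h) - (floor(h / 2) + 1), h, w)
  xx <- matrix(seq_len(w) - (floor(w / 2) + 1), h, w, byrow = TRUE)
  ap <- (yy / ry)^2 + (xx / rx)^2 <= 1
  ap * exp(1i * unclass(screen))
}

# far-field intensity of `field` with an x-shift of `shift_px` pixels,
# applied as a linear phase ramp before the transform (shift theorem)
farfield_intensity <- function(field, shift_px) {
  w <- ncol(field)
  ramp <- exp(2i * pi * shift_px * (seq_len(w) - 1) / w)
  intensity <- Mod(stats::fft(field * matrix(ramp, nrow(field), w,
                                             byrow = TRUE)))^2
  intensity / mean(intensity)
}

#' Render one far-field speckle frame
#'
#' Computes the Fraunhofer intensity of the aperture-limited field
#' `exp(i*phase)` with a tilt-induced linear phase ramp. By the Fourier shift
#' theorem the returned intensity is the tilt-zero pattern translated
#' laterally (circularly) by [tilt_to_pixel_shift()] pixels; translation is
#' exact for integer shifts and band-limited-interpolated for fractional
#' ones. Intensities are non-negative and normalized to unit mean.
#'
#' @param screen A [generate_phase_screen()] result.
#' @param optics An [optics_config()]; its `frame_shape` must match the
#'   screen.
#' @param tilt Surface tilt in radians. The implied shift must stay below a
#'   quarter of the smaller frame dimension.
#' @return Intensity matrix of the same shape as the screen.
#' @export
render_farfield_frame <- function(screen, optics, tilt) {
  stopifnot(inherits(screen, "phase_screen"), inherits(optics, "optics_config"))
  shift <- tilt_to_pixel_shift(tilt, optics)
  lim <- min(nrow(screen), ncol(screen)) / 4
  if (abs(shift) >= lim)
    stop(sprintf("tilt maps to a %.2f px shift, outside +-%g px", shift, lim),
         call. = FALSE)
  farfield_intensity(base_field(screen, optics), shift)
}

#' Respiration schedule with programmable breath-hold episodes
#'
#' Describes the tilt trajectory of the chest surface over one recording:
#' sinusoidal breathing at `breathing_rate`, amplitude `tilt_amplitude`,
#' multiplicatively suppressed to `residual_fraction` inside each cessation
#' interval (1 s cosine taper at the edges), plus slow sinusoidal drift and
#' additive Gaussian tilt noise.
#'
#' @param breathing_rate Breaths per minute, in `[6, 60]`.
#' @param tilt_amplitude Breathing tilt amplitude in radians.
#' @param cessation_intervals List of `c(onset_s, duration_s)` pairs (or an
#'   n-by-2 matrix); intervals must lie inside `[0, duration]` and must not
#'   overlap.
#' @param residual_fraction Fraction of the breathing amplitude retained
#'   during a hold, in `[0, 1)`.
#' @param drift_amplitude,drift_frequency Slow postural drift: amplitude in
#'   radians and frequency in Hz.
#' @param noise_sd SD of additive Gaussian tilt noise, radians.
#' @param duration Recording length in seconds.
#' @param phase Breathing phase offset in radians.
#' @param seed Integer seed for the stochastic terms.
#' @return An object of class `respiration_schedule`.
#' @export
respiration_schedule <- function(breathing_rate = 15,
                                 tilt_amplitude = 1e-3,
                                 cessation_intervals = list(),
                                 residual_fraction = 0.02,
                                 drift_amplitude = 1e-4,
                                 drift_frequency = 0.02,
                                 noise_sd = 0,
                                 duration = 60,
                                 phase = 0,
                                 seed = 1) {
  if (breathing_rate < 6 || breathing_rate > 60)
    stop("'breathing_rate' must lie in [6, 60] breaths/min", call. = FALSE)
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop("'residual_fraction' must lie in [0, 1)", call. = FALSE)
  stopifnot(duration > 0, noise_sd >= 0, drift_amplitude >= 0)
  iv <- if (is.matrix(cessation_intervals)) {
    lapply(seq_len(nrow(cessation_intervals)),
           function(i) cessation_intervals[i, ])
  } else {
    cessation_intervals
  }
  if (length(iv)) {
    ons <- vapply(iv, `[`, numeric(1), 1)
    dur <- vapply(iv, `[`, numeric(1), 2)
    if (any(dur <= 0) || any(ons < 0) || any(ons + dur > duration))
      stop("cessation intervals must lie inside [0, duration]", call. = FALSE)
    o <- order(ons)
    ons <- ons[o]; dur <- dur[o]
    if (length(ons) > 1 && any(ons[-1] < (ons + dur)[-length(ons)]))
      stop("cessation intervals must not overlap", call. = FALSE)
    iv <- Map(c, ons, dur)
  }
  structure(list(breathing_rate = breathing_rate,
                 tilt_amplitude = tilt_amplitude,
                 cessation_intervals = iv,
                 residual_fraction = residual_fraction,
                 drift_amplitude = drift_amplitude,
                 drift_frequency = drift_frequency,
                 noise_sd = noise_sd,
                 duration = duration,
                 phase = phase,
                 seed = as.integer(seed)),
            class = "respiration_schedule")
}

# cosine step: 1 before t0 - width/2, 0 after t0 + width/2, 1/2 at t0
cos_step_down <- function(t, t0, width = 1) {
  u <- pmin(pmax((t - (t0 - width / 2)) / width, 0), 1)
  0.5 * (1 + cos(pi * u))
}

#' Sampled respiration tilt waveform with ground-truth event times
#'
#' Evaluates the schedule on a regular grid at `fs` Hz:
#' `tilt(t) = A * sin(2*pi*f_b*t + phase) * m(t) + drift(t) + noise(t)`,
#' where `m(t)` ramps from 1 to `residual_fraction` through a 1 s cosine
#' taper at each cessation edge. Ground-truth event boundaries are the taper
#' midpoints (the half-suppression instants), which coincide with the
#' scheduled onset/offset.
#'
#' @param schedule A [respiration_schedule()].
#' @param fs Sampling rate in Hz; `duration * fs` must be at least 2.
#' @return Numeric vector of tilts (radians) with attributes `fs`, `time`
#'   and `events` (data frame of onset/offset/duration in seconds).
#' @export
respiration_tilt_waveform <- function(schedule, fs) {
  stopifnot(inherits(schedule, "respiration_schedule"), fs > 0)
  n <- round(schedule$duration * fs)
  if (n < 2) stop("'duration * fs' must be at least 2 samples", call. = FALSE)
  t <- (seq_len(n) - 1) / fs
  f_b <- schedule$breathing_rate / 60
  gate <- rep(0, n)
  for (iv in schedule$cessation_intervals) {
    gate <- gate + (1 - cos_step_down(t, iv[1])) * cos_step_down(t, iv[1] + iv[2])
  }
  gate <- pmin(gate, 1)
  m <- 1 - (1 - schedule$residual_fraction) * gate
  alpha <- schedule$tilt_amplitude * sin(2 * pi * f_b * t + schedule$phase) * m
  if (schedule$drift_amplitude > 0)
    alpha <- alpha + schedule$drift_amplitude *
      sin(2 * pi * schedule$drift_frequency * t)
  if (schedule$noise_sd > 0)
    alpha <- alpha + with_seed(schedule$seed,
                               stats::rnorm(n, 0, schedule$noise_sd))
  ev <- if (length(schedule$cessation_intervals)) {
    on <- vapply(schedule$cessation_intervals, `[`, numeric(1), 1)
    du <- vapply(schedule$cessation_intervals, `[`, numeric(1), 2)
    data.frame(onset = on, offset = on + du, duration = du)
  } else {
    data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0))
  }
  structure(alpha, fs = fs, time = t, events = ev)
}

#' Ground truth for a simulated recording
#'
#' Derives the recording-level class from the scheduled events: no event is
#' `normal`; otherwise the longest event decides, `[10, 20)` s giving
#' `short` and `[20, 30]` s giving `long`.
#'
#' @param events Data frame with columns onset/offset/duration (seconds).
#' @param subject_id,posture Identification metadata.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(events, subject_id = "sim",
                         posture = c("supine", "lateral", "prone")) {
  posture <- match.arg(posture)
  stopifnot(is.data.frame(events))
  cls <- if (nrow(events) == 0) {
    "normal"
  } else {
    d <- max(events$duration)
    if (d < 10) "normal" else if (d < 20) "short" else if (d <= 30) "long"
    else stop("event duration > 30 s has no class label", call. = FALSE)
  }
  structure(list(recording_class = cls, events = events,
                 subject_id = subject_id, posture = posture),
            class = "ground_truth")
}

#' Simulate a full speckle recording
#'
#' Composes the phase screen, the respiration tilt waveform and the
#' far-field renderer into a frame stack: frame `t` is the far-field pattern
#' at tilt `alpha[t]`, with additive Gaussian camera noise (SD =
#' `noise_fraction` of the mean intensity) and optional 8-bit quantization.
#' Deterministic for fixed `(schedule, optics, seed)`.
#'
#' @param schedule A [respiration_schedule()].
#' @param optics An [optics_config()]; `frame_shape` and `frame_rate` set the
#'   stack geometry and sampling.
#' @param seed Integer seed for the phase screen and camera noise (waveform
#'   noise is governed by `schedule$seed`).
#' @param subject_id,posture Metadata forwarded to the ground truth.
#' @return A list with elements `stack` ([frame_stack()]) and `truth`
#'   ([ground_truth()]).
#' @export
simulate_recording <- function(schedule, optics, seed = 1,
                               subject_id = "sim", posture = "supine") {
  stopifnot(inherits(schedule, "respiration_schedule"),
            inherits(optics, "optics_config"))
  alpha <- respiration_tilt_waveform(schedule, optics$frame_rate)
  shifts <- tilt_to_pixel_shift(as.numeric(alpha), optics)
  lim <- min(optics$frame_shape) / 4
  if (max(abs(shifts)) >= lim)
    stop(sprintf("schedule drives shifts to %.2f px, outside +-%g px",
                 max(abs(shifts)), lim), call. = FALSE)
  screen <- generate_phase_screen(optics$frame_shape, seed)
  field <- base_field(screen, optics)
  n <- length(shifts)
  frames <- array(0, dim = c(n, optics$frame_shape[1], optics$frame_shape[2]))
  with_seed(seed + 1L, {
    for (k in seq_len(n)) {
      fr <- farfield_intensity(field, shifts[k])
      if (optics$noise_fraction > 0)
        fr <- fr + stats::rnorm(length(fr), 0, optics$noise_fraction)
      if (optics$quantize_8bit)
        fr <- round(pmin(pmax(fr, 0), 4) / 4 * 255) / 255 * 4
      frames[k, , ] <- fr
    }
  })
  stack <- frame_stack(frames, optics$frame_rate,
                       dtype = if (optics$quantize_8bit) "uint8" else "float")
  list(stack = stack,
       truth = ground_truth(attr(alpha, "events"), subject_id, posture))
}
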