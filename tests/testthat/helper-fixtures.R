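# shared fixtures: tiny optics, integer rolls, brute-force correlation oracle

tiny_optics <- function(shape = c(64, 64), fs = 50, gain = 4000,
                        noise = 0, ...) {
  optics_config(frame_shape = shape, frame_rate = fs, pixel_gain = gain,
                noise_fraction = noise, ...)
}

# circularly shift matrix content by (dy, dx): positive = toward larger index
roll2 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# O(n^4) spatial circular cross-correlation oracle: value at displacement
# (dy, dx) is sum(I1 * roll(I2 toward origin)), matching correlate_pair's
# convention (peak = displacement of frame2 relative to frame1)
brute_correlation <- function(I1, I2) {
  h <- nrow(I1); w <- ncol(I1)
  out <- matrix(0, h, w)
  center <- c(floor(h / 2) + 1, floor(w / 2) + 1)
  for (dy in seq_len(h) - center[1])
    for (dx in seq_len(w) - center[2])
      out[dy + center[1], dx + center[2]] <- sum(I1 * roll2(I2, -dy, -dx))
  out
}

# speckle frame pair separated by a commanded sub-pixel x-shift
shifted_pair <- function(shift, shape = c(64, 64), seed = 5) {
  opt <- tiny_optics(shape, gain = 1)
  scr <- generate_phase_screen(shape, seed)
  list(a = render_farfield_frame(scr, opt, 0),
       b = render_farfield_frame(scr, opt, shift))
}

sine_signal <- function(freq = 0.25, fs = 50, duration = 60, amp = 1,
                        phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  structure(list(values = amp * sin(2 * pi * freq * t + phase), fs = fs),
            class = "respiratory_signal")
}
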