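# Displacement tracking: correlation oracle, sub-pixel refinement, traces.

test_that("background reference is the mean of the leading frames", {
  fr <- array(0, dim = c(4, 8, 8))
  fr[2, , ] <- 2
  stack <- frame_stack(fr, fs = 10)
  expect_equal(background_reference(stack, 1), fr[1, , ])
  expect_equal(background_reference(stack, 2), matrix(1, 8, 8))
  const <- frame_stack(array(3, dim = c(5, 8, 8)), fs = 10)
  expect_equal(background_reference(const, 5), matrix(3, 8, 8))
  expect_error(background_reference(stack, 0), "n_frames")
  expect_error(background_reference(stack, 9), "n_frames")
})

test_that("background subtraction is float, unclipped, shape-checked", {
  fr <- array(1, dim = c(3, 8, 8))
  stack <- frame_stack(fr, fs = 10)
  zero <- subtract_background(stack, matrix(1, 8, 8))
  expect_true(all(zero$frames == 0))
  ident <- subtract_background(stack, matrix(0, 8, 8))
  expect_equal(ident$frames, fr)
  big <- subtract_background(stack, matrix(5, 8, 8))
  expect_true(all(big$frames == -4))      # no clipping
  expect_error(subtract_background(stack, matrix(0, 4, 4)), "shape")

  set.seed(1)
  fr2 <- array(runif(5 * 8 * 8), dim = c(5, 8, 8))
  st2 <- frame_stack(fr2, fs = 10)
  centered <- subtract_background(st2, background_reference(st2, 5))
  expect_equal(mean(centered$frames), 0, tolerance = 1e-12)
})

test_that("frequency-domain correlation matches the brute-force oracle", {
  set.seed(42)
  for (k in 1:20) {
    I1 <- matrix(runif(16 * 16), 16, 16)
    I2 <- matrix(runif(16 * 16), 16, 16)
    fast <- correlate_pair(I1, I2)$values
    slow <- brute_correlation(I1, I2)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-9)
  }
})

test_that("integer circular shifts are recovered exactly", {
  set.seed(7)
  I1 <- matrix(runif(32 * 32), 32, 32)
  for (dy in c(-8, -3, 0, 5, 8)) for (dx in c(-8, -2, 0, 3, 8)) {
    m <- correlate_pair(I1, roll2(I1, dy, dx))
    expect_identical(m$peak, c(as.integer(dy), as.integer(dx)))
    est <- subpixel_peak(m)
    expect_equal(est[["dx"]], dx, tolerance = 1e-6)
    expect_equal(est[["dy"]], dy, tolerance = 1e-6)
  }
})

test_that("autocorrelation peaks at zero and flat maps tie-break to center", {
  set.seed(3)
  I1 <- matrix(runif(16 * 16), 16, 16)
  expect_identical(correlate_pair(I1, I1)$peak, c(0L, 0L))
  flat <- matrix(0, 16, 16)
  expect_warning(m <- correlate_pair(flat, flat), "flat")
  expect_identical(m$peak, c(0L, 0L))
  expect_equal(subpixel_peak(m), c(dx = 0, dy = 0))
})

test_that("correlation displacement is antisymmetric in the frame order", {
  for (s in c(0.3, -0.45, 1.7)) {
    pair <- shifted_pair(s, seed = 13)
    fwd <- subpixel_peak(correlate_pair(pair$a, pair$b))
    bwd <- subpixel_peak(correlate_pair(pair$b, pair$a))
    expect_equal(fwd[["dx"]], -bwd[["dx"]], tolerance = 1e-6)
    expect_equal(fwd[["dy"]], -bwd[["dy"]], tolerance = 1e-6)
  }
})

test_that("parabolic refinement reproduces the closed-form vertex", {
  # build a map whose peak neighbourhood along x is (1, 3, 2)
  v <- matrix(0, 16, 16)
  center <- c(9, 9)
  v[center[1], center[2] - 1] <- 1
  v[center[1], center[2]] <- 3
  v[center[1], center[2] + 1] <- 2
  map <- structure(list(values = v, peak = c(0L, 0L), center = center),
                   class = "correlation_map")
  est <- subpixel_peak(map)
  expect_equal(est[["dx"]], (1 - 2) / (2 * (1 - 6 + 2)))   # = 1/6
  expect_equal(est[["dy"]], 0)                             # symmetric axis

  # symmetric neighbours give no refinement
  v[center[1], center[2] - 1] <- 2
  map$values <- v
  expect_equal(subpixel_peak(map)[["dx"]], 0)
})

test_that("sub-pixel shifts on simulated speckle are recovered within 0.05 px", {
  for (s in c(-0.5, -0.25, 0.1, 0.4, 0.5)) {
    pair <- shifted_pair(s, seed = 23)
    est <- subpixel_peak(correlate_pair(pair$a, pair$b))
    expect_lt(abs(est[["dx"]] - s), 0.05)
  }
})

test_that("track recovers constructed motion and static stacks give zeros", {
  set.seed(9)
  base <- matrix(runif(32 * 32), 32, 32)
  frames <- lapply(0:5, function(k) roll2(base, 0, k))
  stack <- frame_stack(frames, fs = 10)
  tr <- track(stack, n_background = 0)
  expect_equal(tr$dx, rep(1, 5), tolerance = 1e-6)
  expect_equal(tr$dy, rep(0, 5), tolerance = 1e-6)

  static <- frame_stack(lapply(1:4, function(k) base), fs = 10)
  tr0 <- track(static, n_background = 0)
  expect_equal(tr0$dx, rep(0, 3), tolerance = 1e-9)
  expect_equal(tr0$dy, rep(0, 3), tolerance = 1e-9)
})

test_that("moving-average background mode tracks once its window fills", {
  set.seed(31)
  base <- matrix(runif(32 * 32), 32, 32)
  frames <- lapply(0:5, function(k) roll2(base, k, 0))
  stack <- frame_stack(frames, fs = 10)
  tr <- suppressWarnings(track(stack, n_background = 3,
                               background = "moving"))
  expect_equal(tr$dy[3:5], rep(1, 3), tolerance = 1e-6)
})

test_that("cumulative position takes exact prefix sums", {
  tr <- structure(list(dx = c(1, 1, 1), dy = c(1, -1, 1, -1)[1:3], fs = 10),
                  class = "displacement_trace")
  pos <- cumulative_position(tr)
  expect_identical(pos$x, c(1, 2, 3))
  expect_identical(pos$y, c(1, 0, 1))
  set.seed(2)
  tr2 <- structure(list(dx = rnorm(50), dy = rnorm(50), fs = 10),
                   class = "displacement_trace")
  pos2 <- cumulative_position(tr2)
  expect_identical(pos2$x[50], sum(tr2$dx))
})

test_that("simulator round trip: commanded tilt and tracked position align", {
  opt <- tiny_optics(shape = c(64, 64), fs = 25, gain = 4000)
  sch <- respiration_schedule(breathing_rate = 15, tilt_amplitude = 1e-3,
                              drift_amplitude = 0, noise_sd = 0,
                              duration = 12, seed = 4)
  sim <- simulate_recording(sch, opt, seed = 17)
  commanded <- tilt_to_pixel_shift(
    as.numeric(respiration_tilt_waveform(sch, opt$frame_rate)), opt)
  tr <- track(sim$stack, n_background = 0)
  x <- cumulative_position(tr)$x
  expect_gt(cor(x, commanded[-1]), 0.999)

  # commanded amplitude 4 px; fit the tracked sinusoid amplitude
  t <- seq_along(x) / opt$frame_rate
  fit <- stats::lm(x ~ sin(2 * pi * 0.25 * t) + cos(2 * pi * 0.25 * t))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 4, tolerance = 0.1 / 4)
})
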