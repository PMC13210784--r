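# Frame-to-frame displacement tracking: frequency-domain cross-correlation
# with parabolic sub-pixel peak localization.

#' Frame stack container
#'
#' Wraps a `T x H x W` array of non-negative intensities with its
#' acquisition rate. At least two frames are required.
#'
#' @param frames A 3-d array (`T x H x W`) or list of equally sized matrices.
#' @param fs Acquisition rate in Hz.
#' @param dtype Informal dtype note (`"uint8"`, `"uint16"` or `"float"`).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fs, dtype = "float") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must share the same shape", call. = FALSE)
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
    frames <- arr
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] < 2)
    stop("'frames' must be a T x H x W array with T >= 2", call. = FALSE)
  stopifnot(is.numeric(fs), fs > 0)
  structure(list(frames = frames, fs = fs, dtype = dtype),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g Hz (%s, %.1f s)\n",
              d[1], d[2], d[3], x$fs, x$dtype, d[1] / x$fs))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1]

#' Background reference frame
#'
#' Per-pixel mean of the first `n_frames` frames; the static component that
#' is subtracted to enhance the dynamic speckle variations.
#'
#' @param stack A [frame_stack()].
#' @param n_frames Number of leading frames to average, in `[1, T]`.
#' @return An `H x W` matrix.
#' @export
background_reference <- function(stack, n_frames = 50) {
  stopifnot(inherits(stack, "frame_stack"))
  total <- dim(stack$frames)[1]
  if (n_frames < 1 || n_frames > total)
    stop(sprintf("'n_frames' must lie in [1, %d]", total), call. = FALSE)
  if (n_frames == 1) return(stack$frames[1, , ])
  apply(stack$frames[seq_len(n_frames), , , drop = FALSE], c(2, 3), mean)
}

#' Subtract a background frame from every frame
#'
#' Frame-wise floating-point subtraction; no clipping, so the result may be
#' negative.
#'
#' @param stack A [frame_stack()].
#' @param background An `H x W` matrix of matching shape.
#' @return A new [frame_stack()] with `dtype = "float"`.
#' @export
subtract_background <- function(stack, background) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (!identical(dim(background), d[2:3]))
    stop("background shape does not match the frames", call. = FALSE)
  out <- stack$frames - rep(background, each = d[1])
  frame_stack(out, stack$fs, dtype = "float")
}

# circular shift of the quadrants so that zero displacement maps to the
# center cell (floor(H/2)+1, floor(W/2)+1)
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
    c((floor(w / 2) + 1):w, seq_len(floor(w / 2)))]
}

#' Frequency-domain cross-correlation of a frame pair
#'
#' Computes the circular cross-correlation of two frames through the Fourier
#' domain (product of one transform with the conjugate of the other, inverse
#' transformed, real part taken) and re-centers it so that the grid center
#' corresponds to zero displacement. It equals direct circular spatial
#' cross-correlation to numerical precision.
#'
#' The peak location reports the displacement of `frame2` relative to
#' `frame1`: positive `dx` means the pattern moved toward increasing column
#' index going from `frame1` to `frame2` (and positive `dy` toward
#' increasing row index). Displacements are reported in the centered
#' interval `[-H/2, H/2) x [-W/2, W/2)`.
#'
#' Multiple equal maxima are resolved toward the smallest displacement
#' magnitude (then smallest row, then column); an all-flat map yields a peak
#' at zero with a warning.
#'
#' @param frame1,frame2 Matrices of identical shape, at least 8 x 8.
#' @return An object of class `correlation_map`: list with the re-centered
#'   real `values`, the integer displacement `peak = c(dy, dx)`, and `center`.
#' @export
correlate_pair <- function(frame1, frame2) {
  if (!identical(dim(frame1), dim(frame2)))
    stop("frames must have identical shape", call. = FALSE)
  if (any(dim(frame1) < 8))
    stop("frames must be at least 8 x 8", call. = FALSE)
  f1 <- stats::fft(frame1)
  f2 <- stats::fft(frame2)
  correlation_from_ffts(f1, f2)
}

# shared core so track() can reuse per-frame FFTs
correlation_from_ffts <- function(f1, f2) {
  h <- nrow(f1); w <- ncol(f1)
  values <- fftshift2(Re(stats::fft(f2 * Conj(f1), inverse = TRUE)) / (h * w))
  center <- c(floor(h / 2) + 1, floor(w / 2) + 1)
  mx <- max(values)
  if (mx == min(values)) {
    warning("flat correlation map; reporting zero displacement")
    peak <- c(0L, 0L)
  } else {
    idx <- which(values == mx, arr.ind = TRUE)
    disp <- cbind(idx[, 1] - center[1], idx[, 2] - center[2])
    ord <- order(disp[, 1]^2 + disp[, 2]^2, disp[, 1], disp[, 2])
    peak <- as.integer(disp[ord[1], ])
  }
  structure(list(values = values, peak = peak, center = center),
            class = "correlation_map")
}

# parabola vertex offset through (c_minus, c_0, c_plus); 0 when flat
parabolic_offset <- function(c_minus, c_0, c_plus) {
  den <- c_minus - 2 * c_0 + c_plus
  if (den == 0) return(0)
  delta <- (c_minus - c_plus) / (2 * den)
  max(min(delta, 0.5), -0.5)
}

#' Sub-pixel refinement of a correlation peak
#'
#' Refines the integer peak of a [correlate_pair()] map independently per
#' axis by fitting a parabola through the peak value and its two neighbours
#' (with circular wrap at the map edge):
#' `delta = (c_minus - c_plus) / (2 * (c_minus - 2*c_0 + c_plus))`,
#' clamped to `[-0.5, 0.5]`. A flat three-point neighbourhood leaves the
#' integer location unrefined.
#'
#' @param map A `correlation_map`.
#' @return Named numeric `c(dx, dy)` displacement in pixels (x = columns,
#'   y = rows), sign convention as documented in [correlate_pair()].
#' @export
subpixel_peak <- function(map) {
  stopifnot(inherits(map, "correlation_map"))
  if (any(!is.finite(map$values)))
    stop("correlation map contains non-finite values", call. = FALSE)
  v <- map$values
  h <- nrow(v); w <- ncol(v)
  pk <- map$peak + map$center
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- parabolic_offset(v[wrap(pk[1] - 1, h), pk[2]],
                         v[pk[1], pk[2]],
                         v[wrap(pk[1] + 1, h), pk[2]])
  dx <- parabolic_offset(v[pk[1], wrap(pk[2] - 1, w)],
                         v[pk[1], pk[2]],
                         v[pk[1], wrap(pk[2] + 1, w)])
  c(dx = map$peak[2] + dx, dy = map$peak[1] + dy)
}

#' Track frame-to-frame displacement through a stack
#'
#' Establishes a background reference (mean of the first `n_background`
#' frames, or a causal moving average in `"moving"` mode), subtracts it, and
#' for each consecutive frame pair locates the correlation peak with
#' sub-pixel refinement. Both axes are tracked simultaneously; the result is
#' the 2 x N displacement matrix of the pipeline (N = T - 1).
#'
#' @param stack A [frame_stack()].
#' @param n_background Frames averaged for the static background reference
#'   (also the window length in moving mode); `0` disables background
#'   subtraction, which is useful when measuring the bare tracker response
#'   on synthetic stacks that contain no static scene component.
#' @param background Either `"static"` (reference from the leading frames)
#'   or `"moving"` (running mean of the trailing `n_background` frames,
#'   current frame included; the first frame pair is then degenerate and
#'   reports zero displacement with a warning).
#' @return An object of class `displacement_trace`: list with `dx`, `dy`
#'   (pixels) and `fs`.
#' @export
track <- function(stack, n_background = 50,
                  background = c("static", "moving")) {
  stopifnot(inherits(stack, "frame_stack"))
  background <- match.arg(background)
  total <- n_frames(stack)
  n_background <- min(n_background, total)
  fr <- stack$frames
  d <- dim(fr)
  if (n_background == 0) {
    # no background subtraction
  } else if (background == "static") {
    ref <- background_reference(stack, n_background)
    fr <- fr - rep(ref, each = d[1])
  } else {
    csum <- apply(fr, c(2, 3), cumsum)      # T x H x W running totals
    out <- fr
    for (k in seq_len(d[1])) {
      lo <- max(1, k - n_background + 1)
      win <- if (lo == 1) csum[k, , ] else csum[k, , ] - csum[lo - 1, , ]
      out[k, , ] <- fr[k, , ] - win / (k - lo + 1)
    }
    fr <- out
  }
  n <- d[1] - 1
  dx <- numeric(n); dy <- numeric(n)
  f_prev <- stats::fft(fr[1, , ])
  for (k in seq_len(n)) {
    f_next <- stats::fft(fr[k + 1, , ])
    est <- subpixel_peak(correlation_from_ffts(f_prev, f_next))
    dx[k] <- est[["dx"]]; dy[k] <- est[["dy"]]
    f_prev <- f_next
  }
  structure(list(dx = dx, dy = dy, fs = stack$fs),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> N = %d pairs @ %g Hz, rms dx %.3g px, dy %.3g px\n",
              length(x$dx), x$fs, sqrt(mean(x$dx^2)), sqrt(mean(x$dy^2))))
  invisible(x)
}

#' Cumulative position from frame-to-frame displacements
#'
#' Exact prefix sums per axis: the integrated chest-surface position in
#' pixels.
#'
#' @param trace A [track()] result.
#' @return An object of class `position_trace`: list with `x`, `y`, `fs`.
#' @export
cumulative_position <- function(trace) {
  stopifnot(inherits(trace, "displacement_trace"), length(trace$dx) >= 1)
  structure(list(x = cumsum(trace$dx), y = cumsum(trace$dy), fs = trace$fs),
            class = "position_trace")
}
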