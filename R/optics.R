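#' Optical configuration for the far-field speckle simulator
#'
#' Bundles the optical and camera constants that govern how a tilt of the
#' illuminated surface translates into a lateral shift of the recorded
#' speckle pattern. The far-field (Fraunhofer) condition
#' `farfield_distance > spot_diameter^2 / (4 * wavelength)` must hold: it is
#' what makes surface tilt produce a pure translation of the pattern rather
#' than decorrelation.
#'
#' The tilt-to-shift law is linear for small angles; the single calibrated
#' constant `pixel_gain` (pixels per radian) folds the optical proportionality
#' between tilt angle and pattern shift together with the camera-plane
#' magnification, which depends on geometry not otherwise modelled here.
#'
#' `aperture_fraction` sets the diameter of the illuminated aperture relative
#' to the simulation grid and therefore the speckle grain size (grain is
#' roughly `1 / aperture_fraction` pixels). The default produces grains of
#' about 8 px, large enough that three-point parabolic peak interpolation in
#' the tracker recovers sub-pixel shifts to much better than 0.05 px. Smaller
#' grains (toward the ~1 px of typical hardware) can be simulated by raising
#' this value at the cost of sub-pixel accuracy.
#'
#' @param wavelength Laser wavelength in metres (default 780 nm).
#' @param spot_diameter Illuminated spot diameter in metres.
#' @param farfield_distance Observation distance in metres; must satisfy the
#'   far-field condition.
#' @param pixel_gain Pattern shift per unit tilt, pixels/radian; must be > 0.
#' @param frame_shape Integer vector `c(H, W)` of the recorded frame in pixels.
#' @param frame_rate Acquisition rate in Hz (default 200).
#' @param aperture_fraction Aperture diameter as a fraction of the grid
#'   (controls speckle grain size).
#' @param noise_fraction Camera noise: SD of additive Gaussian intensity noise
#'   as a fraction of the mean intensity (default 0.01).
#' @param quantize_8bit If `TRUE`, frames are quantized to 256 intensity
#'   levels, emulating an 8-bit sensor.
#' @return An object of class `optics_config`.
#' @examples
#' opt <- optics_config(frame_shape = c(64, 64), frame_rate = 50)
#' tilt_to_pixel_shift(1e-3, opt)
#' @export
optics_config <- function(wavelength = 780e-9,
                          spot_diameter = 1e-3,
                          farfield_distance = 0.7,
                          pixel_gain = 4000,
                          frame_shape = c(128, 256),
                          frame_rate = 200,
                          aperture_fraction = 0.12,
                          noise_fraction = 0.01,
                          quantize_8bit = FALSE) {
  stopifnot(is.numeric(wavelength), wavelength > 0,
            is.numeric(spot_diameter), spot_diameter > 0,
            is.numeric(farfield_distance), farfield_distance > 0,
            length(frame_shape) == 2, all(frame_shape >= 8))
  if (!is.numeric(pixel_gain) || pixel_gain <= 0)
    stop("'pixel_gain' must be > 0", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("'frame_rate' must be > 0", call. = FALSE)
  if (aperture_fraction <= 0 || aperture_fraction > 1)
    stop("'aperture_fraction' must be in (0, 1]", call. = FALSE)
  if (noise_fraction < 0)
    stop("'noise_fraction' must be >= 0", call. = FALSE)
  crit <- spot_diameter^2 / (4 * wavelength)
  if (farfield_distance <= crit)
    stop(sprintf(paste0("far-field condition violated: need farfield_distance",
                        " > spot_diameter^2/(4*wavelength) = %.4g m"), crit),
         call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength),
                 spot_diameter = as.numeric(spot_diameter),
                 farfield_distance = as.numeric(farfield_distance),
                 pixel_gain = as.numeric(pixel_gain),
                 frame_shape = as.integer(frame_shape),
                 frame_rate = as.numeric(frame_rate),
                 aperture_fraction = as.numeric(aperture_fraction),
                 noise_fraction = as.numeric(noise_fraction),
                 quantize_8bit = isTRUE(quantize_8bit)),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  wavelength     : %.0f nm\n", x$wavelength * 1e9))
  cat(sprintf("  spot diameter  : %.2g m\n", x$spot_diameter))
  cat(sprintf("  far-field dist : %.2g m (critical %.2g m)\n",
              x$farfield_distance, x$spot_diameter^2 / (4 * x$wavelength)))
  cat(sprintf("  pixel gain     : %g px/rad\n", x$pixel_gain))
  cat(sprintf("  frame shape    : %d x %d px @ %g Hz\n",
              x$frame_shape[1], x$frame_shape[2], x$frame_rate))
  invisible(x)
}

#' Convert a surface tilt to a speckle-pattern shift
#'
#' Applies the small-angle linear law: shift in pixels equals
#' `pixel_gain * tilt`. Exactly linear with zero intercept.
#'
#' @param tilt Tilt angle(s) in radians.
#' @param optics An [optics_config()].
#' @return Shift(s) in pixels, same length as `tilt`.
#' @export
tilt_to_pixel_shift <- function(tilt, optics) {
  stopifnot(inherits(optics, "optics_config"))
  optics$pixel_gain * tilt
}
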