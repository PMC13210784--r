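# Readers/writers: frame stacks (multi-page TIFF or raw binary + JSON
# sidecar), displacement/position/respiratory traces (CSV + JSON metadata),
# ground truth and manifests.

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path, required) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar ", sc, " lacks required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta
}

#' Write a frame stack to disk
#'
#' Two on-disk formats, both accompanied by a JSON sidecar
#' (`<path>.json`) holding `frames`, `height`, `width`, `fs_hz`, `dtype`
#' and `byte_order`:
#' * `raw`: frames as little-endian float64, bit-exact round trip;
#' * `tiff`: multi-page 32-bit float TIFF of the intensities scaled by
#'   their maximum (`scale` recorded in the sidecar), lossy only through
#'   the float32 representation.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path (`.tif`/`.tiff` selects TIFF in auto mode).
#' @param format `"auto"`, `"tiff"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, format = c("auto", "tiff", "raw")) {
  stopifnot(inherits(stack, "frame_stack"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  d <- dim(stack$frames)
  meta <- list(frames = d[1], height = d[2], width = d[3], fs_hz = stack$fs,
               dtype = stack$dtype, byte_order = "little", format = format)
  if (format == "tiff") {
    scale <- max(stack$frames)
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(d[1]), function(k) stack$frames[k, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    meta$scale <- scale
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (k in seq_len(d[1]))
      writeBin(as.vector(stack$frames[k, , ]), con,
               size = 8, endian = "little")
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path Path previously given to [write_frame_stack()].
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read_sidecar(path, c("frames", "height", "width", "fs_hz", "dtype"))
  n <- meta$frames; h <- meta$height; w <- meta$width
  arr <- array(0, dim = c(n, h, w))
  if (identical(meta$format, "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != n)
      stop(sprintf("sidecar declares %d frames but file holds %d",
                   n, length(pages)), call. = FALSE)
    scale <- if (is.null(meta$scale)) 1 else meta$scale
    for (k in seq_len(n)) arr[k, , ] <- pages[[k]] * scale
  } else {
    expected <- n * h * w
    vals <- readBin(path, "double", n = expected + 1, size = 8,
                    endian = "little")
    if (length(vals) != expected)
      stop(sprintf("sidecar declares %d frames (%d values) but file holds %d",
                   n, expected, length(vals)), call. = FALSE)
    for (k in seq_len(n))
      arr[k, , ] <- matrix(vals[((k - 1) * h * w + 1):(k * h * w)], h, w)
  }
  frame_stack(arr, as.numeric(meta$fs_hz), dtype = meta$dtype)
}

#' Write a displacement or position trace as CSV
#'
#' Columns `frame_index, dx_px, dy_px` (displacement) or
#' `frame_index, x_px, y_px` (position), with the sampling rate in a JSON
#' sidecar.
#'
#' @param trace A `displacement_trace` or `position_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "displacement_trace")) {
    df <- data.frame(frame_index = seq_along(trace$dx),
                     dx_px = trace$dx, dy_px = trace$dy)
    kind <- "displacement"
  } else if (inherits(trace, "position_trace")) {
    df <- data.frame(frame_index = seq_along(trace$x),
                     x_px = trace$x, y_px = trace$y)
    kind <- "position"
  } else {
    stop("expected a displacement_trace or position_trace", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = trace$fs, kind = kind),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A `displacement_trace` or `position_trace`.
#' @export
read_trace_csv <- function(path) {
  meta <- read_sidecar(path, c("fs_hz", "kind"))
  df <- utils::read.csv(path)
  if (meta$kind == "displacement") {
    structure(list(dx = df$dx_px, dy = df$dy_px, fs = as.numeric(meta$fs_hz)),
              class = "displacement_trace")
  } else {
    structure(list(x = df$x_px, y = df$y_px, fs = as.numeric(meta$fs_hz)),
              class = "position_trace")
  }
}

#' Write a respiratory signal with detected peaks
#'
#' CSV columns `sample_index, value_px, is_peak`; a JSON sidecar carries the
#' sampling rate and summary (`bpm`, `n_peaks` and, when supplied,
#' `rms_ratio_xy`).
#'
#' @param signal A `respiratory_signal`.
#' @param peaks A `breath_peaks` result.
#' @param path Output CSV path.
#' @param rms_ratio_xy Optional horizontal/vertical RMS ratio.
#' @return `path`, invisibly.
#' @export
write_respiratory_csv <- function(signal, peaks, path, rms_ratio_xy = NULL) {
  stopifnot(inherits(signal, "respiratory_signal"),
            inherits(peaks, "breath_peaks"))
  df <- data.frame(sample_index = seq_along(signal$values),
                   value_px = signal$values,
                   is_peak = seq_along(signal$values) %in% peaks$indices)
  utils::write.csv(df, path, row.names = FALSE)
  bpm <- if (length(peaks$indices) >= 2) breathing_rate(peaks) else NA
  meta <- list(fs_hz = signal$fs, bpm = bpm, n_peaks = length(peaks$indices))
  if (!is.null(rms_ratio_xy)) meta$rms_ratio_xy <- rms_ratio_xy
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a respiratory CSV written by [write_respiratory_csv()]
#'
#' @param path CSV path.
#' @return List with `signal` (`respiratory_signal`) and `peaks`
#'   (`breath_peaks`).
#' @export
read_respiratory_csv <- function(path) {
  meta <- read_sidecar(path, "fs_hz")
  df <- utils::read.csv(path)
  signal <- structure(list(values = df$value_px, fs = as.numeric(meta$fs_hz)),
                      class = "respiratory_signal")
  peaks <- structure(list(indices = df$sample_index[df$is_peak],
                          min_sep = NA_real_, fs = as.numeric(meta$fs_hz)),
                     class = "breath_peaks")
  list(signal = signal, peaks = peaks)
}

#' Write ground truth or a classification result as JSON
#'
#' @param x A `ground_truth` or `recording_classification`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(x, path) {
  if (inherits(x, "ground_truth")) {
    out <- list(class = x$recording_class,
                events = x$events,
                subject_id = x$subject_id, posture = x$posture)
  } else if (inherits(x, "recording_classification")) {
    out <- list(label = x$label, amax = x$amax, thr = x$thr_used,
                events = x$events)
  } else {
    stop("expected a ground_truth or recording_classification", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write / read a run manifest
#'
#' A manifest is a data frame with columns `recording_id`, `subject_id`,
#' `posture`, `true_class` and `path` (location of the recording's frame
#' stack or signal).
#'
#' @param manifest The manifest data frame.
#' @param path CSV path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  req <- c("recording_id", "subject_id", "posture", "true_class", "path")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$recording_id))
    stop("manifest recording ids must be unique", call. = FALSE)
  utils::write.csv(manifest[req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (anyDuplicated(df$recording_id))
    stop("manifest recording ids must be unique", call. = FALSE)
  df
}

#' Pipeline configuration
#'
#' Bundles every tunable of the processing chain into one serializable
#' object: optics (for simulation), bandpass spec, detection config,
#' tracker background length, CV scheme and threshold grid, and seeds.
#' Round-trips through JSON bit-exactly via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param optics An [optics_config()].
#' @param filter A [filter_spec()].
#' @param detection A [detection_config()].
#' @param n_background Tracker background frames.
#' @param scheme CV scheme.
#' @param grid Threshold grid.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(optics = optics_config(),
                            filter = filter_spec(),
                            detection = detection_config(),
                            n_background = 50,
                            scheme = "class_wise",
                            grid = threshold_grid(),
                            seed = 1) {
  structure(list(optics = optics, filter = filter, detection = detection,
                 n_background = as.numeric(n_background), scheme = scheme,
                 grid = as.numeric(grid), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(lapply(config, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    optics = do.call(optics_config, raw$optics),
    filter = do.call(filter_spec, raw$filter),
    detection = do.call(detection_config, raw$detection),
    n_background = raw$n_background,
    scheme = raw$scheme,
    grid = raw$grid,
    seed = raw$seed)
}
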