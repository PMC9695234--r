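#' Device B-mode crop configuration
#'
#' The rectangular region of the raw video frame that contains the B-mode
#' image for one ultrasound device, plus the device's nominal frame rate.
#' Coordinates are 0-based and half-open: the crop keeps indices
#' `[x_min, x_max)` along the axis named by `axis_order` and `[y_min, y_max)`
#' along the other, so (0, 400) yields an extent of 400 pixels.
#'
#' @param device_id Short text label for the device.
#' @param x_min,x_max,y_min,y_max Pixel indices of the B-mode rectangle.
#' @param fps Nominal frames per second (positive integer).
#' @param axis_order `"first-axis-is-x"` (default: x indexes the first raster
#'   axis, i.e. matrix rows) or `"first-axis-is-y"`.
#' @return An object of class `usseg_device`.
#' @export
device_crop_config <- function(device_id, x_min, x_max, y_min, y_max, fps,
                               axis_order = c("first-axis-is-x",
                                              "first-axis-is-y")) {
  axis_order <- match.arg(axis_order)
  fps <- as.integer(round(fps)) # integer modulus sampling; round container rates
  if (is.na(fps) || fps < 1L) stop("fps must be a positive integer")
  for (nm in c("x_min", "x_max", "y_min", "y_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop(nm, " must be a single non-negative integer")
  }
  if (!(x_min < x_max)) stop("x_min (", x_min, ") must be < x_max (", x_max, ")")
  if (!(y_min < y_max)) stop("y_min (", y_min, ") must be < y_max (", y_max, ")")
  structure(list(device_id = as.character(device_id),
                 x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 fps = fps, axis_order = axis_order),
            class = "usseg_device")
}

#' Read a device table from YAML
#'
#' The file holds one entry per ultrasound device, with fields exactly as
#' [device_crop_config()], either as a top-level sequence or under a
#' `devices:` key.
#'
#' @param path YAML file path.
#' @return Named list of `usseg_device`, keyed by `device_id`.
#' @export
read_devices_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$devices)) doc$devices else doc
  if (!is.list(entries) || length(entries) == 0L)
    stop("no device entries found in ", path)
  devs <- lapply(entries, function(e) {
    do.call(device_crop_config, e[intersect(names(e),
      c("device_id", "x_min", "x_max", "y_min", "y_max", "fps", "axis_order"))])
  })
  stats::setNames(devs, vapply(devs, `[[`, character(1), "device_id"))
}

#' A single grayscale examination frame
#'
#' @param pixels Numeric matrix, intensities in \[0, 255\].
#' @param frame_id 0-based index within the source video.
#' @param fps Frames per second of the source (fixes `timestamp_s =
#'   frame_id / fps`).
#' @param source_id Examination identifier.
#' @return An object of class `usseg_frame` with fields `pixels`, `frame_id`,
#'   `timestamp_s`, `source_id`.
#' @export
us_frame <- function(pixels, frame_id, fps, source_id = "exam") {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  frame_id <- as.integer(frame_id)
  structure(list(pixels = pixels, frame_id = frame_id,
                 timestamp_s = frame_id / fps,
                 source_id = as.character(source_id)),
            class = "usseg_frame")
}

new_frameset <- function(frames, crop_applied = NULL, fps) {
  ids <- vapply(frames, `[[`, integer(1), "frame_id")
  if (length(ids) > 1L && any(diff(ids) <= 0L))
    stop("frame_ids must be strictly increasing")
  structure(list(frames = frames, crop_applied = crop_applied, fps = fps),
            class = "usseg_frameset")
}

#' @export
print.usseg_frameset <- function(x, ...) {
  cat(sprintf("<usseg_frameset> %d frames, fps %s, crop %s\n",
              length(x$frames), x$fps,
              if (is.null(x$crop_applied)) "none" else
                x$crop_applied$device_id))
  invisible(x)
}

#' Crop a frame to the device's B-mode rectangle
#'
#' Extracts the exact pixel sub-rectangle `[x_min, x_max) x [y_min, y_max)`
#' (no interpolation). Which raster axis "x" refers to is taken from the
#' device's `axis_order`.
#'
#' @param frame A [us_frame()].
#' @param cfg A [device_crop_config()].
#' @return The cropped `usseg_frame` (same `frame_id`/timestamp).
#' @export
crop_frame <- function(frame, cfg) {
  stopifnot(inherits(frame, "usseg_frame"), inherits(cfg, "usseg_device"))
  px <- frame$pixels
  if (cfg$axis_order == "first-axis-is-x") {
    lim1 <- c(cfg$x_min, cfg$x_max, "x"); lim2 <- c(cfg$y_min, cfg$y_max, "y")
  } else {
    lim1 <- c(cfg$y_min, cfg$y_max, "y"); lim2 <- c(cfg$x_min, cfg$x_max, "x")
  }
  m1 <- as.integer(lim1[2]); m2 <- as.integer(lim2[2])
  if (m1 > nrow(px))
    stop(lim1[3], "_max (", m1, ") exceeds the frame extent (", nrow(px),
         ") along the first raster axis")
  if (m2 > ncol(px))
    stop(lim2[3], "_max (", m2, ") exceeds the frame extent (", ncol(px),
         ") along the second raster axis")
  sub <- px[(as.integer(lim1[1]) + 1L):m1, (as.integer(lim2[1]) + 1L):m2,
            drop = FALSE]
  out <- frame
  out$pixels <- sub
  out
}

luminance <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  if (dim(a)[3] >= 3L)
    0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  else a[, , 1]
}

# Read one grayscale frame matrix (0..255) from a PNG file.
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  luminance(a) * 255
}

#' Extract frames from an examination at a fixed sample time
#'
#' Implements the frame-sampling rule of the preprocessing stage: with
#' sampling stride `k = round(fps * sample_time_s)`, exactly the frames whose
#' 0-based `frame_id` is a multiple of `k` are kept, and each kept frame is
#' cropped to the device's B-mode rectangle via [crop_frame()]. Colour frames
#' are converted to grayscale by luminance before cropping.
#'
#' @param video_source One of: a directory of PNG frames (frame order =
#'   lexicographic file order, ids 0-based), a list of numeric matrices, or a
#'   `usseg_frameset` (whose stored `frame_id`s are used, making repeated
#'   sampling idempotent).
#' @param cfg A [device_crop_config()]; supplies `fps` and the crop. Pass
#'   `crop = FALSE` to sample without cropping.
#' @param sample_time_s Sampling interval in seconds (default 1).
#' @param source_id Examination identifier used in frame metadata and output
#'   file names.
#' @param crop Apply the device crop to kept frames (default TRUE).
#' @return A `usseg_frameset` of the kept (cropped) frames.
#' @export
extract_frames <- function(video_source, cfg, sample_time_s = 1,
                           source_id = NULL, crop = TRUE) {
  stopifnot(inherits(cfg, "usseg_device"))
  if (!is.numeric(sample_time_s) || sample_time_s <= 0)
    stop("sample_time_s must be a positive number")
  k <- as.integer(round(cfg$fps * sample_time_s))
  if (k < 1L) stop("sampling stride round(fps * sample_time_s) must be >= 1")

  if (inherits(video_source, "usseg_frameset")) {
    frames <- video_source$frames
  } else if (is.character(video_source)) {
    if (!dir.exists(video_source)) stop("cannot read video source: ",
                                        video_source)
    files <- sort(list.files(video_source, pattern = "\\.png$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames found in ", video_source)
    if (is.null(source_id)) source_id <- basename(video_source)
    # only decode the frames the modulus rule keeps
    keep_idx <- which((seq_along(files) - 1L) %% k == 0L)
    frames <- lapply(keep_idx, function(i)
      us_frame(read_frame_png(files[i]), i - 1L, cfg$fps, source_id))
  } else if (is.list(video_source)) {
    if (is.null(source_id)) source_id <- "exam"
    frames <- lapply(seq_along(video_source), function(i)
      us_frame(video_source[[i]], i - 1L, cfg$fps, source_id))
  } else stop("unsupported video source")

  kept <- Filter(function(f) f$frame_id %% k == 0L, frames)
  if (crop) kept <- lapply(kept, crop_frame, cfg = cfg)
  new_frameset(kept, crop_applied = if (crop) cfg else NULL, fps = cfg$fps)
}

#' Write a frame set to disk as 8-bit grayscale PNGs
#'
#' File names are deterministic: `<source_id>_f<frame_id zero-padded to 6>.png`,
#' so masks can be paired by name later.
#'
#' @param frameset A `usseg_frameset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_frameset <- function(frameset, dir) {
  stopifnot(inherits(frameset, "usseg_frameset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(frameset$frames, function(f) {
    p <- file.path(dir, sprintf("%s_f%06d.png", f$source_id, f$frame_id))
    png::writePNG(f$pixels / 255, p)
    p
  }, character(1))
  invisible(paths)
}
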