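#' Lesion description for a synthetic phantom
#'
#' One focal lesion rendered into a synthetic B-mode frame: an ellipse with
#' optional boundary irregularity, an echogenicity shift relative to the
#' parenchyma (negative = hypoechoic, as most focal liver lesions appear in
#' B-mode; positive = hyperechoic, e.g. hemangioma-like), and edge softness.
#'
#' @param center Lesion center (x, y) in pixel coordinates.
#' @param radii Semi-axes (rx, ry) in pixels.
#' @param echogenicity_offset Signed intensity shift in \[-255, 255\].
#' @param boundary_roughness Relative radial perturbation amplitude in
#'   \[0, 1\]; 0 gives an exact ellipse.
#' @param blur_px Gaussian edge softness (sigma, pixels) applied to the
#'   intensity profile only, never to the ground-truth mask.
#' @return An object of class `usseg_lesion`.
#' @export
lesion_spec <- function(center, radii, echogenicity_offset = -70,
                        boundary_roughness = 0, blur_px = 1) {
  stopifnot(length(center) == 2L, length(radii) == 2L, all(radii > 0),
            boundary_roughness >= 0, boundary_roughness <= 1, blur_px >= 0)
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 echogenicity_offset = as.numeric(echogenicity_offset),
                 boundary_roughness = as.numeric(boundary_roughness),
                 blur_px = as.numeric(blur_px)),
            class = "usseg_lesion")
}

#' Specification of a synthetic B-mode examination
#'
#' Generative description of a speckle-textured grayscale examination with
#' exact ground-truth lesion masks. Identical (spec, seed) pairs render
#' bit-identical output. The frame rate is constrained to the 7-12 fps range
#' of handheld B-mode video.
#'
#' @param width,height Frame extent in pixels.
#' @param fps Frames per second, integer in \[7, 12\].
#' @param duration_s Examination duration in seconds.
#' @param lesions List of [lesion_spec()].
#' @param speckle_scale Relative amplitude of the multiplicative speckle
#'   texture (a smoothed Rayleigh field of unit mean), positive.
#' @param background_level Mean parenchyma intensity in \[0, 255\].
#' @param drift_px_per_s Slow per-axis translation of all lesions, emulating
#'   breathing/probe drift (pixels per second, applied to both axes).
#' @param seed Integer seed; all randomness in rendering derives from it.
#' @return An object of class `usseg_phantom_spec`.
#' @export
phantom_spec <- function(width = 128L, height = 128L, fps = 10L,
                         duration_s = 1, lesions = list(),
                         speckle_scale = 0.25, background_level = 120,
                         drift_px_per_s = 0, seed = 1L) {
  fps <- as.integer(fps)
  if (fps < 7L || fps > 12L) stop("fps must be an integer in [7, 12]")
  stopifnot(width >= 1L, height >= 1L, duration_s > 0, speckle_scale > 0,
            background_level >= 0, background_level <= 255)
  if (inherits(lesions, "usseg_lesion")) lesions <- list(lesions)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration_s = as.numeric(duration_s),
                 lesions = lesions, speckle_scale = as.numeric(speckle_scale),
                 background_level = as.numeric(background_level),
                 drift_px_per_s = as.numeric(drift_px_per_s),
                 seed = as.integer(seed)),
            class = "usseg_phantom_spec")
}

# Evaluate the (possibly roughened) lesion support on the pixel-center grid.
# Roughness uses low-order harmonics with amplitudes/phases derived
# deterministically from (seed, lesion index) so the shape is stable over
# time while the center drifts.
lesion_support <- function(les, cx, cy, width, height, seed, index) {
  dx <- (cx - les$center[1]) / les$radii[1]
  dy <- (cy - les$center[2]) / les$radii[2]
  r2 <- dx^2 + dy^2
  rho <- 1
  if (les$boundary_roughness > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer((as.numeric(seed) * 977 + index * 131) %% 2147483647))
    amp <- stats::runif(4); amp <- amp / sum(amp)
    phase <- stats::runif(4, 0, 2 * pi)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    theta <- atan2(dy, dx)
    rho <- 1 + les$boundary_roughness *
      Reduce(`+`, lapply(1:4, function(h) amp[h] * cos((h + 1) * theta + phase[h])))
  }
  r2 <= rho^2
}

# Mean-one multiplicative speckle texture: a Rayleigh(1) field smoothed with
# a circular 3x3 box (circular boundary keeps the mean exact), rescaled to
# unit mean, with its deviation scaled by speckle_scale.
speckle_texture <- function(width, height, speckle_scale) {
  raw <- matrix(sqrt(-2 * log(stats::runif(width * height))), height, width)
  sh <- function(m, di, dj) {
    ri <- (seq_len(nrow(m)) - 1L + di) %% nrow(m) + 1L
    cj <- (seq_len(ncol(m)) - 1L + dj) %% ncol(m) + 1L
    m[ri, cj, drop = FALSE]
  }
  sm <- Reduce(`+`, lapply(-1:1, function(di)
    Reduce(`+`, lapply(-1:1, function(dj) sh(raw, di, dj))))) / 9
  1 + speckle_scale * (sm / sqrt(pi / 2) - 1)
}

#' Render one phantom frame and its exact ground-truth mask
#'
#' The frame is `clip((background + sum of lesion intensity profiles) *
#' speckle, 0, 255)`; the mask is the union of the crisp lesion supports
#' (before any edge blur), translated by `drift_px_per_s * t_s`. Rendering is
#' deterministic in (spec, t_s): the speckle RNG stream is derived from the
#' spec seed and the frame index.
#'
#' @param spec A [phantom_spec()].
#' @param t_s Time in seconds from examination start, in
#'   \[0, `duration_s`\].
#' @return list with `frame` (a [us_frame()]) and `mask` (a
#'   [binary_mask()]).
#' @export
render_frame <- function(spec, t_s = 0) {
  stopifnot(inherits(spec, "usseg_phantom_spec"))
  if (t_s < 0 || t_s > spec$duration_s)
    stop("t_s must lie in [0, duration_s]")
  W <- spec$width; H <- spec$height
  frame_id <- as.integer(round(t_s * spec$fps))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer((as.numeric(spec$seed) * 7919 + frame_id) %% 2147483647))

  cx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  cy <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  drift <- spec$drift_px_per_s * t_s
  signal <- matrix(spec$background_level, H, W)
  mask <- matrix(0, H, W)
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    les$center <- les$center + drift
    supp <- lesion_support(les, cx, cy, W, H, spec$seed, li)
    if (!any(supp)) {
      warning("lesion ", li, " lies fully outside the canvas; omitted")
      next
    }
    mask[supp] <- 1
    prof <- supp * 1
    if (les$blur_px > 0) prof <- EBImage::gblur(prof, sigma = les$blur_px)
    signal <- signal + les$echogenicity_offset * prof
  }
  tex <- speckle_texture(W, H, spec$speckle_scale)
  px <- pmin(pmax(signal * tex, 0), 255)
  list(frame = us_frame(px, frame_id, spec$fps,
                        source_id = sprintf("phantom%06d", spec$seed)),
       mask = binary_mask(mask))
}

#' Render a full examination to disk
#'
#' Writes all `fps * duration_s` frames as 8-bit grayscale PNGs (a lossless
#' frame-directory "video" that [extract_frames()] can consume), plus exact
#' ground-truth masks for the frames the ingest stage samples at a 1-second
#' interval (ids that are multiples of `fps`), and a JSON manifest of the
#' spec and seed.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory; `frames/` and `masks/` are created
#'   inside.
#' @return Invisibly, list with `frames_dir`, `masks_dir`, `manifest`,
#'   `n_frames`, `n_masks`.
#' @export
render_examination <- function(spec, out_dir) {
  stopifnot(inherits(spec, "usseg_phantom_spec"), spec$duration_s >= 1)
  frames_dir <- file.path(out_dir, "frames")
  masks_dir <- file.path(out_dir, "masks")
  dir.create(frames_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(masks_dir, showWarnings = FALSE, recursive = TRUE)
  n <- as.integer(spec$fps * spec$duration_s)
  n_masks <- 0L
  for (id in seq_len(n) - 1L) {
    rf <- render_frame(spec, id / spec$fps)
    fname <- sprintf("%s_f%06d.png", rf$frame$source_id, id)
    png::writePNG(rf$frame$pixels / 255, file.path(frames_dir, fname))
    if (id %% spec$fps == 0L) {
      write_mask(rf$mask, file.path(masks_dir, mask_filename(fname)))
      n_masks <- n_masks + 1L
    }
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(spec = unclass_deep(spec), n_frames = n,
                            n_masks = n_masks),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(frames_dir = frames_dir, masks_dir = masks_dir,
                 manifest = manifest, n_frames = n, n_masks = n_masks))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Generate the default phantom training suite
#'
#' A reproducible collection of single-frame phantoms emulating the variety
#' of a clinical B-mode dataset: mostly single lesions of moderate relative
#' size, with dedicated small-lesion cases and adjacent-lesion pairs, and a
#' minority of hyperechoic lesions. Lesion-area fractions span roughly
#' 0.5\%-20\% of the frame.
#'
#' @param n Number of phantoms (default 200).
#' @param width,height Frame extent in pixels.
#' @param seed Integer seed for the whole suite.
#' @param small_fraction,multi_fraction Proportion of dedicated small-lesion
#'   (area fraction 0.5-2\%) and two-lesion phantoms.
#' @return List of length `n`; each element has `frame` (matrix, 0-255),
#'   `mask` (a [binary_mask()]), `spec`, and `source_id`.
#' @export
phantom_suite <- function(n = 200L, width = 128L, height = 128L, seed = 1L,
                          small_fraction = 0.15, multi_fraction = 0.15) {
  set.seed(seed)
  kinds <- sample(c(rep("small", round(n * small_fraction)),
                    rep("multi", round(n * multi_fraction)),
                    rep("single", n - round(n * small_fraction) -
                                  round(n * multi_fraction))))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- kinds[i]
    hyper <- stats::runif(1) < 0.2
    offset <- if (hyper) stats::runif(1, 40, 80) else stats::runif(1, -90, -50)
    mk_lesion <- function(frac) {
      aspect <- stats::runif(1, 0.6, 1.6)
      area <- frac * width * height
      rx <- sqrt(area * aspect / pi); ry <- sqrt(area / aspect / pi)
      cx <- stats::runif(1, rx + 2, width - rx - 2)
      cy <- stats::runif(1, ry + 2, height - ry - 2)
      lesion_spec(center = c(cx, cy), radii = c(rx, ry),
                  echogenicity_offset = offset,
                  boundary_roughness = stats::runif(1, 0, 0.3), blur_px = 1)
    }
    lesions <- switch(kind,
      small = list(mk_lesion(stats::runif(1, 0.005, 0.02))),
      single = list(mk_lesion(stats::runif(1, 0.02, 0.20))),
      multi = list(mk_lesion(stats::runif(1, 0.02, 0.08)),
                   mk_lesion(stats::runif(1, 0.02, 0.08))))
    sp <- phantom_spec(width = width, height = height,
                       fps = sample(7:12, 1), duration_s = 1,
                       lesions = lesions, speckle_scale = 0.25,
                       background_level = stats::runif(1, 100, 140),
                       drift_px_per_s = 0,
                       seed = as.integer((as.numeric(seed) * 100003 + i) %%
                                         2147483647))
    rf <- render_frame(sp, 0)
    out[[i]] <- list(frame = rf$frame$pixels, mask = rf$mask, spec = sp,
                     source_id = sprintf("phantom%04d", i))
  }
  out
}

#' Write a phantom suite to frame/mask directories
#'
#' Produces the on-disk layout the training pipeline's [assemble_dataset()]
#' reads: `frames/<id>.png` and `masks/<id>-mask.png`.
#'
#' @param suite Result of [phantom_suite()].
#' @param dir Output directory.
#' @return Invisibly, list with `frames_dir` and `masks_dir`.
#' @export
write_phantom_suite <- function(suite, dir) {
  frames_dir <- file.path(dir, "frames"); masks_dir <- file.path(dir, "masks")
  dir.create(frames_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(masks_dir, showWarnings = FALSE, recursive = TRUE)
  for (ph in suite) {
    fname <- paste0(ph$source_id, "_f000000.png")
    png::writePNG(ph$frame / 255, file.path(frames_dir, fname))
    write_mask(ph$mask, file.path(masks_dir, mask_filename(fname)))
  }
  invisible(list(frames_dir = frames_dir, masks_dir = masks_dir))
}
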