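test_that("a lesion-free phantom has mean intensity near background level", {
  sp <- phantom_spec(width = 256, height = 256, background_level = 120,
                     seed = 4)
  rf <- render_frame(sp, 0)
  expect_equal(sum(rf$mask$pixels), 0)
  expect_lt(abs(mean(rf$frame$pixels) - 120), 3)
})

test_that("an exact ellipse's mask area matches the analytic area", {
  les <- lesion_spec(center = c(64, 60), radii = c(20, 12),
                     boundary_roughness = 0, blur_px = 0)
  sp <- phantom_spec(width = 128, height = 128, lesions = list(les), seed = 2)
  rf <- render_frame(sp, 0)
  area <- pi * 20 * 12
  # Ramanujan perimeter bound for the pixelation error
  perim <- pi * (3 * (20 + 12) - sqrt((3 * 20 + 12) * (20 + 3 * 12)))
  expect_lt(abs(sum(rf$mask$pixels) - area), perim)
})

test_that("rendering is bit-identical for identical spec and seed", {
  les <- lesion_spec(center = c(40, 40), radii = c(10, 8),
                     boundary_roughness = 0.2)
  sp <- phantom_spec(width = 96, height = 96, lesions = list(les), seed = 77)
  a <- render_frame(sp, 0); b <- render_frame(sp, 0)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$mask$pixels, b$mask$pixels)
  # a different seed changes the speckle realisation
  sp2 <- phantom_spec(width = 96, height = 96, lesions = list(les), seed = 78)
  expect_false(identical(render_frame(sp2, 0)$frame$pixels, a$frame$pixels))
})

test_that("examinations write fps*duration frames and per-second masks", {
  dir <- withr::local_tempdir()
  les <- lesion_spec(center = c(30, 30), radii = c(8, 8))
  sp <- phantom_spec(width = 64, height = 64, fps = 10, duration_s = 12,
                     lesions = list(les), seed = 9)
  out <- render_examination(sp, dir)
  expect_equal(out$n_frames, 120L)
  expect_equal(out$n_masks, 12L)
  expect_length(list.files(out$frames_dir, pattern = "\\.png$"), 120L)
  expect_length(list.files(out$masks_dir, pattern = "\\.png$"), 12L)
  expect_true(file.exists(out$manifest))
})

test_that("the ingest stage recovers rendered frames pixel-identically", {
  dir <- withr::local_tempdir()
  les <- lesion_spec(center = c(20, 25), radii = c(6, 9))
  sp <- phantom_spec(width = 48, height = 48, fps = 8, duration_s = 3,
                     lesions = list(les), drift_px_per_s = 1.5, seed = 21)
  render_examination(sp, dir)
  dev <- device_crop_config("phantom", 0, 48, 0, 48, fps = 8)
  fs <- extract_frames(file.path(dir, "frames"), dev, sample_time_s = 1)
  expect_length(fs$frames, 3L)
  for (k in 0:2) {
    direct <- render_frame(sp, k)$frame$pixels
    # PNG quantizes to 8 bits; compare at that resolution
    expect_equal(fs$frames[[k + 1]]$pixels, round(direct * 255 / 255),
                 tolerance = 0.51)
    expect_equal(fs$frames[[k + 1]]$frame_id, k * 8L)
  }
})

test_that("zero drift keeps every ground-truth mask identical", {
  les <- lesion_spec(center = c(30, 30), radii = c(9, 7),
                     boundary_roughness = 0.15)
  sp <- phantom_spec(width = 64, height = 64, fps = 7, duration_s = 3,
                     lesions = list(les), drift_px_per_s = 0, seed = 13)
  m0 <- render_frame(sp, 0)$mask$pixels
  for (t in 1:3)
    expect_identical(render_frame(sp, t)$mask$pixels, m0)
  # with drift, the mask moves
  spd <- phantom_spec(width = 64, height = 64, fps = 7, duration_s = 3,
                      lesions = list(les), drift_px_per_s = 3, seed = 13)
  expect_false(identical(render_frame(spd, 2)$mask$pixels, m0))
})

test_that("two adjacent lesions stay separate connected components", {
  # gap of 2 px between the inner edges
  l1 <- lesion_spec(center = c(30, 40), radii = c(10, 10), blur_px = 0)
  l2 <- lesion_spec(center = c(52, 40), radii = c(10, 10), blur_px = 0)
  sp <- phantom_spec(width = 96, height = 96, lesions = list(l1, l2),
                     seed = 30)
  m <- render_frame(sp, 0)$mask$pixels
  lab <- EBImage::bwlabel(m)
  expect_equal(max(lab), 2)
})

test_that("a lesion fully outside the canvas warns and is omitted", {
  les <- lesion_spec(center = c(500, 500), radii = c(5, 5))
  sp <- phantom_spec(width = 64, height = 64, lesions = list(les), seed = 3)
  expect_warning(rf <- render_frame(sp, 0), "outside")
  expect_equal(sum(rf$mask$pixels), 0)
})

test_that("lesion-area fraction is controllable within 2% absolute", {
  set.seed(55)
  for (p in c(0.01, 0.05, 0.10, 0.20)) {
    r <- sqrt(p * 128 * 128 / pi)
    les <- lesion_spec(center = c(64, 64), radii = c(r, r),
                       boundary_roughness = 0, blur_px = 0)
    sp <- phantom_spec(width = 128, height = 128, lesions = list(les),
                       seed = round(p * 1000))
    frac <- mean(render_frame(sp, 0)$mask$pixels)
    expect_lt(abs(frac - p), 0.02)
  }
})

test_that("the default suite spans small, moderate and multi-lesion cases", {
  suite <- phantom_suite(n = 40, seed = 5)
  expect_length(suite, 40L)
  fracs <- vapply(suite, function(s) mean(s$mask$pixels), numeric(1))
  expect_gt(max(fracs), 0.08)
  expect_lt(min(fracs), 0.03)
  n_lesions <- vapply(suite, function(s) length(s$spec$lesions), numeric(1))
  expect_true(any(n_lesions == 2))
  # every mask is strictly binary, every frame in [0, 255]
  for (s in suite[1:5]) {
    expect_true(all(s$mask$pixels %in% c(0, 1)))
    expect_true(min(s$frame) >= 0 && max(s$frame) <= 255)
  }
  # reproducibility of the whole suite
  suite2 <- phantom_suite(n = 40, seed = 5)
  expect_identical(suite[[17]]$frame, suite2[[17]]$frame)
})

test_that("suites round-trip to the on-disk training layout", {
  dir <- withr::local_tempdir()
  suite <- phantom_suite(n = 4, width = 48, height = 48, seed = 19)
  out <- write_phantom_suite(suite, dir)
  expect_length(list.files(out$frames_dir), 4L)
  expect_length(list.files(out$masks_dir), 4L)
  ds <- assemble_dataset(out$frames_dir, out$masks_dir, resize_to = 32)
  expect_length(ds$x, 4L)
})

test_that("frame rates outside the handheld 7-12 fps range are rejected", {
  expect_error(phantom_spec(fps = 5), "fps")
  expect_error(phantom_spec(fps = 30), "fps")
})
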