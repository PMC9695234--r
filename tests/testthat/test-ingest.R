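test_that("device crop extracts the exact sub-rectangle", {
  dev <- device_crop_config("arietta", 0, 400, 78, 525, fps = 10)
  fr <- gradient_frame(576, 720)
  cr <- crop_frame(fr, dev)
  expect_equal(dim(cr$pixels), c(400L, 447L))
  # pixel-exact copy, no interpolation
  expect_identical(cr$pixels, fr$pixels[1:400, 79:525])

  # identity crop leaves the frame untouched
  full <- device_crop_config("full", 0, 576, 0, 720, fps = 10)
  expect_identical(crop_frame(fr, full)$pixels, fr$pixels)

  # constant frame, interior crop: all pixels keep the constant
  cst <- us_frame(matrix(42, 100, 100), 0L, 10L)
  sub <- crop_frame(cst, device_crop_config("d", 10, 20, 30, 40, fps = 10))
  expect_equal(dim(sub$pixels), c(10L, 10L))
  expect_true(all(sub$pixels == 42))
})

test_that("axis_order controls which raster axis x indexes", {
  fr <- gradient_frame(60, 90)
  dev_x <- device_crop_config("dx", 5, 25, 10, 40, fps = 8,
                              axis_order = "first-axis-is-x")
  dev_y <- device_crop_config("dy", 5, 25, 10, 40, fps = 8,
                              axis_order = "first-axis-is-y")
  expect_equal(dim(crop_frame(fr, dev_x)$pixels), c(20L, 30L))
  expect_equal(dim(crop_frame(fr, dev_y)$pixels), c(30L, 20L))
  expect_identical(crop_frame(fr, dev_y)$pixels, fr$pixels[11:40, 6:25])
})

test_that("out-of-bounds crops name the offending coordinate", {
  fr <- gradient_frame(100, 100)
  dev <- device_crop_config("d", 0, 120, 0, 50, fps = 10)
  expect_error(crop_frame(fr, dev), "x_max \\(120\\)")
  dev2 <- device_crop_config("d", 0, 50, 0, 130, fps = 10)
  expect_error(crop_frame(fr, dev2), "y_max \\(130\\)")
})

test_that("crop config rejects inverted rectangles and bad fps", {
  expect_error(device_crop_config("d", 40, 10, 0, 5, fps = 10), "x_min")
  expect_error(device_crop_config("d", 0, 10, 50, 5, fps = 10), "y_min")
  expect_error(device_crop_config("d", 0, 10, 0, 5, fps = 0), "fps")
})

test_that("frame sampling keeps exactly the ids that are multiples of the stride", {
  # 10 fps, 30 s -> ids 0, 10, ..., 290
  dev <- device_crop_config("d", 0, 32, 0, 40, fps = 10)
  fs <- extract_frames(constant_video(300), dev, sample_time_s = 1)
  ids <- vapply(fs$frames, `[[`, integer(1), "frame_id")
  expect_identical(ids, as.integer(seq(0, 290, by = 10)))

  # 7 fps (the lower bound of handheld B-mode video), 49 frames -> 7 kept
  dev7 <- device_crop_config("d", 0, 32, 0, 40, fps = 7)
  fs7 <- extract_frames(constant_video(49), dev7, sample_time_s = 1)
  expect_length(fs7$frames, 7L)

  # single-frame video: id 0 always satisfies the modulus rule
  fs1 <- extract_frames(constant_video(1), dev, sample_time_s = 1)
  expect_length(fs1$frames, 1L)
  expect_equal(fs1$frames[[1]]$frame_id, 0L)
})

test_that("kept-frame count obeys floor((N-1)/k)+1 against enumeration", {
  set.seed(404)
  for (rep in 1:12) {
    fps <- sample(7:12, 1)
    n <- sample(1:300, 1)
    st <- sample(c(0.5, 1, 2), 1)
    k <- round(fps * st)
    dev <- device_crop_config("d", 0, 8, 0, 8, fps = fps)
    fs <- extract_frames(constant_video(n, 8, 8), dev, sample_time_s = st)
    enum <- sum((seq_len(n) - 1L) %% k == 0L) # per-frame enumeration oracle
    expect_equal(length(fs$frames), enum)
    expect_equal(length(fs$frames), floor((n - 1) / k) + 1)
  }
})

test_that("sampling is idempotent and commutes with cropping", {
  dev <- device_crop_config("d", 2, 20, 4, 30, fps = 9)
  video <- lapply(1:45, function(i) matrix((i * 11) %% 256, 32, 40))
  once <- extract_frames(video, dev, sample_time_s = 1)
  twice <- extract_frames(once, dev, sample_time_s = 1, crop = FALSE)
  expect_length(twice$frames, length(once$frames))
  expect_identical(lapply(twice$frames, `[[`, "pixels"),
                   lapply(once$frames, `[[`, "pixels"))

  # crop-then-sample equals sample-then-crop, pixel-exact
  sampled_raw <- extract_frames(video, dev, sample_time_s = 1, crop = FALSE)
  then_cropped <- lapply(sampled_raw$frames, crop_frame, cfg = dev)
  expect_identical(lapply(once$frames, `[[`, "pixels"),
                   lapply(then_cropped, `[[`, "pixels"))
})

test_that("frame directories round-trip through PNG with deterministic names", {
  dir <- withr::local_tempdir()
  dev <- device_crop_config("d", 0, 12, 0, 16, fps = 8)
  video <- lapply(1:16, function(i) {
    set.seed(i); matrix(sample(0:255, 12 * 16, TRUE), 12, 16)
  })
  fs <- extract_frames(video, dev, sample_time_s = 1, source_id = "examA")
  paths <- write_frameset(fs, dir)
  expect_identical(basename(paths[1]), "examA_f000000.png")
  expect_identical(basename(paths[2]), "examA_f000008.png")

  # reading the directory back as a video source reproduces the frames
  fs2 <- extract_frames(dir, device_crop_config("d", 0, 12, 0, 16, fps = 1),
                        sample_time_s = 1)
  expect_equal(fs2$frames[[1]]$pixels, fs$frames[[1]]$pixels, tolerance = 1e-8)
  expect_error(extract_frames(file.path(dir, "nope"), dev), "cannot read")
})

test_that("device tables load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "devices:",
    "  - device_id: arietta_v70",
    "    x_min: 0", "    x_max: 400", "    y_min: 78", "    y_max: 525",
    "    fps: 10",
    "  - device_id: other",
    "    x_min: 10", "    x_max: 50", "    y_min: 0", "    y_max: 60",
    "    fps: 7", "    axis_order: first-axis-is-y"), path)
  devs <- read_devices_yaml(path)
  expect_named(devs, c("arietta_v70", "other"))
  expect_equal(devs$arietta_v70$x_max, 400L)
  expect_equal(devs$other$axis_order, "first-axis-is-y")
  expect_equal(devs$other$fps, 7L)
})

test_that("timestamps follow frame_id / fps", {
  f <- us_frame(matrix(0, 4, 4), 21L, 7L)
  expect_equal(f$timestamp_s, 3)
})
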