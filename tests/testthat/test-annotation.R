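test_that("no polygons yields an all-zero mask", {
  m <- rasterize(list(), 256, 256)
  expect_equal(sum(m$pixels), 0)
  expect_equal(length(m$pixels), 65536L)
})

test_that("axis-aligned square matches the per-pixel even-odd oracle", {
  sq <- annotation_polygon(rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20)))
  m <- rasterize(sq, 64, 64)
  expect_identical(m$pixels, oracle_rasterize(sq, 64, 64))
  expect_equal(sum(m$pixels), 100) # centers 10.5..19.5 in both axes
})

test_that("union semantics: disjoint adds, identical coincides, never decreases", {
  a <- annotation_polygon(rbind(c(5, 5), c(15, 5), c(15, 15), c(5, 15)))
  b <- annotation_polygon(rbind(c(30, 30), c(45, 30), c(45, 40), c(30, 40)))
  ca <- sum(rasterize(a, 64, 64)$pixels)
  cb <- sum(rasterize(b, 64, 64)$pixels)
  expect_equal(sum(rasterize(list(a, b), 64, 64)$pixels), ca + cb)
  expect_equal(sum(rasterize(list(a, a), 64, 64)$pixels), ca)

  # union monotonicity on random polygons
  set.seed(99)
  polys <- replicate(4, random_polygon(), simplify = FALSE)
  counts <- vapply(seq_along(polys), function(k)
    sum(rasterize(polys[seq_len(k)], 64, 64)$pixels), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("random polygons match the brute-force oracle bit-exactly", {
  set.seed(2024)
  for (i in 1:50) {
    poly <- random_polygon(n_vertices = sample(3:10, 1),
                           center = runif(2, 20, 44),
                           r_range = sort(runif(2, 2, 20)))
    m <- rasterize(poly, 64, 64)
    expect_identical(m$pixels, oracle_rasterize(poly, 64, 64))
    expect_true(all(m$pixels %in% c(0, 1)))
  }
})

test_that("rasterization agrees with an independent point-in-polygon routine", {
  set.seed(5)
  for (i in 1:10) {
    poly <- random_polygon()
    m <- rasterize(poly, 64, 64)
    cx <- rep(seq_len(64) - 0.5, each = 64)
    cy <- rep(seq_len(64) - 0.5, times = 64)
    ref <- mgcv::in.out(rbind(poly$vertices, poly$vertices[1, ]),
                        cbind(cx, cy))
    # boundary-center hits are measure-zero for continuous vertices
    expect_equal(as.vector(m$pixels), as.numeric(ref))
  }
})

test_that("foreground count tracks analytic area for convex polygons", {
  set.seed(31)
  for (i in 1:10) {
    # regular n-gon: convex, area = n r^2 sin(2 pi / n) / 2
    n <- sample(6:20, 1); r <- runif(1, 6, 25)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    v <- cbind(32 + r * cos(ang), 32 + r * sin(ang))
    area <- n * r^2 * sin(2 * pi / n) / 2
    if (area < 100) next
    perim <- n * 2 * r * sin(pi / n)
    count <- sum(rasterize(annotation_polygon(v), 64, 64)$pixels)
    expect_lt(abs(count - area), perim)
  }
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(annotation_polygon(rbind(c(0, 0), c(1, 1))), "degenerate")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(annotation_polygon(bowtie), "not simple")
  expect_error(annotation_polygon(rbind(c(0, 0), c(1, NA), c(2, 2))),
               "finite")
})

test_that("GeoJSON annotations parse, group by frame, and expand MultiPolygons", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(frame = "examA_f000000.png"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(10, 10), list(20, 10),
                                                   list(20, 20), list(10, 20),
                                                   list(10, 10))))),
      list(type = "Feature",
           properties = list(frame = "examA_f000010.png", label = "lesion2"),
           geometry = list(
             type = "MultiPolygon",
             coordinates = list(
               list(list(list(0, 0), list(5, 0), list(5, 5), list(0, 0))),
               list(list(list(30, 30), list(40, 30), list(40, 40),
                         list(30, 30))))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  ann <- read_annotations(path)
  expect_named(ann, c("examA_f000000.png", "examA_f000010.png"))
  expect_length(ann[["examA_f000000.png"]], 1L)
  # MultiPolygon of two parts -> two polygons; vertex bookkeeping: 4 + 3 + 3
  expect_length(ann[["examA_f000010.png"]], 2L)
  nv <- sum(vapply(c(ann[[1]], ann[[2]]),
                   function(p) nrow(p$vertices), numeric(1)))
  expect_equal(nv, 10)
  expect_equal(ann[[2]][[1]]$label, "lesion2")
})

test_that("empty collections and malformed GeoJSON are handled", {
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       path, auto_unbox = TRUE)
  expect_length(read_annotations(path), 0L)

  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(frame = "f.png"),
         geometry = list(type = "Point", coordinates = list(1, 2))))),
    path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "feature 1.*Point")

  writeLines("{not json", path)
  expect_error(read_annotations(path), "malformed GeoJSON")
})

test_that("masks round-trip bit-exactly through 8-bit PNG", {
  dir <- withr::local_tempdir()
  z <- binary_mask(matrix(0, 32, 32))
  p <- file.path(dir, "zero.png")
  write_mask(z, p)
  expect_identical(read_mask(p)$pixels, z$pixels)

  set.seed(8)
  m <- binary_mask(random_binary_matrix(256, 256))
  p2 <- file.path(dir, "rand.png")
  write_mask(m, p2)
  expect_identical(read_mask(p2)$pixels, m$pixels)
})

test_that("mask naming appends -mask to the frame base name", {
  expect_identical(mask_filename("examA_f000010.png"),
                   "examA_f000010-mask.png")
  expect_identical(mask_filename("dir/x.png"), "dir/x-mask.png")
})

test_that("non-binary rasters are rejected with the offending levels", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "grey.png")
  png::writePNG(matrix(c(0, 0.5, 1, 1), 2, 2), p)
  expect_error(read_mask(p), "128")
  expect_error(binary_mask(matrix(c(0, 2), 2, 1)), "other than \\{0, 1\\}")
})
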