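#' Expert annotation polygon
#'
#' A lesion outline drawn on the cropped B-mode frame, as an ordered vertex
#' list in pixel coordinates (x = column, y = row, 0-based; a pixel with
#' 0-based indices (cx, cy) has its center at (cx + 0.5, cy + 0.5)).
#'
#' @param vertices Numeric matrix or data.frame with two columns (x, y) and
#'   at least 3 rows. A closing vertex equal to the first is dropped.
#' @param label Free-text label, default `"lesion"`.
#' @param check Validate that the polygon is simple (non-self-intersecting).
#' @return An object of class `usseg_polygon`.
#' @export
annotation_polygon <- function(vertices, label = "lesion", check = TRUE) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must have two columns (x, y)")
  if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L)
    stop("degenerate polygon: ", nrow(v), " distinct vertices (need >= 3)")
  if (any(!is.finite(v))) stop("polygon vertices must be finite")
  dimnames(v) <- list(NULL, c("x", "y"))
  poly <- structure(list(vertices = v, label = as.character(label)),
                    class = "usseg_polygon")
  if (check && !is_simple_polygon(v))
    stop("polygon is not simple (edges self-intersect)")
  poly
}

# Proper-crossing test between open segments; shared endpoints of adjacent
# edges are allowed.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_cross(v[i, ], v[i %% n + 1L, ], v[j, ], v[j %% n + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Full-frame binary lesion mask
#'
#' The pipeline's universal label raster: 0 = background (normal tissue),
#' 1 = lesion.
#'
#' @param pixels Matrix with values in \{0, 1\} (height rows x width columns).
#' @return An object of class `usseg_mask` with fields `pixels`, `width`,
#'   `height`.
#' @export
binary_mask <- function(pixels) {
  stopifnot(is.matrix(pixels))
  bad <- setdiff(unique(as.vector(pixels)), c(0, 1))
  if (length(bad) > 0L)
    stop("mask contains values other than {0, 1}: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, width = ncol(pixels), height = nrow(pixels)),
            class = "usseg_mask")
}

#' @export
print.usseg_mask <- function(x, ...) {
  cat(sprintf("<usseg_mask> %dx%d (w x h), %d lesion pixels (%.2f%%)\n",
              x$width, x$height, sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

# Even-odd point-in-polygon for a set of points, boundary-inclusive.
# Vectorised over points; loops over edges.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  crossings <- integer(length(px))
  boundary <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]
    x2 <- v[i %% n + 1L, 1]; y2 <- v[i %% n + 1L, 2]
    if (y1 != y2) {
      # half-open in y so a ray through a vertex counts once
      hit <- if (y1 < y2) (py >= y1) & (py < y2) else (py >= y2) & (py < y1)
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(hit & (px < xint))
    }
    # boundary: point exactly on the closed segment
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on <- abs(cross) < 1e-9 &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    boundary <- boundary | on
  }
  (crossings %% 2L == 1L) | boundary
}

#' Rasterize annotation polygons into a binary mask
#'
#' A pixel is lesion (1) iff its center lies inside, or on the boundary of,
#' at least one polygon (even-odd rule); multiple polygons combine by union.
#' An empty polygon list yields an all-zero mask (a frame with no visible
#' lesion).
#'
#' @param polygons List of [annotation_polygon()] (or a single one).
#' @param width,height Canvas extent in pixels.
#' @return A [binary_mask()] of extent `height x width`.
#' @export
rasterize <- function(polygons, width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("width and height must be >= 1")
  if (inherits(polygons, "usseg_polygon")) polygons <- list(polygons)
  m <- matrix(0, height, width)
  if (length(polygons) == 0L) return(binary_mask(m))
  cx <- rep(seq_len(width) - 0.5, each = height)   # pixel-center x per column
  cy <- rep(seq_len(height) - 0.5, times = width)  # pixel-center y per row
  inside <- logical(width * height)
  for (p in polygons) {
    if (!inherits(p, "usseg_polygon"))
      p <- annotation_polygon(p)
    inside <- inside | points_in_polygon(cx, cy, p$vertices)
  }
  m[] <- as.numeric(inside) # point order matches the matrix's column-major layout
  binary_mask(m)
}

#' Read polygon annotations from a GeoJSON FeatureCollection
#'
#' Each feature must be a `Polygon` or `MultiPolygon` (a MultiPolygon expands
#' part-wise into several polygons) keyed to its frame by the
#' `properties$frame` field (the frame file name). Other geometry types are
#' rejected. This is the interchange format for annotations exported from an
#' annotation tool such as QuPath.
#'
#' @param path GeoJSON file path.
#' @return Named list: one element per frame name, each a list of
#'   [annotation_polygon()]. Empty collection gives an empty list.
#' @export
read_annotations <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed GeoJSON: ",
                                           conditionMessage(e)))
  if (is.null(doc$type) || doc$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection, got type: ",
         if (is.null(doc$type)) "<missing>" else doc$type)
  out <- list()
  feats <- doc$features
  ring_to_poly <- function(rings, label, fi) {
    if (length(rings) > 1L)
      stop("feature ", fi, ": polygons with interior rings (holes) are not supported")
    v <- do.call(rbind, lapply(rings[[1]], function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    annotation_polygon(v, label = label)
  }
  for (fi in seq_along(feats)) {
    f <- feats[[fi]]
    g <- f$geometry
    if (is.null(g) || is.null(g$type))
      stop("feature ", fi, ": missing geometry")
    frame <- f$properties$frame
    if (is.null(frame))
      stop("feature ", fi, ": missing properties$frame (target frame file name)")
    label <- if (!is.null(f$properties$label)) f$properties$label else "lesion"
    polys <- switch(g$type,
      Polygon = list(ring_to_poly(g$coordinates, label, fi)),
      MultiPolygon = lapply(g$coordinates, ring_to_poly, label = label, fi = fi),
      stop("feature ", fi, ": unsupported geometry type '", g$type, "'"))
    out[[frame]] <- c(out[[frame]], polys)
  }
  out
}

#' Mask file name for a frame file name
#'
#' Appends `-mask` to the frame's base name: `"examA_f000010.png"` becomes
#' `"examA_f000010-mask.png"`.
#'
#' @param frame_name Frame file name (with or without directory).
#' @return Mask file name.
#' @export
mask_filename <- function(frame_name) {
  ext <- tools::file_ext(frame_name)
  base <- tools::file_path_sans_ext(frame_name)
  if (nzchar(ext)) paste0(base, "-mask.", ext) else paste0(frame_name, "-mask")
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Foreground (lesion) is stored as 255 and background as 0;
#' `read_mask(write_mask(m, p))` round-trips exactly. Reading a PNG that
#' contains any other grey level is a validation error.
#'
#' @param mask A [binary_mask()].
#' @param path PNG file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "usseg_mask"))
  png::writePNG(mask$pixels, path) # 0 -> 0x00, 1 -> 0xFF
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  vals <- unique(as.vector(a))
  bad <- setdiff(vals, c(0, 1))
  if (length(bad) > 0L)
    stop("non-binary mask raster in ", path, ": intensity levels ",
         paste(round(utils::head(bad, 5L) * 255), collapse = ", "),
         " (expected only 0 and 255)")
  binary_mask(a)
}
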