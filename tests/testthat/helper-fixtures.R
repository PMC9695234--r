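# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A deterministic gradient frame so sub-rectangle copies are recognisable.
gradient_frame <- function(nr, nc, frame_id = 0L, fps = 10L,
                           source_id = "exam") {
  px <- outer(seq_len(nr) - 1L, seq_len(nc) - 1L,
              function(i, j) (i * 7 + j * 3) %% 256)
  us_frame(px, frame_id, fps, source_id)
}

# In-memory "video": list of frame matrices.
constant_video <- function(n_frames, nr = 32L, nc = 40L, value = 50) {
  lapply(seq_len(n_frames), function(i) matrix(value, nr, nc))
}

# Brute-force per-pixel even-odd point-in-polygon oracle (scalar loop,
# boundary-inclusive), independent of the vectorised implementation.
oracle_rasterize <- function(polys, width, height) {
  if (inherits(polys, "usseg_polygon")) polys <- list(polys)
  m <- matrix(0, height, width)
  for (r in seq_len(height)) {
    for (cc in seq_len(width)) {
      px <- cc - 0.5; py <- r - 0.5
      for (p in polys) {
        v <- p$vertices; n <- nrow(v); cross <- 0L; on_edge <- FALSE
        for (i in seq_len(n)) {
          x1 <- v[i, 1]; y1 <- v[i, 2]
          x2 <- v[i %% n + 1L, 1]; y2 <- v[i %% n + 1L, 2]
          if (y1 != y2) {
            hit <- if (y1 < y2) py >= y1 && py < y2 else py >= y2 && py < y1
            if (hit && px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
              cross <- cross + 1L
          }
          d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
          if (abs(d) < 1e-9 && px >= min(x1, x2) - 1e-9 &&
              px <= max(x1, x2) + 1e-9 && py >= min(y1, y2) - 1e-9 &&
              py <= max(y1, y2) + 1e-9)
            on_edge <- TRUE
        }
        if (cross %% 2L == 1L || on_edge) { m[r, cc] <- 1; break }
      }
    }
  }
  m
}

# Random simple polygon: vertices at sorted angles around a center, with
# rejection sampling (wildly uneven radii can still make the closing edge
# cross a spike, which the validity check catches).
random_polygon <- function(n_vertices = 8L, center = c(32, 32),
                           r_range = c(4, 24)) {
  repeat {
    ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
    rad <- stats::runif(n_vertices, r_range[1], r_range[2])
    p <- tryCatch(annotation_polygon(cbind(center[1] + rad * cos(ang),
                                           center[2] + rad * sin(ang))),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

random_binary_matrix <- function(nr, nc, p = 0.3) {
  matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
}

# A tiny trained-free model for plumbing tests.
tiny_unet <- function(input_size = 32L, base_filters = 4L, seed = 1L) {
  set.seed(seed)
  unet_build(unet_config(input_size = input_size, base_filters = base_filters))
}
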