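# Shared fixtures: constructed masks, an independent curvature oracle, and
# lazily rendered/analysed preset scenes (cached across test files).

rect_contour <- function(h, w, H = h + 20L, W = w + 20L) {
  m <- matrix(FALSE, H, W)
  m[11:(10 + h), 11:(10 + w)] <- TRUE
  find_contours(m, 0L)[[1]]
}

# Horizontal 5 x 40 bar starting at column x0 (1-based) in a 40 x 200 frame.
bar_mask <- function(x0, H = 40L, W = 200L) {
  m <- matrix(FALSE, H, W)
  m[18:22, x0:(x0 + 39L)] <- TRUE
  m
}

disc_mask <- function(r, cx = 20, cy = 20, H = 40L, W = 40L) {
  xy <- expand.grid(y = seq_len(H), x = seq_len(W))
  m <- matrix((xy$x - cx)^2 + (xy$y - cy)^2 < r^2, H, W)
  m
}

# Independent circumcircle oracle: circumradius via perpendicular-bisector
# intersection, solved as a 2x2 linear system. Returns 1/R (unsigned),
# 0 for collinear triples.
circumcurvature_oracle <- function(x, y, z) {
  A <- rbind(2 * (y - x), 2 * (z - x))
  b <- c(sum(y^2) - sum(x^2), sum(z^2) - sum(x^2))
  if (abs(det(A)) < 1e-12) return(0)
  center <- solve(A, b)
  1 / sqrt(sum((x - center)^2))
}

# Build a worm_track directly from per-frame midpoints (and optionally
# tracking points / flags), bypassing the imaging pipeline.
make_track <- function(id, frames, midpoints = NULL, tracking_points = NULL,
                       self_collision = NULL, midline_len = 80,
                       area_px = 500) {
  obs <- list()
  for (i in seq_along(frames)) {
    mp <- if (is.null(midpoints)) c(0, 0) else midpoints[[i]]
    tp <- if (is.null(tracking_points)) NULL else tracking_points[[i]]
    sc <- if (is.null(self_collision)) FALSE else self_collision[[i]]
    obs[[as.character(frames[i])]] <- structure(
      list(contour = structure(list(frame_index = frames[i],
                                    boundary = matrix(mp, 1),
                                    mask = matrix(TRUE, 1, 1),
                                    area_px = area_px, centroid = mp,
                                    bbox = c(x0 = 0, y0 = 0, x1 = 1, y1 = 1)),
                               class = "contour_observation"),
           midline = NULL, midline_len_px = midline_len,
           tracking_points = tp,
           midpoint = if (sc) NULL else mp,
           self_collision = sc),
      class = "skeleton_observation")
  }
  structure(list(worm_id = id, observations = obs,
                 first_frame = min(frames), last_frame = max(frames),
                 n_observed = length(frames)),
            class = "worm_track")
}

# Tibble of signed curvature samples for stroke/amplitude unit tests.
make_series <- function(values, point = 1L, frames = seq_along(values) - 1L,
                        frame_rate = 14) {
  tibble::tibble(frame = as.integer(frames), time = frames / frame_rate,
                 point = as.integer(point), curvature = values)
}

# Lazily rendered preset scenes + analyses, shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

get_scene <- function(name, seed = 1L, freq = 1, n_frames = NULL) {
  key <- paste(name, seed, freq, n_frames %||% "d", sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- render_scene(
      scene_preset(name, seed = seed, freq = freq, n_frames = n_frames))
  }
  .fixture_cache[[key]]
}

get_analysis <- function(name, seed = 1L, freq = 1, n_frames = NULL,
                         ucf = 10, frame_rate = NULL) {
  key <- paste("an", name, seed, freq, n_frames %||% "d", ucf, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    r <- get_scene(name, seed, freq, n_frames)
    cfg <- analysis_config(min_size_px = 100, ucf = ucf,
                           frame_rate = frame_rate %||% r$seq$frame_rate)
    .fixture_cache[[key]] <- run_analysis(r$seq, cfg, out_dir = NULL,
                                          annotate = FALSE, plots = FALSE)
  }
  .fixture_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
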