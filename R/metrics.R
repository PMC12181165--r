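#' Analysis configuration
#'
#' The three user parameters plus the frame rate.
#'
#' @param min_size_px Worm Minimum Size: smallest pixel area accepted as a
#'   worm (inclusive).
#' @param ucf Unit Conversion Factor, micrometers per pixel (> 0), obtained
#'   by imaging a ruler at the recording position.
#' @param min_pct Frame Percentage: minimum percentage of video frames a
#'   worm must appear in to be reported (0-100).
#' @param frame_rate Video frame rate, frames/second (> 0).
#' @param amplitude_prose_variant If `TRUE`, dynamic amplitude uses
#'   `max - min` of the signed curvature instead of the default
#'   `|max| - |min|`.
#' @param stroke_point Tracking point used for stroke detection; the default
#'   1 is the end-most interior point, the closest defined curvature to the
#'   worm's end.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(min_size_px = 60, ucf = 1, min_pct = 0,
                            frame_rate = 7.5,
                            amplitude_prose_variant = FALSE,
                            stroke_point = 1L) {
  stopifnot(ucf > 0, frame_rate > 0, min_pct >= 0, min_pct <= 100,
            min_size_px >= 0, stroke_point %in% 1:5)
  structure(list(min_size_px = min_size_px, ucf = ucf, min_pct = min_pct,
                 frame_rate = frame_rate,
                 amplitude_prose_variant = amplitude_prose_variant,
                 stroke_point = as.integer(stroke_point)),
            class = "analysis_config")
}

#' Worm area
#'
#' `area = worm_pixels * ucf^2`, in square micrometers.
#'
#' @param obs A `skeleton_observation` or `contour_observation` (or a bare
#'   pixel count).
#' @param cfg An `analysis_config`.
#' @return Area in um^2.
#' @export
worm_area <- function(obs, cfg) {
  px <- if (is.numeric(obs)) obs
        else if (inherits(obs, "skeleton_observation")) obs$contour$area_px
        else obs$area_px
  px * cfg$ucf^2
}

#' Worm length
#'
#' `length = worm_midline_pixels * ucf`, in micrometers. The midline pixel
#' count is arclength-corrected: diagonal steps along the 8-connected path
#' weigh sqrt(2), so the value is orientation-independent.
#'
#' @param obs A `skeleton_observation` (or a bare midline pixel count).
#' @param cfg An `analysis_config`.
#' @return Length in um, `NA` for self-collision frames.
#' @export
worm_length <- function(obs, cfg) {
  px <- if (is.numeric(obs)) obs else obs$midline_len_px
  px * cfg$ucf
}

#' Per-frame crawl speed
#'
#' Euclidean displacement of the midline midpoint between consecutive
#' observed frames, `|p1 - p0| * ucf * frame_rate`, in um/s. No value is
#' emitted across gaps or censored frames.
#'
#' @param track A `worm_track`.
#' @param cfg An `analysis_config`.
#' @return Tibble with `frame` (the later frame of each pair), `time`
#'   (seconds from frame 0) and `value` (um/s).
#' @export
crawl_speed <- function(track, cfg) {
  mids <- midpoint_table(track)
  if (nrow(mids) < 2L) return(speed_tibble())
  consec <- which(diff(mids$frame) == 1L)
  if (!length(consec)) return(speed_tibble())
  d <- sqrt((mids$x[consec + 1L] - mids$x[consec])^2 +
              (mids$y[consec + 1L] - mids$y[consec])^2)
  tibble::tibble(frame = mids$frame[consec + 1L],
                 time = mids$frame[consec + 1L] / cfg$frame_rate,
                 value = d * cfg$ucf * cfg$frame_rate)
}

speed_tibble <- function() {
  tibble::tibble(frame = integer(0), time = numeric(0), value = numeric(0))
}

# Frames with a usable midpoint (observed, not self-colliding), ordered.
midpoint_table <- function(track) {
  fr <- as.integer(names(track$observations))
  ok <- vapply(track$observations, function(o)
    !isTRUE(o$self_collision) && !is.null(o$midpoint), logical(1))
  fr <- fr[ok]
  o <- order(fr)
  mids <- t(vapply(track$observations[ok], function(o) as.numeric(o$midpoint),
                   numeric(2)))
  tibble::tibble(frame = unname(fr[o]), x = unname(mids[o, 1]),
                 y = unname(mids[o, 2]))
}

#' Signed Menger curvature of three points
#'
#' The curvature at `y` is the inverse radius of the circle through `x`,
#' `y`, `z`: `|c| = 4 * area(x, y, z) / (|x-y| |y-z| |z-x|)`. The sign is
#' the turn direction, the z-component of the cross product
#' `(y - x) x (z - y)`; collinear points give exactly 0.
#'
#' @param x,y,z Length-2 numeric positions (same length unit `u`).
#' @return Signed curvature in `1/u`; error if any two points coincide.
#' @export
menger_curvature <- function(x, y, z) {
  a <- y - x
  b <- z - y
  c_ <- z - x
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c_^2))
  if (la == 0 || lb == 0 || lc == 0) {
    stop("undefined curvature: coincident points")
  }
  cross <- a[1] * b[2] - a[2] * b[1]
  2 * cross / (la * lb * lc)
}

#' Signed curvature time series at the interior tracking points
#'
#' For every observed, un-censored frame of a track, computes the signed
#' Menger curvature at tracking points 1..5 (curvature is undefined at the
#' two ends) from triples of consecutive tracking points, with coordinates
#' converted to micrometers first. The skeleton has no intrinsic head/tail
#' orientation, so each frame's point order is aligned to the previous
#' frame's by end proximity before signing; a flip reverses the point
#' indices and the sign together.
#'
#' @param track A `worm_track`.
#' @param cfg An `analysis_config`.
#' @return Tibble with `frame`, `time` (s), `point` (1-5), `curvature`
#'   (1/um).
#' @export
curvature_series <- function(track, cfg) {
  fr <- as.integer(names(track$observations))
  o <- order(fr)
  fr <- fr[o]
  obs <- track$observations[o]
  prev_ends <- NULL
  rows_frame <- integer(0); rows_point <- integer(0); rows_c <- numeric(0)
  for (k in seq_along(obs)) {
    ob <- obs[[k]]
    if (isTRUE(ob$self_collision) || is.null(ob$tracking_points)) {
      prev_ends <- NULL  # orientation memory does not cross a censored gap
      next
    }
    tp <- ob$tracking_points * cfg$ucf
    if (!is.null(prev_ends)) {
      same <- sum((tp[1, ] - prev_ends[[1]])^2) + sum((tp[7, ] - prev_ends[[2]])^2)
      flip <- sum((tp[1, ] - prev_ends[[2]])^2) + sum((tp[7, ] - prev_ends[[1]])^2)
      if (flip < same) tp <- tp[7:1, , drop = FALSE]
    }
    prev_ends <- list(tp[1, ], tp[7, ])
    for (p in 1:5) {
      cv <- tryCatch(
        menger_curvature(tp[p, ], tp[p + 1, ], tp[p + 2, ]),
        error = function(e) NA_real_)
      if (!is.na(cv)) {
        rows_frame <- c(rows_frame, fr[k])
        rows_point <- c(rows_point, p)
        rows_c <- c(rows_c, cv)
      }
    }
  }
  tibble::tibble(frame = rows_frame, time = rows_frame / cfg$frame_rate,
                 point = rows_point, curvature = rows_c)
}

#' Detect strokes as curvature zero crossings
#'
#' A stroke is a sign change of the signed curvature at a designated
#' tracking point between consecutive defined samples: the new nonzero sign
#' is compared against the last nonzero sign, so exact zeros pass through
#' without themselves counting. Events never span a censored gap (a jump of
#' more than one frame resets the comparison).
#'
#' @param series A curvature series from [curvature_series()].
#' @param point_index Tracking point (1-5) whose curvature is monitored; by
#'   default the end-most interior point 1.
#' @return Tibble of stroke events: `frame`, `direction` (`"+-"` or `"-+"`).
#' @export
detect_strokes <- function(series, point_index = 1L) {
  s <- series[series$point == point_index, , drop = FALSE]
  s <- s[order(s$frame), , drop = FALSE]
  ev_frame <- integer(0); ev_dir <- character(0)
  last_sign <- 0
  last_frame <- NA_integer_
  for (i in seq_len(nrow(s))) {
    if (!is.na(last_frame) && s$frame[i] - last_frame > 1L) last_sign <- 0
    sg <- sign(s$curvature[i])
    if (sg != 0) {
      if (last_sign != 0 && sg != last_sign) {
        ev_frame <- c(ev_frame, s$frame[i])
        ev_dir <- c(ev_dir, if (sg < 0) "+-" else "-+")
      }
      last_sign <- sg
    }
    last_frame <- s$frame[i]
  }
  tibble::tibble(frame = ev_frame, direction = ev_dir)
}

#' Wave initiation rate
#'
#' A wave is counted every two strokes; partial strokes are rounded down to
#' the last complete stroke. The rate is waves per minute of un-censored
#' tracked time.
#'
#' @param strokes Stroke events from [detect_strokes()].
#' @param observed_duration Un-censored tracked time, seconds (> 0).
#' @return Waves per minute.
#' @export
wave_initiation_rate <- function(strokes, observed_duration) {
  if (!is.numeric(observed_duration) || observed_duration <= 0) {
    stop("undefined rate: observed_duration must be positive")
  }
  waves <- floor(nrow(strokes) / 2)
  waves / observed_duration * 60
}

#' Per-interval swim speed
#'
#' Swimming worms jitter laterally with each stroke; the jitter cancels over
#' a full undulation period. The midpoint position is therefore taken only
#' at every second stroke (stroke 0 -> 2 -> 4 ...), and the speed over each
#' two-stroke interval is `displacement * ucf / duration`. Intervals
#' containing censored or missing frames are dropped.
#'
#' @param track A `worm_track`.
#' @param strokes Stroke events from [detect_strokes()].
#' @param cfg An `analysis_config`.
#' @return Tibble with `frame0`, `frame1`, `time` (interval midpoint, s),
#'   `value` (um/s); empty when fewer than 2 strokes exist.
#' @export
swim_speed <- function(track, strokes, cfg) {
  b <- two_stroke_boundaries(strokes)
  out <- tibble::tibble(frame0 = integer(0), frame1 = integer(0),
                        time = numeric(0), value = numeric(0))
  if (length(b) < 2L) return(out)
  mids <- midpoint_table(track)
  for (k in seq_len(length(b) - 1L)) {
    f0 <- b[k]; f1 <- b[k + 1L]
    span <- mids$frame >= f0 & mids$frame <= f1
    # every frame of the interval must carry a usable midpoint
    if (sum(span) != f1 - f0 + 1L) next
    i0 <- which(mids$frame == f0); i1 <- which(mids$frame == f1)
    disp <- sqrt((mids$x[i1] - mids$x[i0])^2 + (mids$y[i1] - mids$y[i0])^2)
    dur <- (f1 - f0) / cfg$frame_rate
    out <- tibble::add_row(out, frame0 = f0, frame1 = f1,
                           time = (f0 + f1) / 2 / cfg$frame_rate,
                           value = disp * cfg$ucf / dur)
  }
  out
}

# Frames of stroke events 1, 3, 5, ... (1-based): consecutive boundaries
# enclose exactly two strokes.
two_stroke_boundaries <- function(strokes) {
  if (nrow(strokes) < 1L) return(integer(0))
  strokes$frame[seq(1L, nrow(strokes), by = 2L)]
}

#' Per-interval dynamic amplitude
#'
#' Over each two-stroke interval, taking all defined tracking points and
#' frames together (the maximum and minimum need not come from the same
#' point), `amplitude = |max curvature| - |min curvature|` — the magnitude
#' of how far the body bends one way beyond the other. With
#' `cfg$amplitude_prose_variant = TRUE` the peak-to-peak `max - min` is
#' reported instead.
#'
#' @param series A curvature series from [curvature_series()].
#' @param strokes Stroke events from [detect_strokes()].
#' @param cfg An `analysis_config`.
#' @return Tibble with `frame0`, `frame1`, `time`, `value` (1/um).
#' @export
dynamic_amplitude <- function(series, strokes,
                              cfg = analysis_config()) {
  b <- two_stroke_boundaries(strokes)
  out <- tibble::tibble(frame0 = integer(0), frame1 = integer(0),
                        time = numeric(0), value = numeric(0))
  if (length(b) < 2L) return(out)
  for (k in seq_len(length(b) - 1L)) {
    f0 <- b[k]; f1 <- b[k + 1L]
    vals <- series$curvature[series$frame >= f0 & series$frame <= f1]
    if (!length(vals)) next
    v <- if (isTRUE(cfg$amplitude_prose_variant)) max(vals) - min(vals)
         else abs(max(vals)) - abs(min(vals))
    out <- tibble::add_row(out, frame0 = f0, frame1 = f1,
                           time = (f0 + f1) / 2 / cfg$frame_rate, value = v)
  }
  out
}

#' Summarize all six metrics for a set of tracks
#'
#' Produces the long per-sample table (per-frame rows for area, length and
#' crawl speed; per-interval rows for swim speed and dynamic amplitude;
#' per-worm wave rate) and per-worm summary means. Censored frames
#' contribute no rows; per-worm means average only defined samples. Worms
#' with no defined sample for a metric are omitted from that metric's
#' summary.
#'
#' @param tracks List of `worm_track` (already frame-percentage filtered).
#' @param cfg An `analysis_config`.
#' @return A `metrics_table`: list with tibbles `samples` (`metric`,
#'   `worm_id`, `frame`, `time`, `value`, `unit`) and `summary` (`metric`,
#'   `worm_id`, `mean_value`, `unit`).
#' @export
summarize_metrics <- function(tracks, cfg) {
  samples <- list()
  for (tr in tracks) {
    tr <- censor_self_collisions(tr)
    wid <- tr$worm_id
    fr <- as.integer(names(tr$observations))
    ok <- vapply(tr$observations, function(o)
      !isTRUE(o$self_collision) && !is.null(o$midpoint), logical(1))
    if (any(ok)) {
      obs_ok <- tr$observations[ok]
      f_ok <- fr[ok]
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "worm_area", worm_id = wid, frame = unname(f_ok),
        time = f_ok / cfg$frame_rate,
        value = unname(vapply(obs_ok, worm_area, numeric(1), cfg = cfg)),
        unit = "um^2")
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "worm_length", worm_id = wid, frame = unname(f_ok),
        time = f_ok / cfg$frame_rate,
        value = unname(vapply(obs_ok, worm_length, numeric(1), cfg = cfg)),
        unit = "um")
    }
    cs <- crawl_speed(tr, cfg)
    if (nrow(cs)) {
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "crawl_speed", worm_id = wid, frame = cs$frame,
        time = cs$time, value = cs$value, unit = "um/s")
    }
    series <- curvature_series(tr, cfg)
    strokes <- detect_strokes(series, cfg$stroke_point)
    ss <- swim_speed(tr, strokes, cfg)
    if (nrow(ss)) {
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "swim_speed", worm_id = wid, frame = ss$frame1,
        time = ss$time, value = ss$value, unit = "um/s")
    }
    da <- dynamic_amplitude(series, strokes, cfg)
    if (nrow(da)) {
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "dynamic_amplitude", worm_id = wid, frame = da$frame1,
        time = da$time, value = da$value, unit = "1/um")
    }
    dur <- sum(ok) / cfg$frame_rate
    if (dur > 0 && nrow(series)) {
      samples[[length(samples) + 1L]] <- tibble::tibble(
        metric = "wave_initiation_rate", worm_id = wid,
        frame = NA_integer_, time = NA_real_,
        value = wave_initiation_rate(strokes, dur), unit = "waves/min")
    }
  }
  samples <- if (length(samples)) dplyr::bind_rows(samples) else
    tibble::tibble(metric = character(0), worm_id = integer(0),
                   frame = integer(0), time = numeric(0),
                   value = numeric(0), unit = character(0))
  summary <- dplyr::summarise(
    dplyr::group_by(samples, .data$metric, .data$worm_id, .data$unit),
    mean_value = mean(.data$value), .groups = "drop")
  summary <- summary[, c("metric", "worm_id", "mean_value", "unit")]
  structure(list(samples = samples, summary = summary),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table> %d sample rows, %d summary rows, %d worms\n",
              nrow(x$samples), nrow(x$summary),
              length(unique(x$summary$worm_id))))
  invisible(x)
}

#' @importFrom rlang .data
NULL
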