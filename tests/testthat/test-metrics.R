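cfg1 <- analysis_config(min_size_px = 0, ucf = 1, frame_rate = 7.5)

test_that("worm area is pixel count times the squared conversion factor", {
  expect_equal(worm_area(1000, analysis_config(ucf = 2.5)), 6250)
  expect_equal(worm_area(1234, cfg1), 1234)
  rect <- matrix(FALSE, 30, 40)
  rect[11:20, 11:30] <- TRUE
  o <- find_contours(rect, 0L)[[1]]
  expect_equal(worm_area(o, analysis_config(ucf = 3)), 1800)
})

test_that("worm length is midline pixels times the conversion factor", {
  expect_equal(worm_length(150, analysis_config(ucf = 3)), 450)
  expect_equal(worm_length(81, cfg1), 81)
})

test_that("crawl speed is midpoint displacement times ucf times fps", {
  tr <- make_track(1L, 0:1, midpoints = list(c(10, 10), c(13, 14)))
  cs <- crawl_speed(tr, cfg1)
  expect_equal(cs$value, 37.5)  # 5 px at 7.5 fps
  still <- make_track(1L, 0:3, midpoints = rep(list(c(4, 4)), 4))
  expect_equal(crawl_speed(still, cfg1)$value, rep(0, 3))
  # no value across a frame gap
  gap <- make_track(1L, c(0L, 2L), midpoints = list(c(0, 0), c(2, 0)))
  expect_equal(nrow(crawl_speed(gap, cfg1)), 0L)
})

test_that("Menger curvature matches the circumcircle and signs by turn", {
  expect_identical(menger_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(abs(menger_curvature(c(2, 0), c(0, 2), c(-2, 0))), 0.5)
  # left turn positive, right turn negative (y-down flips handedness but the
  # convention only needs to be consistent)
  expect_equal(menger_curvature(c(0, 0), c(1, 0), c(2, 1)),
               -menger_curvature(c(0, 0), c(1, 0), c(2, -1)))
  expect_error(menger_curvature(c(0, 0), c(0, 0), c(1, 1)), "coincident")

  set.seed(42)
  for (i in 1:1000) {
    pts <- matrix(stats::runif(6, -10, 10), 3, 2)
    got <- abs(menger_curvature(pts[1, ], pts[2, ], pts[3, ]))
    expect_lt(abs(got - circumcurvature_oracle(pts[1, ], pts[2, ], pts[3, ])),
              1e-9)
  }
})

test_that("stroke detection counts sign changes, zeros pass through", {
  s <- make_series(c(1, -1, 1, -1, 1))
  expect_equal(nrow(detect_strokes(s)), 4L)
  expect_equal(detect_strokes(s)$direction, c("+-", "-+", "+-", "-+"))
  expect_equal(nrow(detect_strokes(make_series(c(2, 1, 3, 0.5)))), 0L)
  expect_equal(nrow(detect_strokes(make_series(c(1, 0, -1)))), 1L)
  # a censored gap resets the comparison: no stroke across it
  gap <- make_series(c(1, -1), frames = c(0L, 5L))
  expect_equal(nrow(detect_strokes(gap)), 0L)
})

test_that("waves are floor(strokes / 2) per minute of tracked time", {
  st4 <- tibble::tibble(frame = c(1L, 5L, 9L, 13L), direction = "+-")
  expect_equal(wave_initiation_rate(st4, 30), 4)
  st3 <- st4[1:3, ]
  expect_equal(wave_initiation_rate(st3, 60), 1)  # rounds down to 1 wave
  expect_error(wave_initiation_rate(st4, 0), "positive")
})

test_that("swim speed uses two-stroke interval boundaries", {
  # midpoint moves 28 um between stroke boundaries 2 s apart (fps 7.5)
  frames <- 0:15
  mids <- lapply(frames, function(f) c(f * 28 / 15, 0))
  tr <- make_track(1L, frames, midpoints = mids)
  strokes <- tibble::tibble(frame = c(0L, 7L, 15L), direction = "+-")
  ss <- swim_speed(tr, strokes, cfg1)
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$value, 28 / 2)
  # fewer than 2 strokes: empty series
  expect_equal(nrow(swim_speed(tr, strokes[1, ], cfg1)), 0L)
  # an interval with a missing frame is dropped
  tr2 <- make_track(1L, setdiff(frames, 8L), midpoints = mids[-9])
  expect_equal(nrow(swim_speed(tr2, strokes, cfg1)), 0L)
})

test_that("dynamic amplitude applies |max| - |min| over the interval", {
  strokes <- tibble::tibble(frame = c(0L, 3L, 6L), direction = "+-")
  s1 <- make_series(c(0.4, 0.1, -0.3, 0.2, 0.4, -0.1, 0.05))
  expect_equal(dynamic_amplitude(s1, strokes)$value, 0.4 - 0.3)
  s2 <- make_series(c(0.4, -0.4, 0.2, -0.2, 0.1, -0.1, 0))
  expect_equal(dynamic_amplitude(s2, strokes)$value, 0)
  s3 <- make_series(c(0.5, 0.2, 0.3, 0.2, 0.5, 0.4, 0.3))
  expect_equal(dynamic_amplitude(s3, strokes)$value, 0.3)
  # prose variant: peak-to-peak of the signed values
  cfgp <- analysis_config(amplitude_prose_variant = TRUE)
  expect_equal(dynamic_amplitude(s1, strokes, cfgp)$value, 0.7)
})

test_that("curvature vanishes on straight worms and is defined per frame", {
  w <- worm_spec(length_um = 800, width_um = 60, kappa0 = 0,
                 drift = c(600, 0), position = c(700, 1200))
  r <- render_scene(scene_spec(list(w), n_frames = 30, noise = 0.02))
  cfg <- analysis_config(min_size_px = 100, ucf = 10, frame_rate = 7.5)
  res <- run_analysis(r$seq, cfg, out_dir = NULL, annotate = FALSE,
                      plots = FALSE)
  series <- curvature_series(res$tracks[[1]], cfg)
  # well below the typical undulation scale of 5e-3 1/um
  expect_lt(max(abs(series$curvature)), 0.1 * 0.005)
  # a single-frame track still has spatial curvature
  one <- res$tracks[[1]]
  one$observations <- one$observations[1]
  expect_equal(nrow(curvature_series(one, cfg)), 5L)
})

test_that("unit scaling laws hold exactly", {
  res <- get_analysis("curl", n_frames = 60)
  tracks <- res$tracks
  s <- 3.7
  base <- summarize_metrics(tracks, analysis_config(ucf = 10, frame_rate = 14))
  scaled <- summarize_metrics(tracks, analysis_config(ucf = 10 * s,
                                                      frame_rate = 14))
  fac <- c(worm_area = s^2, worm_length = s, crawl_speed = s, swim_speed = s,
           dynamic_amplitude = 1 / s, wave_initiation_rate = 1)
  for (m in names(fac)) {
    b <- base$summary$mean_value[base$summary$metric == m]
    sc <- scaled$summary$mean_value[scaled$summary$metric == m]
    if (length(b)) expect_equal(sc, b * fac[[m]], tolerance = 1e-12)
  }
})

test_that("summaries are means of defined samples only", {
  areas <- c(100, 200, 300)
  tr <- make_track(1L, 0:2, midpoints = rep(list(c(1, 1)), 3))
  for (i in 1:3) tr$observations[[i]]$contour$area_px <- areas[i]
  tab <- summarize_metrics(list(tr), cfg1)
  expect_equal(tab$summary$mean_value[tab$summary$metric == "worm_area"], 200)

  # censored frames contribute no rows
  sc_flags <- list(FALSE, TRUE, FALSE)
  trc <- make_track(2L, 0:2, midpoints = rep(list(c(1, 1)), 3),
                    self_collision = sc_flags)
  tabc <- summarize_metrics(list(trc), cfg1)
  expect_equal(sum(tabc$samples$metric == "worm_area"), 2L)

  # a two-worm scene reports exactly two worm ids per metric
  res <- get_analysis("collision")
  # after re-identification there are 4 ids, but each frame-level metric row
  # belongs to a real track; area rows must cover all retained ids
  ids <- sort(unique(res$table$samples$worm_id[
    res$table$samples$metric == "worm_area"]))
  expect_setequal(ids, vapply(res$tracks, function(t) t$worm_id, integer(1)))
})
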