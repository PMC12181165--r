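test_that("well-separated worms keep one ID each for the whole video", {
  worms <- list(
    worm_spec(length_um = 700, width_um = 60, kappa0 = 0,
              drift = c(400, 0), position = c(700, 600)),
    worm_spec(length_um = 700, width_um = 60, kappa0 = 0,
              drift = c(400, 0), position = c(700, 1800)))
  r <- render_scene(scene_spec(worms, n_frames = 30, noise = 0.02))
  cfg <- analysis_config(min_size_px = 100, ucf = 10, frame_rate = 7.5)
  res <- run_analysis(r$seq, cfg, out_dir = NULL, annotate = FALSE,
                      plots = FALSE)
  expect_length(res$tracks, 2L)
  expect_length(res$events, 0L)
  for (tr in res$tracks) expect_equal(tr$n_observed, 30L)
  # assignment follows the simulated trajectories: track centroids stay in
  # their own lane
  ys <- vapply(res$tracks, function(tr)
    mean(vapply(tr$observations, function(o) o$contour$centroid[2],
                numeric(1))), numeric(1))
  expect_lt(abs(sort(ys)[1] - 60), 5)
  expect_lt(abs(sort(ys)[2] - 180), 5)
})

test_that("a head-on collision censors both worms and re-issues IDs", {
  r <- get_scene("collision")
  res <- get_analysis("collision")
  overlap <- r$truth$frame[r$truth$collision == 1]
  expect_length(res$events, 1L)
  ev <- res$events[[1]]
  expect_equal(ev$kind, "worm-worm")
  expect_setequal(ev$participant_ids, c(1L, 2L))
  expect_setequal(ev$successor_ids, c(3L, 4L))
  # original IDs end before the overlap, successors begin after it
  expect_lte(ev$start_frame, min(overlap) + 1L)
  expect_gte(ev$end_frame, max(overlap))
  for (tr in res$tracks) {
    if (tr$worm_id %in% ev$participant_ids) {
      expect_lt(tr$last_frame, ev$start_frame)
    } else {
      expect_gte(tr$first_frame, ev$end_frame)
    }
    # no observations inside the censored interval
    fr <- as.integer(names(tr$observations))
    expect_false(any(fr >= ev$start_frame & fr < ev$end_frame))
  }
})

test_that("an empty observation list marks all tracks missing, no new IDs", {
  st <- tracker_state()
  o <- lapply(find_contours(bar_mask(20L), 0L), skeletonize)
  st <- match_frame(st, o, 0L)
  expect_equal(st$next_id, 2L)
  st <- match_frame(st, list(), 1L)
  expect_equal(st$next_id, 2L)
  expect_equal(st$active[[1]]$missing, 1L)
})

test_that("a track missing longer than the patience closes; IDs never reuse", {
  st <- tracker_state(patience = 5L)
  mk <- function(fi, x0) lapply(find_contours(bar_mask(x0), fi), skeletonize)
  st <- match_frame(st, mk(0L, 20L), 0L)
  for (fi in 1:6) st <- match_frame(st, list(), fi)
  expect_length(st$active, 0L)
  # a reappearing blob gets a fresh ID
  st <- match_frame(st, mk(7L, 24L), 7L)
  expect_equal(st$active[[1]]$id, 2L)
})

test_that("self-collision censoring keeps the ID but drops metric samples", {
  res <- get_analysis("curl")
  r <- get_scene("curl")
  curl_frames <- r$truth$frame[r$truth$curl == 1]
  expect_length(res$tracks, 1L)
  tr <- res$tracks[[1]]
  expect_equal(tr$n_observed, r$seq$n_frames)  # curl frames still observed
  flagged <- as.integer(names(Filter(function(o) o$self_collision,
                                     tr$observations)))
  expect_setequal(flagged, curl_frames)
  s <- get_analysis("curl")$table$samples
  expect_false(any(s$frame %in% curl_frames &
                     s$metric %in% c("worm_area", "worm_length"), na.rm = TRUE))
  # censor_self_collisions is the identity on clean tracks
  clean <- make_track(1L, 0:4, midpoints = as.list(rep(list(c(1, 1)), 5)))
  expect_identical(censor_self_collisions(clean)$n_observed, 5L)
})

test_that("frame-percentage filtering is inclusive and exact", {
  t140 <- make_track(1L, seq_len(140))
  t150 <- make_track(2L, seq_len(150))
  kept <- filter_frame_percentage(list(t140, t150), 300L, 50)
  expect_equal(vapply(kept, function(t) t$worm_id, integer(1)), 2L)
  expect_length(filter_frame_percentage(list(t140, t150), 300L, 0), 2L)
  # the recommended operating point: 50% of a 450-frame video means every
  # reported worm carries at least 225 frames, comfortably above 200
  tracks <- lapply(1:5, function(i) make_track(i, seq_len(100 + 50 * i)))
  kept2 <- filter_frame_percentage(tracks, 450L, 50)
  n_obs <- vapply(kept2, function(t) t$n_observed, integer(1))
  expect_true(all(n_obs >= 225))
  expect_true(all(n_obs >= 200))
  expect_equal(length(kept2), sum(vapply(tracks, function(t)
    t$n_observed, integer(1)) >= 225))
})

test_that("IDs are monotone and participants never reappear", {
  res <- get_analysis("collision")
  ids <- vapply(res$tracks, function(t) t$worm_id, integer(1))
  firsts <- vapply(res$tracks, function(t) t$first_frame, integer(1))
  expect_true(all(diff(firsts[order(ids)]) >= 0))
  for (ev in res$events) {
    for (pid in ev$participant_ids) {
      tr <- res$tracks[[which(ids == pid)]]
      expect_lt(tr$last_frame, ev$start_frame)
    }
  }
})

test_that("tracking output is invariant to segmentation chunking", {
  r <- get_scene("collision", n_frames = 30)
  cfg <- analysis_config(min_size_px = 100, ucf = 10, frame_rate = 7.5)
  a <- run_analysis(r$seq, cfg, out_dir = NULL, chunk_size = 1,
                    annotate = FALSE, plots = FALSE)
  b <- run_analysis(r$seq, cfg, out_dir = NULL, chunk_size = 30,
                    annotate = FALSE, plots = FALSE)
  expect_identical(a$table, b$table)
  expect_identical(lapply(a$tracks, unclass), lapply(b$tracks, unclass))
})
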