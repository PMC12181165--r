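#' Run the full analysis pipeline on a recording
#'
#' Decodes the recording, builds the temporal-median background, segments
#' frames in chunks (optionally on several workers; results are merged in
#' frame-index order, so output is identical for any chunking), skeletonizes,
#' tracks with collision censoring, applies the frame-percentage filter, and
#' computes the six metrics. Writes per-metric tables, metric-vs-time plots,
#' a run manifest and (optionally) the annotated recording to `out_dir`.
#'
#' @param video Path to a recording (see [load_video()]) or a
#'   `frame_sequence`.
#' @param cfg An `analysis_config`.
#' @param out_dir Output directory, created if needed; `NULL` to skip all
#'   file output and return the in-memory results only.
#' @param chunk_size Frames per segmentation chunk; default
#'   `max(1, n_frames / workers)`.
#' @param workers Parallel workers for segmentation (forked; 1 = serial).
#' @param annotate Write the annotated recording (`annotated.tif`).
#' @param plots Write metric-vs-time plots.
#' @return Invisibly, a list with `table` (`metrics_table`), `tracks`,
#'   `events`, `manifest`.
#' @export
run_analysis <- function(video, cfg, out_dir = NULL, chunk_size = NULL,
                         workers = 1L, annotate = !is.null(out_dir),
                         plots = !is.null(out_dir)) {
  stopifnot(inherits(cfg, "analysis_config"))
  t0 <- proc.time()[["elapsed"]]
  seq <- if (inherits(video, "frame_sequence")) video else
    load_video(video, frame_rate_override = cfg$frame_rate)
  bg <- build_background(seq)
  t1 <- proc.time()[["elapsed"]]

  if (is.null(chunk_size)) chunk_size <- max(1L, seq$n_frames %/% workers)
  chunks <- chunk_frames(seq, chunk_size)
  seg_chunk <- function(ch) {
    lapply(seq_along(ch$frames), function(k) {
      obs <- segment_frame(ch$frames[[k]], bg, cfg, ch$start + k - 1L)
      Filter(Negate(is.null), lapply(obs, skeletonize))
    })
  }
  per_chunk <- if (workers > 1L) {
    parallel::mclapply(chunks, seg_chunk, mc.cores = workers)
  } else {
    lapply(chunks, seg_chunk)
  }
  # merge strictly in frame-index order regardless of completion order
  obs_by_frame <- do.call(c, per_chunk)
  t2 <- proc.time()[["elapsed"]]

  trk <- track_worms(obs_by_frame, seq$n_frames)
  n_total <- length(trk$tracks)
  kept <- filter_frame_percentage(trk$tracks, seq$n_frames, cfg$min_pct)
  if (!length(kept)) {
    warning("no tracks pass the ", cfg$min_pct, "% frame-percentage filter")
  }
  table <- summarize_metrics(kept, cfg)
  t3 <- proc.time()[["elapsed"]]

  manifest <- list(
    input = if (is.character(video)) video else "<in-memory frame_sequence>",
    version = as.character(utils::packageVersion("wormtrackr")),
    config = list(min_size_px = cfg$min_size_px, ucf = cfg$ucf,
                  min_pct = cfg$min_pct, frame_rate = cfg$frame_rate),
    counts = list(frames = seq$n_frames,
                  contours = sum(vapply(obs_by_frame, length, integer(1))),
                  tracks_total = n_total, tracks_kept = length(kept),
                  tracks_filtered = n_total - length(kept),
                  collision_events = length(trk$events)),
    timings_s = list(decode_background = round(t1 - t0, 3),
                     segmentation = round(t2 - t1, 3),
                     tracking_metrics = round(t3 - t2, 3)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_tables(table, out_dir)
    write_manifest(manifest, file.path(out_dir, "run_manifest.txt"))
    if (plots) plot_metrics(table, out_dir)
    if (annotate) {
      write_annotated_video(seq, kept, file.path(out_dir, "annotated.tif"),
                            events = trk$events)
    }
  }
  invisible(list(table = table, tracks = kept, events = trk$events,
                 manifest = manifest))
}

#' Export metric tables
#'
#' One frame-by-frame CSV and one per-worm summary CSV per metric, plus a
#' combined long-format table (`all_metrics.csv`) holding every metric —
#' the single-file bulk download. Units are stated in the value column
#' header.
#'
#' @param table A `metrics_table`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(table, out_dir) {
  stopifnot(inherits(table, "metrics_table"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot write tables: unwritable directory ", out_dir)
  }
  paths <- character(0)
  for (m in c("worm_area", "worm_length", "crawl_speed", "swim_speed",
              "dynamic_amplitude", "wave_initiation_rate")) {
    s <- table$samples[table$samples$metric == m, , drop = FALSE]
    unit <- if (nrow(s)) s$unit[1] else metric_unit(m)
    fb <- s[, c("worm_id", "frame", "time", "value")]
    names(fb) <- c("worm_id", "frame", "time_s", paste0("value_", safe_unit(unit)))
    p1 <- file.path(out_dir, paste0(m, "_frames.csv"))
    write.csv(fb, p1, row.names = FALSE)
    sm <- table$summary[table$summary$metric == m, c("worm_id", "mean_value")]
    names(sm) <- c("worm_id", paste0("mean_value_", safe_unit(unit)))
    p2 <- file.path(out_dir, paste0(m, "_summary.csv"))
    write.csv(sm, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  pall <- file.path(out_dir, "all_metrics.csv")
  write.csv(table$samples, pall, row.names = FALSE)
  invisible(c(paths, pall))
}

metric_unit <- function(m) {
  switch(m, worm_area = "um^2", worm_length = "um", crawl_speed = "um/s",
         swim_speed = "um/s", dynamic_amplitude = "1/um",
         wave_initiation_rate = "waves/min")
}

safe_unit <- function(u) gsub("/", "_per_", gsub("\\^", "", u))

write_manifest <- function(manifest, path) {
  flat <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, if (is.list(v)) flat(v, key) else paste0(key, " = ", v))
    }
    out
  }
  writeLines(flat(manifest), path)
  invisible(path)
}

#' Metric-vs-time plots
#'
#' One PNG per metric with a line per worm; per-worm wave rates are drawn
#' as a point chart. Intended for quick troubleshooting of a run.
#'
#' @param table A `metrics_table`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
plot_metrics <- function(table, out_dir) {
  paths <- character(0)
  for (m in unique(table$samples$metric)) {
    s <- table$samples[table$samples$metric == m, , drop = FALSE]
    if (!nrow(s)) next
    p <- if (all(is.na(s$time))) {
      ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$worm_id),
                                      y = .data$value)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "worm", y = paste0(m, " (", s$unit[1], ")"))
    } else {
      ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$value,
                                      color = factor(.data$worm_id))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = paste0(m, " (", s$unit[1], ")"),
                      color = "worm")
    }
    f <- file.path(out_dir, paste0(m, ".png"))
    ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 110)
    paths <- c(paths, f)
  }
  invisible(paths)
}
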