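#' Load a recording as a frame sequence
#'
#' Reads a multi-page TIFF stack, a single-image file, or a directory of
#' numbered PNG/TIFF frames into a `frame_sequence`: an ordered list of 8-bit
#' grayscale intensity matrices plus the frame rate. Color input is converted
#' to grayscale (Rec. 601 luma) before any processing, since every downstream
#' operator is defined on intensity masks.
#'
#' The frame rate is taken from a plain-text sidecar (`<stem>.fps` next to a
#' stack file, or `fps.txt` inside a frame directory) containing a single
#' number, unless `frame_rate_override` is given. Container videos (AVI/MP4)
#' are supported after conversion to a frame stack, e.g.
#' `ffmpeg -i rec.avi frames/%05d.png`.
#'
#' @param path Path to a `.tif`/`.tiff` stack or a directory of frames.
#' @param frame_rate_override Optional frames/second, taking precedence over
#'   any sidecar metadata.
#' @return A `frame_sequence` with fields `frames` (list of matrices in
#'   `[0, 1]`), `frame_rate`, `width`, `height`, `n_frames`.
#' @export
load_video <- function(path, frame_rate_override = NULL) {
  if (!file.exists(path)) {
    stop("cannot decode video: no such file or directory: ", path)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    files <- sort(files)
    if (length(files) < 2L) {
      stop("cannot decode video: fewer than 2 frames in directory: ", path)
    }
    frames <- lapply(files, read_frame_file)
    fps_file <- file.path(path, "fps.txt")
  } else {
    if (file.size(path) == 0L) {
      stop("cannot decode video: empty file: ", path)
    }
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff")) {
      stop("cannot decode video: unsupported container '", ext, "' for ", path,
           " (use a TIFF stack or a PNG/TIFF frame directory)")
    }
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("cannot decode video: ", path,
                                               " (", conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) {
      stop("cannot decode video: fewer than 2 frames in ", path)
    }
    frames <- lapply(pages, to_gray)
    fps_file <- paste0(tools::file_path_sans_ext(path), ".fps")
  }
  frame_rate <- frame_rate_override
  if (is.null(frame_rate)) {
    if (!file.exists(fps_file)) {
      stop("no frame-rate metadata for ", path,
           ": supply frame_rate_override or a sidecar file ", fps_file)
    }
    frame_rate <- as.numeric(readLines(fps_file, n = 1L, warn = FALSE))
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("cannot decode video: frames differ in dimensions in ", path)
  }
  frame_sequence(frames, frame_rate)
}

#' Construct a frame sequence from in-memory frames
#'
#' @param frames List of numeric matrices (grayscale, values in `[0, 1]`),
#'   all with identical dimensions.
#' @param frame_rate Frames per second (> 0).
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, frame_rate) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      is.na(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  d <- dim(frames[[1]])
  structure(
    list(frames = frames, frame_rate = frame_rate,
         width = d[2], height = d[1], n_frames = length(frames)),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.3g fps\n",
              x$n_frames, x$width, x$height, x$frame_rate))
  invisible(x)
}

read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext == "png") png::readPNG(f) else tiff::readTIFF(f)
  to_gray(img)
}

# Collapse an array with trailing channel dimension to a grayscale matrix.
to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  # quantize to 8-bit levels so file round-trips are exact
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

#' Partition a frame sequence into chunks
#'
#' Chunks tile the sequence without overlap or gap, so per-frame results
#' merged in index order reproduce sequential processing exactly regardless
#' of the order in which chunks are processed. This is the contract that
#' makes parallel segmentation order-invariant.
#'
#' @param seq A `frame_sequence`.
#' @param chunk_size Frames per chunk (>= 1); the last chunk may be short.
#' @return List of `frame_chunk` objects with `start`, `end` (0-based,
#'   half-open) and `frames`.
#' @export
chunk_frames <- function(seq, chunk_size) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is.numeric(chunk_size) || length(chunk_size) != 1L || chunk_size < 1) {
    stop("chunk_size must be a single count >= 1")
  }
  chunk_size <- as.integer(chunk_size)
  starts <- seq.int(0L, seq$n_frames - 1L, by = chunk_size)
  lapply(starts, function(s) {
    e <- min(s + chunk_size, seq$n_frames)
    structure(list(start = s, end = e,
                   frames = seq$frames[(s + 1L):e]),
              class = "frame_chunk")
  })
}

#' Write an annotated frame stack
#'
#' Renders each frame as RGB with worm outlines and midlines drawn, a numeric
#' ID label at each worm's midpoint, and a distinct highlight style for
#' collision intervals (yellow) versus tracked frames (blue). The output is a
#' multi-page TIFF with the same frame count and dimensions as the input.
#'
#' @param seq The `frame_sequence` that was analysed.
#' @param tracks List of `worm_track` objects (may be empty).
#' @param path Output `.tif`/`.tiff` path.
#' @param events Optional list of `collision_event` objects; merged blobs
#'   inside their intervals are highlighted in the collision style when the
#'   event carries per-frame regions.
#' @return Invisibly, `path`.
#' @export
write_annotated_video <- function(seq, tracks, path, events = list()) {
  stopifnot(inherits(seq, "frame_sequence"))
  col_track <- c(0.1, 0.35, 0.95)   # blue: tracked
  col_coll  <- c(0.95, 0.85, 0.05)  # yellow: collision / self-collision
  col_mid   <- c(0.9, 0.15, 0.15)
  pages <- vector("list", seq$n_frames)
  for (i in seq_len(seq$n_frames)) {
    g <- seq$frames[[i]]
    rgb <- array(g, dim = c(nrow(g), ncol(g), 3L))
    fi <- i - 1L
    for (tr in tracks) {
      obs <- tr$observations[[as.character(fi)]]
      if (is.null(obs)) next
      style <- if (isTRUE(obs$self_collision)) col_coll else col_track
      rgb <- draw_points(rgb, obs$contour$boundary, style)
      if (!is.null(obs$midline)) rgb <- draw_points(rgb, obs$midline, col_mid)
      anchor <- if (!is.null(obs$midpoint)) obs$midpoint else obs$contour$centroid
      rgb <- draw_label(rgb, tr$worm_id, anchor, style)
    }
    for (ev in events) {
      if (fi >= ev$start_frame && fi < ev$end_frame &&
          !is.null(ev$regions[[as.character(fi)]])) {
        rgb <- draw_points(rgb, ev$regions[[as.character(fi)]], col_coll)
      }
    }
    pages[[i]] <- rgb
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path), error = function(e) {
    stop("cannot write annotated video to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

# Set pixels (n x 2 matrix of 0-based x,y) to an RGB color, clipped to frame.
draw_points <- function(rgb, xy, col) {
  if (is.null(xy) || NROW(xy) == 0L) return(rgb)
  xy <- round(as.matrix(xy))
  keep <- xy[, 1] >= 0 & xy[, 1] < dim(rgb)[2] &
          xy[, 2] >= 0 & xy[, 2] < dim(rgb)[1]
  xy <- xy[keep, , drop = FALSE]
  for (k in 1:3) {
    rgb[cbind(xy[, 2] + 1L, xy[, 1] + 1L, k)] <- col[k]
  }
  rgb
}

# 3x5 bitmap digit font, glyphs column-wise strings of 15 bits.
.digit_font <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r) {
    m <- do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]])))
    which(m == 1L, arr.ind = TRUE)  # (row, col), 1-based
  })
})

# Stamp the decimal digits of `id` near anchor (0-based x,y).
draw_label <- function(rgb, id, anchor, col) {
  digits <- strsplit(as.character(id), "")[[1]]
  x0 <- round(anchor[1]) + 4L
  y0 <- round(anchor[2]) - 8L
  for (d in digits) {
    px <- .digit_font[[d]]
    if (!is.null(px)) {
      xy <- cbind(x0 + px[, 2] - 1L, y0 + px[, 1] - 1L)
      rgb <- draw_points(rgb, xy, col)
    }
    x0 <- x0 + 4L
  }
  rgb
}
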