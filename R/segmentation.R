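#' Build a temporal-median background model
#'
#' The per-pixel temporal median over sampled frames removes anything that
#' moves (worms) and keeps anything static (substrate, debris, illumination
#' pattern), provided each pixel is worm-free in more than half of the
#' sampled frames. Static debris therefore never becomes a tracked worm: it
#' cancels in the background subtraction.
#'
#' @param seq A `frame_sequence` (>= 2 frames).
#' @param sample_stride Use every `sample_stride`-th frame (default chosen so
#'   at most ~25 frames enter the median).
#' @return A `background_model` with fields `reference` (matrix) and
#'   `polarity` (`"dark-on-light"` or `"light-on-dark"`).
#' @export
build_background <- function(seq, sample_stride = NULL) {
  stopifnot(inherits(seq, "frame_sequence"), seq$n_frames >= 2L)
  if (is.null(sample_stride)) {
    sample_stride <- max(1L, seq$n_frames %/% 25L)
  }
  if (sample_stride < 1) stop("sample_stride must be >= 1")
  idx <- seq.int(1L, seq$n_frames, by = as.integer(sample_stride))
  arr <- vapply(seq$frames[idx], identity,
                matrix(0, seq$height, seq$width))
  ref <- if (length(idx) == 1L) seq$frames[[1L]] else
    apply(arr, c(1, 2), median)
  # foreground darker or lighter than background, judged on the largest
  # deviations over the sampled frames
  dev <- seq$frames[[1L]] - ref
  pol <- if (sum(dev[dev < 0]^2) >= sum(dev[dev > 0]^2))
    "dark-on-light" else "light-on-dark"
  structure(list(reference = ref, polarity = pol),
            class = "background_model")
}

#' Segment the foreground of one frame
#'
#' Thresholds the absolute difference between a frame and the background
#' reference at an automatically chosen (Otsu) level, then removes speckle
#' by opening-by-reconstruction: a 3x3 morphological opening decides which
#' components survive, and surviving components are kept pixel-exact (so a
#' noiseless rendering segments to exactly its rendered mask, while isolated
#' noise pixels vanish). Frames indistinguishable from the background
#' (difference range below ~2 intensity levels) yield an empty mask rather
#' than thresholded sensor noise.
#'
#' @param frame Intensity matrix, same dimensions as the background.
#' @param bg A `background_model`.
#' @return Logical foreground mask, same dimensions as `frame`.
#' @export
preprocess_frame <- function(frame, bg) {
  stopifnot(inherits(bg, "background_model"))
  if (!identical(dim(frame), dim(bg$reference))) {
    stop("frame dimensions ", paste(dim(frame), collapse = "x"),
         " do not match background ",
         paste(dim(bg$reference), collapse = "x"))
  }
  d <- abs(frame - bg$reference)
  if (max(d) < 2 / 255) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  thr <- EBImage::otsu(EBImage::Image(d), range = c(0, max(d)))
  # frames with little or no foreground would otherwise have Otsu split the
  # sensor noise itself; floor the threshold at 5x the robust noise scale
  thr <- max(thr, 5 * stats::mad(d))
  mask <- d > thr
  opened <- EBImage::opening(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3, shape = "box"))
  opened <- as.numeric(opened) > 0.5
  # reconstruction: keep, pixel-exact, every component with a surviving core
  lab <- .cc_label(matrix(as.integer(mask), nrow(frame), ncol(frame)), 8L)
  keep <- setdiff(unique(lab[opened]), 0L)
  matrix(lab %in% keep & mask, nrow(frame), ncol(frame))
}

#' Extract worm-candidate contours from a binary mask
#'
#' One observation per 8-connected foreground component, with its outer
#' boundary, pixel area ("worm pixels"), centroid and bounding box.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param frame_index 0-based frame index recorded on each observation.
#' @return List of `contour_observation` objects, ordered by label.
#' @export
find_contours <- function(mask, frame_index) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- .cc_label(m, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)  # (row, col) 1-based
    ys <- idx[, 1] - 1L
    xs <- idx[, 2] - 1L
    bbox <- c(x0 = min(xs), y0 = min(ys), x1 = max(xs) + 1L, y1 = max(ys) + 1L)
    sub <- matrix(FALSE, bbox["y1"] - bbox["y0"], bbox["x1"] - bbox["x0"])
    sub[cbind(ys - bbox["y0"] + 1L, xs - bbox["x0"] + 1L)] <- TRUE
    contour_observation(
      frame_index = frame_index,
      boundary = boundary_pixels(sub, bbox),
      mask = sub,
      area_px = nrow(idx),
      centroid = c(mean(xs), mean(ys)),
      bbox = bbox)
  })
}

contour_observation <- function(frame_index, boundary, mask, area_px,
                                centroid, bbox) {
  structure(list(frame_index = frame_index, boundary = boundary, mask = mask,
                 area_px = area_px, centroid = centroid, bbox = bbox),
            class = "contour_observation")
}

# Outer boundary: foreground pixels with a 4-neighbour outside the component.
# Returned as (x, y) 0-based full-frame coordinates, ordered by a walk along
# the EBImage contour tracer.
boundary_pixels <- function(sub, bbox) {
  padded <- matrix(0L, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub * 1L
  oc <- EBImage::ocontour(EBImage::Image(t(padded)))
  if (length(oc) == 0L) return(matrix(numeric(0), 0, 2))
  xy <- oc[[1]]  # 0-based (x, y) in padded transposed image
  cbind(x = xy[, 1] - 1L + bbox["x0"], y = xy[, 2] - 1L + bbox["y0"],
        deparse.level = 0)
}

#' Filter observations by minimum worm size
#'
#' Retains observations whose pixel area is at least `min_size_px`
#' (inclusive threshold). Order is preserved; the filter is idempotent.
#'
#' @param obs List of `contour_observation`.
#' @param min_size_px Minimum pixel count (>= 0).
#' @return Filtered list.
#' @export
filter_min_size <- function(obs, min_size_px) {
  stopifnot(min_size_px >= 0)
  Filter(function(o) o$area_px >= min_size_px, obs)
}

#' Filter observations touching the frame edge
#'
#' Removes observations whose mask intersects row 0, column 0, the last row,
#' or the last column: a body clipped by the field of view has unmeasurable
#' area and length.
#'
#' @param obs List of `contour_observation`.
#' @param width,height Frame dimensions in pixels.
#' @return Filtered list (order preserved; idempotent).
#' @export
filter_edge_touching <- function(obs, width, height) {
  Filter(function(o) {
    o$bbox["x0"] > 0L && o$bbox["y0"] > 0L &&
      o$bbox["x1"] < width && o$bbox["y1"] < height
  }, obs)
}

#' Segment one frame end to end
#'
#' Convenience composition: `preprocess_frame`, `find_contours`,
#' `filter_min_size`, `filter_edge_touching`. Depends only on the frame and
#' the background model, which is what makes chunked parallel segmentation
#' order-invariant.
#'
#' @param frame Intensity matrix.
#' @param bg A `background_model`.
#' @param cfg An `analysis_config`.
#' @param frame_index 0-based frame index.
#' @return List of `contour_observation`.
#' @export
segment_frame <- function(frame, bg, cfg, frame_index) {
  mask <- preprocess_frame(frame, bg)
  obs <- find_contours(mask, frame_index)
  obs <- filter_min_size(obs, cfg$min_size_px)
  filter_edge_touching(obs, ncol(frame), nrow(frame))
}
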