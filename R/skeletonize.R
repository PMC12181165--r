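#' Reduce a worm contour to an ordered midline
#'
#' Thins the body mask to a 1-pixel-wide skeleton (Guo-Hall), prunes spurs
#' shorter than 10% of the longest endpoint-to-endpoint path, orders the
#' remaining path end to end, and extends both ends along their local
#' tangents to the contour boundary (thinning retracts the tips by about half
#' the body width; the extension restores the full head-to-tail midline).
#' Seven tracking points are placed at equal arclength fractions
#' \{0, 1/6, ..., 1\}; the midpoint is tracking point 3 (fraction 1/2), the
#' middle pixel along the midline.
#'
#' Self-collisions (closed curls, overlapping body) leave no unambiguous
#' midline; the observation is returned with `self_collision = TRUE` and no
#' midline, and contributes no metric data until the posture opens.
#'
#' @param contour A `contour_observation` that passed the segmentation
#'   filters.
#' @return A `skeleton_observation`, or `NULL` (with a message) for
#'   degenerate shapes that thin to fewer than 7 pixels without being
#'   self-collisions.
#' @export
skeletonize <- function(contour) {
  stopifnot(inherits(contour, "contour_observation"))
  an <- skeleton_analysis(contour)
  if (an$self_collision) {
    return(skeleton_observation(contour, midline = NULL, midline_len_px = NA_real_,
                                tracking_points = NULL, midpoint = NULL,
                                self_collision = TRUE))
  }
  if (is.null(an$path) || nrow(an$path) < 7L) {
    message("dropping degenerate shape in frame ", contour$frame_index,
            ": midline of ", NROW(an$path), " px")
    return(NULL)
  }
  path <- extend_to_boundary(an$path, contour$mask)
  # a digital 8-connected path staircases around the true curve; a short
  # moving average (ends pinned) removes the zigzag before measuring
  smooth <- smooth_path(path)
  steps <- sqrt(rowSums(diff(smooth)^2))
  len <- 1 + sum(steps)
  tp <- sample_tracking_points(smooth)
  skeleton_observation(
    contour, midline = path + rep(c(contour$bbox["x0"], contour$bbox["y0"]),
                                  each = nrow(path)),
    midline_len_px = len,
    tracking_points = tp + rep(c(contour$bbox["x0"], contour$bbox["y0"]),
                               each = 7L),
    midpoint = tp[4, ] + c(contour$bbox["x0"], contour$bbox["y0"]),
    self_collision = FALSE)
}

skeleton_observation <- function(contour, midline, midline_len_px,
                                 tracking_points, midpoint, self_collision) {
  structure(list(contour = contour, midline = midline,
                 midline_len_px = midline_len_px,
                 tracking_points = tracking_points, midpoint = midpoint,
                 self_collision = self_collision),
            class = "skeleton_observation")
}

# Core skeleton geometry: thin, build the pixel graph, find the longest
# endpoint-to-endpoint path, measure residual branches, detect holes/cycles.
# Coordinates in the returned path are (x, y), 0-based, relative to the
# contour's cropped mask.
skeleton_analysis <- function(contour) {
  sub <- contour$mask
  if (has_interior_hole(sub)) {
    return(list(self_collision = TRUE, path = NULL, skeleton = NULL))
  }
  skel <- .thin_mask(matrix(as.integer(sub), nrow(sub), ncol(sub)))
  pix <- which(skel == 1L, arr.ind = TRUE)  # (row, col) 1-based
  if (nrow(pix) <= 1L) {
    return(list(self_collision = FALSE, path = NULL, skeleton = skel))
  }
  g <- skeleton_graph(skel, pix)
  # cycles: edges >= vertices - components + 1
  if (g$n_edges >= nrow(pix) - g$n_components + 1L) {
    return(list(self_collision = TRUE, path = NULL, skeleton = skel))
  }
  ends <- which(g$degree == 1L)
  if (length(ends) < 2L) {
    return(list(self_collision = TRUE, path = NULL, skeleton = skel))
  }
  # longest path on a tree: double BFS restricted to the largest component
  comp_main <- as.integer(names(which.max(table(g$component))))
  start <- ends[g$component[ends] == comp_main][1]
  far1 <- bfs_farthest(g, start)
  far2 <- bfs_farthest(g, far1$node)
  main_path <- far2$path                      # vertex indices, ordered
  main_len <- far2$dist
  # residual branches: endpoint distance off the main path
  on_path <- logical(nrow(pix))
  on_path[main_path] <- TRUE
  other_ends <- setdiff(ends[g$component[ends] == comp_main], main_path)
  for (e in other_ends) {
    if (branch_length(g, e, on_path) > 0.10 * main_len) {
      return(list(self_collision = TRUE, path = NULL, skeleton = skel))
    }
  }
  # small disconnected fragments (thinning artifacts) are ignored
  path_xy <- cbind(pix[main_path, 2] - 1L, pix[main_path, 1] - 1L)
  list(self_collision = FALSE, path = path_xy, skeleton = skel)
}

# TRUE if the mask contains an interior hole: a background component (4-conn)
# of the padded complement that does not touch the pad border.
has_interior_hole <- function(sub) {
  padded <- matrix(1L, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- 1L - (sub * 1L)
  lab <- .cc_label(padded, 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  max(lab) > length(setdiff(border_labels, 0L))
}

# Adjacency structure over skeleton pixels (8-connectivity).
skeleton_graph <- function(skel, pix) {
  H <- nrow(skel)
  key <- (pix[, 2] - 1L) * H + pix[, 1]          # linear index
  lookup <- setNames(seq_along(key), key)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  adj <- vector("list", nrow(pix))
  deg <- integer(nrow(pix))
  for (k in seq_len(nrow(offs))) {
    ny <- pix[, 1] + offs$dy[k]
    nx <- pix[, 2] + offs$dx[k]
    ok <- ny >= 1 & ny <= H & nx >= 1 & nx <= ncol(skel)
    nkey <- (nx - 1L) * H + ny
    hit <- ok & !is.na(lookup[as.character(nkey)])
    nbr <- lookup[as.character(nkey[hit])]
    src <- which(hit)
    for (i in seq_along(src)) {
      adj[[src[i]]] <- c(adj[[src[i]]], nbr[i])
    }
    deg[src] <- deg[src] + 1L
  }
  # connected components of the skeleton graph
  comp <- integer(nrow(pix))
  cc <- 0L
  for (v in seq_len(nrow(pix))) {
    if (comp[v] != 0L) next
    cc <- cc + 1L
    queue <- v
    comp[v] <- cc
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- cc
          queue <- c(queue, w)
        }
      }
    }
  }
  # weighted edges: 1 for rook steps, sqrt(2) for diagonal
  wfun <- function(a, b) sqrt(sum((pix[a, ] - pix[b, ])^2))
  list(adj = adj, degree = deg, component = comp, n_components = cc,
       n_edges = sum(deg) %/% 2L, weight = wfun, pix = pix)
}

# Dijkstra-lite on the (tree) skeleton graph; returns the farthest vertex,
# its weighted distance, and the path to it.
bfs_farthest <- function(g, start) {
  n <- length(g$adj)
  dist <- rep(Inf, n)
  parent <- integer(n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    for (w in g$adj[[u]]) {
      nd <- dist[u] + g$weight(u, w)
      if (nd < dist[w]) {
        dist[w] <- nd
        parent[w] <- u
        queue <- c(queue, w)
      }
    }
  }
  reach <- which(is.finite(dist))
  node <- reach[which.max(dist[reach])]
  path <- node
  while (parent[path[1]] != 0L) path <- c(parent[path[1]], path)
  list(node = node, dist = dist[node], path = path)
}

# Weighted distance from an off-path endpoint to the nearest main-path vertex.
branch_length <- function(g, from, on_path) {
  dist <- 0
  prev <- 0L
  v <- from
  repeat {
    nxt <- setdiff(g$adj[[v]], prev)
    if (length(nxt) == 0L) return(dist)
    # at a branch point several continuations exist; stop there
    w <- nxt[1]
    dist <- dist + g$weight(v, w)
    if (on_path[w]) return(dist)
    if (length(nxt) > 1L) return(dist)
    prev <- v
    v <- w
  }
}

# Moving-average smoothing of an ordered pixel path; window is odd, ends
# are padded by repetition so the path endpoints stay fixed.
smooth_path <- function(path, window = 5L) {
  n <- nrow(path)
  if (n < window) return(path)
  h <- window %/% 2L
  padded <- rbind(path[rep(1L, h), , drop = FALSE], path,
                  path[rep(n, h), , drop = FALSE])
  k <- rep(1 / window, window)
  out <- cbind(stats::filter(padded[, 1], k)[(h + 1):(h + n)],
               stats::filter(padded[, 2], k)[(h + 1):(h + n)])
  out[1, ] <- path[1, ]
  out[n, ] <- path[n, ]
  out
}

# Extend both path ends along their local tangent until leaving the mask.
extend_to_boundary <- function(path, sub, tangent_span = 4L, max_ext = 25L) {
  extend_one <- function(p) {
    n <- nrow(p)
    k <- min(tangent_span, n - 1L)
    v <- p[n, ] - p[n - k, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(p)
    v <- v / nv
    added <- NULL
    pos <- p[n, ]
    for (s in seq(0.5, max_ext, by = 0.5)) {
      q <- round(p[n, ] + v * s)
      if (q[1] < 0 || q[2] < 0 || q[1] >= ncol(sub) || q[2] >= nrow(sub)) break
      if (!sub[q[2] + 1L, q[1] + 1L]) break
      if (!identical(q, pos)) {
        added <- rbind(added, q)
        pos <- q
      }
    }
    if (is.null(added)) p else rbind(p, added)
  }
  path <- extend_one(path)
  path <- extend_one(path[nrow(path):1, , drop = FALSE])
  path
}

#' Place seven tracking points along a midline
#'
#' Points at arclength fractions \{0, 1/6, 2/6, ..., 1\}, each snapped to the
#' nearest path pixel, with points 0 and 6 at the path ends. Arclength is
#' accumulated along the 8-connected path with diagonal steps weighted
#' sqrt(2).
#'
#' @param midline Ordered `n x 2` matrix of (x, y) path pixels, `n >= 7`.
#' @return A `7 x 2` matrix of (x, y) positions.
#' @export
sample_tracking_points <- function(midline) {
  midline <- as.matrix(midline)
  if (nrow(midline) < 7L) {
    stop("degenerate shape: midline of ", nrow(midline), " px is too short ",
         "for 7 tracking points")
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(midline)^2))))
  total <- s[length(s)]
  targets <- total * (0:6) / 6
  idx <- vapply(targets, function(t) which.min(abs(s - t)), integer(1))
  idx[1] <- 1L
  idx[7] <- nrow(midline)
  midline[idx, , drop = FALSE]
}

#' Detect a self-collision posture
#'
#' A worm tied into a closed curl or overlapping its own body has no
#' unambiguous midline. The posture is flagged when (a) the contour mask
#' contains an interior hole (a curl closing a loop), or (b) the pruned
#' skeleton retains a cycle, more than 2 endpoints, or a branch longer than
#' 10% of the main path (body overlap).
#'
#' @param contour A `contour_observation`.
#' @return Logical flag.
#' @export
detect_self_collision <- function(contour) {
  skeleton_analysis(contour)$self_collision
}
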