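#' Track worms across a segmented frame sequence
#'
#' Assigns persistent IDs by greedy best-overlap association (mask/bounding
#' box overlap first, nearest centroid within one median body length as the
#' fallback gate). An observation overlapping two or more active tracks
#' starts a worm-worm collision: the participating IDs are terminated, the
#' merged blob is followed but never measured, and when it resolves into two
#' or more separate size-gated observations each worm receives a fresh ID.
#' IDs are never reused. A track missing for more than `patience` consecutive
#' frames without a collision is closed.
#'
#' Self-collision (curl) frames keep their track ID — the worm never merged
#' with another — but carry no midline and contribute no metric samples.
#'
#' @param obs_by_frame List over frames (index 1 = frame 0) of lists of
#'   `skeleton_observation`.
#' @param n_frames Total frame count of the video.
#' @param patience Maximum consecutive missing frames before a track closes.
#' @return List with `tracks` (list of `worm_track`) and `events` (list of
#'   `collision_event`).
#' @export
track_worms <- function(obs_by_frame, n_frames, patience = 5L) {
  st <- tracker_state(patience)
  for (i in seq_len(n_frames)) {
    obs <- if (i <= length(obs_by_frame)) obs_by_frame[[i]] else list()
    st <- match_frame(st, obs, i - 1L)
  }
  finalize_tracker(st)
}

#' @rdname track_worms
#' @param patience Maximum consecutive missing frames before a track closes.
#' @export
tracker_state <- function(patience = 5L) {
  structure(list(active = list(), closed = list(), regions = list(),
                 events = list(), next_id = 1L, patience = patience),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' The single-frame association step; see [track_worms()] for the rules.
#' Consumes frames strictly in order, which is what makes tracking output
#' independent of how segmentation was chunked.
#'
#' @param st A `tracker_state`.
#' @param obs List of `skeleton_observation` for this frame.
#' @param frame_index 0-based frame index.
#' @return The updated `tracker_state`.
#' @export
match_frame <- function(st, obs, frame_index) {
  stopifnot(inherits(st, "tracker_state"))
  n_obs <- length(obs)
  n_act <- length(st$active)
  obs_taken <- rep(FALSE, n_obs)

  # --- collision-region continuation / resolution -------------------------
  if (length(st$regions)) {
    keep_regions <- list()
    for (rg in st$regions) {
      hits <- which(!obs_taken &
                      vapply(obs, function(o)
                        mask_overlap(o$contour, rg$contour) > 0, logical(1)))
      if (length(hits) >= 2L) {
        # separation: event closes, fresh IDs for each emerging worm
        succ <- integer(0)
        for (h in hits) {
          st <- start_track(st, obs[[h]], frame_index)
          succ <- c(succ, st$next_id - 1L)
          obs_taken[h] <- TRUE
        }
        ev <- st$events[[rg$event]]
        ev$end_frame <- frame_index
        ev$successor_ids <- succ
        st$events[[rg$event]] <- ev
      } else if (length(hits) == 1L) {
        rg$contour <- obs[[hits]]$contour
        rg$missing <- 0L
        ev <- st$events[[rg$event]]
        ev$regions[[as.character(frame_index)]] <- obs[[hits]]$contour$boundary
        st$events[[rg$event]] <- ev
        obs_taken[hits] <- TRUE
        keep_regions <- c(keep_regions, list(rg))
      } else {
        rg$missing <- rg$missing + 1L
        if (rg$missing <= st$patience) keep_regions <- c(keep_regions, list(rg))
        else {
          ev <- st$events[[rg$event]]
          ev$end_frame <- frame_index
          st$events[[rg$event]] <- ev
        }
      }
    }
    st$regions <- keep_regions
  }

  # --- overlap matrix against active tracks -------------------------------
  if (n_act && n_obs) {
    ov <- matrix(0, n_obs, n_act)
    for (j in seq_len(n_act)) {
      last <- st$active[[j]]$last_contour
      for (i in seq_len(n_obs)) {
        if (!obs_taken[i]) ov[i, j] <- mask_overlap(obs[[i]]$contour, last)
      }
    }
  } else {
    ov <- matrix(0, n_obs, max(n_act, 0L))
  }

  # --- worm-worm collision starts -----------------------------------------
  track_dead <- rep(FALSE, n_act)
  if (n_act && n_obs) {
    for (i in seq_len(n_obs)) {
      if (obs_taken[i]) next
      parts <- which(ov[i, ] > 0 & !track_dead)
      if (length(parts) >= 2L) {
        ids <- vapply(st$active[parts], function(a) a$id, integer(1))
        ev <- collision_event(start_frame = frame_index,
                              participant_ids = ids, kind = "worm-worm")
        ev$regions[[as.character(frame_index)]] <- obs[[i]]$contour$boundary
        st$events <- c(st$events, list(ev))
        st$regions <- c(st$regions, list(list(
          contour = obs[[i]]$contour, event = length(st$events),
          missing = 0L)))
        for (p in parts) {
          st$closed <- c(st$closed, list(st$active[[p]]))
          track_dead[p] <- TRUE
        }
        obs_taken[i] <- TRUE
        ov[i, ] <- 0
      }
    }
  }

  # --- greedy one-to-one assignment by overlap ----------------------------
  track_taken <- track_dead
  if (n_act && n_obs) {
    repeat {
      best <- arrayInd(which.max(ov), dim(ov))
      if (ov[best] <= 0) break
      i <- best[1]; j <- best[2]
      if (!obs_taken[i] && !track_taken[j]) {
        st$active[[j]] <- append_obs(st$active[[j]], obs[[i]], frame_index)
        obs_taken[i] <- TRUE
        track_taken[j] <- TRUE
      }
      ov[i, ] <- 0
      ov[, j] <- 0
    }
  }

  # --- centroid fallback within one body length ---------------------------
  if (n_act && any(!obs_taken)) {
    body <- body_length_scale(st$active)
    for (i in which(!obs_taken)) {
      free <- which(!track_taken)
      if (!length(free)) break
      d <- vapply(st$active[free], function(a)
        sqrt(sum((a$last_contour$centroid - obs[[i]]$contour$centroid)^2)),
        numeric(1))
      j <- free[which.min(d)]
      if (min(d) <= body) {
        st$active[[j]] <- append_obs(st$active[[j]], obs[[i]], frame_index)
        obs_taken[i] <- TRUE
        track_taken[j] <- TRUE
      }
    }
  }

  # --- leftovers start fresh tracks ---------------------------------------
  for (i in which(!obs_taken)) {
    # blobs overlapping an open collision region were consumed above; any
    # remaining observation is a newly visible worm
    st <- start_track(st, obs[[i]], frame_index)
  }

  # --- age out unmatched tracks -------------------------------------------
  # tracks appended during this frame (collision successors, fresh IDs) sit
  # beyond position n_act and are kept as-is
  new_tracks <- if (length(st$active) > n_act)
    st$active[(n_act + 1L):length(st$active)] else list()
  keep <- list()
  for (j in seq_len(n_act)) {
    if (track_dead[j]) next
    tr <- st$active[[j]]
    if (!track_taken[j]) {
      tr$missing <- tr$missing + 1L
      if (tr$missing > st$patience) {
        st$closed <- c(st$closed, list(tr))
        next
      }
    }
    keep <- c(keep, list(tr))
  }
  keep <- c(keep, new_tracks)
  st$active <- keep[order(vapply(keep, function(t) t$id, integer(1)))]
  st
}

start_track <- function(st, o, frame_index) {
  tr <- list(id = st$next_id, observations = list(), first_frame = frame_index,
             last_frame = frame_index, missing = 0L, last_contour = NULL)
  tr <- append_obs(tr, o, frame_index)
  st$active <- c(st$active, list(tr))
  st$next_id <- st$next_id + 1L
  st
}

append_obs <- function(tr, o, frame_index) {
  tr$observations[[as.character(frame_index)]] <- o
  tr$last_frame <- frame_index
  tr$last_contour <- o$contour
  tr$missing <- 0L
  tr
}

# Median midline length over active tracks; generous default when unknown.
body_length_scale <- function(active) {
  lens <- unlist(lapply(active, function(a) {
    ls <- vapply(a$observations, function(o)
      if (is.na(o$midline_len_px)) NA_real_ else o$midline_len_px, numeric(1))
    ls[!is.na(ls)]
  }))
  if (!length(lens)) return(50)
  median(lens)
}

mask_overlap <- function(a, b) {
  x0 <- max(a$bbox["x0"], b$bbox["x0"]); x1 <- min(a$bbox["x1"], b$bbox["x1"])
  y0 <- max(a$bbox["y0"], b$bbox["y0"]); y1 <- min(a$bbox["y1"], b$bbox["y1"])
  if (x0 >= x1 || y0 >= y1) return(0)
  sa <- a$mask[(y0 - a$bbox["y0"] + 1L):(y1 - a$bbox["y0"]),
               (x0 - a$bbox["x0"] + 1L):(x1 - a$bbox["x0"]), drop = FALSE]
  sb <- b$mask[(y0 - b$bbox["y0"] + 1L):(y1 - b$bbox["y0"]),
               (x0 - b$bbox["x0"] + 1L):(x1 - b$bbox["x0"]), drop = FALSE]
  sum(sa & sb)
}

collision_event <- function(start_frame, participant_ids, kind) {
  structure(list(start_frame = start_frame, end_frame = NA_integer_,
                 participant_ids = participant_ids,
                 successor_ids = integer(0), kind = kind, regions = list()),
            class = "collision_event")
}

finalize_tracker <- function(st) {
  all_tracks <- c(st$closed, st$active)
  tracks <- lapply(all_tracks, function(tr) {
    structure(list(worm_id = tr$id, observations = tr$observations,
                   first_frame = tr$first_frame, last_frame = tr$last_frame,
                   n_observed = length(tr$observations)),
              class = "worm_track")
  })
  tracks <- tracks[order(vapply(tracks, function(t) t$worm_id, integer(1)))]
  list(tracks = tracks, events = st$events)
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> id %d, frames [%d, %d], %d observed\n",
              x$worm_id, x$first_frame, x$last_frame, x$n_observed))
  invisible(x)
}

#' Censor self-collision frames of a track
#'
#' Frames flagged as self-collisions retain the detection (they count as
#' observed — the worm never merged with another and keeps its ID) but any
#' midline-derived fields are removed so no metric can draw on them.
#'
#' @param track A `worm_track`.
#' @return The track with self-collision frames stripped of midline data.
#' @export
censor_self_collisions <- function(track) {
  stopifnot(inherits(track, "worm_track"))
  track$observations <- lapply(track$observations, function(o) {
    if (isTRUE(o$self_collision)) {
      o$midline <- NULL
      o$tracking_points <- NULL
      o$midpoint <- NULL
      o$midline_len_px <- NA_real_
    }
    o
  })
  track
}

#' Apply the frame-percentage filter
#'
#' Removes tracks observed in fewer than `min_pct` percent of the video's
#' frames (inclusive threshold). Sporadic detections — debris drifting into
#' focus, worms at the field edge — rarely persist, so the filter suppresses
#' false positives; 50% with at least 200 total frames is a practical
#' operating point.
#'
#' @param tracks List of `worm_track`.
#' @param total_frames Total frame count of the video.
#' @param min_pct Minimum percentage (0-100).
#' @return Filtered list of tracks.
#' @export
filter_frame_percentage <- function(tracks, total_frames, min_pct) {
  stopifnot(min_pct >= 0, min_pct <= 100)
  Filter(function(tr) 100 * tr$n_observed / total_frames >= min_pct, tracks)
}
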