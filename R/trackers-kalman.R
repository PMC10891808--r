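#' Configurations for the Kalman-based trackers
#'
#' `sort_config()` follows the canonical SORT settings: Hungarian association
#' on `1 - IOU` against Kalman-predicted boxes, tracks deleted after going
#' unmatched for more than `max_age` frames (default 1), and a track's box
#' emitted only once it has been matched `min_hits` frames in a row (the
#' burn-in is waived during the first `min_hits` frames of the stream).
#'
#' `deepsort_config()` adds an age-ordered matching cascade: confirmed tracks
#' are matched level by level in increasing time-since-update, so recently
#' seen tracks get first claim on detections; leftovers then go through plain
#' IOU association. The appearance term is a pluggable hook: `similarity`
#' may be a function `(track, det) -> [0, 1]` (the track's `last_det` field
#' holds the detection row it last matched, so identity oracles can be built
#' in tests); when `NULL`, the cascade runs on IOU alone.
#'
#' `modified_deepsort_config()` layers the re-identification rule on top: the
#' tracker counts instances as the number of boxes, and on a detection frame
#' loss (fewer detections than boxes emitted in the previous frame) it
#' computes pairwise IOU among the stored boxes; every pair overlapping at
#' IOU >= `retain_iou` (default 0.9) has its box values and IDs retained into
#' the next step, for `retain_frames` frames (default 1).
#'
#' `byte_config()` drives two-stage score-split association: stage 1 matches
#' high-score detections (score >= `high_score`) to all predicted tracks;
#' stage 2 matches the remaining low-score detections (score in
#' `[low_score, high_score)`) to the tracks left unmatched by stage 1. Only
#' unmatched high-score detections may spawn new tracks, so low-confidence
#' clutter can extend an existing track through an occlusion dip but can
#' never create one.
#'
#' @param iou_threshold minimum IOU for an association.
#' @param max_age frames a track survives without a match.
#' @param min_hits consecutive matches before a track's box is emitted.
#' @export
sort_config <- function(iou_threshold = 0.3, max_age = 1L, min_hits = 3L) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1, max_age >= 0, min_hits >= 1)
  list(iou_threshold = iou_threshold, max_age = as.integer(max_age),
       min_hits = as.integer(min_hits))
}

#' @rdname sort_config
#' @param similarity optional appearance hook, `function(track, det)`
#'   returning a similarity in `[0, 1]`; `NULL` for IOU-only matching.
#' @param similarity_gate maximum cost `1 - similarity` accepted when the
#'   hook is in use.
#' @export
deepsort_config <- function(iou_threshold = 0.3, max_age = 30L, min_hits = 3L,
                            similarity = NULL, similarity_gate = 0.5) {
  c(sort_config(iou_threshold, max_age, min_hits),
    list(similarity = similarity, similarity_gate = similarity_gate))
}

#' @rdname sort_config
#' @param retain_iou pairwise-IOU level at or above which stored boxes and
#'   their IDs are retained across a detection frame loss.
#' @param retain_frames how many frames a retained box persists.
#' @export
modified_deepsort_config <- function(iou_threshold = 0.3, max_age = 30L,
                                     min_hits = 3L, similarity = NULL,
                                     similarity_gate = 0.5,
                                     retain_iou = 0.9, retain_frames = 1L) {
  stopifnot(retain_iou > 0, retain_iou <= 1)
  c(deepsort_config(iou_threshold, max_age, min_hits, similarity, similarity_gate),
    list(retain_iou = retain_iou, retain_frames = as.integer(retain_frames)))
}

#' @rdname sort_config
#' @param high_score,low_score score split for the two association stages;
#'   requires `0 <= low_score < high_score <= 1`.
#' @export
byte_config <- function(high_score = 0.5, low_score = 0.1,
                        iou_threshold = 0.3, max_age = 30L) {
  stopifnot(low_score >= 0, low_score < high_score, high_score <= 1)
  list(high_score = high_score, low_score = low_score,
       iou_threshold = iou_threshold, max_age = as.integer(max_age))
}

new_kf_track <- function(trk, box, frame, det = NULL) {
  list(id = new_track_id(trk), kf = kf_box_init(box),
       time_since_update = 0L, hits = 1L, hit_streak = 1L,
       created = frame, last_det = det)
}

kf_track_update <- function(t, box, det = NULL) {
  t$kf <- kalman_update(t$kf, box)
  t$time_since_update <- 0L
  t$hits <- t$hits + 1L
  t$hit_streak <- t$hit_streak + 1L
  if (!is.null(det)) t$last_det <- det
  t
}

predicted_boxes <- function(tracks) {
  if (!length(tracks)) return(matrix(numeric(0), 0L, 4L))
  do.call(rbind, lapply(tracks, function(t) kf_box_state_to_box(t$kf)))
}

# Emission rule shared by SORT-family trackers: matched this frame and either
# past burn-in or still in the stream's first min_hits frames.
emit_sort_like <- function(tracks, frame, min_hits) {
  ids <- integer(0); boxes <- NULL
  for (t in tracks) {
    if (t$time_since_update == 0L &&
        (t$hit_streak >= min_hits || frame <= min_hits)) {
      ids <- c(ids, t$id)
      boxes <- rbind(boxes, kf_box_state_to_box(t$kf))
    }
  }
  frame_result(ids, boxes, rep("active", length(ids)))
}

step_frame.sort_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  for (ti in seq_along(trk$tracks)) {
    trk$tracks[[ti]]$kf <- kalman_predict(trk$tracks[[ti]]$kf)
    trk$tracks[[ti]]$time_since_update <- trk$tracks[[ti]]$time_since_update + 1L
  }
  asg <- associate_iou(predicted_boxes(trk$tracks), db, cfg$iou_threshold)
  for (k in seq_len(nrow(asg$matches))) {
    ti <- asg$matches[k, 1L]; dj <- asg$matches[k, 2L]
    trk$tracks[[ti]] <- kf_track_update(trk$tracks[[ti]], db[dj, ],
                                        dets[dj, , drop = FALSE])
  }
  for (ti in asg$unmatched_tracks) trk$tracks[[ti]]$hit_streak <- 0L
  for (dj in asg$unmatched_dets)
    trk$tracks[[length(trk$tracks) + 1L]] <-
      new_kf_track(trk, db[dj, ], frame, dets[dj, , drop = FALSE])
  trk$tracks <- Filter(function(t) t$time_since_update <= cfg$max_age, trk$tracks)
  emit_sort_like(trk$tracks, frame, cfg$min_hits)
}

# Age-ordered matching cascade. Returns assignment in the same shape as
# assign_tracks() but with indices into `tracks`/`dets`.
cascade_match <- function(trk, dets, db) {
  cfg <- trk$cfg
  nt <- length(trk$tracks)
  tsu <- vapply(trk$tracks, `[[`, integer(1), "time_since_update")
  unmatched_d <- seq_len(nrow(db))
  matches <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("track", "det")))
  for (level in sort(unique(tsu))) {
    if (!length(unmatched_d)) break
    lvl_tracks <- which(tsu == level)
    tb <- predicted_boxes(trk$tracks[lvl_tracks])
    if (is.null(cfg$similarity)) {
      asg <- associate_iou(tb, db[unmatched_d, , drop = FALSE], cfg$iou_threshold)
    } else {
      cost <- matrix(1, length(lvl_tracks), length(unmatched_d))
      for (a in seq_along(lvl_tracks))
        for (b in seq_along(unmatched_d))
          cost[a, b] <- 1 - cfg$similarity(trk$tracks[[lvl_tracks[a]]],
                                           dets[unmatched_d[b], , drop = FALSE])
      # gate out spatially impossible pairs regardless of appearance
      cost[iou_pairs(tb, db[unmatched_d, , drop = FALSE]) == 0] <- 1
      asg <- assign_tracks(cost, reject_above = cfg$similarity_gate)
    }
    if (nrow(asg$matches)) {
      matches <- rbind(matches,
                       cbind(track = lvl_tracks[asg$matches[, 1L]],
                             det = unmatched_d[asg$matches[, 2L]]))
      unmatched_d <- unmatched_d[asg$unmatched_dets]
    }
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1L]),
       unmatched_dets = unmatched_d)
}

deepsort_core_step <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  for (ti in seq_along(trk$tracks)) {
    trk$tracks[[ti]]$kf <- kalman_predict(trk$tracks[[ti]]$kf)
    trk$tracks[[ti]]$time_since_update <- trk$tracks[[ti]]$time_since_update + 1L
  }
  asg <- cascade_match(trk, dets, db)
  # leftover IOU association for tracks the cascade left behind
  if (length(asg$unmatched_tracks) && length(asg$unmatched_dets)) {
    tb <- predicted_boxes(trk$tracks[asg$unmatched_tracks])
    asg2 <- associate_iou(tb, db[asg$unmatched_dets, , drop = FALSE],
                          cfg$iou_threshold)
    if (nrow(asg2$matches)) {
      asg$matches <- rbind(asg$matches,
                           cbind(track = asg$unmatched_tracks[asg2$matches[, 1L]],
                                 det = asg$unmatched_dets[asg2$matches[, 2L]]))
      asg$unmatched_tracks <- asg$unmatched_tracks[asg2$unmatched_tracks]
      asg$unmatched_dets <- asg$unmatched_dets[asg2$unmatched_dets]
    }
  }
  for (k in seq_len(nrow(asg$matches))) {
    ti <- asg$matches[k, 1L]; dj <- asg$matches[k, 2L]
    trk$tracks[[ti]] <- kf_track_update(trk$tracks[[ti]], db[dj, ],
                                        dets[dj, , drop = FALSE])
  }
  for (ti in asg$unmatched_tracks) trk$tracks[[ti]]$hit_streak <- 0L
  for (dj in asg$unmatched_dets)
    trk$tracks[[length(trk$tracks) + 1L]] <-
      new_kf_track(trk, db[dj, ], frame, dets[dj, , drop = FALSE])
  trk$tracks <- Filter(function(t) t$time_since_update <= cfg$max_age, trk$tracks)
  emit_sort_like(trk$tracks, frame, cfg$min_hits)
}

step_frame.deepsort_tracker <- function(trk, dets, frame) {
  deepsort_core_step(trk, dets, frame)
}

init_state.modified_deepsort_tracker <- function(trk) {
  trk$prev_emitted <- NULL      # previous frame's (id, box) table
  trk$retained <- list()        # id -> list(box, frames_left)
  invisible(trk)
}

step_frame.modified_deepsort_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  out <- deepsort_core_step(trk, dets, frame)
  prev <- trk$prev_emitted
  retained_now <- list()
  # detection frame loss: fewer boxes now than instances stored last frame
  if (!is.null(prev) && nrow(dets) < nrow(prev) && nrow(prev) >= 2L) {
    pb <- as.matrix(prev[, c("x1", "y1", "x2", "y2")])
    ov <- iou_pairs(pb, pb)
    for (a in seq_len(nrow(prev) - 1L)) {
      for (b in seq(a + 1L, nrow(prev))) {
        if (ov[a, b] >= cfg$retain_iou) {
          for (r in c(a, b)) {
            id <- prev$id[r]
            if (!(id %in% out$id) && !(as.character(id) %in% names(retained_now)))
              retained_now[[as.character(id)]] <-
                list(box = pb[r, ], frames_left = cfg$retain_frames)
          }
        }
      }
    }
  }
  # carry over retentions whose lifetime has not yet elapsed
  for (nm in names(trk$retained)) {
    rec <- trk$retained[[nm]]
    if (rec$frames_left > 1L && !(as.integer(nm) %in% out$id) &&
        is.null(retained_now[[nm]]))
      retained_now[[nm]] <- list(box = rec$box, frames_left = rec$frames_left - 1L)
  }
  if (length(retained_now)) {
    add <- frame_result(as.integer(names(retained_now)),
                        do.call(rbind, lapply(retained_now, `[[`, "box")),
                        rep("lost", length(retained_now)))
    out <- rbind(out, add)
    out <- out[order(out$id), , drop = FALSE]
  }
  trk$retained <- retained_now
  trk$prev_emitted <- out
  out
}

init_state.bytetrack_tracker <- function(trk) invisible(trk)

step_frame.bytetrack_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  hi <- which(dets$score >= cfg$high_score)
  lo <- which(dets$score >= cfg$low_score & dets$score < cfg$high_score)
  for (ti in seq_along(trk$tracks)) {
    trk$tracks[[ti]]$kf <- kalman_predict(trk$tracks[[ti]]$kf)
    trk$tracks[[ti]]$time_since_update <- trk$tracks[[ti]]$time_since_update + 1L
  }
  # stage 1: high-score detections against all tracks
  asg1 <- associate_iou(predicted_boxes(trk$tracks),
                        db[hi, , drop = FALSE], cfg$iou_threshold)
  for (k in seq_len(nrow(asg1$matches))) {
    ti <- asg1$matches[k, 1L]; dj <- hi[asg1$matches[k, 2L]]
    trk$tracks[[ti]] <- kf_track_update(trk$tracks[[ti]], db[dj, ],
                                        dets[dj, , drop = FALSE])
  }
  # stage 2: low-score detections against the leftovers
  left <- asg1$unmatched_tracks
  if (length(left) && length(lo)) {
    asg2 <- associate_iou(predicted_boxes(trk$tracks[left]),
                          db[lo, , drop = FALSE], cfg$iou_threshold)
    for (k in seq_len(nrow(asg2$matches))) {
      ti <- left[asg2$matches[k, 1L]]; dj <- lo[asg2$matches[k, 2L]]
      trk$tracks[[ti]] <- kf_track_update(trk$tracks[[ti]], db[dj, ],
                                          dets[dj, , drop = FALSE])
    }
    left <- left[asg2$unmatched_tracks]
  }
  for (ti in left) trk$tracks[[ti]]$hit_streak <- 0L
  # only unmatched HIGH-score detections may spawn
  for (dj in hi[asg1$unmatched_dets])
    trk$tracks[[length(trk$tracks) + 1L]] <-
      new_kf_track(trk, db[dj, ], frame, dets[dj, , drop = FALSE])
  trk$tracks <- Filter(function(t) t$time_since_update <= cfg$max_age, trk$tracks)
  emit_sort_like(trk$tracks, frame, 1L)
}
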