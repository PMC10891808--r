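#' Configurations for the simple trackers
#'
#' `iou_config()` drives the plain IOU tracker: frame-to-frame Hungarian
#' association on `1 - IOU` with no motion model. A track unmatched for more
#' than `max_age` consecutive frames is dropped; the default `max_age = 0`
#' drops a track the first frame it goes unseen, which is what makes the
#' plain tracker mint a fresh ID after any detection gap of two or more
#' frames.
#'
#' `centroid_config()` drives both centroid trackers: greedy nearest-centroid
#' matching, accepting a pair only when the centroid distance is at most
#' `max_distance` px, and carrying an unseen track for up to
#' `max_disappeared` frames before dropping it. The Kalman variant matches
#' detections against constant-velocity predicted centroids instead of the
#' last observed ones.
#'
#' @param iou_threshold minimum IOU for an association (default 0.3).
#' @param max_age frames a track may go unmatched before deletion.
#' @export
iou_config <- function(iou_threshold = 0.3, max_age = 0L) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1, max_age >= 0)
  list(iou_threshold = iou_threshold, max_age = as.integer(max_age))
}

#' @rdname iou_config
#' @param max_distance maximum centroid displacement for a match (px).
#' @param max_disappeared frames an unseen track is kept alive.
#' @export
centroid_config <- function(max_distance = 150, max_disappeared = 20L) {
  stopifnot(max_distance > 0, max_disappeared > 0)
  list(max_distance = max_distance, max_disappeared = as.integer(max_disappeared))
}

step_frame.iou_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  tb <- do.call(rbind, lapply(trk$tracks, `[[`, "box"))
  asg <- associate_iou(as_box_matrix0(tb), db, cfg$iou_threshold)
  ids <- integer(0); boxes <- NULL
  keep <- logical(length(trk$tracks))
  for (k in seq_len(nrow(asg$matches))) {
    ti <- asg$matches[k, 1L]; dj <- asg$matches[k, 2L]
    trk$tracks[[ti]]$box <- db[dj, ]
    trk$tracks[[ti]]$miss <- 0L
    keep[ti] <- TRUE
    ids <- c(ids, trk$tracks[[ti]]$id)
    boxes <- rbind(boxes, db[dj, ])
  }
  for (ti in asg$unmatched_tracks) {
    trk$tracks[[ti]]$miss <- trk$tracks[[ti]]$miss + 1L
    keep[ti] <- trk$tracks[[ti]]$miss <= cfg$max_age
  }
  trk$tracks <- trk$tracks[keep]
  for (dj in asg$unmatched_dets) {
    id <- new_track_id(trk)
    trk$tracks[[length(trk$tracks) + 1L]] <- list(id = id, box = db[dj, ], miss = 0L)
    ids <- c(ids, id)
    boxes <- rbind(boxes, db[dj, ])
  }
  frame_result(ids, boxes, rep("active", length(ids)))
}

# Greedy nearest-centroid matching: pairs accepted in ascending distance
# order (ties broken toward the lower track id, then lower detection index).
greedy_centroid_match <- function(track_centroids, track_ids, det_centroids,
                                  max_distance) {
  nt <- nrow(track_centroids); nd <- nrow(det_centroids)
  if (nt == 0L || nd == 0L)
    return(list(matches = cbind(track = integer(0), det = integer(0)),
                unmatched_tracks = seq_len(nt), unmatched_dets = seq_len(nd)))
  dx <- outer(track_centroids[, 1], det_centroids[, 1], `-`)
  dy <- outer(track_centroids[, 2], det_centroids[, 2], `-`)
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= max_distance, arr.ind = TRUE)
  ord <- order(dist[cand], track_ids[cand[, 1]], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  matches <- NULL
  for (k in seq_len(nrow(cand))) {
    ti <- cand[k, 1]; dj <- cand[k, 2]
    if (!used_t[ti] && !used_d[dj]) {
      used_t[ti] <- TRUE; used_d[dj] <- TRUE
      matches <- rbind(matches, c(ti, dj))
    }
  }
  if (is.null(matches)) matches <- matrix(integer(0), 0L, 2L)
  colnames(matches) <- c("track", "det")
  list(matches = matches,
       unmatched_tracks = which(!used_t), unmatched_dets = which(!used_d))
}

step_frame.centroid_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  dc <- box_center(as_box_matrix0(db))
  tc <- do.call(rbind, lapply(trk$tracks, `[[`, "centroid"))
  tids <- vapply(trk$tracks, `[[`, integer(1), "id")
  m <- greedy_centroid_match(if (is.null(tc)) matrix(numeric(0), 0, 2) else tc,
                             tids, dc, cfg$max_distance)
  ids <- integer(0); boxes <- NULL
  keep <- rep(TRUE, length(trk$tracks))
  for (k in seq_len(nrow(m$matches))) {
    ti <- m$matches[k, 1L]; dj <- m$matches[k, 2L]
    trk$tracks[[ti]]$box <- db[dj, ]
    trk$tracks[[ti]]$centroid <- dc[dj, ]
    trk$tracks[[ti]]$disappeared <- 0L
    ids <- c(ids, trk$tracks[[ti]]$id)
    boxes <- rbind(boxes, db[dj, ])
  }
  for (ti in m$unmatched_tracks) {
    trk$tracks[[ti]]$disappeared <- trk$tracks[[ti]]$disappeared + 1L
    keep[ti] <- trk$tracks[[ti]]$disappeared <= cfg$max_disappeared
  }
  trk$tracks <- trk$tracks[keep]
  for (dj in m$unmatched_dets) {
    id <- new_track_id(trk)
    trk$tracks[[length(trk$tracks) + 1L]] <-
      list(id = id, box = db[dj, ], centroid = dc[dj, ], disappeared = 0L)
    ids <- c(ids, id)
    boxes <- rbind(boxes, db[dj, ])
  }
  frame_result(ids, boxes, rep("active", length(ids)))
}

step_frame.centroid_kalman_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  dc <- box_center(as_box_matrix0(db))
  # predict every track's centroid forward one frame
  for (ti in seq_along(trk$tracks))
    trk$tracks[[ti]]$kf <- kalman_predict(trk$tracks[[ti]]$kf)
  tc <- do.call(rbind, lapply(trk$tracks, function(t) t$kf$x[1:2]))
  tids <- vapply(trk$tracks, `[[`, integer(1), "id")
  m <- greedy_centroid_match(if (is.null(tc)) matrix(numeric(0), 0, 2) else tc,
                             tids, dc, cfg$max_distance)
  ids <- integer(0); boxes <- NULL
  keep <- rep(TRUE, length(trk$tracks))
  for (k in seq_len(nrow(m$matches))) {
    ti <- m$matches[k, 1L]; dj <- m$matches[k, 2L]
    trk$tracks[[ti]]$kf <- kalman_update(trk$tracks[[ti]]$kf, dc[dj, ])
    trk$tracks[[ti]]$box <- db[dj, ]
    trk$tracks[[ti]]$disappeared <- 0L
    ids <- c(ids, trk$tracks[[ti]]$id)
    boxes <- rbind(boxes, db[dj, ])
  }
  for (ti in m$unmatched_tracks) {
    trk$tracks[[ti]]$disappeared <- trk$tracks[[ti]]$disappeared + 1L
    keep[ti] <- trk$tracks[[ti]]$disappeared <= cfg$max_disappeared
  }
  trk$tracks <- trk$tracks[keep]
  for (dj in m$unmatched_dets) {
    id <- new_track_id(trk)
    trk$tracks[[length(trk$tracks) + 1L]] <-
      list(id = id, box = db[dj, ], kf = kf_centroid_init(dc[dj, ]),
           disappeared = 0L)
    ids <- c(ids, id)
    boxes <- rbind(boxes, db[dj, ])
  }
  frame_result(ids, boxes, rep("active", length(ids)))
}
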