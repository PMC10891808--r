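#' Customized tracking algorithm (CTA) configuration
#'
#' The CTA is a history-buffered IOU tracker built for fixed pens where the
#' same small set of animals stays in view for hours: minting a new track ID
#' for a cow that was merely missed or occluded is its failure criterion. On
#' top of plain frame-to-frame IOU association it applies three resolution
#' mechanisms, in order, before a frame's result is emitted:
#'
#' 1. **Miss-detection re-identification.** The tracker stores every track's
#'    last box for a window of `n_history` frames. A detection that base
#'    association could not match is compared (IOU, best pair first) against
#'    the stored boxes of currently unseen IDs; at `reid_iou` or above the
#'    stored ID is reassigned instead of minting a new one.
#' 2. **Object-occlusion resolution.** Whenever the number of previously
#'    tracked IDs `P_ID` exceeds the detection count `D_ID` minus one, each
#'    ID absent from the current frame is recorded as a miss record `M_ID`
#'    with its last box and a running miss duration. When a fresh track is
#'    minted while miss records are outstanding, the IOU between the fresh
#'    box and each stored miss box is recalculated, the fresh track is
#'    deleted, and the best-overlapping missing ID is reassigned (any
#'    overlap qualifies: in a closed pen a new track appearing on top of a
#'    recorded miss is that missing animal). The mechanism stays out of the
#'    other two mechanisms' regimes: it skips pairs the history buffer
#'    could still resolve at `reid_iou` (mechanism 1's case) and skips IDs
#'    on the occlusion list (mechanism 3's case). It is what rescues a cow
#'    that slid behind the camera stand and re-emerged displaced, or whose
#'    gap outlived a buffer refresh.
#' 3. **Cow-occlusion resolution.** An ID that vanishes while its box
#'    overlaps another current track's box at `occlusion_iou` or above enters
#'    an occlusion list together with its last box. A freshly minted track
#'    whose box overlaps an occlusion-list entry at `occlusion_iou` or above
#'    takes over that entry's ID (highest IOU wins, consumed entries leave
#'    the list); otherwise the new ID stands.
#'
#' Missing IDs are coasted while their miss record is alive: the stored box
#' is re-emitted with `status = "lost"` so downstream evaluation sees a
#' continuous trajectory. Deleted fresh IDs are never re-used; the global ID
#' counter only moves forward.
#'
#' @param n_history length of the history window, frames. The default 20
#'   matches the flow-chart refresh interval; 8 is the documented alternative
#'   preset.
#' @param reid_iou minimum IOU between an unmatched detection and a stored
#'   box for mechanisms 1 and 2 to reassign the stored ID.
#' @param occlusion_iou minimum IOU for occlusion-list entry and consumption
#'   in mechanism 3. Deliberately lower than `reid_iou`: a cow emerging from
#'   behind another is necessarily displaced from where it vanished.
#' @param buffer_mode `"block_refresh"` (window cleared every `n_history`
#'   frames, reseeded with the current frame) or `"sliding"` (rolling
#'   window).
#' @param iou_threshold base frame-to-frame association gate.
#' @param coast re-emit stored boxes of missing IDs flagged `"lost"`.
#' @param disable_miss,disable_object_occ,disable_cow_occ ablation switches
#'   turning individual mechanisms off.
#' @export
cta_config <- function(n_history = 20L, reid_iou = 0.5, occlusion_iou = 0.25,
                       buffer_mode = c("block_refresh", "sliding"),
                       iou_threshold = 0.3, coast = TRUE,
                       disable_miss = FALSE, disable_object_occ = FALSE,
                       disable_cow_occ = FALSE) {
  stopifnot(n_history >= 1, reid_iou > 0, reid_iou <= 1,
            occlusion_iou > 0, occlusion_iou <= 1)
  list(n_history = as.integer(n_history), reid_iou = reid_iou,
       occlusion_iou = occlusion_iou, buffer_mode = match.arg(buffer_mode),
       iou_threshold = iou_threshold, coast = isTRUE(coast),
       disable_miss = isTRUE(disable_miss),
       disable_object_occ = isTRUE(disable_object_occ),
       disable_cow_occ = isTRUE(disable_cow_occ))
}

init_state.cta_tracker <- function(trk) {
  trk$active <- list()        # id (chr) -> box seen in the previous frame
  trk$buffer <- list(window_start = 1L, entries = list())
  trk$miss_records <- list()  # id -> list(box, since, gate_ok)
  trk$occlusion <- list()     # id -> list(box, since, occluder)
  trk$last_created <- c(id = NA_integer_, frame = NA_integer_)
  invisible(trk)
}

#' CTA history buffer update
#'
#' Folds one frame of detection-backed tracks into the n-frame history
#' buffer. Under `block_refresh` the buffer accumulates for `n_history`
#' frames and is then cleared and reseeded with the current frame; under
#' `sliding` entries older than `n_history` frames fall out of a rolling
#' window.
#'
#' @param buffer a list with `window_start` and `entries` (id -> list(box,
#'   last_seen)).
#' @param frame current frame index.
#' @param ids,boxes the detection-backed track IDs and their n x 4 boxes.
#' @param cfg a [cta_config()].
#' @return the updated buffer.
#' @export
cta_update_history <- function(buffer, frame, ids, boxes, cfg) {
  if (cfg$buffer_mode == "block_refresh" &&
      frame >= buffer$window_start + cfg$n_history) {
    buffer$window_start <- frame
    buffer$entries <- list()
  }
  for (k in seq_along(ids))
    buffer$entries[[as.character(ids[k])]] <-
      list(box = boxes[k, ], last_seen = frame)
  if (cfg$buffer_mode == "sliding") {
    cutoff <- frame - cfg$n_history + 1L
    buffer$entries <- Filter(function(e) e$last_seen >= cutoff, buffer$entries)
  }
  buffer
}

# Greedy best-first IOU matching between candidate stored boxes (with ids)
# and detection boxes: highest IOU pair first, ties to the lower id then the
# lower detection index; pairs below `threshold` never match.
greedy_iou_claim <- function(cand_ids, cand_boxes, det_boxes, threshold) {
  nd <- nrow(det_boxes)
  out <- rep(NA_integer_, nd)
  if (length(cand_ids) == 0L || nd == 0L) return(out)
  ov <- iou_pairs(as_box_matrix0(cand_boxes), det_boxes)
  pairs <- which(ov >= threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(out)
  ord <- order(-ov[pairs], cand_ids[pairs[, 1]], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  used_c <- logical(length(cand_ids))
  for (k in seq_len(nrow(pairs))) {
    ci <- pairs[k, 1]; dj <- pairs[k, 2]
    if (!used_c[ci] && is.na(out[dj])) {
      used_c[ci] <- TRUE
      out[dj] <- cand_ids[ci]
    }
  }
  out
}

#' CTA resolution mechanisms
#'
#' The three per-frame resolution steps, exposed for inspection and testing;
#' [tracker_step()] on a `"cta"` tracker applies them in this order after
#' base IOU association. Each returns, for every queried detection box, the
#' stored ID it reassigns or `NA` where no stored candidate clears the
#' threshold (best-IOU pair first, ties to the lower ID, each stored ID
#' claimable once).
#'
#' `cta_resolve_miss()` matches unmatched detections against history-buffer
#' boxes of currently unseen IDs at `reid_iou` or above.
#' `cta_resolve_object_occlusion()` recalculates the IOU between freshly
#' spawned tracks' boxes and outstanding miss-record boxes and reassigns on
#' any overlap, except that a candidate still in the history buffer is only
#' claimable below `reid_iou` (at or above it the pair belongs to mechanism
#' 1, which already declined it or was ablated — the gate and occlusion-list
#' scoping live in the tracker step). `cta_resolve_cow_occlusion()` matches
#' freshly spawned tracks' boxes against occlusion-list entries at
#' `occlusion_iou` or above.
#'
#' @param ids integer vector of stored candidate IDs.
#' @param boxes n x 4 matrix of the candidates' stored boxes.
#' @param det_boxes m x 4 matrix of query boxes.
#' @param reid_iou,occlusion_iou acceptance thresholds (see [cta_config()]).
#' @param in_buffer logical vector: is each candidate still present in the
#'   history buffer?
#' @return integer vector of length `nrow(det_boxes)`: reassigned ID or `NA`.
#' @export
cta_resolve_miss <- function(ids, boxes, det_boxes, reid_iou = 0.5) {
  greedy_iou_claim(ids, boxes, det_boxes, reid_iou)
}

#' @rdname cta_resolve_miss
#' @export
cta_resolve_object_occlusion <- function(ids, boxes, det_boxes,
                                         reid_iou = 0.5,
                                         in_buffer = rep(FALSE, length(ids))) {
  nd <- nrow(det_boxes)
  out <- rep(NA_integer_, nd)
  if (length(ids) == 0L || nd == 0L) return(out)
  ov <- iou_pairs(as_box_matrix0(boxes), det_boxes)
  ov[ov <= 0] <- NA                      # no overlap, no claim
  if (any(in_buffer)) {
    sub <- ov[in_buffer, , drop = FALSE]
    sub[sub >= reid_iou] <- NA
    ov[in_buffer, ] <- sub
  }
  pairs <- which(!is.na(ov), arr.ind = TRUE)
  if (!nrow(pairs)) return(out)
  ord <- order(-ov[pairs], ids[pairs[, 1]], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  used <- logical(length(ids))
  for (k in seq_len(nrow(pairs))) {
    ci <- pairs[k, 1]; dj <- pairs[k, 2]
    if (!used[ci] && is.na(out[dj])) {
      used[ci] <- TRUE
      out[dj] <- ids[ci]
    }
  }
  out
}

#' @rdname cta_resolve_miss
#' @export
cta_resolve_cow_occlusion <- function(ids, boxes, det_boxes, occlusion_iou = 0.25) {
  greedy_iou_claim(ids, boxes, det_boxes, occlusion_iou)
}

step_frame.cta_tracker <- function(trk, dets, frame) {
  cfg <- trk$cfg
  db <- det_boxes(dets)
  nd <- nrow(db)
  p_id <- length(trk$buffer$entries)

  prev_ids <- as.integer(names(trk$active))
  prev_boxes <- do.call(rbind, trk$active)

  # --- base frame-to-frame IOU association -------------------------------
  asg <- associate_iou(as_box_matrix0(prev_boxes), db, cfg$iou_threshold)
  cur_ids <- prev_ids[asg$matches[, 1L]]
  cur_boxes <- db[asg$matches[, 2L], , drop = FALSE]
  unmatched_dets <- asg$unmatched_dets

  # --- newly missing ids: miss records + occlusion-list entry ------------
  newly_missing <- asg$unmatched_tracks
  for (ti in newly_missing) {
    id <- prev_ids[ti]
    # L_ID rule: a track created this very frame cannot be declared missing
    lc <- trk$last_created
    if (!is.na(lc[["id"]]) && id == lc[["id"]] && lc[["frame"]] == frame) next
    gate_ok <- p_id > nd - 1L
    trk$miss_records[[as.character(id)]] <-
      list(box = prev_boxes[ti, ], since = frame, gate_ok = gate_ok)
    # occlusion-list entries are recorded even when mechanism 3's
    # resolution is ablated: they scope mechanism 2 away from cow-cow cases
    if (nrow(cur_boxes)) {
      ov <- iou_pairs(matrix(prev_boxes[ti, ], 1L), cur_boxes)
      j <- which.max(ov)
      if (length(j) && ov[j] >= cfg$occlusion_iou)
        trk$occlusion[[as.character(id)]] <-
          list(box = prev_boxes[ti, ], since = frame, occluder = cur_ids[j])
    }
  }

  reclaim <- function(id, box) {
    cur_ids <<- c(cur_ids, id)
    cur_boxes <<- rbind(cur_boxes, box)
    trk$miss_records[[as.character(id)]] <- NULL
    trk$occlusion[[as.character(id)]] <- NULL
  }

  # --- mechanism 1: miss-detection re-id against the history buffer ------
  if (!cfg$disable_miss && length(unmatched_dets)) {
    cand <- trk$buffer$entries[!(names(trk$buffer$entries) %in% as.character(cur_ids))]
    if (length(cand)) {
      got <- cta_resolve_miss(as.integer(names(cand)),
                              do.call(rbind, lapply(cand, `[[`, "box")),
                              db[unmatched_dets, , drop = FALSE], cfg$reid_iou)
      for (k in seq_along(got)) {
        if (!is.na(got[k])) reclaim(got[k], db[unmatched_dets[k], ])
      }
      unmatched_dets <- unmatched_dets[is.na(got)]
    }
  }

  # --- remaining detections spawn fresh ids ------------------------------
  fresh_ids <- integer(0)
  for (dj in unmatched_dets) {
    id <- new_track_id(trk)
    fresh_ids <- c(fresh_ids, id)
    trk$last_created <- c(id = id, frame = frame)
  }
  fresh_boxes <- db[unmatched_dets, , drop = FALSE]

  # --- mechanism 2: object-occlusion resolution --------------------------
  # Gate-recorded miss ids reclaim freshly spawned tracks by recalculated
  # IOU; occlusion-list ids are mechanism 3's business.
  if (!cfg$disable_object_occ && length(fresh_ids)) {
    mr <- trk$miss_records
    eligible <- names(mr)[vapply(names(mr), function(nm) {
      mr[[nm]]$gate_ok && !(nm %in% names(trk$occlusion)) &&
        !(as.integer(nm) %in% cur_ids)
    }, logical(1))]
    if (length(eligible)) {
      got <- cta_resolve_object_occlusion(
        as.integer(eligible),
        do.call(rbind, lapply(mr[eligible], `[[`, "box")),
        fresh_boxes, cfg$reid_iou,
        in_buffer = eligible %in% names(trk$buffer$entries))
      keep <- is.na(got)
      for (k in seq_along(got))
        if (!is.na(got[k])) reclaim(got[k], fresh_boxes[k, ])
      fresh_ids <- fresh_ids[keep]
      fresh_boxes <- fresh_boxes[keep, , drop = FALSE]
    }
  }

  # --- mechanism 3: cow-occlusion resolution -----------------------------
  if (!cfg$disable_cow_occ && length(fresh_ids) && length(trk$occlusion)) {
    occ <- trk$occlusion[!(as.integer(names(trk$occlusion)) %in% cur_ids)]
    if (length(occ)) {
      got <- cta_resolve_cow_occlusion(
        as.integer(names(occ)),
        do.call(rbind, lapply(occ, `[[`, "box")),
        fresh_boxes, cfg$occlusion_iou)
      keep <- is.na(got)
      for (k in seq_along(got))
        if (!is.na(got[k])) reclaim(got[k], fresh_boxes[k, ])
      fresh_ids <- fresh_ids[keep]
      fresh_boxes <- fresh_boxes[keep, , drop = FALSE]
    }
  }

  cur_ids <- c(cur_ids, fresh_ids)
  cur_boxes <- rbind(cur_boxes, fresh_boxes)

  # --- expire stale bookkeeping ------------------------------------------
  expired <- vapply(trk$miss_records, function(r) frame - r$since + 1L > cfg$n_history,
                    logical(1))
  trk$miss_records <- trk$miss_records[!expired]
  occ_old <- vapply(trk$occlusion, function(r) frame - r$since + 1L > cfg$n_history,
                    logical(1))
  trk$occlusion <- trk$occlusion[!occ_old]

  # --- coast still-missing ids -------------------------------------------
  coast_ids <- integer(0); coast_boxes <- NULL
  if (cfg$coast) {
    for (nm in names(trk$miss_records)) {
      id <- as.integer(nm)
      if (!(id %in% cur_ids)) {
        coast_ids <- c(coast_ids, id)
        coast_boxes <- rbind(coast_boxes, trk$miss_records[[nm]]$box)
      }
    }
  }

  # --- history buffer and next-frame state -------------------------------
  trk$buffer <- cta_update_history(trk$buffer, frame, cur_ids, cur_boxes, cfg)
  trk$active <- stats::setNames(
    lapply(seq_along(cur_ids), function(k) cur_boxes[k, ]),
    as.character(cur_ids))

  rbind(frame_result(cur_ids, cur_boxes, rep("active", length(cur_ids))),
        frame_result(coast_ids, coast_boxes, rep("lost", length(coast_ids))))
}
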