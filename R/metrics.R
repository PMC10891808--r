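#' Detection accuracy and multi-object tracking accuracy
#'
#' `detection_accuracy()` is the classification accuracy of the detector over
#' object-frames,
#' `100 * (TP + TN) / (TP + FP + TN + FN)`,
#' reported as a percentage. `mota()` is the MOT16 Multi-Object Tracking
#' Accuracy,
#' `100 * (1 - (FN + FP + IDS) / GT)`,
#' where GT is the total number of ground-truth object-frames, FN the missed
#' object-frames, FP the false tracks, and IDS the identity switches; it can
#' be negative when errors outnumber ground-truth entries.
#'
#' Both return the raw percentage; use `round2()` for the conventional
#' two-decimal display (half-up).
#'
#' @param tp,fp,tn,fn non-negative detection counts.
#' @return a percentage (numeric scalar).
#' @examples
#' detection_accuracy(17990, 0, 0, 10)       # 99.944...
#' round2(mota(213915, 0, 10, 3))            # 99.99
#' @export
detection_accuracy <- function(tp, fp = 0, tn = 0, fn = 0) {
  denom <- tp + fp + tn + fn
  if (denom <= 0) stop("detection accuracy undefined: zero total count")
  100 * (tp + tn) / denom
}

#' @rdname detection_accuracy
#' @param gt total ground-truth object-frames (> 0).
#' @param ids identity-switch count.
#' @export
mota <- function(gt, fp = 0, fn = 0, ids = 0) {
  if (gt <= 0) stop("MOTA undefined: no ground-truth object-frames")
  100 * (1 - (fn + fp + ids) / gt)
}

#' @rdname detection_accuracy
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round2 <- function(x, digits = 2) {
  # round-half-up, the convention used for printed percentages
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score a track stream against ground truth
#'
#' Frame-by-frame MOT16-style evaluation: in every frame, predicted boxes are
#' matched one-to-one to ground-truth boxes by the Hungarian algorithm on
#' `1 - IOU`, rejecting pairs below `match_iou`. Unmatched ground-truth boxes
#' count as misses (FN), unmatched predictions as false tracks (FP), and an
#' identity switch (IDS) is counted whenever a ground-truth identity's
#' matched track ID differs from the track ID it most recently matched.
#'
#' @param pred a track stream (`frame, id, x1, y1, x2, y2`).
#' @param gt a ground-truth stream in the same layout.
#' @param match_iou minimum IOU for a prediction to cover a ground-truth box
#'   (default 0.5, the MOT16 convention).
#' @param n_frames frame range to evaluate; defaults to the maximum frame
#'   present in either stream.
#' @return a list of counts `gt, fp, fn, ids` plus `mota` (percentage).
#' @examples
#' s <- data.frame(frame = 1:3, id = 1L, x1 = 0, y1 = 0, x2 = 100, y2 = 100)
#' score_stream(s, s)$mota   # 100
#' @export
score_stream <- function(pred, gt, match_iou = 0.5, n_frames = NULL) {
  if (nrow(gt) == 0L) stop("MOTA undefined: empty ground-truth stream")
  if (is.null(n_frames)) n_frames <- max(gt$frame, pred$frame, 0L)
  if (nrow(pred) && max(pred$frame) > max(gt$frame))
    stop("frame-range mismatch: predictions extend beyond ground truth")
  gt_split <- split(seq_len(nrow(gt)), gt$frame)
  pr_split <- if (nrow(pred)) split(seq_len(nrow(pred)), pred$frame) else list()
  fp <- fn <- ids <- 0L
  last_match <- integer(0)    # gt identity (chr name) -> last matched track id
  last_match <- stats::setNames(integer(0), character(0))
  for (f in seq_len(n_frames)) {
    gi <- gt_split[[as.character(f)]]
    pi <- pr_split[[as.character(f)]]
    ng <- length(gi); np <- length(pi)
    if (ng == 0L && np == 0L) next
    if (ng == 0L) { fp <- fp + np; next }
    if (np == 0L) { fn <- fn + ng; next }
    gb <- as.matrix(gt[gi, c("x1", "y1", "x2", "y2")])
    pb <- as.matrix(pred[pi, c("x1", "y1", "x2", "y2")])
    asg <- assign_tracks(iou_matrix(gb, pb), reject_above = 1 - match_iou)
    fn <- fn + length(asg$unmatched_tracks)
    fp <- fp + length(asg$unmatched_dets)
    for (k in seq_len(nrow(asg$matches))) {
      gid <- as.character(gt$id[gi[asg$matches[k, 1L]]])
      tid <- pred$id[pi[asg$matches[k, 2L]]]
      prev <- last_match[gid]
      if (!is.na(prev) && length(prev) && prev != tid) ids <- ids + 1L
      last_match[gid] <- tid
    }
  }
  total_gt <- nrow(gt)
  list(gt = total_gt, fp = fp, fn = fn, ids = ids,
       mota = mota(total_gt, fp = fp, fn = fn, ids = ids))
}

#' Count superfluous track IDs
#'
#' The qualitative failure criterion for pen tracking: the number of distinct
#' track IDs a tracker emitted beyond the number of true objects, floored at
#' zero. A perfect run over a fixed herd emits exactly one ID per animal.
#'
#' @param pred a track stream with an `id` column.
#' @param n_true_objects number of true objects (>= 1).
#' @return a non-negative integer.
#' @export
id_increment_count <- function(pred, n_true_objects) {
  stopifnot(n_true_objects >= 1)
  max(0L, length(unique(pred$id)) - as.integer(n_true_objects))
}

#' Run and score several trackers on one detection stream
#'
#' Convenience comparison: runs each named tracker (fresh state, default or
#' supplied configuration) over the same detection stream and scores it
#' against the ground truth, yielding one summary row per tracker.
#'
#' @param dets a detection stream (`frame, x1, y1, x2, y2, score`).
#' @param gt the ground-truth stream.
#' @param trackers character vector of tracker names (see [tracker()]).
#' @param configs optional named list of configuration lists, keyed by
#'   tracker name.
#' @param match_iou evaluation matching threshold.
#' @param n_frames frames to process (default: max ground-truth frame).
#' @return a data frame with columns `tracker, n_ids, gt, fp, fn, ids, mota`.
#' @export
compare_trackers <- function(dets, gt,
                             trackers = c("sort", "deepsort", "modified_deepsort",
                                          "bytetrack", "centroid",
                                          "centroid_kalman", "iou", "cta"),
                             configs = list(), match_iou = 0.5,
                             n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(gt$frame)
  rows <- lapply(trackers, function(nm) {
    trk <- tracker(nm, config = configs[[nm]])
    res <- track_stream(trk, dets, n_frames = n_frames)
    sc <- score_stream(res, gt, match_iou = match_iou, n_frames = n_frames)
    data.frame(tracker = nm, n_ids = length(unique(res$id)),
               gt = sc$gt, fp = sc$fp, fn = sc$fn, ids = sc$ids,
               mota = round2(sc$mota))
  })
  do.call(rbind, rows)
}
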