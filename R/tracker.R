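#' Create a tracker
#'
#' Constructs a stateful tracker object implementing the shared per-frame
#' contract: feed it one frame of detections at a time with [tracker_step()]
#' and it returns that frame's (track id, box) assignments. All eight
#' algorithms share the same interface, a global monotone ID counter starting
#' at 1, and deterministic tie-breaking (lower track id wins any tie), so a
#' given stream and configuration always reproduce the same output.
#'
#' Available trackers:
#' * `"iou"` — frame-to-frame IOU association only ([iou_config()]);
#' * `"centroid"` — greedy nearest-centroid matching ([centroid_config()]);
#' * `"centroid_kalman"` — centroid matching against constant-velocity Kalman
#'   predictions;
#' * `"sort"` — Kalman box prediction + Hungarian IOU association
#'   ([sort_config()]);
#' * `"deepsort"` — SORT with an age-ordered matching cascade and a pluggable
#'   appearance-similarity hook ([deepsort_config()]);
#' * `"modified_deepsort"` — Deep SORT plus a re-identification rule that, on
#'   detection frame loss, retains stored boxes overlapping at IOU >= 0.9
#'   ([modified_deepsort_config()]);
#' * `"bytetrack"` — two-stage score-split association ([byte_config()]);
#' * `"cta"` — the customized tracking algorithm with history-buffered
#'   re-identification ([cta_config()]).
#'
#' @param name one of the tracker names above.
#' @param config a configuration list from the matching `*_config()` helper
#'   (defaults used when omitted).
#' @return a tracker object (an environment with class
#'   `c("<name>_tracker", "tracker")`).
#' @examples
#' trk <- tracker("iou")
#' d <- data.frame(frame = 1, x1 = 0, y1 = 0, x2 = 100, y2 = 100, score = 1)
#' tracker_step(trk, d)
#' @export
tracker <- function(name = c("sort", "deepsort", "modified_deepsort",
                             "bytetrack", "centroid", "centroid_kalman",
                             "iou", "cta"),
                    config = NULL) {
  name <- match.arg(name)
  cfg_default <- switch(name,
    sort = sort_config(), deepsort = deepsort_config(),
    modified_deepsort = modified_deepsort_config(),
    bytetrack = byte_config(), centroid = centroid_config(),
    centroid_kalman = centroid_config(), iou = iou_config(),
    cta = cta_config())
  if (!is.null(config)) cfg_default[names(config)] <- config
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$cfg <- cfg_default
  e$next_id <- 1L
  e$last_frame <- 0L
  e$tracks <- list()
  class(e) <- c(paste0(name, "_tracker"), "tracker")
  init_state(e)
  e
}

init_state <- function(trk) UseMethod("init_state")
init_state.default <- function(trk) invisible(trk)

new_track_id <- function(trk) {
  id <- trk$next_id
  trk$next_id <- id + 1L
  id
}

#' Advance a tracker by one frame
#'
#' @param trk a [tracker()] object.
#' @param dets a data frame of this frame's detections with columns
#'   `x1, y1, x2, y2` (half-open pixel corners), optionally `frame`, `score`
#'   (default 1), and any extra columns (passed through to similarity hooks).
#'   May have zero rows: empty frames are valid steps and drive the trackers'
#'   aging/miss logic.
#' @param frame the frame index (1-based); taken from `dets$frame` when
#'   omitted. Must strictly increase across calls on the same tracker.
#' @return a data frame with one row per emitted track: columns `frame`, `id`,
#'   `x1, y1, x2, y2`, `status` (`"active"` for a detection-backed box,
#'   `"lost"` for a coasted/retained box), ordered by ascending `id`. IDs are
#'   unique within a frame.
#' @export
tracker_step <- function(trk, dets, frame = NULL) {
  stopifnot(inherits(trk, "tracker"))
  if (is.null(dets)) dets <- empty_detections()
  if (is.null(frame)) {
    if (nrow(dets) == 0L || is.null(dets$frame))
      stop("frame index required when detections are empty")
    frame <- unique(dets$frame)
  }
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame))
    stop("detections must all share a single frame index")
  if (frame <= trk$last_frame)
    stop(sprintf("stream-order error: frame %d after frame %d (frames must strictly increase)",
                 frame, trk$last_frame))
  if (nrow(dets)) {
    stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(dets)))
    if (is.null(dets$score)) dets$score <- 1
    if (any(dets$x2 <= dets$x1) || any(dets$y2 <= dets$y1))
      stop("invalid detection box")
  } else {
    dets <- empty_detections()
  }
  trk$last_frame <- frame
  out <- step_frame(trk, dets, frame)
  if (nrow(out)) {
    out <- out[order(out$id), , drop = FALSE]
    if (anyDuplicated(out$id))
      stop("internal error: duplicate track id emitted in one frame")
  }
  res <- data.frame(frame = rep(frame, nrow(out)), out, row.names = NULL)
  res
}

step_frame <- function(trk, dets, frame) UseMethod("step_frame")

empty_detections <- function() {
  data.frame(frame = integer(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0), score = numeric(0))
}

frame_result <- function(ids, boxes, status) {
  if (length(ids) == 0L)
    return(data.frame(id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), status = character(0)))
  boxes <- as_box_matrix(boxes)
  data.frame(id = as.integer(ids),
             x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4],
             status = status, row.names = NULL)
}

det_boxes <- function(dets) {
  cbind(x1 = dets$x1, y1 = dets$y1, x2 = dets$x2, y2 = dets$y2)
}

#' Run a tracker over a whole detection stream
#'
#' Drives [tracker_step()] over every frame from 1 to `n_frames` (empty frames
#' included) and binds the per-frame results into one track stream.
#'
#' @inheritParams tracker_step
#' @param stream a detection data frame with a `frame` column.
#' @param n_frames last frame to process; defaults to `max(stream$frame)`.
#' @return a track stream: `frame, id, x1, y1, x2, y2, status`.
#' @export
track_stream <- function(trk, stream, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- if (nrow(stream)) max(stream$frame) else 0L
  by_frame <- if (nrow(stream)) split(seq_len(nrow(stream)), stream$frame) else list()
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    idx <- by_frame[[as.character(f)]]
    dets <- if (is.null(idx)) empty_detections() else stream[idx, , drop = FALSE]
    out[[f]] <- tracker_step(trk, dets, frame = f)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Shared association helper: Hungarian on 1 - IOU with an IOU gate.
associate_iou <- function(track_boxes, det_boxes, iou_threshold) {
  assign_tracks(iou_matrix(track_boxes, det_boxes),
                reject_above = 1 - iou_threshold)
}
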