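# Shared fixture builders: tiny hand-made detection streams.

det_frame <- function(frame, boxes, score = 1, gt_id = NULL) {
  boxes <- matrix(boxes, ncol = 4, byrow = is.null(dim(boxes)))
  d <- data.frame(frame = frame, x1 = boxes[, 1], y1 = boxes[, 2],
                  x2 = boxes[, 3], y2 = boxes[, 4],
                  score = rep_len(score, nrow(boxes)))
  if (!is.null(gt_id)) d$gt_id <- gt_id
  d
}

# a static stream: the same boxes every frame
static_stream <- function(boxes, n_frames, score = 1) {
  do.call(rbind, lapply(seq_len(n_frames), function(f)
    det_frame(f, boxes, score = score)))
}

# brute-force minimum assignment cost by permutation enumeration
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(brute_force_assignment_cost(t(cost)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    s <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (s < best) best <- s
  }
  best
}

# pixel-count IOU oracle: rasterize both boxes on a unit grid
raster_iou <- function(a, b, res = 1) {
  xs <- seq(floor(min(a[1], b[1])), ceiling(max(a[3], b[3])) - res, by = res)
  ys <- seq(floor(min(a[2], b[2])), ceiling(max(a[4], b[4])) - res, by = res)
  cx <- rep(xs + res / 2, times = length(ys))
  cy <- rep(ys + res / 2, each = length(xs))
  in_a <- cx >= a[1] & cx < a[3] & cy >= a[2] & cy < a[4]
  in_b <- cx >= b[1] & cx < b[3] & cy >= b[2] & cy < b[4]
  if (!any(in_a | in_b)) return(0)
  sum(in_a & in_b) / sum(in_a | in_b)
}

# integer-corner boxes so unit-grid rasterization is an exact oracle
random_box <- function(max_xy = 500, min_wh = 5, max_wh = 120) {
  x <- sample.int(max_xy, 1); y <- sample.int(max_xy, 1)
  c(x, y, x + sample(min_wh:max_wh, 1), y + sample(min_wh:max_wh, 1))
}

all_tracker_names <- c("sort", "deepsort", "modified_deepsort", "bytetrack",
                       "centroid", "centroid_kalman", "iou", "cta")
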