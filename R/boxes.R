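#' Bounding boxes
#'
#' Boxes are axis-aligned pixel rectangles in image coordinates (origin
#' top-left), stored as half-open corner form `(x_min, y_min, x_max, y_max)`:
#' the max edges are exclusive, so a box of width w placed at left edge l has
#' `x_max = l + w` and the width/area arithmetic is exact. Throughout the
#' package a set of boxes is a numeric matrix with one row per box and columns
#' `x1, y1, x2, y2`.
#'
#' @param x1,y1,x2,y2 numeric vectors of corner coordinates (px).
#' @return `bbox()` returns an n x 4 numeric matrix of validated boxes.
#' @examples
#' b <- bbox(0, 0, 100, 50)
#' box_area(b)   # 5000
#' @export
bbox <- function(x1, y1, x2, y2) {
  m <- cbind(x1 = as.numeric(x1), y1 = as.numeric(y1),
             x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (nrow(m) && (any(m[, "x2"] <= m[, "x1"]) || any(m[, "y2"] <= m[, "y1"])))
    stop("invalid bounding box: max edges must exceed min edges")
  if (nrow(m) && any(!is.finite(m)))
    stop("invalid bounding box: non-finite coordinate")
  m
}

#' @rdname bbox
#' @param box an n x 4 box matrix (or length-4 vector).
#' @export
box_area <- function(box) {
  box <- as_box_matrix(box)
  (box[, 3] - box[, 1]) * (box[, 4] - box[, 2])
}

#' @rdname bbox
#' @export
box_center <- function(box) {
  box <- as_box_matrix(box)
  cbind(cx = (box[, 1] + box[, 3]) / 2, cy = (box[, 2] + box[, 4]) / 2)
}

# Accept a bare length-4 vector where a 1-row matrix is meant.
as_box_matrix <- function(box) {
  if (is.null(dim(box))) {
    stopifnot(length(box) == 4L)
    box <- matrix(as.numeric(box), nrow = 1L,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  }
  box
}

#' Intersection over union
#'
#' The association affinity used by every tracker in the package: area of the
#' intersection of two boxes divided by the area of their union. Disjoint
#' boxes score 0, identical boxes score 1, and the measure is symmetric.
#'
#' @param a,b boxes as length-4 vectors or 1-row matrices.
#' @return a number in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  as.numeric(iou_pairs(as_box_matrix(a), as_box_matrix(b)))
}

# Pairwise IOU between two box sets: returns an nrow(A) x nrow(B) matrix.
iou_pairs <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(matrix(numeric(0), nrow(A), nrow(B)))
  # intersection extents (outer pmax/pmin give all pairs at once)
  ix1 <- outer(A[, 1], B[, 1], pmax)
  iy1 <- outer(A[, 2], B[, 2], pmax)
  ix2 <- outer(A[, 3], B[, 3], pmin)
  iy2 <- outer(A[, 4], B[, 4], pmin)
  iw <- pmax(ix2 - ix1, 0)
  ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  union <- outer(box_area(A), box_area(B), `+`) - inter
  ifelse(union > 0, inter / union, 0)
}

#' IOU cost matrix
#'
#' Builds the assignment input shared by all trackers: entry (i, j) is
#' `1 - iou(track_i, detection_j)`, so a perfect overlap costs 0 and disjoint
#' boxes cost 1. Either input may be empty, giving a degenerate matrix.
#'
#' @param tracks,dets box matrices (n x 4 and m x 4).
#' @return an n x m matrix of costs in `[0, 1]`.
#' @export
iou_matrix <- function(tracks, dets) {
  1 - iou_pairs(as_box_matrix0(tracks), as_box_matrix0(dets))
}

# like as_box_matrix but tolerates 0-row input given as NULL
as_box_matrix0 <- function(box) {
  if (is.null(box)) return(matrix(numeric(0), 0L, 4L))
  as_box_matrix(box)
}

# rectangle intersection; NULL when empty
box_intersect <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  r <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  if (r[3] <= r[1] || r[4] <= r[2]) return(NULL)
  r
}

# MOT (left, top, width, height) <-> half-open corners. Exact by construction.
ltwh_to_box <- function(l, t, w, h) cbind(x1 = l, y1 = t, x2 = l + w, y2 = t + h)
box_to_ltwh <- function(box) {
  box <- as_box_matrix(box)
  cbind(left = box[, 1], top = box[, 2],
        width = box[, 3] - box[, 1], height = box[, 4] - box[, 2])
}
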