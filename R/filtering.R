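#' Detection-stream cleanup: area thresholds and region of interest
#'
#' Fixed-camera pen footage produces two characteristic kinds of spurious
#' detection: non-cow objects (people, vehicles) whose boxes fall outside the
#' plausible cow-area band, and detections outside the designated pen area.
#' `area_noise_filter()` keeps exactly the detections whose box area lies in
#' the closed band `[th1, th2]` (defaults 5000 and 30000 px^2, the cow-area
#' band for a 2048 x 2048 overhead view). `roi_filter()` restricts a stream to
#' a rectangular region of interest, either by requiring the box center to lie
#' inside it (`mode = "center_inside"`, the default, which never alters a
#' detector box) or by clipping boxes to the region and dropping the emptied
#' ones (`mode = "clip"`).
#'
#' Both filters are idempotent and return a subsequence of their input (order
#' preserved, no new detections).
#'
#' @param dets a detection data frame with columns `x1, y1, x2, y2` (plus any
#'   others, preserved).
#' @param th1,th2 closed area band bounds in px^2; requires `0 < th1 < th2`.
#' @param inclusive keep boxes whose area equals a bound (default TRUE).
#' @return a detection data frame.
#' @examples
#' d <- data.frame(frame = 1, x1 = 0, y1 = 0, x2 = c(60, 100), y2 = c(60, 100),
#'                 score = 1)
#' area_noise_filter(d)   # drops the 3600 px^2 person-sized box
#' @export
area_noise_filter <- function(dets, th1 = 5000, th2 = 30000, inclusive = TRUE) {
  stopifnot(th1 > 0, th1 < th2)
  if (nrow(dets) == 0L) return(dets)
  a <- (dets$x2 - dets$x1) * (dets$y2 - dets$y1)
  keep <- if (inclusive) a >= th1 & a <= th2 else a > th1 & a < th2
  dets[keep, , drop = FALSE]
}

#' Region-of-interest configuration
#'
#' The designated pen area in the image, as `(x, y, w, h)` in pixels. The
#' defaults describe the pen used throughout the package's worked examples:
#' a 1330 x 1592 region at (339, 261) inside a 2048 x 2048 frame.
#'
#' @param x,y top-left corner (px).
#' @param w,h extent (px), both positive.
#' @export
roi_config <- function(x = 339, y = 261, w = 1330, h = 1592) {
  stopifnot(w > 0, h > 0)
  list(x = x, y = y, w = w, h = h)
}

#' @rdname area_noise_filter
#' @param roi a [roi_config()] list.
#' @param mode `"center_inside"` or `"clip"`.
#' @export
roi_filter <- function(dets, roi = roi_config(), mode = c("center_inside", "clip")) {
  mode <- match.arg(mode)
  if (nrow(dets) == 0L) return(dets)
  rb <- c(roi$x, roi$y, roi$x + roi$w, roi$y + roi$h)
  if (mode == "center_inside") {
    cx <- (dets$x1 + dets$x2) / 2
    cy <- (dets$y1 + dets$y2) / 2
    keep <- cx >= rb[1] & cx < rb[3] & cy >= rb[2] & cy < rb[4]
    dets[keep, , drop = FALSE]
  } else {
    x1 <- pmax(dets$x1, rb[1]); y1 <- pmax(dets$y1, rb[2])
    x2 <- pmin(dets$x2, rb[3]); y2 <- pmin(dets$y2, rb[4])
    keep <- x2 > x1 & y2 > y1
    out <- dets[keep, , drop = FALSE]
    out$x1 <- x1[keep]; out$y1 <- y1[keep]
    out$x2 <- x2[keep]; out$y2 <- y2[keep]
    out
  }
}

#' Linear contrast stretch inside a region of interest
#'
#' Maps each pixel inside the ROI by `clip(gain * v + bias)` to the valid
#' intensity range and leaves pixels outside the ROI unchanged. A minimal
#' linear map: it exists to exercise the ROI-mask path on synthetic images;
#' pen footage preprocessing needs nothing stronger before detection streams
#' are consumed.
#'
#' @param intensities a 2-D numeric matrix of pixel intensities (rows = y).
#' @param roi a [roi_config()] list in (x, y, w, h) pixel coordinates.
#' @param gain multiplicative factor (> 0).
#' @param bias additive offset.
#' @param range valid intensity range to clip to, default `c(0, 255)`.
#' @return a matrix of the same shape.
#' @export
contrast_stretch <- function(intensities, roi = roi_config(), gain = 1,
                             bias = 0, range = c(0, 255)) {
  stopifnot(is.matrix(intensities), gain > 0)
  rows <- intersect(seq_len(nrow(intensities)), seq(roi$y + 1, roi$y + roi$h))
  cols <- intersect(seq_len(ncol(intensities)), seq(roi$x + 1, roi$x + roi$w))
  if (length(rows) && length(cols)) {
    v <- intensities[rows, cols] * gain + bias
    intensities[rows, cols] <- pmin(pmax(v, range[1]), range[2])
  }
  intensities
}
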