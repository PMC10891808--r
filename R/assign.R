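#' Minimum-cost one-to-one assignment with gating
#'
#' Solves the linear assignment problem between tracks (rows) and detections
#' (columns) of a finite cost matrix, then demotes any matched pair whose cost
#' exceeds `reject_above` to unmatched on both sides. This is the standard
#' association step of IOU-based trackers: with costs `1 - IOU`,
#' `reject_above = 1 - iou_threshold` implements the usual IOU gate.
#'
#' The optimum is computed by a Jonker-Volgonant style shortest augmenting
#' path Hungarian algorithm (O(n^3)); rectangular matrices are handled by
#' solving on the transposed orientation when rows exceed columns. Ties between
#' equal-cost assignments are broken deterministically toward lower row index.
#'
#' @param cost numeric matrix of finite costs (tracks x detections).
#' @param reject_above matched pairs costing strictly more than this are
#'   dropped. Default `Inf` keeps every matched pair.
#' @return a list with integer matrix `matches` (columns `track`, `det`, row
#'   indices into `cost`), and integer vectors `unmatched_tracks`,
#'   `unmatched_dets`.
#' @examples
#' assign_tracks(matrix(c(0.2, 0.8, 0.9, 0.1), 2), reject_above = 0.5)
#' @export
assign_tracks <- function(cost, reject_above = Inf) {
  stopifnot(is.matrix(cost))
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(list(matches = matrix(integer(0), 0L, 2L,
                                 dimnames = list(NULL, c("track", "det"))),
                unmatched_tracks = seq_len(n), unmatched_dets = seq_len(m)))
  }
  if (any(!is.finite(cost))) stop("assignment costs must be finite")
  if (n <= m) {
    rc <- hungarian_lsap(cost)            # row i -> column rc[i]
    matches <- cbind(track = seq_len(n), det = rc)
  } else {
    cr <- hungarian_lsap(t(cost))         # column j -> row cr[j]
    matches <- cbind(track = cr, det = seq_len(m))
    matches <- matches[order(matches[, 1L]), , drop = FALSE]
  }
  keep <- cost[matches] <= reject_above
  matches <- matches[keep, , drop = FALSE]
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1L]),
       unmatched_dets = setdiff(seq_len(m), matches[, 2L]))
}

# Hungarian algorithm, shortest augmenting path formulation.
# cost: n x m with n <= m; returns integer vector p, row i assigned column p[i].
hungarian_lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m)
  colrow <- integer(m + 1L)   # column -> assigned row (0 = free); m+1 virtual
  VIRT <- m + 1L
  for (i in seq_len(n)) {
    colrow[VIRT] <- i
    j0 <- VIRT
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    way <- integer(m)
    repeat {
      used[j0] <- TRUE
      i0 <- colrow[j0]
      u0 <- u[i0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u0 - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      # relabel potentials along the alternating tree
      for (j in seq_len(m)) {
        if (used[j]) { u[colrow[j]] <- u[colrow[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      u[colrow[VIRT]] <- u[colrow[VIRT]] + delta
      j0 <- j1
      if (colrow[j0] == 0L) break
    }
    repeat {                  # augment along the recorded path
      j1 <- way[j0]
      colrow[j0] <- if (j1 == VIRT) i else colrow[j1]
      j0 <- j1
      if (j0 == VIRT) break
    }
  }
  p <- integer(n)
  for (j in seq_len(m)) if (colrow[j] > 0L) p[colrow[j]] <- j
  p
}
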