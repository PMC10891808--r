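#' Constant-velocity Kalman filters for box and centroid motion
#'
#' Two linear-Gaussian motion models drive the Kalman-based trackers:
#'
#' * the 7-state box model used by SORT-style trackers, with state
#'   `(cx, cy, s, r, vcx, vcy, vs)` where `s` is box area (scale), `r` the
#'   width/height aspect ratio (held constant: no aspect velocity), and the
#'   velocities are per-frame;
#' * the 4-state centroid model `(cx, cy, vx, vy)` used by the centroid +
#'   Kalman tracker.
#'
#' `kalman_predict()` and `kalman_update()` perform the textbook linear
#' predict/update cycle on a state object created by `kf_box_init()` or
#' `kf_centroid_init()`; the covariance stays symmetric by construction
#' (Joseph-free symmetrization after each update). Noise covariances follow
#' the community SORT defaults and can be overridden through the `q_*`/`r_*`
#' arguments.
#'
#' @param box a length-4 box `(x1, y1, x2, y2)` initializing the filter.
#' @param state a filter state as returned by the init/predict/update
#'   functions: a list with `x` (state mean), `P` (covariance), and the model
#'   matrices `F`, `H`, `Q`, `R`.
#' @param measurement for the box model a length-4 box; for the centroid model
#'   a length-2 center `(cx, cy)`.
#' @return a state object; `kf_box_state_to_box()` returns the length-4 box
#'   implied by a box-model state (area clamped to >= 1 px^2).
#' @name kalman
NULL

box_to_z <- function(box) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  c(box[1] + w / 2, box[2] + h / 2, w * h, w / h)
}

z_to_box <- function(z) {
  s <- max(z[3], 1)            # minimum-area clamp: coasting must not
  r <- max(z[4], 1e-6)         # produce degenerate boxes
  w <- sqrt(s * r); h <- s / w
  c(z[1] - w / 2, z[2] - h / 2, z[1] + w / 2, z[2] + h / 2)
}

#' @rdname kalman
#' @export
kf_box_init <- function(box) {
  F7 <- diag(7); F7[1, 5] <- F7[2, 6] <- F7[3, 7] <- 1
  H <- cbind(diag(4), matrix(0, 4, 3))
  R <- diag(c(1, 1, 10, 10))
  P <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))
  list(x = c(box_to_z(box), 0, 0, 0), P = P, F = F7, H = H, Q = Q, R = R)
}

#' @rdname kalman
#' @param center length-2 centroid `(cx, cy)` initializing the filter.
#' @param q_pos,q_vel,r_pos process/measurement noise variances for the
#'   centroid model (px^2).
#' @export
kf_centroid_init <- function(center, q_pos = 1, q_vel = 0.01, r_pos = 1) {
  F4 <- diag(4); F4[1, 3] <- F4[2, 4] <- 1
  H <- cbind(diag(2), matrix(0, 2, 2))
  list(x = c(center[1], center[2], 0, 0),
       P = diag(c(10, 10, 1e3, 1e3)),
       F = F4, H = H,
       Q = diag(c(q_pos, q_pos, q_vel, q_vel)),
       R = diag(c(r_pos, r_pos)))
}

#' @rdname kalman
#' @export
kalman_predict <- function(state) {
  # SORT convention: a negative predicted scale would invert the box; freeze
  # the scale velocity instead.
  if (length(state$x) == 7L && state$x[3] + state$x[7] <= 0) state$x[7] <- 0
  state$x <- drop(state$F %*% state$x)
  P <- state$F %*% state$P %*% t(state$F) + state$Q
  state$P <- (P + t(P)) / 2
  state
}

#' @rdname kalman
#' @export
kalman_update <- function(state, measurement) {
  z <- if (length(state$x) == 7L) box_to_z(measurement) else as.numeric(measurement)
  H <- state$H
  y <- z - drop(H %*% state$x)
  S <- H %*% state$P %*% t(H) + state$R
  K <- state$P %*% t(H) %*% solve(S)
  state$x <- state$x + drop(K %*% y)
  P <- (diag(length(state$x)) - K %*% H) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

#' @rdname kalman
#' @export
kf_box_state_to_box <- function(state) z_to_box(state$x[1:4])
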