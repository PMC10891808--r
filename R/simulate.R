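#' Synthetic pen-scenario configuration
#'
#' Describes a simulated fixed-pen recording: a small herd moving inside the
#' pen region of a 2048 x 2048 overhead view at 10 frames per second, with
#' the three degradations that break naive trackers — per-frame detection
#' dropouts, suppression while crossing a static occluder (a camera stand),
#' and suppression of the smaller cow when two ground-truth boxes overlap —
#' plus spurious non-cow detections whose areas fall outside the cow-area
#' band.
#'
#' Cattle in a pen are mostly stationary with short walking bouts, so each
#' cow alternates rest periods (mean `rest_mean` frames) and walking bouts
#' (mean `walk_mean` frames) toward random waypoints at up to `speed_max`
#' px/frame. Pen cattle show site fidelity, so waypoints are drawn within a
#' home range of radius `home_range` px around each cow's starting area;
#' solid bodies cannot interpenetrate, so deep box overlaps only arise from
#' genuine occlusion geometry. Consecutive suppressed frames per cow are
#' capped at `max_gap` (detectors recover a partial view before long), which
#' also keeps every gap within the default CTA history window.
#'
#' @param n_cows herd size (4-8 typical).
#' @param n_frames stream length in frames.
#' @param fps frame rate metadata (default 10).
#' @param pen the pen region, a [roi_config()].
#' @param cow_area_range box-area band for cows, px^2.
#' @param speed_max maximum walking speed, px/frame.
#' @param rest_mean,walk_mean mean rest/walk bout lengths, frames.
#' @param home_range radius of each cow's waypoint area, px.
#' @param excursion_prob probability that a walking bout is an excursion to
#'   anywhere in the pen (feeding/watering trips) rather than within the
#'   home range; excursions are what carry cows past the camera stand and
#'   through other cows' areas.
#' @param occluder_zone static occluder rectangle `(x1, y1, x2, y2)` in image
#'   coordinates, or `NULL` for none.
#' @param dropout_prob per-frame, per-cow probability of a missed detection.
#' @param occlusion_suppress_iou ground-truth overlap at which the smaller
#'   cow becomes occluded (ties: lower identity is the occludee).
#' @param occlusion_miss_prob per-frame probability that an occluded cow's
#'   detection is actually suppressed. Partial occlusion drops a
#'   segmentation detector intermittently rather than continuously, so gap
#'   lengths are geometric with mean `1 / (1 - occlusion_miss_prob)` (capped
#'   at `max_gap`), matching the few-frame gaps of the scripted scenarios;
#'   set to 1 for deterministic suppression.
#' @param noise_rate expected spurious detections per frame.
#' @param noise_area_range area range for spurious detections; must lie
#'   outside `cow_area_range`.
#' @param jitter detector localization noise: uniform box-corner
#'   perturbation, +/- px.
#' @param max_gap cap on consecutive suppressed frames per cow.
#' @param seed RNG seed; the whole scenario is reproducible from it.
#' @param script optional scripted scenario (used by [preset()]): a list with
#'   `boxes` (per-cow list of n_frames x 4 ground-truth boxes) and
#'   `suppressed` (n_frames x n_cows logical matrix).
#' @return a configuration list of class `sim_config`.
#' @export
sim_config <- function(n_cows = 4L, n_frames = 600L, fps = 10,
                       pen = roi_config(),
                       cow_area_range = c(5000, 30000),
                       speed_max = 5, rest_mean = 80, walk_mean = 20,
                       home_range = 350, excursion_prob = 0.2,
                       occluder_zone = c(950, 950, 1100, 1100),
                       dropout_prob = 0.02,
                       occlusion_suppress_iou = 0.3,
                       occlusion_miss_prob = 0.75,
                       noise_rate = 0.05,
                       noise_area_range = c(1500, 4500),
                       jitter = 2, max_gap = 12L, seed = 1L,
                       script = NULL) {
  stopifnot(n_cows >= 1, n_frames >= 1, fps > 0,
            dropout_prob >= 0, dropout_prob <= 1,
            cow_area_range[1] > 0, cow_area_range[2] > cow_area_range[1])
  if (noise_area_range[1] >= cow_area_range[1] &&
      noise_area_range[1] <= cow_area_range[2])
    stop("noise areas must lie outside the cow-area band")
  # largest cow must fit the pen
  if (sqrt(cow_area_range[2] * 2) > min(pen$w, pen$h))
    stop("infeasible config: cow areas cannot fit the pen")
  structure(list(n_cows = as.integer(n_cows), n_frames = as.integer(n_frames),
                 fps = fps, pen = pen, cow_area_range = cow_area_range,
                 speed_max = speed_max, rest_mean = rest_mean,
                 walk_mean = walk_mean, home_range = home_range,
                 excursion_prob = excursion_prob,
                 occluder_zone = occluder_zone,
                 dropout_prob = dropout_prob,
                 occlusion_suppress_iou = occlusion_suppress_iou,
                 occlusion_miss_prob = occlusion_miss_prob,
                 noise_rate = noise_rate, noise_area_range = noise_area_range,
                 jitter = jitter, max_gap = as.integer(max_gap),
                 seed = as.integer(seed), script = script),
            class = "sim_config")
}

#' Simulate a pen scenario
#'
#' Generates ground-truth trajectories and a degraded detection stream from a
#' [sim_config()]. Every detection either derives from a ground-truth box
#' (with bounded corner jitter) or is logged as noise; every suppression is
#' logged with its cause.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `pen_scenario` with elements `gt` (frame, id,
#'   x1..y2), `dets` (frame, x1..y2, score, gt_id with `NA` for noise),
#'   `events` (frame, event, identity), and `config`.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(cfg$seed)

  if (is.null(cfg$script)) {
    traj <- random_walk_trajectories(cfg)
  } else {
    traj <- cfg$script$boxes
  }
  n <- cfg$n_cows; nf <- cfg$n_frames

  gt <- vector("list", nf)
  det <- vector("list", nf)
  events <- list()
  run <- integer(n)     # consecutive suppressed frames per cow
  for (f in seq_len(nf)) {
    boxes <- do.call(rbind, lapply(traj, function(m) m[f, ]))
    gt[[f]] <- data.frame(frame = f, id = seq_len(n),
                          x1 = boxes[, 1], y1 = boxes[, 2],
                          x2 = boxes[, 3], y2 = boxes[, 4])
    if (is.null(cfg$script)) {
      cause <- character(n)
      # static occluder: cow substantially inside the occluder zone
      if (!is.null(cfg$occluder_zone)) {
        for (i in seq_len(n)) {
          inter <- box_intersect(boxes[i, ], cfg$occluder_zone)
          if (!is.null(inter) &&
              box_area(inter) / box_area(boxes[i, ]) >= 0.3)
            cause[i] <- "object_occlusion"
        }
      }
      # cow-cow: the smaller of an overlapping pair is the occludee
      ov <- iou_pairs(boxes, boxes)
      areas <- box_area(boxes)
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (n >= 2L && ov[i, j] > cfg$occlusion_suppress_iou) {
          k <- if (areas[i] < areas[j] || (areas[i] == areas[j])) i else j
          cause[k] <- "cow_occlusion"
        }
      }
      # occluded cows are dropped intermittently, not continuously
      occ_rnd <- stats::runif(n)
      for (i in seq_len(n))
        if (cause[i] != "" && occ_rnd[i] >= cfg$occlusion_miss_prob)
          cause[i] <- ""
      drop_rnd <- stats::runif(n)
      for (i in seq_len(n)) if (cause[i] == "" && drop_rnd[i] < cfg$dropout_prob)
        cause[i] <- "dropout"
      # cap consecutive suppression: the detector recovers a partial view
      suppressed <- cause != "" & run < cfg$max_gap
    } else {
      suppressed <- cfg$script$suppressed[f, ]
      cause <- ifelse(suppressed, "scripted_miss", "")
    }
    run <- ifelse(suppressed, run + 1L, 0L)
    for (i in which(suppressed))
      events[[length(events) + 1L]] <-
        data.frame(frame = f, event = cause[i], identity = i)

    vis <- which(!suppressed)
    if (length(vis)) {
      jb <- boxes[vis, , drop = FALSE]
      if (cfg$jitter > 0)
        jb <- jb + matrix(stats::runif(4 * length(vis), -cfg$jitter, cfg$jitter),
                          ncol = 4)
      det[[f]] <- data.frame(frame = f, x1 = jb[, 1], y1 = jb[, 2],
                             x2 = jb[, 3], y2 = jb[, 4],
                             score = round(stats::runif(length(vis), 0.6, 1), 2),
                             gt_id = vis)
    }
    # spurious non-cow detections, areas outside the cow band
    n_noise <- if (cfg$noise_rate > 0) stats::rpois(1, cfg$noise_rate) else 0L
    if (n_noise > 0) {
      na_ <- stats::runif(n_noise, cfg$noise_area_range[1], cfg$noise_area_range[2])
      nr <- stats::runif(n_noise, 0.5, 2)
      nw <- sqrt(na_ * nr); nh <- na_ / nw
      nx <- stats::runif(n_noise, 0, 2048 - nw)
      ny <- stats::runif(n_noise, 0, 2048 - nh)
      det[[f]] <- rbind(det[[f]],
                        data.frame(frame = f, x1 = nx, y1 = ny,
                                   x2 = nx + nw, y2 = ny + nh,
                                   score = round(stats::runif(n_noise, 0.3, 0.9), 2),
                                   gt_id = NA_integer_))
      for (k in seq_len(n_noise))
        events[[length(events) + 1L]] <-
          data.frame(frame = f, event = "noise", identity = NA_integer_)
    }
  }
  structure(list(
    gt = do.call(rbind, c(gt, list(make.row.names = FALSE))),
    dets = if (length(det)) do.call(rbind, c(det, list(make.row.names = FALSE)))
           else empty_detections(),
    events = if (length(events))
      do.call(rbind, c(events, list(make.row.names = FALSE)))
    else data.frame(frame = integer(0), event = character(0),
                    identity = integer(0)),
    config = cfg), class = "pen_scenario")
}

# Resting spots avoid the occluder zone (cows walk past the camera stand,
# they do not bed down inside its shadow) and keep separation from other
# cows' spots, so occlusion events are transient crossings rather than
# permanent overlaps: that is the regime the trackers are evaluated in,
# with every gap bounded by max_gap.
sample_waypoint <- function(lo_x, hi_x, lo_y, hi_y, zone, others_x, others_y,
                            min_sep = 180, margin = 100) {
  for (try in 1:30) {
    x <- stats::runif(1, lo_x, hi_x)
    y <- stats::runif(1, lo_y, hi_y)
    in_zone <- !is.null(zone) && x >= zone[1] - margin && x <= zone[3] + margin &&
      y >= zone[2] - margin && y <= zone[4] + margin
    clear <- !length(others_x) ||
      all(sqrt((others_x - x)^2 + (others_y - y)^2) >= min_sep)
    if (!in_zone && clear) return(c(x, y))
  }
  c(x, y)
}

# Rest/walk waypoint trajectories clipped to the pen; one n_frames x 4 box
# matrix per cow.
random_walk_trajectories <- function(cfg) {
  pen <- cfg$pen
  # sample areas inside the band with margin so corner jitter cannot push a
  # cow's box area out of the band
  a <- stats::runif(cfg$n_cows, cfg$cow_area_range[1] * 1.4,
                    cfg$cow_area_range[2] * 0.85)
  r <- stats::runif(cfg$n_cows, 0.8, 1.6)
  w <- sqrt(a * r); h <- a / w
  lo_x <- pen$x + w / 2; hi_x <- pen$x + pen$w - w / 2
  lo_y <- pen$y + h / 2; hi_y <- pen$y + pen$h - h / 2
  # spread starting positions on a jittered grid to avoid initial pile-ups
  ncol_grid <- ceiling(sqrt(cfg$n_cows))
  nrow_grid <- ceiling(cfg$n_cows / ncol_grid)
  gx <- pen$x + (matrix(seq_len(ncol_grid), nrow_grid, ncol_grid, byrow = TRUE) - 0.5) /
    ncol_grid * pen$w
  gy <- pen$y + (matrix(rep(seq_len(nrow_grid), each = ncol_grid),
                        nrow_grid, ncol_grid, byrow = TRUE) - 0.5) / nrow_grid * pen$h
  cx <- pmin(pmax(as.vector(t(gx))[seq_len(cfg$n_cows)] +
                    stats::runif(cfg$n_cows, -40, 40), lo_x), hi_x)
  cy <- pmin(pmax(as.vector(t(gy))[seq_len(cfg$n_cows)] +
                    stats::runif(cfg$n_cows, -40, 40), lo_y), hi_y)
  # nudge any start position out of the occluder zone
  if (!is.null(cfg$occluder_zone)) {
    for (i in seq_len(cfg$n_cows)) {
      z <- cfg$occluder_zone
      m <- max(w[i], h[i]) / 2 + 20
      if (cx[i] >= z[1] - m && cx[i] <= z[3] + m &&
          cy[i] >= z[2] - m && cy[i] <= z[4] + m) {
        p <- sample_waypoint(lo_x[i], hi_x[i], lo_y[i], hi_y[i], z,
                             cx[-i], cy[-i])
        cx[i] <- p[1]; cy[i] <- p[2]
      }
    }
  }
  walking <- rep(FALSE, cfg$n_cows)
  wp_x <- cx; wp_y <- cy
  speed <- stats::runif(cfg$n_cows, 0.4, 1) * cfg$speed_max
  # site fidelity: waypoints stay within each cow's home range
  hr <- cfg$home_range
  wlo_x <- pmax(lo_x, cx - hr); whi_x <- pmin(hi_x, cx + hr)
  wlo_y <- pmax(lo_y, cy - hr); whi_y <- pmin(hi_y, cy + hr)
  out <- lapply(seq_len(cfg$n_cows), function(i)
    matrix(NA_real_, cfg$n_frames, 4))
  box_of <- function(i, x, y) c(x - w[i] / 2, y - h[i] / 2,
                                x + w[i] / 2, y + h[i] / 2)
  # solid bodies: a step may not push two cows into deep overlap (an
  # overhead view shows partial occlusion, never interpenetration); blocked
  # cows try oblique headings, else wait for the other to pass
  try_step <- function(i, ang_off) {
    dx <- wp_x[i] - cx[i]; dy <- wp_y[i] - cy[i]
    d <- sqrt(dx^2 + dy^2)
    if (d < 1e-9) return(TRUE)
    ang <- atan2(dy, dx) + ang_off
    step <- min(speed[i], d)
    nx <- pmin(pmax(cx[i] + cos(ang) * step, lo_x[i]), hi_x[i])
    ny <- pmin(pmax(cy[i] + sin(ang) * step, lo_y[i]), hi_y[i])
    nb <- box_of(i, nx, ny)
    others <- setdiff(seq_len(cfg$n_cows), i)
    ob <- do.call(rbind, lapply(others, function(j) box_of(j, cx[j], cy[j])))
    if (max(iou_pairs(matrix(nb, 1), ob)) > 0.45) return(FALSE)
    cx[i] <<- nx; cy[i] <<- ny
    TRUE
  }
  # a cow only beds down in the clear: its whole box outside the occluder
  # zone (margin scaled to its own half-width) and not deep under a herd mate
  clear_here <- function(i) {
    z <- cfg$occluder_zone
    m <- max(w[i], h[i]) / 2 + 20
    if (!is.null(z) && cx[i] >= z[1] - m && cx[i] <= z[3] + m &&
        cy[i] >= z[2] - m && cy[i] <= z[4] + m) return(FALSE)
    others <- setdiff(seq_len(cfg$n_cows), i)
    if (!length(others)) return(TRUE)
    ob <- do.call(rbind, lapply(others, function(j) box_of(j, cx[j], cy[j])))
    max(iou_pairs(matrix(box_of(i, cx[i], cy[i]), 1), ob)) < 0.2
  }
  for (f in seq_len(cfg$n_frames)) {
    for (i in seq_len(cfg$n_cows)) {
      if (walking[i]) {
        if (stats::runif(1) < 1 / cfg$walk_mean && clear_here(i)) {
          walking[i] <- FALSE
        } else {
          moved <- FALSE
          for (a in c(0, pi / 4, -pi / 4, pi / 2, -pi / 2)) {
            if (try_step(i, a)) { moved <- TRUE; break }
          }
          if (sqrt((wp_x[i] - cx[i])^2 + (wp_y[i] - cy[i])^2) < speed[i] &&
              clear_here(i))
            walking[i] <- FALSE
          if (!moved && stats::runif(1) < 0.1) {
            # long block: give up on this waypoint, pick another
            p <- sample_waypoint(wlo_x[i], whi_x[i], wlo_y[i], whi_y[i],
                                 cfg$occluder_zone, wp_x[-i], wp_y[-i])
            wp_x[i] <- p[1]; wp_y[i] <- p[2]
          }
        }
      } else if (stats::runif(1) < 1 / cfg$rest_mean) {
        walking[i] <- TRUE
        p <- if (stats::runif(1) < cfg$excursion_prob) {
          # cross-pen excursion: target mirrors the current position through
          # the pen center, so the path passes the central camera stand
          tx <- min(max(2 * (pen$x + pen$w / 2) - cx[i], lo_x[i]), hi_x[i])
          ty <- min(max(2 * (pen$y + pen$h / 2) - cy[i], lo_y[i]), hi_y[i])
          sample_waypoint(max(lo_x[i], tx - 200), min(hi_x[i], tx + 200),
                          max(lo_y[i], ty - 200), min(hi_y[i], ty + 200),
                          cfg$occluder_zone, wp_x[-i], wp_y[-i])
        } else
          sample_waypoint(wlo_x[i], whi_x[i], wlo_y[i], whi_y[i],
                          cfg$occluder_zone, wp_x[-i], wp_y[-i])
        wp_x[i] <- p[1]; wp_y[i] <- p[2]
        speed[i] <- stats::runif(1, 0.4, 1) * cfg$speed_max
      }
      out[[i]][f, ] <- c(cx[i] - w[i] / 2, cy[i] - h[i] / 2,
                         cx[i] + w[i] / 2, cy[i] + h[i] / 2)
    }
  }
  out
}

#' Scripted figure-scenario presets
#'
#' Three deterministic scenarios reproducing the canonical failure timelines
#' that motivate the CTA's three mechanisms:
#'
#' * `"fig14_miss"`: four stationary cows; cow 3's detection is missing for
#'   frames 12-13 and returns in place at frame 14 — a plain miss detection.
#' * `"fig16_object_occlusion"`: four stationary cows; cow 3 sits at the
#'   camera-stand zone and is suppressed for frames 16-21, returning in place
#'   at frame 22 — a gap that straddles the 20-frame history refresh.
#' * `"fig18_cow_occlusion"`: six cows; cows 4 and 6 overlap the larger cow 3
#'   and are suppressed for frames 28-33, re-emerging at frame 34 displaced
#'   from where they vanished.
#'
#' On each preset the CTA keeps the original IDs (zero ID increments) while
#' the plain IOU tracker mints new ones.
#'
#' @param name preset name.
#' @return a [sim_config()] with a scripted timeline (no jitter, no dropout,
#'   no noise).
#' @export
preset <- function(name = c("fig14_miss", "fig16_object_occlusion",
                            "fig18_cow_occlusion")) {
  name <- match.arg(name)
  static_box <- function(cx, cy, w, h, nf)
    matrix(rep(c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2), each = nf),
           nf, 4)
  if (name == "fig14_miss") {
    nf <- 30L
    boxes <- list(static_box(600, 600, 110, 110, nf),
                  static_box(1400, 600, 110, 110, nf),
                  static_box(600, 1400, 110, 110, nf),
                  static_box(1400, 1400, 110, 110, nf))
    sup <- matrix(FALSE, nf, 4)
    sup[12:13, 3] <- TRUE
  } else if (name == "fig16_object_occlusion") {
    nf <- 40L
    boxes <- list(static_box(600, 600, 110, 110, nf),
                  static_box(1400, 600, 110, 110, nf),
                  static_box(1050, 1050, 110, 110, nf),  # at the camera stand
                  static_box(600, 1500, 110, 110, nf))
    sup <- matrix(FALSE, nf, 4)
    sup[16:21, 3] <- TRUE
  } else {
    nf <- 45L
    boxes <- list(static_box(500, 500, 110, 110, nf),
                  static_box(1500, 500, 110, 110, nf),
                  static_box(1000, 1000, 140, 140, nf),  # the occluder cow
                  static_box(940, 1000, 110, 110, nf),
                  static_box(500, 1600, 110, 110, nf),
                  static_box(1060, 1000, 110, 110, nf))
    # occludees re-emerge displaced outward after the occlusion
    boxes[[4]][34:nf, ] <- matrix(rep(c(835, 945, 945, 1055), each = nf - 33L),
                                  ncol = 4)
    boxes[[6]][34:nf, ] <- matrix(rep(c(1055, 945, 1165, 1055), each = nf - 33L),
                                  ncol = 4)
    sup <- matrix(FALSE, nf, 6)
    sup[28:33, c(4, 6)] <- TRUE
  }
  sim_config(n_cows = length(boxes), n_frames = nf, dropout_prob = 0,
             noise_rate = 0, jitter = 0, max_gap = nf,
             script = list(boxes = boxes, suppressed = sup))
}
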