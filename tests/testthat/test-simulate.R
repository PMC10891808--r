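test_that("scenarios are byte-identical under one seed and differ across seeds", {
  cfg <- sim_config(n_cows = 4, n_frames = 60, seed = 42)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a, b)
  c_ <- simulate_scenario(sim_config(n_cows = 4, n_frames = 60, seed = 43))
  expect_false(identical(a$dets, c_$dets))
  # global RNG state is untouched by simulation
  set.seed(1); before <- runif(3)
  set.seed(1); simulate_scenario(cfg); after <- runif(3)
  expect_identical(before, after)
})

test_that("the clean limit reproduces ground truth exactly", {
  cfg <- sim_config(n_cows = 4, n_frames = 40, dropout_prob = 0,
                    occluder_zone = NULL, noise_rate = 0, jitter = 0,
                    seed = 6)
  sc <- simulate_scenario(cfg)
  expect_equal(nrow(sc$dets), nrow(sc$gt))
  expect_equal(sc$dets[, c("x1", "y1", "x2", "y2")],
               sc$gt[, c("x1", "y1", "x2", "y2")])
  expect_equal(nrow(sc$events), 0L)
  # perfect detections treated as tracks score perfectly
  pseudo <- sc$dets; pseudo$id <- pseudo$gt_id
  s <- score_stream(pseudo, sc$gt)
  expect_equal(s[c("fp", "fn", "ids")], list(fp = 0L, fn = 0L, ids = 0L))
})

test_that("every detection is ground-truth-derived or logged, and noise sits outside the cow band", {
  sc <- simulate_scenario(sim_config(n_cows = 5, n_frames = 150,
                                     noise_rate = 0.3, seed = 14))
  noise <- sc$dets[is.na(sc$dets$gt_id), ]
  expect_equal(nrow(noise), sum(sc$events$event == "noise"))
  a <- box_area(as.matrix(noise[, c("x1", "y1", "x2", "y2")]))
  expect_true(all(a < 5000 | a > 30000))
  cows <- sc$dets[!is.na(sc$dets$gt_id), ]
  ca <- box_area(as.matrix(cows[, c("x1", "y1", "x2", "y2")]))
  expect_true(all(ca >= 5000 & ca <= 30000))
  # the area filter removes all noise and no cows
  kept <- area_noise_filter(sc$dets)
  expect_equal(sum(is.na(kept$gt_id)), 0L)
  expect_equal(sum(!is.na(kept$gt_id)), nrow(cows))
  # every suppressed cow-frame is logged
  miss_log <- sc$events[sc$events$event != "noise", ]
  expect_equal(nrow(sc$gt) - nrow(cows), nrow(miss_log))
})

test_that("suppression gaps never exceed the configured cap", {
  sc <- simulate_scenario(sim_config(n_cows = 6, n_frames = 400,
                                     dropout_prob = 0.05, max_gap = 10L,
                                     seed = 25))
  for (i in 1:6) {
    frames <- sc$dets$frame[!is.na(sc$dets$gt_id) & sc$dets$gt_id == i]
    gaps <- diff(sort(unique(c(0L, frames))))
    expect_lte(max(gaps) - 1L, 10L)
  }
})

test_that("presets script the documented miss intervals", {
  sc14 <- simulate_scenario(preset("fig14_miss"))
  m <- sc14$events[sc14$events$identity == 3, ]
  expect_equal(m$frame, 12:13)
  expect_equal(nrow(sc14$events), 2L)    # exactly one two-frame miss interval
  sc16 <- simulate_scenario(preset("fig16_object_occlusion"))
  expect_equal(sc16$events$frame[sc16$events$identity == 3], 16:21)
  sc18 <- simulate_scenario(preset("fig18_cow_occlusion"))
  expect_equal(sc18$events$frame[sc18$events$identity == 4], 28:33)
  expect_equal(sc18$events$frame[sc18$events$identity == 6], 28:33)
  # occludees genuinely overlap the occluder cow at suppression onset
  g27 <- sc18$gt[sc18$gt$frame == 27, ]
  occ <- unlist(g27[g27$id == 3, c("x1", "y1", "x2", "y2")])
  for (i in c(4, 6))
    expect_gte(iou(unlist(g27[g27$id == i, c("x1", "y1", "x2", "y2")]), occ),
               0.25)
  expect_error(preset("fig99"))
})

test_that("infeasible pens are rejected", {
  expect_error(sim_config(pen = roi_config(w = 100, h = 100)), "infeasible")
  expect_error(sim_config(noise_area_range = c(6000, 7000)), "outside")
})
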