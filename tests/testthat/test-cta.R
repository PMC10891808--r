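test_that("history buffer refreshes by block and slides by window", {
  cfg <- cta_config(n_history = 5L)
  buf <- list(window_start = 1L, entries = list())
  b <- matrix(c(0, 0, 10, 10), 1)
  for (f in 1:5) buf <- cta_update_history(buf, f, 1L, b, cfg)
  expect_equal(names(buf$entries), "1")
  # frame 6 completes the window: refresh seeds with the current frame only
  buf <- cta_update_history(buf, 6L, 2L, b, cfg)
  expect_equal(buf$window_start, 6L)
  expect_equal(names(buf$entries), "2")
  # sliding mode: old ids fall out of the rolling window
  cfg2 <- cta_config(n_history = 3L, buffer_mode = "sliding")
  buf2 <- list(window_start = 1L, entries = list())
  buf2 <- cta_update_history(buf2, 1L, 1L, b, cfg2)
  for (f in 2:5) buf2 <- cta_update_history(buf2, f, 2L, b, cfg2)
  expect_equal(names(buf2$entries), "2")
})

test_that("miss re-identification is best-first with competition", {
  stored <- rbind(c(0, 0, 100, 100), c(300, 0, 400, 100))
  # det 1 overlaps stored 1 moderately; det 2 overlaps it better
  dets <- rbind(c(40, 0, 140, 100), c(10, 0, 110, 100))
  got <- cta_resolve_miss(c(7L, 9L), stored, dets, reid_iou = 0.3)
  expect_equal(got, c(NA_integer_, 7L))    # higher-IOU det wins the ID
  # identical re-detection reclaims; far-off detection does not
  got2 <- cta_resolve_miss(5L, matrix(c(0, 0, 100, 100), 1),
                           rbind(c(0, 0, 100, 100), c(900, 900, 950, 950)),
                           reid_iou = 0.5)
  expect_equal(got2, c(5L, NA_integer_))
})

test_that("the three scripted failure scenarios are each resolved by the CTA", {
  for (p in c("fig14_miss", "fig16_object_occlusion", "fig18_cow_occlusion")) {
    sc <- simulate_scenario(preset(p))
    res <- track_stream(tracker("cta"), sc$dets, sc$config$n_frames)
    expect_equal(id_increment_count(res, sc$config$n_cows), 0L, info = p)
    expect_true(all(tapply(res$id, res$frame, anyDuplicated) == 0L), info = p)
    # the occludee comes back under its original id, actively detected
    last <- res[res$frame == sc$config$n_frames & res$status == "active", ]
    expect_setequal(last$id, seq_len(sc$config$n_cows))
  }
})

test_that("the plain IOU tracker mints new ids on each scripted scenario", {
  for (p in c("fig14_miss", "fig16_object_occlusion", "fig18_cow_occlusion")) {
    sc <- simulate_scenario(preset(p))
    res <- track_stream(tracker("iou"), sc$dets, sc$config$n_frames)
    expect_gte(id_increment_count(res, sc$config$n_cows), 1L)
  }
})

test_that("disabling a mechanism breaks exactly its own scenario family", {
  fam <- list(fig14_miss = "disable_miss",
              fig16_object_occlusion = "disable_object_occ",
              fig18_cow_occlusion = "disable_cow_occ")
  for (p in names(fam)) {
    sc <- simulate_scenario(preset(p))
    full <- id_increment_count(
      track_stream(tracker("cta"), sc$dets, sc$config$n_frames),
      sc$config$n_cows)
    ablated <- id_increment_count(
      track_stream(tracker("cta", stats::setNames(list(TRUE), fam[[p]])),
                   sc$dets, sc$config$n_frames),
      sc$config$n_cows)
    expect_equal(full, 0L, info = p)
    expect_gt(ablated, full, label = p)
  }
})

test_that("no-net-loss frames leave the id set untouched (gate no-op)", {
  b <- rbind(c(100, 100, 210, 210), c(500, 500, 610, 610),
             c(900, 100, 1010, 210))
  trk <- tracker("cta")
  for (f in 1:6) tracker_step(trk, det_frame(f, b))
  r <- tracker_step(trk, det_frame(7, b))
  expect_equal(r$id, 1:3)
  expect_true(all(r$status == "active"))
})

test_that("two cows hidden across a buffer refresh are both restored", {
  b <- rbind(c(100, 100, 210, 210), c(500, 500, 610, 610),
             c(900, 100, 1010, 210), c(1200, 500, 1310, 610))
  trk <- tracker("cta", list(n_history = 8L))
  for (f in 1:6) tracker_step(trk, det_frame(f, b))
  # cows 1 and 3 vanish for frames 7..10; the window refreshes at frame 9
  for (f in 7:10) tracker_step(trk, det_frame(f, b[c(2, 4), ]))
  r <- tracker_step(trk, det_frame(11, b))
  expect_equal(r$id[r$status == "active"], 1:4)
  expect_equal(id_increment_count(r, 4), 0L)
})

test_that("a genuinely new cow far from any occlusion keeps its fresh id", {
  b <- rbind(c(100, 100, 210, 210), c(500, 500, 610, 610))
  trk <- tracker("cta")
  for (f in 1:5) tracker_step(trk, det_frame(f, b))
  r <- tracker_step(trk, det_frame(6, rbind(b, c(1500, 1500, 1610, 1610))))
  expect_equal(r$id, 1:3)
})

test_that("missing cows are coasted as lost and never duplicate an id", {
  b <- rbind(c(100, 100, 210, 210), c(500, 500, 610, 610))
  trk <- tracker("cta")
  for (f in 1:3) tracker_step(trk, det_frame(f, b))
  r <- tracker_step(trk, det_frame(4, b[2, , drop = FALSE]))
  expect_equal(r$id, 1:2)
  expect_equal(r$status, c("lost", "active"))
  expect_equal(unlist(r[1, c("x1", "y1", "x2", "y2")], use.names = FALSE),
               b[1, ])
  r2 <- tracker_step(trk, det_frame(5, b))
  expect_equal(r2$status, c("active", "active"))
  # coasting off: the missing cow simply disappears from the output
  trk2 <- tracker("cta", list(coast = FALSE))
  for (f in 1:3) tracker_step(trk2, det_frame(f, b))
  r3 <- tracker_step(trk2, det_frame(4, b[2, , drop = FALSE]))
  expect_equal(r3$id, 2L)
})

test_that("a clean herd tracked over several windows emits exactly k ids", {
  cfg <- sim_config(n_cows = 6, n_frames = 70, dropout_prob = 0,
                    occluder_zone = NULL, noise_rate = 0, seed = 31)
  sc <- simulate_scenario(cfg)
  res <- track_stream(tracker("cta"), sc$dets, 70)   # > 3 window refreshes
  expect_equal(length(unique(res$id)), 6L)
})

test_that("id increments under dropout are monotone across trackers' memory", {
  # same stream: CTA resolves what the memory-less IOU tracker cannot
  sc <- simulate_scenario(sim_config(n_cows = 5, n_frames = 200,
                                     dropout_prob = 0.05, occluder_zone = NULL,
                                     noise_rate = 0, seed = 12))
  cta_ids <- id_increment_count(track_stream(tracker("cta"), sc$dets, 200), 5)
  iou_ids <- id_increment_count(track_stream(tracker("iou"), sc$dets, 200), 5)
  expect_equal(cta_ids, 0L)
  expect_gt(iou_ids, 0L)
})
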