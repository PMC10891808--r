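two_static <- function() rbind(c(100, 100, 210, 210), c(500, 500, 610, 610))

test_that("plain IOU tracker mints a new ID after any gap beyond max_age", {
  b <- two_static()
  trk <- tracker("iou")              # max_age = 0
  tracker_step(trk, det_frame(1, b))
  tracker_step(trk, det_frame(2, b[2, , drop = FALSE]))   # object 1 missing
  r <- tracker_step(trk, det_frame(3, b))                 # back in place
  expect_setequal(r$id, c(2L, 3L))   # fresh ID for the re-detection
  # with max_age = 1 the same gap is bridged
  trk2 <- tracker("iou", list(max_age = 1L))
  tracker_step(trk2, det_frame(1, b))
  tracker_step(trk2, det_frame(2, b[2, , drop = FALSE]))
  r2 <- tracker_step(trk2, det_frame(3, b))
  expect_equal(r2$id, 1:2)
})

test_that("centroid tracker follows nearest centroids, jumps mint new IDs", {
  trk <- tracker("centroid")
  tracker_step(trk, det_frame(1, c(100, 100, 200, 200)))
  # small jitter keeps the ID
  r <- tracker_step(trk, det_frame(2, c(105, 103, 205, 203)))
  expect_equal(r$id, 1L)
  # a jump beyond max_distance (150) becomes a new object
  r <- tracker_step(trk, det_frame(3, c(400, 400, 500, 500)))
  expect_equal(r$id, 2L)
})

test_that("two objects swapping positions in one step swap IDs (hand trace)", {
  a <- c(100, 100, 200, 200); b <- c(220, 100, 320, 200)
  trk <- tracker("centroid")
  tracker_step(trk, det_frame(1, rbind(a, b)))
  # swap: detection order also swapped; nearest centroid keeps each ID at its
  # old position, i.e. the IDs follow position, not object
  r <- tracker_step(trk, det_frame(2, rbind(b, a)))
  expect_equal(r$id, 1:2)
  expect_equal(unlist(r[r$id == 1, c("x1", "y1", "x2", "y2")],
                      use.names = FALSE), a)
})

test_that("centroid-Kalman bridges a dropout of a fast mover that plain centroid loses", {
  # object moving +100 px/frame; after a 1-frame dropout the displacement
  # from the last seen position is 200 px > max_distance
  mk <- function(t) det_frame(t, c(100 + 100 * t, 100, 200 + 100 * t, 200))
  plain <- tracker("centroid")
  kal <- tracker("centroid_kalman")
  for (t in 1:6) { tracker_step(plain, mk(t)); tracker_step(kal, mk(t)) }
  tracker_step(plain, NULL, frame = 7)   # dropout
  tracker_step(kal, NULL, frame = 7)
  rp <- tracker_step(plain, mk(8))
  rk <- tracker_step(kal, mk(8))
  expect_equal(rp$id, 2L)   # plain tracker lost it
  expect_equal(rk$id, 1L)   # prediction carried the ID through
})

test_that("stationary objects give centroid and centroid-Kalman identical output", {
  s <- static_stream(two_static(), 12)
  a <- track_stream(tracker("centroid"), s, 12)
  b <- track_stream(tracker("centroid_kalman"), s, 12)
  expect_equal(a$id, b$id)
  expect_equal(a[, c("x1", "y1", "x2", "y2")], b[, c("x1", "y1", "x2", "y2")])
})

test_that("SORT re-identifies within max_age but not beyond it", {
  b <- two_static()
  trk <- tracker("sort", list(min_hits = 1L))   # max_age = 1
  tracker_step(trk, det_frame(1, b))
  tracker_step(trk, det_frame(2, b))
  tracker_step(trk, det_frame(3, b[2, , drop = FALSE]))     # 1-frame gap: kept
  r <- tracker_step(trk, det_frame(4, b))
  expect_equal(r$id, 1:2)
  # 2-frame gap with max_age = 1 kills the track
  tracker_step(trk, det_frame(5, b[2, , drop = FALSE]))
  tracker_step(trk, det_frame(6, b[2, , drop = FALSE]))
  r <- tracker_step(trk, det_frame(7, b))
  expect_setequal(r$id, c(2L, 3L))
})

test_that("SORT boxes converge to truth on a linear-motion stream", {
  trk <- tracker("sort", list(min_hits = 1L))
  for (t in 1:15) {
    truth <- c(100 + 5 * t, 200, 180 + 5 * t, 260)
    r <- tracker_step(trk, det_frame(t, truth))
  }
  expect_equal(r$id, 1L)
  expect_lt(max(abs(unlist(r[1, c("x1", "y1", "x2", "y2")]) - truth)), 2)
})

test_that("deepsort with a ground-truth similarity oracle avoids crossing switches", {
  # two objects cross paths; boxes overlap heavily mid-crossing
  mk <- function(t) det_frame(t, rbind(
    c(100 + 24 * t, 100, 220 + 24 * t, 220),
    c(460 - 24 * t, 100, 580 - 24 * t, 220)), gt_id = c(1L, 2L))
  oracle <- function(track, det) {
    as.numeric(identical(track$last_det$gt_id, det$gt_id))
  }
  ds <- tracker("deepsort", list(similarity = oracle, min_hits = 1L))
  ids_by_gt <- list()
  for (t in 1:15) {
    r <- tracker_step(ds, mk(t))
    d <- mk(t)
    for (g in 1:2) {
      row <- which.max(sapply(seq_len(nrow(r)), function(i)
        iou(unlist(r[i, c("x1", "y1", "x2", "y2")]),
            unlist(d[d$gt_id == g, c("x1", "y1", "x2", "y2")]))))
      ids_by_gt[[as.character(g)]] <-
        union(ids_by_gt[[as.character(g)]], r$id[row])
    }
  }
  # each object kept one ID through the crossing
  expect_equal(lengths(ids_by_gt), c(`1` = 1L, `2` = 1L))
})

test_that("deepsort without similarity behaves like a cascade-ordered SORT", {
  sc <- simulate_scenario(sim_config(n_cows = 4, n_frames = 60,
                                     dropout_prob = 0, occluder_zone = NULL,
                                     noise_rate = 0, seed = 4))
  a <- track_stream(tracker("deepsort"), sc$dets, 60)
  b <- track_stream(tracker("sort", list(max_age = 30L)), sc$dets, 60)
  expect_equal(a$id, b$id)
  # a constant (uninformative) similarity must not break IOU-gated matching
  const <- tracker("deepsort", list(similarity = function(track, det) 0.6,
                                    min_hits = 1L))
  s <- static_stream(two_static(), 8)
  r <- track_stream(const, s, 8)
  expect_equal(length(unique(r$id)), 2L)
})

test_that("modified deepsort retains overlapping stored boxes across frame loss", {
  # boxes overlapping at IOU >= 0.9: 100x100 offset by 2 px
  a <- c(100, 100, 200, 200); b <- c(102, 100, 202, 200)
  far <- c(600, 600, 700, 700)
  trk <- tracker("modified_deepsort", list(min_hits = 1L))
  tracker_step(trk, det_frame(1, rbind(a, b, far)))
  tracker_step(trk, det_frame(2, rbind(a, b, far)))
  # detection frame loss: the overlapping pair disappears
  r <- tracker_step(trk, det_frame(3, far))
  expect_setequal(r$id[r$status == "lost"], 1:2)   # both IDs retained
  # below-threshold overlap is not retained
  c2 <- c(160, 100, 260, 200)   # IOU vs a well below 0.9
  trk2 <- tracker("modified_deepsort", list(min_hits = 1L))
  tracker_step(trk2, det_frame(1, rbind(a, c2, far)))
  tracker_step(trk2, det_frame(2, rbind(a, c2, far)))
  r2 <- tracker_step(trk2, det_frame(3, far))
  expect_equal(nrow(r2[r2$status == "lost", ]), 0L)
  # without frame loss, identical to the deepsort core
  s <- static_stream(two_static(), 10)
  expect_equal(track_stream(tracker("modified_deepsort"), s, 10),
               track_stream(tracker("deepsort"), s, 10))
})

test_that("bytetrack bridges a low-score dip and never spawns from low scores", {
  b <- two_static()
  trk <- tracker("bytetrack")
  tracker_step(trk, det_frame(1, b, score = 0.9))
  tracker_step(trk, det_frame(2, b, score = 0.9))
  # object 1 drops to a low score (occlusion dip): stage 2 keeps its ID
  r <- tracker_step(trk, det_frame(3, b, score = c(0.2, 0.9)))
  expect_equal(r$id, 1:2)
  # an isolated low-score detection never creates a track
  r <- tracker_step(trk, rbind(det_frame(4, b, score = 0.9),
                               det_frame(4, c(900, 900, 1000, 1000),
                                         score = 0.3)))
  expect_equal(r$id, 1:2)
  # all-high scores: equivalent to SORT with the same max_age
  s <- static_stream(two_static(), 10, score = 0.9)
  expect_equal(track_stream(tracker("bytetrack"), s, 10)$id,
               track_stream(tracker("sort", list(max_age = 30L, min_hits = 1L)),
                            s, 10)$id)
})

test_that("IOU-tracker id count grows with dropout probability (fixed seeds)", {
  n_ids <- sapply(c(0, 0.03, 0.08), function(p) {
    sc <- simulate_scenario(sim_config(n_cows = 4, n_frames = 150,
                                       dropout_prob = p, occluder_zone = NULL,
                                       noise_rate = 0, seed = 19))
    length(unique(track_stream(tracker("iou"), sc$dets, 150)$id))
  })
  expect_true(all(diff(n_ids) >= 0))
  expect_gt(n_ids[3], n_ids[1])
})
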