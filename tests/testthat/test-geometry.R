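test_that("iou matches hand-computed values and basic identities", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  # intersection 50, union 150
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
})

test_that("iou is symmetric, bounded, and agrees with a rasterized oracle", {
  set.seed(101)
  for (k in 1:200) {
    a <- random_box(); b <- random_box()
    v <- iou(a, b)
    expect_identical(v, iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, raster_iou(a, b), tolerance = 1e-12)
  }
})

test_that("iou_matrix equals elementwise 1 - iou and handles empty input", {
  set.seed(7)
  A <- do.call(rbind, replicate(4, random_box(), simplify = FALSE))
  B <- do.call(rbind, replicate(5, random_box(), simplify = FALSE))
  M <- iou_matrix(A, B)
  for (i in 1:4) for (j in 1:5)
    expect_equal(M[i, j], 1 - iou(A[i, ], B[j, ]))
  expect_equal(dim(iou_matrix(NULL, B)), c(0L, 5L))
  expect_equal(dim(iou_matrix(A, NULL)), c(4L, 0L))
  # identical boxes give zero cost; disjoint give 1
  expect_equal(iou_matrix(A, A)[cbind(1:4, 1:4)], rep(0, 4))
})

test_that("assignment achieves the brute-force permutation minimum", {
  set.seed(13)
  for (k in 1:200) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- assign_tracks(cost)
    expect_equal(sum(cost[a$matches]),
                 brute_force_assignment_cost(cost), tolerance = 1e-12)
    # one-to-one and complete partition on both sides
    expect_false(anyDuplicated(a$matches[, 1]) > 0)
    expect_false(anyDuplicated(a$matches[, 2]) > 0)
    expect_setequal(c(a$matches[, 1], a$unmatched_tracks), seq_len(n))
    expect_setequal(c(a$matches[, 2], a$unmatched_dets), seq_len(m))
  }
})

test_that("assignment gating demotes over-threshold pairs to both sides", {
  a <- assign_tracks(matrix(c(0.2, 0.8, 0.9, 0.1), 2, 2), reject_above = 0.5)
  expect_equal(a$matches, cbind(track = 1:2, det = 1:2))
  # a forced bad pairing is rejected, leaving the pair unmatched exactly once
  cost <- matrix(1, 3, 3)
  cost[1, 2] <- 0; cost[2, 3] <- 0
  a <- assign_tracks(cost, reject_above = 0.5)
  expect_equal(a$unmatched_tracks, 3L)
  expect_equal(a$unmatched_dets, 1L)
  # degenerate shapes
  e <- assign_tracks(matrix(numeric(0), 0, 3))
  expect_equal(e$unmatched_dets, 1:3)
  expect_equal(nrow(e$matches), 0L)
})

test_that("constant-velocity Kalman tracks a linear trajectory", {
  # centroid model, object moving +5 px/frame in x
  kf <- kf_centroid_init(c(0, 50))
  for (t in 1:10) {
    kf <- kalman_predict(kf)
    kf <- kalman_update(kf, c(5 * t, 50))
  }
  kf <- kalman_predict(kf)
  expect_equal(kf$x[1], 55, tolerance = 0.1)  # closed form: x = 5 * 11
  expect_equal(kf$x[2], 50, tolerance = 0.1)

  # box model: stationary measurements drive velocity to zero
  b <- c(100, 100, 150, 150)
  kb <- kf_box_init(b)
  for (t in 1:20) {
    kb <- kalman_predict(kb)
    kb <- kalman_update(kb, b)
  }
  expect_lt(max(abs(kb$x[5:7])), 1e-3)
  expect_equal(kf_box_state_to_box(kb), b, tolerance = 0.01)
})

test_that("Kalman covariance stays symmetric positive semi-definite", {
  set.seed(3)
  kf <- kf_box_init(c(10, 10, 60, 40))
  for (t in 1:30) {
    kf <- kalman_predict(kf)
    expect_equal(kf$P, t(kf$P))
    expect_true(all(eigen(kf$P, only.values = TRUE)$values > -1e-8))
    if (t %% 3 != 0)  # intermittent measurements
      kf <- kalman_update(kf, c(10 + t, 10, 60 + t, 40 + runif(1)))
  }
})

test_that("zero process and measurement agreement keeps prediction in place", {
  kf <- kf_centroid_init(c(100, 200))
  p <- kalman_predict(kf)
  expect_equal(p$x[1:2], c(100, 200))  # zero initial velocity
})
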