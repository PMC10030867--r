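test_that("matching rate follows the symmetric percentage formula", {
  expect_equal(matching_rate(22, 22, 22), 100)
  expect_equal(round(matching_rate(128, 119, 96), 1), 77.7)
  expect_equal(matching_rate(40, 60, 0), 0)
  # symmetry in the two keypoint counts
  expect_equal(matching_rate(10, 30, 7), matching_rate(30, 10, 7))
  expect_error(matching_rate(0, 0, 0), "undefined")
})

test_that("reference patch covers 50% of the ROI about the same center", {
  f <- matrix(runif(120 * 140), 120, 140)
  v <- new_vessel_video(list(f))
  p <- reference_patch(v, roi_box(10, 5, 100, 80))
  expect_identical(dim(p), c(40L, 50L))
  org <- attr(p, "origin")
  # patch center equals ROI center under floor rounding
  expect_equal(unname(org[2] + 50 / 2), 10 + 100 / 2)
  expect_equal(unname(org[1] + 40 / 2), 5 + 80 / 2)

  p2 <- reference_patch(v, roi_box(0, 0, 4, 4))
  expect_identical(dim(p2), c(2L, 2L))
  expect_error(reference_patch(v, roi_box(0, 0, 3, 4)), "too small")
})

test_that("correlation recovers shifts and matches the direct double-sum", {
  set.seed(7)
  f <- matrix(runif(40 * 40), 40, 40)
  p <- f[11:20, 16:25]
  attr(p, "origin") <- c(row0 = 10, col0 = 15)
  r <- correlate(f, p)
  expect_equal(unname(r$offset), c(0, 0))
  expect_equal(r$peak, 1, tolerance = 1e-9)
  # a shifted origin reports the relative displacement
  attr(p, "origin") <- c(row0 = 13, col0 = 10)
  r2 <- correlate(f, p)
  expect_equal(unname(r2$offset), c(5, -3))

  # perfect anticorrelation
  neg <- 1 - f[5:12, 5:12]
  rn <- correlate(f, neg, method = "direct")
  expect_equal(min(rn$G), -1, tolerance = 1e-9)

  # hand-sized instance: fast equals the direct Eq oracle
  fr <- matrix(c(1, 2, 3, 4, 2, 0, 1, 3, 4, 4, 1, 0, 2, 3, 0, 1) / 4, 4, 4)
  pa <- matrix(c(1, 0, 2, 3) / 3, 2, 2)
  expect_equal(correlate(fr, pa, method = "fast")$G,
               correlate(fr, pa, method = "direct")$G, tolerance = 1e-10)

  expect_error(correlate(f, matrix(0.5, 4, 4)), "zero-variance")
})

test_that("Shi-Tomasi detection is deterministic and finds junction corners", {
  expect_identical(nrow(detect_keypoints(matrix(0.5, 64, 64))), 0L)

  f <- fx_jittered()$video$frames[[1]]
  k1 <- detect_keypoints(f)
  k2 <- detect_keypoints(f)
  expect_identical(k1, k2)
  expect_gt(nrow(k1), 4)

  # at least one corner lands within 3 px of a true junction (thin tubes,
  # so the junction wedge sits at the centerline scale)
  sy <- make_vessel_tree(3, seed = 5, layout = "y", width_range = c(2, 5))
  rvy <- render_video(sy, quiet_motion(), speeds = 0, n_frames = 2)
  ky <- detect_keypoints(rvy$video$frames[[1]], max_points = 30)
  j <- rvy$truth$junctions[1, ]
  d <- sqrt((ky[, "y"] + 1 - j[1])^2 + (ky[, "x"] + 1 - j[2])^2)
  expect_lte(min(d), 3)
})

test_that("Lucas-Kanade tracking recovers translations to subpixel accuracy", {
  set.seed(11)
  f1 <- scleraflow:::gauss_blur(matrix(runif(80 * 80), 80, 80), 1)
  pts <- detect_keypoints(f1, max_points = 15)

  tr0 <- track_keypoints(f1, f1, pts)
  expect_true(all(abs(tr0$displacement[tr0$status, ]) < 0.05))

  f2 <- scleraflow:::shift_int(f1, 3, 0, fill = mean(f1))
  tr <- track_keypoints(f1, f2, pts)
  d <- tr$displacement[tr$status, , drop = FALSE]
  expect_gt(nrow(d), 4)
  expect_true(all(abs(d[, 1] - 3) < 0.25))
  expect_true(all(abs(d[, 2]) < 0.25))

  # a textureless point is flagged lost
  flat <- matrix(0.5, 80, 80); flat[60:80, 60:80] <- f1[60:80, 60:80]
  trf <- track_keypoints(flat, flat, cbind(x = 10, y = 10))
  expect_false(trf$status[1])
})

test_that("frame offset is the component-wise median of tracked points", {
  mk <- function(d) list(displacement = d, status = rep(TRUE, nrow(d)),
                         points = d)
  expect_equal(unname(frame_offset(mk(cbind(c(2, 2, 2), c(0, 0, 0))))), c(2, 0))
  expect_equal(unname(frame_offset(mk(cbind(c(1, 2, 9), c(0, 0, 0))))), c(2, 0))
  expect_equal(unname(frame_offset(mk(cbind(c(1, 3), c(1, 3))))), c(2, 2))
  lost <- list(displacement = cbind(1, 1), status = FALSE, points = cbind(1, 1))
  expect_error(frame_offset(lost), "all points lost")
})

test_that("stabilization recovers phantom camera offsets within 1 px", {
  rv <- fx_jittered()
  for (mth in c("keypoint", "correlation")) {
    st <- stabilize(rv$video, method = mth)
    err <- sqrt(rowSums((st$offsets - rv$truth$offsets)^2))
    expect_gte(mean(err <= 1), 0.95)
    expect_lte(mean(err), 1)
  }
})

test_that("stabilizing an already-static video is the identity up to crop", {
  f <- fx_single_static()$video$frames[[1]]
  v <- new_vessel_video(rep(list(f), 4))
  st <- stabilize(v, method = "correlation")
  expect_true(all(st$offsets == 0))
  expect_equal(st$video$frames[[1]], f)
})

test_that("stabilization is idempotent within 1 px", {
  rv <- fx_jittered()
  sub <- new_vessel_video(rv$video$frames[1:12])
  st1 <- stabilize(sub, method = "correlation")
  st2 <- stabilize(st1$video, method = "correlation")
  expect_lte(max(abs(st2$offsets)), 1)
})

test_that("keypoint and correlation agree on a low-noise phantom", {
  rv <- fx_jittered()
  sub <- new_vessel_video(rv$video$frames[1:12])
  sk <- stabilize(sub, method = "keypoint")
  sc <- stabilize(sub, method = "correlation")
  expect_lte(stats::median(abs(sk$offsets - sc$offsets)), 1)
})
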