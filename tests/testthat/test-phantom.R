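test_that("vessel trees are deterministic and respect branching structure", {
  s1 <- make_vessel_tree(3, seed = 7)
  s2 <- make_vessel_tree(3, seed = 7)
  expect_identical(s1, s2)

  s_one <- make_vessel_tree(1, seed = 4)
  expect_length(s_one$segments, 1L)
  expect_null(s_one$junctions)

  expect_error(make_vessel_tree(2, seed = 1, canvas = c(32, 32)), "canvas")
})

test_that("a 2-branch tree renders with exactly one junction in its skeleton", {
  scene <- make_vessel_tree(2, seed = 21)
  rv <- render_video(scene, quiet_motion(), speeds = 0, n_frames = 2)
  sk <- skeletonize(rv$truth$mask)
  n_branch <- sum(vapply(sk$nodes, function(n) n$type == "branch", TRUE))
  expect_identical(n_branch, 1L)
})

test_that("static defect-free scenes render identical frames in [0,1]", {
  rv <- fx_single_static()
  expect_identical(rv$video$frames[[1]], rv$video$frames[[2]])
  expect_true(all(rv$video$frames[[1]] >= 0 & rv$video$frames[[1]] <= 1))
})

test_that("rendering is bitwise deterministic for a fixed seed", {
  scene <- make_vessel_tree(2, seed = 9)
  mo <- phantom_motion(jitter_sd = 3, seed = 5)
  a <- render_video(scene, mo, speeds = 1, n_frames = 4)
  b <- render_video(scene, mo, speeds = 1, n_frames = 4)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$truth$offsets, b$truth$offsets)
})

test_that("in-tube texture advects at the prescribed speed (1-D correlation oracle)", {
  rv <- fx_straight_v2()
  cl <- rv$truth$centerline[[1]]
  v1 <- scleraflow:::bilinear_sample(rv$video$frames[[1]], cl$row, cl$col)
  v2 <- scleraflow:::bilinear_sample(rv$video$frames[[2]], cl$row, cl$col)
  lags <- -10:10 # centerline samples are spaced 0.5 px
  cc <- vapply(lags, function(L) {
    n <- length(v1); i <- (1 + max(0, L)):(n + min(0, L))
    stats::cor(v1[i - L], v2[i])
  }, 0)
  expect_equal(lags[which.max(cc)] * 0.5, 2) # true speed 2 px/frame
})

test_that("jump frames displace the view beyond the drift constant", {
  scene <- make_vessel_tree(1, seed = 3)
  mo <- phantom_motion(jitter_sd = 3, jump_frames = 10L, seed = 5)
  rv <- render_video(scene, mo, speeds = 0, n_frames = 12)
  d <- sqrt(sum((rv$truth$offsets[10, ] - rv$truth$offsets[9, ])^2))
  expect_gt(d, 100)
})

test_that("conserve_flow speeds satisfy Q balance at the bifurcation", {
  y <- fx_y_conserved()
  area <- vapply(y$scene$segments, function(s) pi * (mean(s$width) / 2)^2, 0)
  q_parent <- y$speeds[1] * area[1]
  q_kids <- sum(y$speeds[2:3] * area[2:3])
  expect_lt(abs(q_parent - q_kids) / q_parent, 0.01)
})

test_that("centerline lies inside the rendered mask", {
  rv <- fx_single_static()
  cl <- do.call(rbind, rv$truth$centerline)
  idx <- cbind(pmin(pmax(round(cl$row), 1), nrow(rv$truth$mask)),
               pmin(pmax(round(cl$col), 1), ncol(rv$truth$mask)))
  expect_true(all(rv$truth$mask[idx]))
})

test_that("speeds beyond the tube length are rejected as aliasing", {
  scene <- make_vessel_tree(1, seed = 3)
  expect_error(render_video(scene, quiet_motion(), speeds = 1e4, n_frames = 2),
               "aliasing")
})

test_that("phantom output round-trips through plain-text files", {
  rv <- fx_single_static()
  dir <- withr::local_tempdir()
  write_video(rv$video, file.path(dir, "frames"))
  write_ground_truth(rv$truth, file.path(dir, "truth"))
  back <- read_video(file.path(dir, "frames"))
  expect_length(back$frames, 2L)
  expect_lt(max(abs(back$frames[[1]] - rv$video$frames[[1]])), 1 / 255)
  m <- read_mask_png(file.path(dir, "truth", "mask.png"))
  expect_identical(m, rv$truth$mask)
})
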