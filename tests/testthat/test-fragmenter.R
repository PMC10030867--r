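mk_gmap <- function(g) structure(list(g = g, I_max = max(g), I_min = min(g)),
                                 class = "gradient_map")

test_that("weighted centroid matches hand-computed oracles", {
  g <- matrix(0, 5, 12)
  roi <- roi_box(0, 0, 12, 5)

  # single informative pixel
  g1 <- g; g1[3, 4] <- 0.8
  c1 <- weighted_centroid(mk_gmap(g1), roi, threshold = 0.5)
  expect_equal(c(c1$x_c, c1$y_c), c(3, 2)) # 0-based

  # two equal weights at columns 0 and 10
  g2 <- g; g2[1, 1] <- 0.6; g2[1, 11] <- 0.6
  c2 <- weighted_centroid(mk_gmap(g2), roi, threshold = 0.5)
  expect_equal(c2$x_c, 5)

  # weights 1.0 and 0.5: x_c = 10 * (0.5/1.5)
  g3 <- g; g3[1, 1] <- 1.0; g3[1, 11] <- 0.5
  c3 <- weighted_centroid(mk_gmap(g3), roi, threshold = 0.3)
  expect_equal(c3$x_c, 10 * 0.5 / 1.5, tolerance = 1e-12)
  # literal pixel-count denominator is available behind a flag
  c3n <- weighted_centroid(mk_gmap(g3), roi, threshold = 0.3, literal_n = TRUE)
  expect_equal(c3n$x_c, 10 * 0.5 / 2)

  expect_error(weighted_centroid(mk_gmap(g), roi, threshold = 0.5), "centroid")
})

test_that("fragments split at the drift limit and discard short runs", {
  ctr <- function(x) list(x_c = x, y_c = 0)

  static <- replicate(50, ctr(60), simplify = FALSE)
  fs <- split_fragments(static, fragmenter_config())
  expect_length(fs, 1L)
  expect_identical(c(fs[[1]]$start, fs[[1]]$end), c(1L, 50L))

  drift <- lapply(c(50, 52, 160, 162), ctr)
  fd <- split_fragments(drift, fragmenter_config())
  expect_length(fd, 2L)
  expect_identical(c(fd[[1]]$start, fd[[1]]$end), c(1L, 2L))
  expect_identical(c(fd[[2]]$start, fd[[2]]$end), c(3L, 4L))

  none <- vector("list", 10)
  expect_length(split_fragments(none, fragmenter_config()), 0L)

  # displacement is measured against the fragment's first frame
  slow <- lapply(seq(0, 120, by = 10), ctr)
  fslow <- split_fragments(slow, fragmenter_config())
  expect_gt(length(fslow), 1L)
  for (f in fslow) {
    d <- sqrt(rowSums(sweep(f$centers, 2, f$centers[1, ])^2))
    expect_true(all(d <= 100))
  }
})

test_that("common box takes corner extremes and minimum extents", {
  frag <- list(start = 1L, end = 3L,
               centers = cbind(x_c = c(50, 50, 50), y_c = c(40, 40, 40)))
  rois <- list(roi_box(0, 0, 100, 80), roi_box(10, 5, 90, 70),
               roi_box(5, 2, 95, 75))
  fb <- common_box(frag, rois)
  # brute-force corner enumeration oracle
  xs <- c(0, 100, 10, 100, 5, 100); ys <- c(0, 80, 5, 75, 2, 77)
  expect_equal(fb$common_box$x_c1, 0)
  expect_equal(fb$common_box$y_c1, 0)
  expect_equal(fb$common_box$x_c2, 100)
  expect_equal(fb$common_box$y_c2, 80)
  expect_equal(fb$common_box$w_b, min(100, 90, 95))
  expect_equal(fb$common_box$h_b, min(80, 70, 75))

  # identical ROIs: common box equals that ROI
  frag2 <- list(start = 1L, end = 2L,
                centers = cbind(x_c = c(20, 20), y_c = c(15, 15)))
  rois2 <- list(roi_box(4, 6, 40, 30), roi_box(4, 6, 40, 30))
  fb2 <- common_box(frag2, rois2)
  expect_equal(unlist(fb2$common_box),
               c(x_c1 = 4, y_c1 = 6, x_c2 = 44, y_c2 = 36, w_b = 40, h_b = 30))
})

test_that("cropping yields constant-shape windows containing the vessel", {
  rv <- fx_single_static()
  video <- new_vessel_video(rep(rv$video$frames[1], 4))
  res <- roi_from_frame(video$frames[[1]])
  ctr <- weighted_centroid(res$gmap, res$roi, res$threshold)
  frag <- list(start = 1L, end = 4L,
               centers = cbind(x_c = rep(ctr$x_c, 4), y_c = rep(ctr$y_c, 4)))
  frag <- common_box(frag, rep(list(res$roi), 4))
  cropped <- crop_fragment(video, frag)
  dims <- vapply(cropped$frames, dim, integer(2))
  expect_true(all(dims[1, ] == frag$common_box$h_b))
  expect_true(all(dims[2, ] == frag$common_box$w_b))
  # the vessel is present in every cropped frame (minimum well below background)
  expect_true(all(vapply(cropped$frames, min, 0) < 0.4))

  # full-frame ROI: crop is the identity
  d <- dim(video$frames[[1]])
  frag_full <- list(start = 1L, end = 1L,
                    centers = cbind(x_c = (d[2] - 1) / 2, y_c = (d[1] - 1) / 2))
  frag_full <- common_box(frag_full, list(roi_box(0, 0, d[2], d[1])))
  out <- crop_fragment(video, frag_full)
  expect_length(out$frames, 1L)
  expect_equal(out$frames[[1]], video$frames[[1]])
})
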