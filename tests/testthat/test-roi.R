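test_that("gradient magnitude matches the direct Sobel oracle", {
  # constant frame: zero everywhere
  g0 <- gradient_magnitude(matrix(0.5, 16, 16))
  expect_true(all(g0$g == 0))

  # vertical step edge of height h responds with 4h on the edge columns
  h <- 0.3
  step <- cbind(matrix(0.2, 5, 3), matrix(0.2 + h, 5, 2))
  gs <- gradient_magnitude(step)
  # direct 3x3 correlation oracle with replicate borders
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  pad <- scleraflow:::pad_replicate(step, 1)
  oracle <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    win <- pad[r:(r + 2), c:(c + 2)]
    oracle[r, c] <- max(abs(sum(win * sob)), abs(sum(win * t(sob))))
  }
  expect_equal(gs$g, oracle, tolerance = 1e-12)
  expect_equal(max(gs$g), 4 * h)

  # transposing the frame transposes the map
  f <- matrix(runif(64, 0.2, 0.8), 8, 8)
  expect_equal(gradient_magnitude(t(f))$g, t(gradient_magnitude(f)$g))
})

test_that("contrast index applies the 0.3 informativity threshold", {
  mkg <- function(lo, hi) {
    g <- matrix(seq(lo, hi, length.out = 16), 4, 4)
    structure(list(g = g, I_max = max(g), I_min = min(g)),
              class = "gradient_map")
  }
  r <- contrast_index(mkg(40 / 255, 60 / 255))
  expect_equal(r$C, 0.2)
  expect_true(r$low_informativity)

  r2 <- contrast_index(mkg(0, 0.4))
  expect_equal(r2$C, 1)
  expect_false(r2$low_informativity)

  r3 <- contrast_index(mkg(0.3, 0.3))
  expect_equal(r3$C, 0)
  expect_true(r3$low_informativity)

  expect_warning(rb <- contrast_index(mkg(0, 0)), "blank")
  expect_equal(rb$C, 0)
  expect_true(rb$low_informativity)
})

test_that("knee threshold finds the maximum bend of the cumulative histogram", {
  # degenerate: all pixels at one level
  g1 <- matrix(0.7, 10, 10)
  expect_equal(knee_threshold(structure(list(g = g1), class = "gradient_map")),
               0.7)

  # two-slope histogram: 90% of mass low, the rest spread high
  set.seed(1)
  vals <- c(runif(900, 0, 0.2), runif(100, 0.2, 1))
  g2 <- matrix(vals, 25, 40)
  thr <- knee_threshold(structure(list(g = g2), class = "gradient_map"),
                        n_bins = 64L)
  # brute-force oracle: maximum perpendicular distance to the chord
  edges <- seq(0, max(vals), length.out = 65)
  bin <- pmin(pmax(ceiling(vals / max(vals) * 64), 1), 64)
  cum <- cumsum(tabulate(bin, 64))
  nz <- which(tabulate(bin, 64) > 0); b0 <- nz[1]; b1 <- nz[length(nz)]
  dx <- b1 - b0; dy <- cum[b1] - cum[b0]
  dist <- vapply(b0:b1, function(b)
    abs(dy * (b - b0) - dx * (cum[b] - cum[b0])) / sqrt(dx^2 + dy^2), 0)
  oracle_bin <- (b0:b1)[which.max(dist)]
  expect_equal(thr, edges[oracle_bin + 1])
  expect_gt(thr, 0.15); expect_lt(thr, 0.5)

  # near-uniform histogram: tie rule lands in the lowest bins
  g3 <- matrix(seq(1 / 256, 1, length.out = 256), 16, 16)
  thr3 <- knee_threshold(structure(list(g = g3), class = "gradient_map"))
  expect_lte(thr3, 3 / 256 + 1e-9)
})

test_that("ROI covers the phantom tube and ignores small debris", {
  rv <- fx_single_static()
  res <- roi_from_frame(rv$video$frames[[1]])
  expect_s3_class(res$roi, "roi_box")
  idx <- which(rv$truth$mask, arr.ind = TRUE)
  # bounding box of the tube, allowing the dilation + Sobel support margin
  marg <- 2 + 2
  expect_lte(res$roi$x0, min(idx[, 2]) - 1)
  expect_gte(res$roi$x0 + res$roi$width, max(idx[, 2]))
  expect_lte(res$roi$y0, min(idx[, 1]) - 1)
  expect_gte(res$roi$y0 + res$roi$height, max(idx[, 1]))
  expect_gte(res$roi$x0, min(idx[, 2]) - 1 - marg)
  expect_lte(res$roi$y0 + res$roi$height, max(idx[, 1]) + marg)
  # inside the frame, deterministic
  d <- dim(rv$video$frames[[1]])
  expect_lte(res$roi$x0 + res$roi$width, d[2])
  expect_identical(roi_from_frame(rv$video$frames[[1]])$roi, res$roi)

  # constant frame: low informativity, ROI absent
  res0 <- suppressWarnings(roi_from_frame(matrix(0.4, 64, 64)))
  expect_null(res0$roi)
  expect_true(res0$contrast$low_informativity)
})

test_that("debris specks below the size filter do not influence the box", {
  # two dark bars plus isolated 3-px specks on a flat background
  f <- matrix(0.6, 80, 100)
  f[30:36, 20:80] <- 0.15
  f[50:56, 25:75] <- 0.15
  f_clean <- f
  f[10, 10:12] <- 0.15 # speck far outside the bars
  f[70, 90:92] <- 0.15
  r_speck <- roi_from_frame(f, min_object_px = 20)
  r_clean <- roi_from_frame(f_clean, min_object_px = 20)
  expect_identical(unclass(r_speck$roi)[c("x0", "y0", "width", "height")],
                   unclass(r_clean$roi)[c("x0", "y0", "width", "height")])
})

test_that("raising the binarization threshold never adds foreground", {
  rv <- fx_single_static()
  g <- gradient_magnitude(rv$video$frames[[1]])$g
  counts <- vapply(seq(0, max(g), length.out = 12),
                   function(t) sum(g >= t), 0)
  expect_true(all(diff(counts) <= 0))
})
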