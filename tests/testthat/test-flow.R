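test_that("dense flow is zero for identical frames and recovers translations", {
  set.seed(2)
  f1 <- scleraflow:::gauss_blur(matrix(runif(100 * 100), 100, 100), 1)
  fl0 <- dense_flow(f1, f1)
  expect_lte(max(fl0$magnitude), 0.05)

  f2 <- scleraflow:::shift_int(f1, 0, 2, fill = mean(f1)) # dy = +2
  fl <- dense_flow(f1, f2)
  interior <- 20:80
  med_mag <- stats::median(fl$magnitude[interior, interior])
  expect_lt(abs(med_mag - 2) / 2, 0.1)
  med_phase <- stats::median(fl$phase[interior, interior])
  expect_lt(abs(med_phase - pi / 2), 10 * pi / 180)

  # stored polar channels agree with their definition
  expect_lt(max(abs(fl$magnitude - sqrt(fl$u^2 + fl$v^2))), 1e-6)
  expect_true(all(fl$phase >= 0 & fl$phase < 2 * pi))

  expect_error(dense_flow(f1, f1[1:50, ]), "shape")
})

test_that("flow determinism holds for fixed inputs", {
  set.seed(4)
  f1 <- scleraflow:::gauss_blur(matrix(runif(60 * 60), 60, 60), 1)
  f2 <- scleraflow:::shift_int(f1, 1, 1, fill = 0.5)
  expect_identical(dense_flow(f1, f2), dense_flow(f1, f2))
})

test_that("HSV rendering encodes phase as hue and magnitude as value", {
  z <- matrix(0, 20, 20)
  img0 <- flow_to_hsv(new_flow_field(z, z))
  expect_true(all(img0 == 0))

  right <- flow_to_hsv(new_flow_field(z + 2, z))
  for (k in 1:3)
    expect_equal(max(abs(right[, , k] - right[1, 1, k])), 0)

  # opposite flows: hues half the circle apart
  u <- cbind(matrix(2, 20, 10), matrix(-2, 20, 10))
  fl <- new_flow_field(u, z)
  h1 <- fl$phase[1, 1] / (2 * pi); h2 <- fl$phase[1, 20] / (2 * pi)
  expect_equal(abs(h1 - h2), 0.5, tolerance = 1e-9)
})

test_that("brightness equalization converges to the target mean", {
  f05 <- matrix(c(0.3, 0.7), 8, 8)
  expect_equal(equalize_brightness(f05), f05)

  fq <- matrix(0.25, 8, 8)
  out <- equalize_brightness(fq, max_iter = 1L, tolerance = 0)
  expect_equal(out, matrix(0.5, 8, 8)) # 0.25 ^ (ln .5 / ln .25) = 0.5

  set.seed(6)
  fr <- matrix(runif(400, 0.05, 0.95), 20, 20)
  eq <- equalize_brightness(fr)
  expect_lte(abs(mean(eq) - 0.5), 1e-3)

  expect_warning(equalize_brightness(matrix(0, 4, 4)), "no-op")
})

test_that("background normalization fills with the halo mean", {
  # toy 5x5 with hand-computed halo mean
  f <- matrix(seq(0.1, 0.9, length.out = 25), 5, 5)
  mask <- matrix(FALSE, 5, 5); mask[3, 3] <- TRUE
  out <- normalize_background(f, mask, halo = 1L)
  ring <- scleraflow:::dilate_disc(mask, 1L) & !mask
  expect_equal(unique(out[!mask]), mean(f[ring]))
  expect_equal(out[3, 3], f[3, 3])

  # gradient background + flat tube: background becomes exactly constant,
  # tube bits untouched
  g <- matrix(rep(seq(0.2, 0.8, length.out = 40), each = 30), 30, 40)
  m <- matrix(FALSE, 30, 40); m[14:17, 5:35] <- TRUE
  g[m] <- 0.15
  out2 <- normalize_background(g, m)
  expect_length(unique(out2[!m]), 1L)
  expect_identical(out2[m], g[m])

  # mask everywhere: identity
  expect_identical(normalize_background(g, matrix(TRUE, 30, 40), halo = 2), g)

  expect_warning(normalize_background(g, m & FALSE), "empty mask")
})

test_that("velocity profiles read the phantom advection speed", {
  rv <- fx_straight_v2()
  mask <- binarize_mask(segment_vessels(rv$video$frames[[1]]))
  sk <- skeletonize(mask)
  main <- sk$segments[[which.max(vapply(sk$segments, function(s) s$length, 0))]]
  flows <- phantom_flows(rv, mask = mask)

  pr <- velocity_profile(flows, main)
  expect_length(pr$v_rel, nrow(main$path))
  expect_true(all(diff(pr$s) > 0))
  expect_lt(abs(profile_summary(pr) - 2) / 2, 0.15)

  z <- new_flow_field(matrix(0, nrow(rv$truth$mask), ncol(rv$truth$mask)),
                      matrix(0, nrow(rv$truth$mask), ncol(rv$truth$mask)))
  pr0 <- velocity_profile(z, main)
  expect_true(all(pr0$v_rel == 0))

  far <- list(path = cbind(10000, 10000))
  expect_error(velocity_profile(flows, far), "bounds")
})

test_that("volumetric speed and calibration follow their unit chains", {
  expect_equal(volumetric_speed(0, 5)$Q, 0)
  vs <- volumetric_speed(2, 2)
  expect_equal(vs$S, pi)
  expect_equal(vs$Q, 2 * pi)
  expect_error(volumetric_speed(1, 0), "width")

  expect_equal(as.numeric(calibrate(1, 1, 1)), 1e-6)
  expect_equal(as.numeric(calibrate(0, 2, 30)), 0)
  expect_equal(as.numeric(calibrate(10, 2.5, 100)), 2.5e-3)
  un <- calibrate(3)
  expect_false(attr(un, "calibrated"))
  expect_equal(as.numeric(un), 3)
})
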