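# Dense optical flow by polynomial expansion (Farneback) and the photometric
# preprocessing around it (constant background fill, iterative brightness
# equalization).

# Polynomial expansion: fit f ~ r1 + r2 x + r3 y + r4 x^2 + r5 y^2 + r6 xy
# in a Gaussian-weighted neighborhood around every pixel (x = column offset,
# y = row offset). Returns the quadratic (A) and linear (b) parts.
poly_expansion <- function(img, poly_n = 5L, poly_sigma = 1.1) {
  t <- seq(-poly_n, poly_n)
  g <- exp(-t^2 / (2 * poly_sigma^2)); g <- g / sum(g)
  w0 <- g; w1 <- t * g; w2 <- t^2 * g
  m2 <- sum(w2)
  m4 <- sum(t^4 * g)
  # normal matrix for basis (1, x, y, x2, y2, xy) under the separable weight
  G <- matrix(0, 6, 6)
  G[1, 1] <- 1
  G[1, 4] <- G[4, 1] <- G[1, 5] <- G[5, 1] <- m2
  G[2, 2] <- G[3, 3] <- m2
  G[4, 4] <- G[5, 5] <- m4
  G[4, 5] <- G[5, 4] <- m2^2
  G[6, 6] <- m2^2
  Gi <- solve(G)
  M00 <- xcorr_sep(img, kx = w0, ky = w0)
  M10 <- xcorr_sep(img, kx = w1, ky = w0)
  M01 <- xcorr_sep(img, kx = w0, ky = w1)
  M20 <- xcorr_sep(img, kx = w2, ky = w0)
  M02 <- xcorr_sep(img, kx = w0, ky = w2)
  M11 <- xcorr_sep(img, kx = w1, ky = w1)
  r <- function(i) Gi[i, 1] * M00 + Gi[i, 2] * M10 + Gi[i, 3] * M01 +
    Gi[i, 4] * M20 + Gi[i, 5] * M02 + Gi[i, 6] * M11
  list(b1 = r(2), b2 = r(3),       # linear terms (x, y)
       a11 = r(4), a22 = r(5), a12 = r(6) / 2)
}

# one Farneback refinement pass at a single scale
farneback_update <- function(p1, p2, u, v, winsize, gaussian_win = TRUE) {
  nr <- nrow(u); nc <- ncol(u)
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Rw <- as.vector(pmin(pmax(R + v, 1), nr))
  Cw <- as.vector(pmin(pmax(C + u, 1), nc))
  take <- function(m) matrix(bilinear_sample(m, Rw, Cw), nr, nc)
  a11 <- (p1$a11 + take(p2$a11)) / 2
  a22 <- (p1$a22 + take(p2$a22)) / 2
  a12 <- (p1$a12 + take(p2$a12)) / 2
  h1 <- a11 * u + a12 * v + (p1$b1 - take(p2$b1)) / 2
  h2 <- a12 * u + a22 * v + (p1$b2 - take(p2$b2)) / 2
  wk <- if (gaussian_win) gauss_kernel(winsize / 5, radius = (winsize - 1) %/% 2)
        else rep(1 / winsize, winsize)
  sm <- function(m) xcorr_sep(m, wk, wk)
  G11 <- sm(a11^2 + a12^2)
  G12 <- sm(a12 * (a11 + a22))
  G22 <- sm(a12^2 + a22^2)
  H1 <- sm(a11 * h1 + a12 * h2)
  H2 <- sm(a12 * h1 + a22 * h2)
  det <- G11 * G22 - G12^2
  ok <- det > 1e-12
  un <- u; vn <- v
  un[ok] <- (G22[ok] * H1[ok] - G12[ok] * H2[ok]) / det[ok]
  vn[ok] <- (G11[ok] * H2[ok] - G12[ok] * H1[ok]) / det[ok]
  list(u = un, v = vn)
}

# bilinear resize of one matrix to a target shape
resize_bilinear <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  matrix(bilinear_sample(m, rep(ri, times = nc), rep(ci, each = nr)), nr, nc)
}

#' Dense optical flow (Farneback polynomial expansion)
#'
#' Per-pixel displacement field between two frames, estimated coarse-to-fine
#' over an image pyramid from local quadratic polynomial expansions.
#' Deterministic for fixed inputs and parameters.
#'
#' @param frame1,frame2 numeric matrices of equal shape.
#' @param pyr_scale pyramid downscaling factor (default 0.5).
#' @param levels pyramid levels (default 3).
#' @param winsize averaging window for the flow solve (default 15).
#' @param gaussian_win weight the solve window with a Gaussian instead of a
#'   box (default TRUE; reduces bleed-in of neighboring static structure and
#'   generally gives a more accurate field).
#' @param iterations refinement passes per level (default 3).
#' @param poly_n neighborhood half-size of the expansion (default 5).
#' @param poly_sigma Gaussian weighting SD of the expansion (default 1.1).
#' @return A `flow_field`: list with `u` (x/column displacement), `v`
#'   (y/row displacement), `magnitude`, `phase` (radians in \[0, 2 pi)).
#' @export
dense_flow <- function(frame1, frame2, pyr_scale = 0.5, levels = 3L,
                       winsize = 15L, iterations = 3L, poly_n = 5L,
                       poly_sigma = 1.1, gaussian_win = TRUE) {
  if (!all(dim(frame1) == dim(frame2))) stop("frames must share one shape")
  dims <- list(dim(frame1))
  for (l in seq_len(levels - 1L)) {
    d <- round(dims[[l]] * pyr_scale)
    if (min(d) < 4 * poly_n) break
    dims[[l + 1L]] <- d
  }
  L <- length(dims)
  pyr1 <- vector("list", L); pyr2 <- vector("list", L)
  pyr1[[1]] <- frame1; pyr2[[1]] <- frame2
  for (l in seq_len(L - 1L)) {
    s1 <- gauss_blur(pyr1[[l]], 1); s2 <- gauss_blur(pyr2[[l]], 1)
    pyr1[[l + 1L]] <- resize_bilinear(s1, dims[[l + 1L]][1], dims[[l + 1L]][2])
    pyr2[[l + 1L]] <- resize_bilinear(s2, dims[[l + 1L]][1], dims[[l + 1L]][2])
  }
  u <- matrix(0, dims[[L]][1], dims[[L]][2])
  v <- matrix(0, dims[[L]][1], dims[[L]][2])
  for (l in L:1) {
    if (!all(dim(u) == dims[[l]])) {
      sc_r <- dims[[l]][1] / nrow(u); sc_c <- dims[[l]][2] / ncol(u)
      u <- resize_bilinear(u, dims[[l]][1], dims[[l]][2]) * sc_c
      v <- resize_bilinear(v, dims[[l]][1], dims[[l]][2]) * sc_r
    }
    e1 <- poly_expansion(pyr1[[l]], poly_n, poly_sigma)
    e2 <- poly_expansion(pyr2[[l]], poly_n, poly_sigma)
    for (it in seq_len(iterations)) {
      fl <- farneback_update(e1, e2, u, v, winsize, gaussian_win)
      u <- fl$u; v <- fl$v
    }
  }
  new_flow_field(u, v)
}

#' Construct a flow field from its components
#' @param u,v displacement components (x/column and y/row, px per frame).
#' @return A `flow_field` with polar channels filled.
#' @export
new_flow_field <- function(u, v) {
  structure(list(u = u, v = v,
                 magnitude = sqrt(u^2 + v^2),
                 phase = atan2(v, u) %% (2 * pi)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %dx%d, median |d| = %.3f px, max %.3f px\n",
              nrow(x$u), ncol(x$u), stats::median(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Render a flow field as an HSV color image
#'
#' Hue encodes phase (full hue circle = 2 pi), value encodes magnitude
#' normalized by its 99th percentile, saturation is 1. Visualization only.
#'
#' @param flow a `flow_field`.
#' @return numeric array (rows x cols x 3) of RGB values in \[0,1\].
#' @export
flow_to_hsv <- function(flow) {
  h <- flow$phase / (2 * pi)
  q <- stats::quantile(flow$magnitude, 0.99, names = FALSE)
  val <- if (q > 0) pmin(flow$magnitude / q, 1) else flow$magnitude * 0
  cols <- grDevices::col2rgb(grDevices::hsv(as.vector(h), 1, as.vector(val))) / 255
  array(c(cols[1, ], cols[2, ], cols[3, ]),
        dim = c(nrow(flow$u), ncol(flow$u), 3))
}
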