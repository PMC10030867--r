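# Low-level raster helpers shared by every stage.
#
# Convention (all modules): frames are plain numeric matrices [row, col] with
# values in [0, 1]; public coordinates are 0-based with x = column, y = row,
# origin at the top-left; crop windows are half-open [x0, x0 + w).

#' Clamp values into [0, 1]
#' @param x numeric vector/matrix.
#' @return `x` with values clipped to the unit interval.
#' @keywords internal
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Validate a single grayscale frame
#' @param frame numeric matrix.
#' @param min_dim minimum allowed side length.
#' @return the frame, invisibly.
#' @keywords internal
check_frame <- function(frame, min_dim = 2L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a 2-D numeric matrix (single-channel image)")
  if (nrow(frame) < min_dim || ncol(frame) < min_dim)
    stop(sprintf("frame must be at least %dx%d", min_dim, min_dim))
  invisible(frame)
}

#' Replicate-pad a matrix
#' @param img matrix.
#' @param top,bottom,left,right padding widths in pixels.
#' @keywords internal
pad_replicate <- function(img, top, bottom = top, left = top, right = left) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, top), seq_len(nr), rep(nr, bottom))
  ci <- c(rep(1L, left), seq_len(nc), rep(nc, right))
  img[ri, ci, drop = FALSE]
}

#' 2-D correlation with a small kernel, replicate borders
#'
#' Applied as correlation (no kernel flip): out(r, c) =
#' sum_k K(i, j) * img(r + i - ic, c + j - jc) with (ic, jc) the kernel center.
#' @param img numeric matrix.
#' @param kern numeric matrix with odd dimensions.
#' @keywords internal
xcorr2 <- function(img, kern) {
  hr <- (nrow(kern) - 1L) %/% 2L
  hc <- (ncol(kern) - 1L) %/% 2L
  p <- pad_replicate(img, hr, hr, hc, hc)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      k <- kern[i, j]
      if (k != 0)
        out <- out + k * p[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

#' Separable correlation (row kernel then column kernel), replicate borders
#' @param img numeric matrix.
#' @param kx kernel applied along columns (x direction), odd length.
#' @param ky kernel applied along rows (y direction), odd length.
#' @keywords internal
xcorr_sep <- function(img, kx, ky = kx) {
  nr <- nrow(img); nc <- ncol(img)
  hx <- (length(kx) - 1L) %/% 2L
  hy <- (length(ky) - 1L) %/% 2L
  # along x (columns)
  if (hx > 0L || length(kx) == 1L) {
    p <- pad_replicate(img, 0L, 0L, hx, hx)
    tmp <- matrix(0, nr, nc)
    for (j in seq_along(kx))
      if (kx[j] != 0) tmp <- tmp + kx[j] * p[, j:(j + nc - 1L), drop = FALSE]
  } else tmp <- img
  # along y (rows)
  if (hy > 0L || length(ky) == 1L) {
    p <- pad_replicate(tmp, hy, hy, 0L, 0L)
    out <- matrix(0, nr, nc)
    for (i in seq_along(ky))
      if (ky[i] != 0) out <- out + ky[i] * p[i:(i + nr - 1L), , drop = FALSE]
  } else out <- tmp
  out
}

#' Normalized 1-D Gaussian kernel
#' @param sigma standard deviation in pixels.
#' @param radius half-width; defaults to ceiling(3 sigma).
#' @keywords internal
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  t <- seq(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with replicate borders
#' @keywords internal
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  xcorr_sep(img, k, k)
}

#' Integer-shift an image, filling exposed borders
#'
#' Content moves by (+dx, +dy): the pixel at (r, c) of the output is the input
#' pixel at (r - dy, c - dx).
#' @param img matrix.
#' @param dx,dy integer shifts in pixels (x = column, y = row).
#' @param fill value for exposed pixels.
#' @keywords internal
shift_int <- function(img, dx, dy, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Bilinear sampling at fractional positions
#' @param img matrix.
#' @param r,c numeric vectors of row/column positions, 1-based; positions are
#'   clamped to the image domain.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

#' Halve an image for a pyramid level (blur then 2x decimation)
#' @keywords internal
pyr_down <- function(img) {
  s <- gauss_blur(img, 1)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

#' Remove connected components smaller than a pixel count
#' @param bw logical matrix.
#' @param min_px minimum component size kept.
#' @keywords internal
filter_small_objects <- function(bw, min_px) {
  if (min_px <= 1L || !any(bw)) return(bw)
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(bw), ncol(bw)))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(bw), ncol(bw))
}

#' Binary dilation by a disc
#' @keywords internal
dilate_disc <- function(bw, radius) {
  if (radius <= 0 || !any(bw)) return(bw)
  sz <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(sz, shape = "disc")
  out <- EBImage::dilate(matrix(as.numeric(bw), nrow(bw), ncol(bw)), brush)
  as.matrix(EBImage::imageData(out)) > 0.5
}
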