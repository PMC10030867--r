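# Fragment stabilization: zero-normalized cross-correlation against a
# reference patch, or Shi-Tomasi keypoints tracked with pyramidal
# Lucas-Kanade flow; the per-frame offset is the median keypoint shift.

#' Reference patch for correlation registration
#'
#' Cuts the centered sub-window covering 50% of the ROI's linear extent in
#' each axis from the first frame; its position is recorded so correlation
#' offsets are measured relative to it.
#'
#' @param video a `vessel_video` (the fragment).
#' @param roi a `roi_box` on the first frame.
#' @return numeric matrix with attribute `origin` = c(row0, col0)
#'   (0-based top-left of the patch in frame coordinates).
#' @export
reference_patch <- function(video, roi) {
  if (roi$width < 4 || roi$height < 4) stop("ROI too small for a reference patch")
  w2 <- roi$width %/% 2L; h2 <- roi$height %/% 2L
  x0 <- roi$x0 + (roi$width - w2) %/% 2L
  y0 <- roi$y0 + (roi$height - h2) %/% 2L
  patch <- video$frames[[1]][(y0 + 1L):(y0 + h2), (x0 + 1L):(x0 + w2), drop = FALSE]
  attr(patch, "origin") <- c(row0 = y0, col0 = x0)
  patch
}

# direct double-sum zero-normalized cross-correlation (oracle-grade)
zncc_direct <- function(frame, patch) {
  M <- nrow(frame); N <- ncol(frame); K <- nrow(patch); L <- ncol(patch)
  J0 <- patch - mean(patch)
  sJ <- sum(J0^2)
  if (sJ == 0) stop("zero-variance patch: correlation undefined")
  G <- matrix(0, M - K + 1L, N - L + 1L)
  for (k in seq_len(M - K + 1L)) {
    for (l in seq_len(N - L + 1L)) {
      w <- frame[k:(k + K - 1L), l:(l + L - 1L)]
      w0 <- w - mean(w)
      sw <- sum(w0^2)
      G[k, l] <- if (sw == 0) 0 else sum(w0 * J0) / sqrt(sw * sJ)
    }
  }
  G
}

# FFT numerator + integral-image denominators; equals zncc_direct to ~1e-12
zncc_fast <- function(frame, patch) {
  M <- nrow(frame); N <- ncol(frame); K <- nrow(patch); L <- ncol(patch)
  J0 <- patch - mean(patch)
  sJ <- sum(J0^2)
  if (sJ == 0) stop("zero-variance patch: correlation undefined")
  # cross-correlation of frame with J0 via zero-padded FFT
  P <- matrix(0, M, N)
  P[1:K, 1:L] <- J0
  num_full <- Re(stats::fft(stats::fft(frame) * Conj(stats::fft(P)), inverse = TRUE)) / (M * N)
  num <- num_full[1:(M - K + 1L), 1:(N - L + 1L), drop = FALSE]
  # window sums via summed-area tables
  sat <- function(x) {
    x <- apply(x, 2, cumsum)
    t(apply(x, 1, cumsum))
  }
  wsum <- function(S) {
    Sp <- rbind(0, cbind(0, S))
    a <- Sp[(K + 1L):(M + 1L), (L + 1L):(N + 1L), drop = FALSE]
    b <- Sp[1:(M - K + 1L), (L + 1L):(N + 1L), drop = FALSE]
    cc <- Sp[(K + 1L):(M + 1L), 1:(N - L + 1L), drop = FALSE]
    d <- Sp[1:(M - K + 1L), 1:(N - L + 1L), drop = FALSE]
    a - b - cc + d
  }
  s1 <- wsum(sat(frame))
  s2 <- wsum(sat(frame^2))
  varw <- pmax(s2 - s1^2 / (K * L), 0)
  den <- sqrt(varw * sJ)
  G <- ifelse(den > 1e-12, num / den, 0)
  pmin(pmax(G, -1), 1)
}

#' Zero-normalized cross-correlation of a patch over a frame
#'
#' Evaluates the correlation map over all valid integer shifts and returns
#' the offset of the best match relative to the patch's recorded origin.
#' Ties at the peak break toward the smallest offset magnitude.
#'
#' @param frame numeric matrix.
#' @param patch numeric matrix smaller than `frame`, with nonzero variance;
#'   optionally carrying an `origin` attribute (see [reference_patch()]).
#' @param method `"fast"` (FFT + integral images) or `"direct"` (double sum).
#' @return list with `G` (correlation map over valid top-left positions),
#'   `offset` = c(dx, dy), `peak` (correlation value at the maximum).
#' @export
correlate <- function(frame, patch, method = c("fast", "direct")) {
  method <- match.arg(method)
  if (nrow(patch) > nrow(frame) || ncol(patch) > ncol(frame))
    stop("patch must be smaller than frame")
  G <- if (method == "fast") zncc_fast(frame, patch) else zncc_direct(frame, patch)
  origin <- attr(patch, "origin")
  if (is.null(origin)) origin <- c(0, 0)
  peak <- max(G)
  cand <- which(G >= peak - 1e-12, arr.ind = TRUE)
  dx <- (cand[, 2] - 1L) - origin[2]
  dy <- (cand[, 1] - 1L) - origin[1]
  ord <- order(dx^2 + dy^2, dy, dx)
  best <- ord[1]
  list(G = G, offset = c(dx = dx[best], dy = dy[best]), peak = peak)
}

# Sobel derivative pair used by the corner detector and tracker
image_gradients <- function(img) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
  list(Ix = xcorr2(img, sx), Iy = xcorr2(img, t(sx)))
}

#' Shi-Tomasi corner detection
#'
#' Minimum eigenvalue of the 3x3-summed structure tensor; keeps maxima above
#' `quality` times the global maximum with greedy non-maximum suppression at
#' `min_distance`, ordered by response then row-major position.
#'
#' @param frame numeric matrix.
#' @param max_points maximum number of corners returned.
#' @param quality fraction of the strongest response kept (default 0.01).
#' @param min_distance minimum spacing between corners in px.
#' @return n x 2 matrix with columns `x`, `y` (0-based px); may have 0 rows.
#' @export
detect_keypoints <- function(frame, max_points = 50L, quality = 0.01,
                             min_distance = 7) {
  g <- image_gradients(frame)
  box <- matrix(1, 3, 3)
  Axx <- xcorr2(g$Ix^2, box); Ayy <- xcorr2(g$Iy^2, box)
  Axy <- xcorr2(g$Ix * g$Iy, box)
  tr <- Axx + Ayy
  dt <- sqrt(pmax((Axx - Ayy)^2 + 4 * Axy^2, 0))
  resp <- (tr - dt) / 2
  # exclude the border band where gradients are replicate-padded
  resp[c(1:2, nrow(resp) - 1:0), ] <- 0
  resp[, c(1:2, ncol(resp) - 1:0)] <- 0
  mx <- max(resp)
  if (mx <= 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cand <- which(resp >= quality * mx, arr.ind = TRUE)
  vals <- resp[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(0, 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) &&
        any((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 < min_distance^2))
      next
    keep <- rbind(keep, p)
    if (nrow(keep) >= max_points) break
  }
  out <- cbind(x = keep[, 2] - 1, y = keep[, 1] - 1)
  rownames(out) <- NULL
  out
}

#' Pyramidal Lucas-Kanade keypoint tracking
#'
#' Solves the 2x2 least-squares flow system on a fixed window around each
#' point, refined coarse-to-fine over a Gaussian image pyramid. Points whose
#' structure tensor is ill-conditioned or that leave the frame are flagged
#' lost.
#'
#' @param frame1,frame2 numeric matrices of equal shape.
#' @param points n x 2 matrix (`x`, `y`, 0-based) of positions on `frame1`.
#' @param window odd window size in px (default 15).
#' @param levels pyramid levels (default 3).
#' @param max_iter,eps iteration control at each level.
#' @return list with `points` (input), `displacement` (n x 2, dx/dy),
#'   `status` (logical, TRUE = tracked).
#' @export
track_keypoints <- function(frame1, frame2, points, window = 15L, levels = 3L,
                            max_iter = 15L, eps = 0.01) {
  n <- nrow(points)
  disp <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("dx", "dy")))
  status <- rep(FALSE, n)
  if (!n) return(list(points = points, displacement = disp, status = status))
  hw <- (window - 1) / 2
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  pyr1 <- list(frame1); pyr2 <- list(frame2)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr1[[l]])) < 2 * window) break
    pyr1[[l + 1L]] <- pyr_down(pyr1[[l]])
    pyr2[[l + 1L]] <- pyr_down(pyr2[[l]])
  }
  L <- length(pyr1)
  grads <- lapply(pyr1, image_gradients)
  for (i in seq_len(n)) {
    # 1-based position at full resolution
    p0 <- c(points[i, 2] + 1, points[i, 1] + 1) # (row, col)
    g <- c(0, 0) # (drow, dcol) guess
    ok <- TRUE
    for (l in L:1) {
      sc <- 2^(l - 1L)
      pl <- (p0 - 1) / sc + 1
      f1 <- pyr1[[l]]; f2 <- pyr2[[l]]
      rr <- pl[1] + off$dr; cc <- pl[2] + off$dc
      if (min(rr) < 1 || max(rr) > nrow(f1) || min(cc) < 1 || max(cc) > ncol(f1)) {
        if (l == 1) ok <- FALSE
        next
      }
      Ixw <- bilinear_sample(grads[[l]]$Ix, rr, cc)
      Iyw <- bilinear_sample(grads[[l]]$Iy, rr, cc)
      Gm <- matrix(c(sum(Ixw^2), sum(Ixw * Iyw), sum(Ixw * Iyw), sum(Iyw^2)), 2, 2)
      ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-7 * length(Ixw)) { ok <- FALSE; break }
      I1w <- bilinear_sample(f1, rr, cc)
      for (it in seq_len(max_iter)) {
        r2 <- rr + g[1]; c2 <- cc + g[2]
        if (min(r2) < 0 || max(r2) > nrow(f2) + 1 ||
            min(c2) < 0 || max(c2) > ncol(f2) + 1) { ok <- FALSE; break }
        e <- I1w - bilinear_sample(f2, r2, c2)
        b <- c(sum(e * Iyw), sum(e * Ixw)) # (row, col) ordering
        dlt <- solve(Gm[2:1, 2:1, drop = FALSE], b) # reorder to (row, col)
        g <- g + dlt
        if (sqrt(sum(dlt^2)) < eps) break
      }
      if (!ok) break
      if (l > 1) g <- g * 2
    }
    tgt <- p0 + g
    if (ok && tgt[1] >= 1 && tgt[1] <= nrow(frame1) &&
        tgt[2] >= 1 && tgt[2] <= ncol(frame1) && all(is.finite(g))) {
      disp[i, ] <- c(g[2], g[1]) # back to (dx, dy)
      status[i] <- TRUE
    }
  }
  list(points = points, displacement = disp, status = status)
}

#' Symmetric keypoint matching rate (percent)
#'
#' Mr = M * 200 / (Kp1 + Kp2).
#'
#' @param Kp1,Kp2 keypoint counts on the two frames.
#' @param M matched-point count.
#' @return matching rate in percent.
#' @export
matching_rate <- function(Kp1, Kp2, M) {
  if (Kp1 + Kp2 <= 0) stop("matching rate undefined: no keypoints")
  M * 200 / (Kp1 + Kp2)
}

#' Frame offset as the median keypoint displacement
#'
#' @param track result of [track_keypoints()].
#' @return c(dx, dy): component-wise median over tracked points (even counts
#'   average the middle two).
#' @export
frame_offset <- function(track) {
  d <- track$displacement[track$status, , drop = FALSE]
  if (!nrow(d)) stop("offset undefined: all points lost")
  c(dx = stats::median(d[, 1]), dy = stats::median(d[, 2]))
}

#' Stabilize a video fragment
#'
#' Estimates each frame's translation relative to frame 1 (keypoints tracked
#' from frame 1, or correlation against the frame-1 reference patch), then
#' shifts every frame back and crops to the common valid region. With
#' `method = "keypoint"`, frames where fewer than 4 points survive fall back
#' to correlation.
#'
#' @param video a `vessel_video` with >= 2 frames.
#' @param method `"keypoint"` (default) or `"correlation"`.
#' @param roi optional `roi_box` on frame 1 (reference region); derived with
#'   [roi_from_frame()] when absent, falling back to the full frame.
#' @param max_points,quality,min_distance Shi-Tomasi settings.
#' @param window,levels Lucas-Kanade settings.
#' @return list with `video` (stabilized, cropped), `offsets` (n x 2 matrix
#'   dx/dy, frame 1 = 0), `method` (per-frame method actually used).
#' @export
stabilize <- function(video, method = c("keypoint", "correlation"), roi = NULL,
                      max_points = 50L, quality = 0.01, min_distance = 7,
                      window = 15L, levels = 3L) {
  method <- match.arg(method)
  n <- length(video$frames)
  if (n < 2) stop("stabilization needs at least 2 frames")
  d <- dim(video$frames[[1]])
  if (is.null(roi)) {
    rr <- roi_from_frame(video$frames[[1]])
    roi <- rr$roi
    if (is.null(roi))
      roi <- roi_box(x0 = 0, y0 = 0, width = d[2], height = d[1])
  }
  # photometric normalization so illumination drift does not bias tracking
  norm1 <- function(f) {
    f0 <- f - mean(f)
    s <- stats::sd(as.vector(f0))
    if (s > 0) f0 / s else f0
  }
  nf <- lapply(video$frames, norm1)
  patch <- reference_patch(new_vessel_video(nf), roi)
  offsets <- matrix(0, n, 2, dimnames = list(NULL, c("dx", "dy")))
  used <- rep(method, n)
  pts <- if (method == "keypoint")
    detect_keypoints(nf[[1]], max_points, quality, min_distance) else NULL
  for (t in 2:n) {
    o <- NULL
    if (method == "keypoint" && !is.null(pts) && nrow(pts) >= 4L) {
      tr <- track_keypoints(nf[[1]], nf[[t]], pts, window = window, levels = levels)
      if (sum(tr$status) >= 4L) o <- frame_offset(tr)
    }
    if (is.null(o)) {
      o <- correlate(nf[[t]], patch, method = "fast")$offset
      used[t] <- "correlation"
    }
    offsets[t, ] <- o
  }
  ri <- round(offsets)
  x0 <- 1L + max(0L, max(ri[, 1])); x1 <- d[2] + min(0L, min(ri[, 1]))
  y0 <- 1L + max(0L, max(ri[, 2])); y1 <- d[1] + min(0L, min(ri[, 2]))
  if (x0 > x1 || y0 > y1) stop("stabilization failed: empty common region")
  out <- vector("list", n)
  for (t in seq_len(n)) {
    sh <- shift_int(video$frames[[t]], -ri[t, 1], -ri[t, 2], fill = 0)
    out[[t]] <- sh[y0:y1, x0:x1, drop = FALSE]
  }
  list(video = new_vessel_video(out, um_per_px = video$um_per_px, fps = video$fps),
       offsets = offsets, method = used)
}
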