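# Fragmenting the video: track the weighted centroid of the informative
# region, cut the sequence wherever the centroid drifts beyond the limit
# (default 100 px), and crop each fragment to a common contrast box.

#' Weighted centroid of informative pixels in an ROI
#'
#' Centroid of the pixels inside `roi` whose gradient value is at least
#' `threshold`, weighted by intensity scaled so the maximum in-ROI intensity
#' has unit weight (the normalization coefficient `p`). The default
#' denominator is the sum of weights (the standard center of mass); setting
#' `literal_n = TRUE` divides by the pixel count instead.
#'
#' @param gmap a `gradient_map`.
#' @param roi a `roi_box`.
#' @param threshold gradient cutoff defining informative pixels.
#' @param literal_n use the pixel count as the denominator.
#' @return list with `x_c`, `y_c` (0-based px), `p`, `n`, `support`
#'   (n x 2 matrix of 0-based row/col indices), `weights`.
#' @export
weighted_centroid <- function(gmap, roi, threshold, literal_n = FALSE) {
  g <- gmap$g
  rr <- (roi$y0 + 1L):(roi$y0 + roi$height)
  cc <- (roi$x0 + 1L):(roi$x0 + roi$width)
  sub <- g[rr, cc, drop = FALSE]
  sel <- which(sub >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) stop("centroid undefined: no informative pixel in ROI")
  wts <- sub[sel]
  p <- 1 / max(wts)
  w <- wts * p
  xs <- (sel[, 2] - 1L) + roi$x0 # 0-based columns
  ys <- (sel[, 1] - 1L) + roi$y0
  denom <- if (literal_n) nrow(sel) else sum(w)
  list(x_c = sum(xs * w) / denom, y_c = sum(ys * w) / denom,
       p = p, n = nrow(sel),
       support = cbind(row = ys, col = xs), weights = w)
}

#' Fragmenter configuration
#'
#' @param drift_limit maximum centroid displacement (px) from a fragment's
#'   first frame before the fragment is closed (default 100).
#' @param min_fragment_len fragments shorter than this are discarded.
#' @return list of settings.
#' @export
fragmenter_config <- function(drift_limit = 100, min_fragment_len = 2L) {
  stopifnot(drift_limit > 0, min_fragment_len >= 1)
  list(drift_limit = drift_limit, min_fragment_len = as.integer(min_fragment_len))
}

#' Split a video into fragments with a persistent informative region
#'
#' Greedy scan over frames: a fragment ends at frame t when the Euclidean
#' displacement of frame t+1's centroid from the centroid of the fragment's
#' first frame exceeds `cfg$drift_limit`, or when frame t+1 has no ROI.
#' Fragments shorter than `cfg$min_fragment_len` are dropped.
#'
#' @param centers list with one element per frame: a centroid list
#'   (`x_c`, `y_c`) or `NULL` where the frame has no ROI.
#' @param cfg a [fragmenter_config()].
#' @return list of fragments: `start`, `end` (1-based, inclusive),
#'   `centers` (per-frame x_c/y_c matrix).
#' @export
split_fragments <- function(centers, cfg = fragmenter_config()) {
  n <- length(centers)
  frags <- list()
  t <- 1L
  while (t <= n) {
    if (is.null(centers[[t]])) { t <- t + 1L; next }
    start <- t
    ref <- c(centers[[t]]$x_c, centers[[t]]$y_c)
    while (t + 1L <= n && !is.null(centers[[t + 1L]])) {
      nxt <- c(centers[[t + 1L]]$x_c, centers[[t + 1L]]$y_c)
      if (sqrt(sum((nxt - ref)^2)) > cfg$drift_limit) break
      t <- t + 1L
    }
    if (t - start + 1L >= cfg$min_fragment_len) {
      ctr <- t(vapply(centers[start:t],
                      function(ci) c(ci$x_c, ci$y_c), numeric(2)))
      colnames(ctr) <- c("x_c", "y_c")
      frags[[length(frags) + 1L]] <-
        list(start = start, end = t, centers = ctr, common_box = NULL)
    }
    t <- t + 1L
  }
  frags
}

#' Fill a fragment's common contrast box
#'
#' Corners are the elementwise min/max of all per-frame ROI corner
#' coordinates over the fragment; the common size (w_b, h_b) is the minimum
#' per-frame ROI width/height. The crop window of that size is centered on
#' each frame's centroid and shifted inward to stay inside the frame.
#'
#' @param fragment a fragment from [split_fragments()].
#' @param rois list of per-frame `roi_box` (full-video indexing).
#' @return the fragment with `common_box` filled: list `x_c1`, `y_c1`,
#'   `x_c2`, `y_c2` (corner extremes), `w_b`, `h_b`.
#' @export
common_box <- function(fragment, rois) {
  idx <- fragment$start:fragment$end
  rs <- rois[idx]
  if (any(vapply(rs, is.null, TRUE)))
    stop("every frame in the fragment must have an ROI")
  x0 <- vapply(rs, function(r) r$x0, 0L)
  y0 <- vapply(rs, function(r) r$y0, 0L)
  x1 <- vapply(rs, function(r) r$x0 + r$width, 0L)   # half-open
  y1 <- vapply(rs, function(r) r$y0 + r$height, 0L)
  w_b <- min(x1 - x0); h_b <- min(y1 - y0)
  if (w_b < 1 || h_b < 1) stop("degenerate common box")
  fragment$common_box <- list(x_c1 = min(x0), y_c1 = min(y0),
                              x_c2 = max(x1), y_c2 = max(y1),
                              w_b = w_b, h_b = h_b)
  fragment
}

#' Crop a fragment to its common box
#'
#' Returns frames `start..end` cropped to windows of (w_b, h_b) centered on
#' each frame's centroid; windows near the border are shifted inward rather
#' than padded, so all output frames share one shape.
#'
#' @param video a `vessel_video`.
#' @param fragment a fragment with `common_box` filled.
#' @return a `vessel_video` of the cropped frames.
#' @export
crop_fragment <- function(video, fragment) {
  cb <- fragment$common_box
  if (is.null(cb)) stop("common_box must be filled before cropping")
  d <- dim(video$frames[[1]])
  if (cb$w_b > d[2] || cb$h_b > d[1]) stop("common box exceeds frame size")
  out <- vector("list", fragment$end - fragment$start + 1L)
  for (i in seq_along(out)) {
    ctr <- fragment$centers[i, ]
    x0 <- round(ctr[1] - cb$w_b / 2) # 0-based
    y0 <- round(ctr[2] - cb$h_b / 2)
    x0 <- min(max(x0, 0L), d[2] - cb$w_b)
    y0 <- min(max(y0, 0L), d[1] - cb$h_b)
    out[[i]] <- video$frames[[fragment$start + i - 1L]][
      (y0 + 1L):(y0 + cb$h_b), (x0 + 1L):(x0 + cb$w_b), drop = FALSE]
  }
  new_vessel_video(out, um_per_px = video$um_per_px, fps = video$fps)
}
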