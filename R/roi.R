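# Region-of-interest detection: gradient magnitude (Sobel), Michelson-type
# contrast on the gradient image, cumulative-histogram knee threshold, and
# the debris-filtered bounding box of informative structure.

#' Gradient magnitude as the maximum of the two Sobel responses
#'
#' Applies the 3x3 horizontal and vertical Sobel operators (replicate
#' borders) and takes the per-pixel maximum of their absolute values.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @return A `gradient_map`: list with `g` (nonnegative matrix), `I_max`,
#'   `I_min` (extremes of `g`).
#' @export
gradient_magnitude <- function(frame) {
  check_frame(frame, min_dim = 3L)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (columns)
  sy <- t(sx)                                                # d/dy (rows)
  g <- pmax(abs(xcorr2(frame, sx)), abs(xcorr2(frame, sy)))
  structure(list(g = g, I_max = max(g), I_min = min(g)), class = "gradient_map")
}

#' Michelson-type contrast of a gradient map
#'
#' C = (I_max - I_min) / (I_max + I_min) over the gradient image; frames with
#' C below `c_threshold` are flagged as low-informativity. A blank map
#' (I_max + I_min = 0) yields C = 0 with the flag set and a warning.
#'
#' @param gmap a `gradient_map`.
#' @param c_threshold informativity cutoff (default 0.3).
#' @return list with `C` and `low_informativity`.
#' @export
contrast_index <- function(gmap, c_threshold = 0.3) {
  s <- gmap$I_max + gmap$I_min
  if (s == 0) {
    warning("blank gradient map: contrast undefined, reported as 0")
    return(list(C = 0, low_informativity = TRUE))
  }
  C <- (gmap$I_max - gmap$I_min) / s
  list(C = C, low_informativity = C < c_threshold)
}

#' Cumulative-histogram knee threshold
#'
#' Builds an `n_bins` histogram of the gradient values on \[0, max(g)\],
#' forms its cumulative curve, draws the chord between the first and last
#' nonempty bins, and returns the (upper edge) value of the bin at maximum
#' perpendicular distance from the chord. Ties break toward the lowest bin.
#'
#' @param gmap a `gradient_map` (or a plain numeric matrix).
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold on the gradient scale.
#' @export
knee_threshold <- function(gmap, n_bins = 256L) {
  g <- if (inherits(gmap, "gradient_map")) gmap$g else gmap
  if (!all(is.finite(g))) stop("gradient map must be finite")
  gmax <- max(g)
  if (gmax <= 0) return(0)
  edges <- seq(0, gmax, length.out = n_bins + 1L)
  bin <- pmin(pmax(ceiling(as.vector(g) / gmax * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  cum <- cumsum(counts)
  nz <- which(counts > 0)
  b0 <- nz[1]; b1 <- nz[length(nz)]
  if (b0 == b1) return(edges[b0 + 1L])
  # perpendicular distance of (b, cum[b]) from the chord (b0,cum[b0])-(b1,cum[b1])
  x <- b0:b1
  y <- cum[x]
  dx <- b1 - b0; dy <- cum[b1] - cum[b0]
  dist <- abs(dy * (x - b0) - dx * (y - cum[b0])) / sqrt(dx^2 + dy^2)
  kb <- x[which.max(dist)] # which.max takes the first (lowest-bin) maximum
  edges[kb + 1L]
}

#' Region of interest of one frame
#'
#' Pipeline: Sobel gradient -> contrast index -> knee threshold -> binarize
#' (g >= threshold) -> remove components smaller than `min_object_px` ->
#' dilate by a disc of `dilation_radius` -> bounding box of the surviving
#' objects. If the frame is low-informativity (C < `c_threshold`) or nothing
#' survives the size filter, the ROI is reported absent (`roi = NULL`).
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param min_object_px minimum connected-component size kept (default 20).
#' @param dilation_radius disc radius for object linking (default 2).
#' @param c_threshold informativity cutoff (default 0.3).
#' @return list with `roi` (a `roi_box` or NULL), `contrast` (see
#'   [contrast_index()]), `threshold`, `gmap`, and `mask` (the binarized,
#'   filtered, dilated gradient support).
#' @export
roi_from_frame <- function(frame, min_object_px = 20L, dilation_radius = 2L,
                           c_threshold = 0.3) {
  gmap <- gradient_magnitude(frame)
  cr <- contrast_index(gmap, c_threshold = c_threshold)
  if (cr$low_informativity)
    return(list(roi = NULL, contrast = cr, threshold = NA_real_,
                gmap = gmap, mask = NULL))
  thr <- knee_threshold(gmap)
  bw <- gmap$g >= thr
  bw <- filter_small_objects(bw, min_object_px)
  if (!any(bw))
    return(list(roi = NULL, contrast = cr, threshold = thr,
                gmap = gmap, mask = bw))
  bw <- dilate_disc(bw, dilation_radius)
  idx <- which(bw, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  roi <- roi_box(x0 = c0 - 1L, y0 = r0 - 1L,
                 width = c1 - c0 + 1L, height = r1 - r0 + 1L)
  list(roi = roi, contrast = cr, threshold = thr, gmap = gmap, mask = bw)
}

#' ROI bounding box
#'
#' Coordinates are 0-based, x = column, y = row, half-open: the box covers
#' columns \[x0, x0 + width) and rows \[y0, y0 + height).
#'
#' @param x0,y0 top-left corner (0-based px).
#' @param width,height box size in px (>= 1).
#' @param frame_index optional frame number.
#' @return a `roi_box`.
#' @export
roi_box <- function(x0, y0, width, height, frame_index = NA_integer_) {
  stopifnot(width >= 1, height >= 1, x0 >= 0, y0 >= 0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 frame_index = frame_index),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("roi_box: [%d, %d) x [%d, %d) (w=%d, h=%d)\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height, x$width, x$height))
  invisible(x)
}
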