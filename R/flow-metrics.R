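# Photometric normalization under the mask, velocity profiles along the
# skeleton midline, vessel width from the distance transform, volumetric
# speed and physical calibration.

#' Replace the background with a constant halo mean
#'
#' Pixels outside the vessel mask are set to the mean intensity of a halo
#' ring around the vessels (the mask dilated by `halo` px, minus the mask);
#' in-vessel intensities are untouched.
#'
#' @param frame numeric matrix.
#' @param mask logical matrix, TRUE = vessel.
#' @param halo ring width in px (default 5).
#' @return frame with constant background.
#' @export
normalize_background <- function(frame, mask, halo = 5L) {
  if (!any(mask)) {
    warning("empty mask: filling the whole frame with its global mean")
    frame[] <- mean(frame)
    return(frame)
  }
  ring <- dilate_disc(mask, halo) & !mask
  if (!any(ring)) return(frame) # mask covers everything
  const <- mean(frame[ring])
  frame[!mask] <- const
  frame
}

#' Iterative brightness equalization toward a target mean
#'
#' Repeatedly raises the image to the power ln(gamma)/ln(mean) until the
#' mean intensity is within `tolerance` of `gamma` (iterative n-th root /
#' n-th power equalization).
#'
#' @param frame numeric matrix with values in \[0, 1\].
#' @param gamma target mean intensity (default 0.5).
#' @param tolerance convergence band on the mean (default 1e-3).
#' @param max_iter iteration cap (default 50).
#' @return equalized frame in \[0, 1\].
#' @export
equalize_brightness <- function(frame, gamma = 0.5, tolerance = 1e-3,
                                max_iter = 50L) {
  stopifnot(gamma > 0, gamma < 1)
  m <- mean(frame)
  if (m <= 0 || m >= 1) {
    warning("frame mean outside (0,1): equalization is a no-op")
    return(frame)
  }
  for (i in seq_len(max_iter)) {
    if (abs(m - gamma) <= tolerance) break
    frame <- clamp01(frame)^(log(gamma) / log(m))
    m <- mean(frame)
  }
  frame
}

#' Relative velocity profile along a skeleton segment
#'
#' At each centerline pixel, the optical-flow magnitude is averaged over a
#' (2 half_window + 1) px square neighborhood; values are then reduced over
#' the supplied frame pairs (median by default, robust to pulsatility) and
#' ordered by arc length.
#'
#' @param flows a `flow_field` or list of them.
#' @param segment one element of `vessel_skeleton$segments`.
#' @param half_window neighborhood half-size in px (default 1).
#' @param reduce `"median"` (default) or `"mean"` across frame pairs.
#' @return list with `s` (arc-length positions, px) and `v_rel`
#'   (px/frame), one entry per centerline pixel.
#' @export
velocity_profile <- function(flows, segment, half_window = 1L,
                             reduce = c("median", "mean")) {
  reduce <- match.arg(reduce)
  if (inherits(flows, "flow_field")) flows <- list(flows)
  path <- segment$path
  d <- dim(flows[[1]]$magnitude)
  if (min(path) < 1 || max(path[, 1]) > d[1] || max(path[, 2]) > d[2])
    stop("segment outside flow-field bounds")
  n <- nrow(path)
  per_pair <- matrix(0, n, length(flows))
  for (k in seq_along(flows)) {
    mag <- flows[[k]]$magnitude
    for (i in seq_len(n)) {
      r <- path[i, 1]; c <- path[i, 2]
      rr <- max(1, r - half_window):min(d[1], r + half_window)
      cc <- max(1, c - half_window):min(d[2], c + half_window)
      per_pair[i, k] <- mean(mag[rr, cc])
    }
  }
  v <- if (reduce == "median") apply(per_pair, 1, stats::median)
       else rowMeans(per_pair)
  st <- abs(path[-1, , drop = FALSE] - path[-n, , drop = FALSE])
  ds <- c(0, ifelse(rowSums(st) == 2, sqrt(2), 1))
  list(s = cumsum(ds), v_rel = as.vector(v))
}

#' Summary speed of a velocity profile
#'
#' Median (or mean) of the profile after trimming `trim_px` of arc length at
#' each end, provided at least 10 px remain. Flow read adjacent to branch
#' nodes, vessel ends and mask boundaries is biased low (the displacement
#' solve there mixes in static structure), so segment-level speeds are
#' summarized over the segment interior.
#'
#' @param profile result of [velocity_profile()].
#' @param trim_px arc length (px) discarded at each end (default 12).
#' @param reduce `"median"` (default) or `"mean"`.
#' @return scalar speed (px/frame).
#' @export
profile_summary <- function(profile, trim_px = 12, reduce = c("median", "mean")) {
  reduce <- match.arg(reduce)
  s <- profile$s; v <- profile$v_rel
  keep <- s >= trim_px & s <= max(s) - trim_px
  if (sum(keep) < 10) keep <- rep(TRUE, length(v))
  if (reduce == "median") stats::median(v[keep]) else mean(v[keep])
}

#' Vessel width along a skeleton segment
#'
#' Per-centerline-pixel diameter from the Euclidean distance transform of
#' the mask: width = 2 d - 1, where d is the distance from the centerline
#' pixel to the nearest background pixel.
#'
#' @param mask logical matrix, TRUE = vessel.
#' @param segment one element of `vessel_skeleton$segments`.
#' @return numeric vector of widths (px), one per centerline pixel.
#' @export
vessel_width <- function(mask, segment) {
  path <- segment$path
  if (any(!mask[path])) stop("centerline pixel off the mask")
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  dm <- as.matrix(EBImage::imageData(dm))
  2 * dm[path] - 1
}

#' Cross-sectional area and volumetric speed
#'
#' Assumes a circular cross-section: S = pi (width/2)^2, Q = v S. Units
#' propagate (px^3/frame for relative inputs; m^3/s when `v` and `width`
#' are calibrated).
#'
#' @param v linear speed (>= 0).
#' @param width vessel diameter (> 0).
#' @return list with `S` and `Q`.
#' @export
volumetric_speed <- function(v, width) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(v < 0)) stop("v must be nonnegative")
  S <- pi * (width / 2)^2
  list(S = S, Q = v * S)
}

#' Convert relative speed to physical units
#'
#' v_phys = v_rel * um_per_px * fps * 1e-6 (m/s).
#'
#' @param v_rel relative speed in px/frame.
#' @param um_per_px spatial calibration (micrometers per pixel).
#' @param fps frame rate (1/s).
#' @return speed in m/s; if either calibration constant is missing, returns
#'   `v_rel` unchanged with attribute `calibrated = FALSE`.
#' @export
calibrate <- function(v_rel, um_per_px, fps) {
  if (missing(um_per_px) || missing(fps) ||
      is.null(um_per_px) || is.null(fps)) {
    attr(v_rel, "calibrated") <- FALSE
    return(v_rel)
  }
  stopifnot(um_per_px > 0, fps > 0)
  out <- v_rel * um_per_px * fps * 1e-6
  attr(out, "calibrated") <- TRUE
  out
}
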