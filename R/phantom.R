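# Synthetic vascular phantom: a branching tube tree carrying advected speckle
# texture at known per-segment speeds, rendered as an unstable grayscale video
# (translation jitter, occasional large jumps, illumination drift, defocus
# blur) with full ground truth for every downstream stage.

#' Generate a connected vessel tree
#'
#' Builds a tree of tube segments on a canvas. Each segment is a smooth
#' subpixel polyline with a slowly varying width; every segment after the
#' first attaches to an existing segment, creating one junction per branch.
#' The `"y"` layout places a parent tube that bifurcates into two children at
#' its distal end (the configuration used for flow-conservation checks).
#'
#' @param n_branches number of tube segments (>= 1).
#' @param seed integer seed; fixes the scene exactly.
#' @param canvas `c(height, width)` in pixels, at least 64 x 64.
#' @param width_range allowed tube widths in pixels (`c(min, max)`).
#' @param layout `"random"` (default), `"straight"` (one horizontal tube;
#'   requires `n_branches = 1`) or `"y"` (requires `n_branches = 3`).
#' @param background_level background intensity in \[0, 1\].
#' @param vessel_contrast intensity offset of vessels from background.
#' @param background_texture amplitude of the static band-limited background
#'   texture (scleral tissue is not optically flat; this also anchors
#'   registration the way static structure does in real scenes). Set 0 for a
#'   perfectly flat background.
#' @param polarity `"dark"` (vessels darker than background, default) or
#'   `"bright"`.
#' @return A `phantom_scene` object: list with `segments` (each holding
#'   `points` (n x 2 matrix, row/col, subpixel), `width` (per-point px),
#'   `parent`, `attach_frac`), `canvas`, `background_level`,
#'   `vessel_contrast`, `polarity`, `junctions` (k x 2 matrix, row/col).
#' @export
make_vessel_tree <- function(n_branches, seed, canvas = c(160L, 160L),
                             width_range = c(2, 12),
                             layout = c("random", "straight", "y"),
                             background_level = 0.6, vessel_contrast = 0.5,
                             background_texture = 0.12,
                             polarity = c("dark", "bright")) {
  layout <- match.arg(layout)
  polarity <- match.arg(polarity)
  if (n_branches < 1) stop("n_branches must be >= 1")
  if (min(canvas) < 64) stop("canvas too small: need at least 64x64")
  if (n_branches > floor(min(canvas) / 24))
    stop("canvas too small for the requested number of branches")
  if (layout == "y" && n_branches != 3)
    stop("layout 'y' requires n_branches = 3")
  if (layout == "straight" && n_branches > 3)
    stop("layout 'straight' supports at most 3 segments")
  set.seed(seed)
  margin <- 14
  h <- canvas[1]; w <- canvas[2]

  grow <- function(start, heading, len, w0, w1) {
    # heading random-walks; steer back toward the canvas center near borders
    step <- 2
    n <- max(2L, ceiling(len / step))
    pts <- matrix(0, n + 1L, 2L)
    pts[1L, ] <- start
    th <- heading
    ctr <- c(h, w) / 2
    for (i in seq_len(n)) {
      th <- th + stats::rnorm(1, 0, 0.09)
      p <- pts[i, ] + step * c(sin(th), cos(th))
      if (p[1] < margin || p[1] > h - margin ||
          p[2] < margin || p[2] > w - margin) {
        to_ctr <- atan2(ctr[2] - pts[i, 2], 0) # placeholder, replaced below
        to_ctr <- atan2(ctr[1] - pts[i, 1], ctr[2] - pts[i, 2])
        # our heading convention: (drow, dcol) = (sin th, cos th)
        th <- th + 0.5 * (atan2(sin(to_ctr - th), cos(to_ctr - th)))
        p <- pts[i, ] + step * c(sin(th), cos(th))
        p[1] <- min(max(p[1], margin), h - margin)
        p[2] <- min(max(p[2], margin), w - margin)
      }
      pts[i + 1L, ] <- p
    }
    widths <- seq(w0, w1, length.out = n + 1L)
    list(points = pts, width = widths)
  }

  segments <- vector("list", n_branches)
  if (layout == "straight") {
    # straight main tube; optional short oblique side branches whose
    # junctions give the registration static anchor points, as vessel
    # branch nodes do in real scenes
    wt <- min(max(9, width_range[1]), width_range[2])
    n1 <- 60L
    p1 <- cbind(rep(h / 2, n1), seq(margin + 1, w - margin - 1, length.out = n1))
    segments[[1]] <- list(points = p1, width = rep(wt, n1),
                          parent = NA_integer_, attach_frac = NA_real_)
    if (n_branches >= 2) {
      wb <- max(width_range[1], 0.45 * wt)
      for (k in 2:n_branches) {
        u <- if (k == 2) 0.15 else 0.85
        idx <- round(u * n1)
        at <- p1[idx, ]
        dir <- if (k == 2) c(-1, 0.35) else c(1, -0.35)
        dir <- dir / sqrt(sum(dir^2))
        len <- 0.22 * min(h, w)
        nb2 <- 20L
        p2 <- cbind(seq(at[1], at[1] + len * dir[1], length.out = nb2),
                    seq(at[2], at[2] + len * dir[2], length.out = nb2))
        p2[, 1] <- pmin(pmax(p2[, 1], margin), h - margin)
        p2[, 2] <- pmin(pmax(p2[, 2], margin), w - margin)
        segments[[k]] <- list(points = p2, width = rep(wb, nb2),
                              parent = 1L, attach_frac = u)
      }
    }
  } else if (layout == "y") {
    wp <- min(max(10, width_range[1]), width_range[2])
    wc <- max(width_range[1], wp * 0.74)
    jr <- c(h * 0.55, w * 0.5)
    n1 <- 40L
    p1 <- cbind(seq(h - margin, jr[1], length.out = n1),
                seq(w * 0.46, jr[2], length.out = n1))
    segments[[1]] <- list(points = p1, width = rep(wp, n1),
                          parent = NA_integer_, attach_frac = NA_real_)
    for (k in 1:2) {
      ang <- if (k == 1) -0.62 else 0.62
      len <- min(h, w) * 0.34
      n2 <- 40L
      dir <- c(-cos(ang), sin(ang)) # upward +/- lateral
      ep <- jr + len * dir
      ep[1] <- max(ep[1], margin); ep[2] <- min(max(ep[2], margin), w - margin)
      p2 <- cbind(seq(jr[1], ep[1], length.out = n2),
                  seq(jr[2], ep[2], length.out = n2))
      segments[[k + 1L]] <- list(points = p2, width = rep(wc, n2),
                                 parent = 1L, attach_frac = 1.0)
    }
  } else {
    w0 <- stats::runif(1, 0.6, 0.85) * width_range[2]
    start <- c(stats::runif(1, 0.35, 0.65) * h, margin + 2)
    root <- grow(start, stats::runif(1, -0.35, 0.35),
                 len = 0.62 * min(h, w), w0 = w0, w1 = max(width_range[1], 0.8 * w0))
    segments[[1]] <- c(root, list(parent = NA_integer_, attach_frac = NA_real_))
    if (n_branches > 1) {
      for (k in 2:n_branches) {
        parent <- sample.int(k - 1L, 1L)
        pp <- segments[[parent]]
        u <- stats::runif(1, 0.35, 0.7)
        idx <- max(2L, round(u * nrow(pp$points)))
        at <- pp$points[idx, ]
        tang <- pp$points[min(idx + 1L, nrow(pp$points)), ] - pp$points[idx - 1L, ]
        th0 <- atan2(tang[1], tang[2]) + sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1.0)
        wk <- max(width_range[1], 0.7 * pp$width[idx])
        child <- grow(at, th0, len = stats::runif(1, 0.3, 0.45) * min(h, w),
                      w0 = wk, w1 = max(width_range[1], 0.85 * wk))
        segments[[k]] <- c(child, list(parent = parent, attach_frac = u))
      }
    }
  }
  junctions <- NULL
  for (s in segments)
    if (!is.na(s$parent)) junctions <- rbind(junctions, s$points[1L, ])
  structure(list(segments = segments, canvas = as.integer(canvas),
                 background_level = background_level,
                 vessel_contrast = vessel_contrast,
                 background_texture = background_texture, polarity = polarity,
                 junctions = junctions, seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene: %d segment(s), %d junction(s), canvas %dx%d, %s vessels\n",
              length(x$segments),
              if (is.null(x$junctions)) 0L else nrow(x$junctions),
              x$canvas[1], x$canvas[2], x$polarity))
  invisible(x)
}

#' Acquisition-defect specification for phantom rendering
#'
#' Defaults emulate moderately unstable hand-held-style acquisition:
#' per-frame integer translation jitter of SD 3 px, mild defocus variation,
#' and a 5% illumination drift. `jump_frames` lists frames (1-based) at which
#' the view jumps to a new position by more than the fragmenter's drift limit.
#'
#' @param jitter_sd SD of the per-frame translation jitter in px.
#' @param jump_frames integer vector of frames receiving a large jump.
#' @param blur_sd_range range of the per-frame Gaussian blur SD in px.
#' @param illumination_drift_amplitude fraction of the dynamic range.
#' @param seed integer; fixes the whole motion realization.
#' @param subpixel logical; if `FALSE` (default) offsets are integer px.
#' @return A `phantom_motion` list.
#' @export
phantom_motion <- function(jitter_sd = 3, jump_frames = integer(0),
                           blur_sd_range = c(0, 0.8),
                           illumination_drift_amplitude = 0.05,
                           seed = 1L, subpixel = FALSE) {
  stopifnot(jitter_sd >= 0, length(blur_sd_range) == 2,
            illumination_drift_amplitude >= 0)
  structure(list(jitter_sd = jitter_sd, jump_frames = as.integer(jump_frames),
                 blur_sd_range = blur_sd_range,
                 illumination_drift_amplitude = illumination_drift_amplitude,
                 seed = as.integer(seed), subpixel = isTRUE(subpixel)),
            class = "phantom_motion")
}

#' Assign per-segment advection speeds
#'
#' With `conserve_flow = TRUE`, child speeds are chosen so that the parent's
#' volumetric flow Q = v * S (S = pi (w/2)^2 from the mean tube width,
#' circular cross-section) is split among its children: all children of one
#' parent share a common velocity v_c = v_p * S_p / sum(S_children).
#'
#' @param scene a `phantom_scene`.
#' @param v_root root-segment speed in px/frame.
#' @param conserve_flow logical.
#' @return numeric vector of per-segment speeds (px/frame).
#' @export
assign_speeds <- function(scene, v_root, conserve_flow = FALSE) {
  n <- length(scene$segments)
  v <- rep(v_root, n)
  if (!conserve_flow || n == 1L) return(v)
  area <- vapply(scene$segments, function(s) pi * (mean(s$width) / 2)^2, 0)
  parent <- vapply(scene$segments, function(s)
    if (is.na(s$parent)) 0L else as.integer(s$parent), 0L)
  for (p in seq_len(n)) {
    kids <- which(parent == p)
    if (length(kids)) v[kids] <- v[p] * area[p] / sum(area[kids])
  }
  v
}

# Dense resampling of one segment at a fixed arc-length step.
# Returns points, tangents, normals, widths and arc positions.
resample_segment <- function(seg, ds = 0.5) {
  pts <- seg$points
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  sq <- seq(0, L, by = ds)
  r <- stats::approx(s, pts[, 1], xout = sq)$y
  c_ <- stats::approx(s, pts[, 2], xout = sq)$y
  w <- stats::approx(s, seg$width, xout = sq)$y
  n <- length(sq)
  tr <- c(r[2] - r[1], diff(r, lag = 2) / 2, r[n] - r[n - 1])
  tc <- c(c_[2] - c_[1], diff(c_, lag = 2) / 2, c_[n] - c_[n - 1])
  nrm <- sqrt(tr^2 + tc^2); nrm[nrm == 0] <- 1
  tr <- tr / nrm; tc <- tc / nrm
  list(r = r, c = c_, w = w, s = sq, tr = tr, tc = tc,
       nr = -tc, nc = tr, length = L)
}

# Map every canvas pixel inside a tube to (segment, arc position s, lateral
# offset l, local width). Overlaps resolved toward the smallest |l| / (w/2).
stamp_tubes <- function(scene, ds = 0.5) {
  h <- scene$canvas[1]; w <- scene$canvas[2]
  best <- matrix(Inf, h, w)
  seg_id <- matrix(0L, h, w)
  s_map <- matrix(0, h, w); l_map <- matrix(0, h, w); w_map <- matrix(0, h, w)
  dense <- lapply(scene$segments, resample_segment, ds = ds)
  disc_cache <- list()
  for (k in seq_along(dense)) {
    dn <- dense[[k]]
    for (j in seq_along(dn$r)) {
      rad <- dn$w[j] / 2
      ri <- as.integer(ceiling(rad))
      key <- as.character(ri)
      if (is.null(disc_cache[[key]])) {
        o <- expand.grid(dr = -ri:ri, dc = -ri:ri)
        disc_cache[[key]] <- as.matrix(o[o$dr^2 + o$dc^2 <= (ri + 0.5)^2, ])
      }
      off <- disc_cache[[key]]
      pr <- round(dn$r[j]) + off[, 1]
      pc <- round(dn$c[j]) + off[, 2]
      ok <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
      if (!any(ok)) next
      pr <- pr[ok]; pc <- pc[ok]
      dr <- pr - dn$r[j]; dc <- pc - dn$c[j]
      l <- dr * dn$nr[j] + dc * dn$nc[j]
      along <- dr * dn$tr[j] + dc * dn$tc[j]
      m <- abs(l) / rad
      inside <- m <= 1 & abs(along) <= ds
      if (!any(inside)) next
      idx <- cbind(pr[inside], pc[inside])
      mi <- m[inside]
      upd <- mi < best[idx]
      if (!any(upd)) next
      idx <- idx[upd, , drop = FALSE]
      best[idx] <- mi[upd]
      seg_id[idx] <- k
      s_map[idx] <- dn$s[j] + along[inside][upd]
      l_map[idx] <- l[inside][upd]
      w_map[idx] <- dn$w[j]
    }
  }
  list(seg_id = seg_id, s = s_map, l = l_map, w = w_map, dense = dense)
}

#' Render a phantom video with ground truth
#'
#' Fills the tube tree with band-limited multiplicative speckle that is
#' advected along each segment's centerline at the prescribed speed
#' (nearest-neighbor resampling in arc length), then applies per-frame global
#' translation, illumination drift and defocus blur per the motion spec.
#'
#' @param scene a `phantom_scene`.
#' @param motion a `phantom_motion`.
#' @param speeds per-segment advection speed in px/frame (recycled).
#' @param n_frames number of frames (>= 2).
#' @return list with `video` (a `vessel_video`: list of frames in \[0,1\])
#'   and `truth`: `offsets` (n_frames x 2, columns dx/dy in px), `mask`
#'   (logical, unshifted scene), `centerline` (per-segment subpixel polylines
#'   with arc length), `speeds`, `junctions`.
#' @export
render_video <- function(scene, motion, speeds, n_frames) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(motion, "phantom_motion"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  speeds <- rep_len(speeds, length(scene$segments))
  if (any(speeds < 0)) stop("speeds must be >= 0")
  st <- stamp_tubes(scene)
  seg_len <- vapply(st$dense, function(d) d$length, 0)
  if (any(speeds > seg_len))
    stop("aliasing: speed exceeds tube length per frame")

  set.seed(motion$seed)
  h <- scene$canvas[1]; w <- scene$canvas[2]

  # per-frame offsets: independent jitter plus persistent large jumps
  jit <- matrix(stats::rnorm(2 * n_frames, 0, motion$jitter_sd), n_frames, 2)
  jit[1, ] <- 0
  if (!motion$subpixel) jit <- round(jit)
  jump <- matrix(0, n_frames, 2)
  for (jf in motion$jump_frames) {
    if (jf < 2 || jf > n_frames) next
    ang <- stats::runif(1, 0, 2 * pi)
    mag <- 120 + 6 * motion$jitter_sd + stats::runif(1, 0, 20)
    dj <- mag * c(cos(ang), sin(ang))
    if (!motion$subpixel) dj <- round(dj)
    jump[jf:n_frames, 1] <- jump[jf:n_frames, 1] + dj[1]
    jump[jf:n_frames, 2] <- jump[jf:n_frames, 2] + dj[2]
  }
  offsets <- jit + jump # columns: dx, dy

  # per-segment speckle grids over (s, l), band-limited, in [0, 1]
  grids <- vector("list", length(st$dense))
  for (k in seq_along(st$dense)) {
    dn <- st$dense[[k]]
    smin <- floor(-speeds[k] * n_frames) - 2L
    smax <- ceiling(dn$length) + 2L
    lmax <- ceiling(max(dn$w) / 2) + 1L
    g <- matrix(stats::runif((smax - smin + 1L) * (2L * lmax + 1L)),
                smax - smin + 1L, 2L * lmax + 1L)
    g <- gauss_blur(g, 1.1)
    g <- (g - min(g)) / max(1e-12, max(g) - min(g))
    grids[[k]] <- list(g = g, smin = smin, lmax = lmax)
  }

  blur_sd <- stats::runif(n_frames, motion$blur_sd_range[1], motion$blur_sd_range[2])
  bg <- scene$background_level
  # static scene background: tissue texture that moves only with the camera
  bg_amp <- if (is.null(scene$background_texture)) 0 else scene$background_texture
  bg_img <- matrix(bg, h, w)
  if (bg_amp > 0) {
    bn <- gauss_blur(matrix(stats::runif(h * w), h, w), 2)
    bn <- (bn - min(bn)) / max(1e-12, max(bn) - min(bn))
    bg_img <- bg_img + bg_amp * (bn - 0.5)
  }
  sgn <- if (scene$polarity == "dark") -1 else 1
  tube <- st$seg_id > 0
  prof <- matrix(0, h, w)
  # cylindrical absorption profile with a crisp wall (vessels have sharp
  # boundaries; the floor keeps an edge step the gradient stages can see)
  prof[tube] <- 0.45 + 0.55 * sqrt(pmax(0, 1 - (st$l[tube] / (st$w[tube] / 2))^2))
  # anti-aliased wall: ~1 px coverage ramp at the boundary, as optics would
  # give; a hard pixel staircase on oblique walls is static high-frequency
  # structure no real camera produces
  alpha <- matrix(0, h, w)
  alpha[tube] <- pmin(1, pmax(0, (st$w[tube] / 2 - abs(st$l[tube])) / 1.2))
  amp <- motion$illumination_drift_amplitude
  ramp <- matrix(rep((seq_len(w) / w) - 0.5, each = h), h, w)

  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    speck <- matrix(0, h, w)
    for (k in seq_along(grids)) {
      sel <- st$seg_id == k
      if (!any(sel)) next
      gi <- grids[[k]]
      # linear interpolation along arc length: rounding s instead leaves a
      # static 1-px staircase carrier on oblique tubes that any optical-flow
      # method locks onto, masking the advection
      sf <- st$s[sel] - speeds[k] * (t - 1) - gi$smin + 1
      sf <- pmin(pmax(sf, 1), nrow(gi$g) - 1e-9)
      i0 <- pmin(floor(sf), nrow(gi$g) - 1L)
      fr_ <- sf - i0
      lf <- st$l[sel] + gi$lmax + 1
      lf <- pmin(pmax(lf, 1), ncol(gi$g) - 1e-9)
      j0 <- pmin(floor(lf), ncol(gi$g) - 1L)
      fl_ <- lf - j0
      speck[sel] <-
        (gi$g[cbind(i0, j0)] * (1 - fr_) + gi$g[cbind(i0 + 1L, j0)] * fr_) * (1 - fl_) +
        (gi$g[cbind(i0, j0 + 1L)] * (1 - fr_) + gi$g[cbind(i0 + 1L, j0 + 1L)] * fr_) * fl_
    }
    img <- bg_img
    # absorption profile is static; the advected speckle modulates it the
    # way red-cell flux modulates capillary darkness (a fraction of the
    # vessel contrast, not the dominant structure in the scene)
    tube_val <- bg + sgn * scene$vessel_contrast * prof[tube] *
      (0.85 + 0.3 * speck[tube])
    img[tube] <- (1 - alpha[tube]) * bg_img[tube] + alpha[tube] * tube_val
    img <- shift_int(img, offsets[t, 1], offsets[t, 2], fill = bg)
    illum <- 1 + amp * sin(2 * pi * (t - 1) / max(8, n_frames / 2)) *
      (0.6 + 0.8 * ramp)
    img <- img * illum
    if (blur_sd[t] > 0.05) img <- gauss_blur(img, blur_sd[t])
    frames[[t]] <- clamp01(img)
  }

  centerline <- lapply(seq_along(st$dense), function(k) {
    dn <- st$dense[[k]]
    data.frame(segment_id = k, order = seq_along(dn$s),
               row = dn$r, col = dn$c, s = dn$s, width = dn$w)
  })
  truth <- list(offsets = offsets, mask = tube, centerline = centerline,
                speeds = speeds, junctions = scene$junctions)
  list(video = new_vessel_video(frames), truth = truth)
}
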