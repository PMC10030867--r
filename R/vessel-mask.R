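# Vessel masking: multi-scale Hessian (Frangi-type) tubularness enhancement
# as the default deterministic segmenter, an optional small patch classifier
# trained on phantom data, and the label/probability evaluation statistics.
# Probability polarity follows the convention 0 = vessel, 1 = non-vessel.

# Hessian of a Gaussian-smoothed image at scale sigma, gamma=2 normalized
gaussian_hessian <- function(img, sigma) {
  radius <- ceiling(3 * sigma)
  t <- seq(-radius, radius)
  g0 <- exp(-t^2 / (2 * sigma^2)); g0 <- g0 / sum(g0)
  g1 <- -t / sigma^2 * g0
  g2 <- (t^2 - sigma^2) / sigma^4 * g0
  s2 <- sigma^2
  list(Hxx = s2 * xcorr_sep(img, kx = g2, ky = g0),
       Hyy = s2 * xcorr_sep(img, kx = g0, ky = g2),
       Hxy = s2 * xcorr_sep(img, kx = g1, ky = g1))
}

# single-scale Frangi-type vesselness (2-D)
vesselness_at_scale <- function(img, sigma, beta = 0.5, dark = TRUE) {
  H <- gaussian_hessian(img, sigma)
  m <- (H$Hxx + H$Hyy) / 2
  sq <- sqrt(((H$Hxx - H$Hyy) / 2)^2 + H$Hxy^2)
  ea <- m + sq; eb <- m - sq
  swap <- abs(ea) < abs(eb) # lambda2 = larger magnitude
  l2 <- ifelse(swap, eb, ea)
  l1 <- ifelse(swap, ea, eb)
  if (!dark) { l1 <- -l1; l2 <- -l2 }
  S2 <- l1^2 + l2^2
  c2 <- max(S2) / 4 # c = half the max Frobenius norm at this scale
  Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  V <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * pmax(c2, 1e-12))))
  V[l2 <= 0] <- 0
  V
}

#' Vessel probability map
#'
#' `method = "classical"` (default): multi-scale Hessian-eigenvalue
#' tubularness enhancement over vessel widths of roughly 2-12 px; the
#' response is calibrated so an automatically chosen operating point (Otsu
#' on the response histogram) maps to probability 0.5, and the result uses
#' the polarity 0 = vessel, 1 = non-vessel. `method = "patch_classifier"`
#' applies a model trained with [train_patch_classifier()] on phantom data.
#'
#' @param frame numeric matrix in \[0, 1\] (stabilized grayscale frame).
#' @param method `"classical"` or `"patch_classifier"`.
#' @param scales Gaussian scales (px) of the Hessian; defaults cover tube
#'   widths of about 2-12 px.
#' @param beta Frangi blobness sensitivity.
#' @param dark TRUE (default) when vessels are darker than the background.
#' @param model classifier from [train_patch_classifier()] (patch path only).
#' @return matrix `P` in \[0, 1\] (0 = vessel), class `vessel_prob`.
#' @export
segment_vessels <- function(frame, method = c("classical", "patch_classifier"),
                            scales = c(1, 1.5, 2, 3, 4, 5, 6), beta = 0.5,
                            dark = TRUE, model = NULL) {
  method <- match.arg(method)
  check_frame(frame, min_dim = 8L)
  if (min(dim(frame)) < 2 * ceiling(3 * max(scales)) + 1)
    stop("frame smaller than the largest filter scale")
  if (method == "classical") {
    V <- matrix(0, nrow(frame), ncol(frame))
    for (s in scales) V <- pmax(V, vesselness_at_scale(frame, s, beta, dark))
    vmax <- max(V)
    if (vmax <= 0) return(structure(matrix(1, nrow(frame), ncol(frame)),
                                    class = "vessel_prob"))
    v01 <- V / vmax
    op <- EBImage::otsu(EBImage::Image(v01), range = c(0, 1))
    op <- max(op, 1e-6)
    P <- 1 - clamp01(0.5 * v01 / op)
  } else {
    if (is.null(model)) stop("patch_classifier requires a trained model")
    P <- predict_patch_classifier(model, frame)
  }
  structure(P, class = "vessel_prob")
}

#' Binarize a vessel probability map
#'
#' Vessel = (P < threshold) under the 0-=-vessel polarity; connected
#' components smaller than `min_object_px` are removed.
#'
#' @param P `vessel_prob` matrix.
#' @param threshold probability cutoff (default 0.5).
#' @param min_object_px minimum component size kept (default 20).
#' @return logical matrix, TRUE = vessel.
#' @export
binarize_mask <- function(P, threshold = 0.5, min_object_px = 20L) {
  bw <- unclass(P) < threshold
  filter_small_objects(bw, min_object_px)
}

#' Segmentation evaluation: accuracy and RMS label/probability deviation
#'
#' Accuracy is the fraction of pixels where the predicted and true labels
#' agree. The deviation statistic compares the binarized result labels x_i
#' (paper polarity: 0 = vessel, 1 = non-vessel) with the probability map:
#' sigma = sqrt(mean((x_i - P_i)^2)).
#'
#' @param pred,truth logical masks (TRUE = vessel) or numeric 0/1 label
#'   matrices already in the 0-=-vessel polarity.
#' @param P probability map matching `pred` (optional; sigma is `NA`
#'   without it).
#' @return list with `accuracy`, `sigma`, `n`.
#' @export
evaluate_segmentation <- function(pred, truth, P = NULL) {
  to_label <- function(m) if (is.logical(m)) 1 - m else m # 0 = vessel
  xp <- to_label(pred); xt <- to_label(truth)
  if (!all(dim(xp) == dim(xt))) stop("shape mismatch between pred and truth")
  acc <- mean(xp == xt)
  sig <- NA_real_
  if (!is.null(P)) {
    if (!all(dim(P) == dim(xp))) stop("shape mismatch between pred and P")
    sig <- sqrt(mean((xp - unclass(P))^2))
  }
  list(accuracy = acc, sigma = sig, n = length(xp))
}

#' Dice overlap of two masks
#' @param a,b logical masks.
#' @return 2|A n B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# ---- optional patch classifier (trained on phantom data only) --------------

extract_patches <- function(frame, centers, half) {
  n <- nrow(centers)
  out <- matrix(0, n, (2 * half + 1)^2)
  for (i in seq_len(n)) {
    r <- centers[i, 1]; c <- centers[i, 2]
    out[i, ] <- as.vector(frame[(r - half):(r + half), (c - half):(c + half)])
  }
  out
}

#' Train the sliding-window patch classifier on phantom data
#'
#' Two-class framing: windows with a vessel at the center (class 0) versus
#' windows without (class 1). Training data come exclusively from seeded
#' phantom scenes; patches are augmented with flips and quarter turns. The
#' classifier is a single-hidden-layer network (`nnet`) over raw patch
#' pixels.
#'
#' @param n_scenes number of phantom scenes to synthesize.
#' @param seed integer seed fixing scenes, sampling and training.
#' @param patch_size odd window size in px (default 17; scale-proportional
#'   stand-in for large-tile windows on full-HD clinical frames).
#' @param n_per_scene training windows sampled per scene and class.
#' @param hidden hidden units.
#' @return model list used by [segment_vessels()] `patch_classifier` path.
#' @export
train_patch_classifier <- function(n_scenes = 3L, seed = 1L, patch_size = 17L,
                                   n_per_scene = 150L, hidden = 6L) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("the patch classifier requires the 'nnet' package")
  half <- (patch_size - 1L) %/% 2L
  X <- NULL; y <- NULL
  for (sc in seq_len(n_scenes)) {
    scene <- make_vessel_tree(2L + (sc %% 3L), seed = seed + sc, canvas = c(128L, 128L))
    rv <- render_video(scene, phantom_motion(jitter_sd = 0, seed = seed + sc),
                       speeds = 0, n_frames = 2L)
    f <- rv$video$frames[[1]]
    m <- rv$truth$mask
    set.seed(seed + 1000L + sc)
    ok <- function(rc) rc[, 1] > half & rc[, 1] <= nrow(f) - half &
      rc[, 2] > half & rc[, 2] <= ncol(f) - half
    pos <- which(m, arr.ind = TRUE); pos <- pos[ok(pos), , drop = FALSE]
    neg <- which(!m, arr.ind = TRUE); neg <- neg[ok(neg), , drop = FALSE]
    pos <- pos[sample.int(nrow(pos), min(n_per_scene, nrow(pos))), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg), min(n_per_scene, nrow(neg))), , drop = FALSE]
    Xp <- extract_patches(f, pos, half)
    Xn <- extract_patches(f, neg, half)
    aug <- function(M) {
      k <- patch_size
      a <- M
      for (i in seq_len(nrow(M))) {
        p <- matrix(M[i, ], k, k)
        a <- rbind(a, as.vector(p[k:1, ]), as.vector(p[, k:1]), as.vector(t(p)))
      }
      a
    }
    Xp <- aug(Xp); Xn <- aug(Xn)
    X <- rbind(X, Xp, Xn)
    y <- c(y, rep(0, nrow(Xp)), rep(1, nrow(Xn))) # paper polarity labels
  }
  set.seed(seed)
  fit <- nnet::nnet(x = X, y = y, size = hidden, maxit = 200, decay = 1e-4,
                    trace = FALSE, MaxNWts = 10000)
  list(fit = fit, patch_size = patch_size, half = half)
}

#' Predict a probability map with the patch classifier
#' @param model from [train_patch_classifier()].
#' @param frame numeric matrix.
#' @param stride sampling stride of window centers (bilinear upsampled).
#' @return matrix in \[0,1\], 0 = vessel.
#' @export
predict_patch_classifier <- function(model, frame, stride = 2L) {
  half <- model$half
  nr <- nrow(frame); nc <- ncol(frame)
  rs <- seq(half + 1L, nr - half, by = stride)
  cs <- seq(half + 1L, nc - half, by = stride)
  grid <- as.matrix(expand.grid(r = rs, c = cs))
  Xg <- extract_patches(frame, grid, half)
  p <- as.vector(stats::predict(model$fit, Xg))
  Pg <- matrix(p, length(rs), length(cs))
  # upsample the stride grid back to full resolution
  out <- matrix(1, nr, nc)
  ri <- stats::approx(rs, seq_along(rs), xout = seq_len(nr), rule = 2)$y
  ci <- stats::approx(cs, seq_along(cs), xout = seq_len(nc), rule = 2)$y
  out[] <- bilinear_sample(Pg, rep(ri, times = nc), rep(ci, each = nr))
  clamp01(out)
}
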