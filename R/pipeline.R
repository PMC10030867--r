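# End-to-end cascade: ROI -> fragments -> stabilization -> vessel mask ->
# optical flow -> per-segment flow and topology metrics, with a
# deterministic JSON report.

#' Pipeline configuration
#'
#' Defaults carry the method's constants end-to-end: informativity cutoff
#' C < 0.3, centroid drift limit 100 px, equalization target gamma = 0.5.
#'
#' @param input path to a video (frame directory or multi-page TIFF); may be
#'   `NULL` when a `vessel_video` is passed to [run_pipeline()] directly.
#' @param out output directory for artifacts; `NULL` disables writing.
#' @param drift_limit centroid drift limit in px.
#' @param c_threshold informativity cutoff on the gradient contrast.
#' @param gamma target mean intensity of brightness equalization.
#' @param stabilizer_method `"keypoint"` or `"correlation"`.
#' @param segmenter `"classical"` or `"patch_classifier"`.
#' @param farneback list of [dense_flow()] parameters.
#' @param um_per_px,fps optional physical calibration.
#' @param min_fragment_len fragments shorter than this are dropped.
#' @param max_flow_pairs cap on consecutive frame pairs used for flow.
#' @param min_object_px,dilation_radius ROI debris filtering settings.
#' @param fill_margin px by which the vessel mask is dilated before the
#'   background constant fill, so the fill boundary clears the true vessel
#'   wall even when the mask runs a pixel thin (an artificial step cut into
#'   moving texture biases the flow solve toward zero).
#' @param dark TRUE when vessels are darker than background.
#' @param seed integer seed recorded in provenance and used by any stochastic
#'   stage (the default cascade is deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out = NULL, drift_limit = 100,
                            c_threshold = 0.3, gamma = 0.5,
                            stabilizer_method = c("keypoint", "correlation"),
                            segmenter = c("classical", "patch_classifier"),
                            farneback = list(), um_per_px = NULL, fps = NULL,
                            min_fragment_len = 2L, max_flow_pairs = 10L,
                            min_object_px = 20L, dilation_radius = 2L,
                            fill_margin = 2L, dark = TRUE, seed = 1L) {
  structure(list(input = input, out = out, drift_limit = drift_limit,
                 c_threshold = c_threshold, gamma = gamma,
                 stabilizer_method = match.arg(stabilizer_method),
                 segmenter = match.arg(segmenter), farneback = farneback,
                 um_per_px = um_per_px, fps = fps,
                 min_fragment_len = as.integer(min_fragment_len),
                 max_flow_pairs = as.integer(max_flow_pairs),
                 min_object_px = as.integer(min_object_px),
                 dilation_radius = as.integer(dilation_radius),
                 fill_margin = as.integer(fill_margin),
                 dark = isTRUE(dark), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Hessian scales that fit inside a frame
fit_scales <- function(d, scales = c(1, 1.5, 2, 3, 4, 5, 6)) {
  ok <- scales[2 * ceiling(3 * scales) + 1 <= min(d)]
  if (!length(ok)) ok <- scales[1]
  ok
}

#' Run the full flow-analysis cascade
#'
#' Stages per fragment: informative-region detection and centroid tracking,
#' fragment splitting at the drift limit, stabilization, vessel masking,
#' background constant fill and brightness equalization, dense optical flow
#' over consecutive pairs, skeletonization, and per-segment velocity, width,
#' volumetric speed and topology metrics. Frames failing the contrast test
#' carry no ROI and never enter a fragment.
#'
#' @param cfg a [pipeline_config()].
#' @param video optional `vessel_video` (otherwise read from `cfg$input`).
#' @return a `pipeline_report`: list with `status`, `fragments` (per-fragment
#'   results) and `provenance`; written to `cfg$out/report.json` when an
#'   output directory is configured.
#' @export
run_pipeline <- function(cfg, video = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  if (is.null(video)) {
    if (is.null(cfg$input)) stop("either cfg$input or video must be given")
    video <- read_video(cfg$input, um_per_px = cfg$um_per_px, fps = cfg$fps)
  }
  n <- length(video$frames)
  rois <- vector("list", n)
  centers <- vector("list", n)
  for (t in seq_len(n)) {
    rr <- roi_from_frame(video$frames[[t]], min_object_px = cfg$min_object_px,
                         dilation_radius = cfg$dilation_radius,
                         c_threshold = cfg$c_threshold)
    rois[[t]] <- rr$roi
    if (!is.null(rr$roi))
      centers[[t]] <- weighted_centroid(rr$gmap, rr$roi, rr$threshold)
  }
  frags <- split_fragments(centers, fragmenter_config(cfg$drift_limit,
                                                      cfg$min_fragment_len))
  if (!length(frags)) {
    rep_ <- structure(list(status = "no informative region",
                           fragments = list(),
                           provenance = pipeline_provenance(cfg)),
                      class = "pipeline_report")
    write_report(rep_, cfg)
    return(rep_)
  }
  model <- if (cfg$segmenter == "patch_classifier")
    train_patch_classifier(seed = cfg$seed) else NULL
  out_frags <- vector("list", length(frags))
  for (fi in seq_along(frags)) {
    fr <- common_box(frags[[fi]], rois)
    cropped <- crop_fragment(video, fr)
    st <- stabilize(cropped, method = cfg$stabilizer_method)
    sv <- st$video
    ref <- sv$frames[[1]]
    P <- segment_vessels(ref, method = cfg$segmenter,
                         scales = fit_scales(dim(ref)), dark = cfg$dark,
                         model = model)
    mask <- binarize_mask(P, min_object_px = cfg$min_object_px)
    res <- list(start = fr$start, end = fr$end,
                common_box = fr$common_box,
                offsets = unname(st$offsets),
                stabilizer_method = unique(st$method[-1]),
                mask_px = sum(mask))
    if (!any(mask)) {
      res$segments <- list(); res$status <- "no vessel detected"
      out_frags[[fi]] <- res
      next
    }
    fill_mask <- dilate_disc(mask, cfg$fill_margin)
    norm <- lapply(sv$frames, function(f)
      equalize_brightness(normalize_background(f, fill_mask), gamma = cfg$gamma))
    npairs <- min(length(norm) - 1L, cfg$max_flow_pairs)
    fb <- cfg$farneback
    flows <- lapply(seq_len(npairs), function(t)
      do.call(dense_flow, c(list(frame1 = norm[[t]], frame2 = norm[[t + 1L]]), fb)))
    skel <- skeletonize(mask)
    topo <- topology_metrics(skel, mask)
    segs <- lapply(skel$segments, function(sg) {
      prof <- velocity_profile(flows, sg)
      wid <- vessel_width(mask, sg)
      v <- profile_summary(prof)
      w <- mean(wid)
      vs <- volumetric_speed(max(v, 0), max(w, 1e-9))
      chord <- sqrt(sum((sg$path[nrow(sg$path), ] - sg$path[1, ])^2))
      list(id = sg$id, length = sg$length, width = w,
           v_rel = v, S = vs$S, Q = vs$Q,
           v_phys = if (!is.null(cfg$um_per_px) && !is.null(cfg$fps))
             as.numeric(calibrate(v, cfg$um_per_px, cfg$fps)) else NULL,
           tortuosity = if (chord > 0) sg$length / chord else NA)
    })
    res$segments <- segs
    res$topology <- topo[c("total_length", "branchiness", "compactness",
                           "n_branch_nodes", "n_endpoints", "n_segments")]
    res$status <- "ok"
    out_frags[[fi]] <- res
    if (!is.null(cfg$out)) {
      fdir <- file.path(cfg$out, sprintf("fragment_%02d", fi))
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      write_mask_png(mask, file.path(fdir, "mask.png"))
      utils::write.csv(
        data.frame(frame = seq_len(nrow(st$offsets)),
                   dx = st$offsets[, 1], dy = st$offsets[, 2],
                   method = st$method),
        file.path(fdir, "offsets.csv"), row.names = FALSE)
      prof_rows <- do.call(rbind, lapply(skel$segments, function(sg) {
        pr <- velocity_profile(flows, sg)
        data.frame(segment_id = sg$id, s_px = pr$s, v_rel = pr$v_rel)
      }))
      if (!is.null(prof_rows))
        utils::write.csv(prof_rows, file.path(fdir, "profiles.csv"),
                         row.names = FALSE)
      if (length(flows))
        png::writePNG(flow_to_hsv(flows[[1]]), file.path(fdir, "flow_hsv.png"))
    }
  }
  rep_ <- structure(list(status = "ok", fragments = out_frags,
                         provenance = pipeline_provenance(cfg)),
                    class = "pipeline_report")
  write_report(rep_, cfg)
  rep_
}

pipeline_provenance <- function(cfg) {
  c_ <- unclass(cfg)
  c_$out <- NULL
  list(config = c_,
       package = "scleraflow",
       version = as.character(utils::packageVersion("scleraflow")),
       seed = cfg$seed)
}

write_report <- function(report, cfg) {
  if (is.null(cfg$out)) return(invisible(NULL))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = 8, null = "null",
                       pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: status '%s', %d fragment(s)\n",
              x$status, length(x$fragments)))
  for (f in x$fragments) {
    cat(sprintf("  frames %d-%d: %d segment(s), %s\n",
                f$start, f$end, length(f$segments), f$status))
  }
  invisible(x)
}

#' Generate a phantom video with ground truth on disk
#'
#' Convenience wrapper for shell use: renders a seeded phantom (3 segments,
#' jitter SD 3, advection 2 px/frame) and writes the frames as PNG plus the
#' ground truth as JSON/PNG/CSV.
#'
#' @param out output directory.
#' @param seed integer seed.
#' @param n_frames number of frames (default 30).
#' @param n_branches tree size (default 3).
#' @param speed root advection speed in px/frame (default 2).
#' @return the ground-truth list, invisibly.
#' @export
simulate_phantom <- function(out, seed = 1L, n_frames = 30L, n_branches = 3L,
                             speed = 2) {
  scene <- make_vessel_tree(n_branches, seed = seed)
  motion <- phantom_motion(seed = seed + 1L)
  rv <- render_video(scene, motion, speeds = assign_speeds(scene, speed),
                     n_frames = n_frames)
  write_video(rv$video, file.path(out, "frames"))
  write_ground_truth(rv$truth, file.path(out, "truth"))
  invisible(rv$truth)
}
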