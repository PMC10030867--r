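# Video container and standard-format I/O (PNG/TIFF frame sequences,
# CSV/JSON artifacts).

#' Construct a vessel_video from a list of frames
#'
#' @param frames list of numeric matrices in \[0, 1\], all the same shape.
#' @param um_per_px optional spatial calibration (micrometers per pixel).
#' @param fps optional temporal calibration (frames per second).
#' @return A `vessel_video` object.
#' @export
new_vessel_video <- function(frames, um_per_px = NULL, fps = NULL) {
  if (!length(frames)) stop("a vessel_video needs at least one frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share one shape")
  structure(list(frames = frames, um_per_px = um_per_px, fps = fps),
            class = "vessel_video")
}

#' @export
print.vessel_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cal <- if (is.null(x$um_per_px)) "uncalibrated" else
    sprintf("%.3g um/px, %.3g fps", x$um_per_px, if (is.null(x$fps)) NA else x$fps)
  cat(sprintf("vessel_video: %d frames of %dx%d (%s)\n",
              length(x$frames), d[1], d[2], cal))
  invisible(x)
}

#' @export
length.vessel_video <- function(x) length(x$frames)

#' Read a video as a directory of numbered frames or a multi-page TIFF
#'
#' Frames are ordered by file name (directory input) or page order (TIFF).
#' 8-bit and 16-bit inputs are scaled into \[0, 1\]; color frames are
#' converted to luma (Rec. 601 weights) with a warning.
#'
#' @param path directory of `.png`/`.tif(f)` frames, or a single TIFF file.
#' @param um_per_px,fps optional calibration, attached to the result.
#' @return A `vessel_video`.
#' @export
read_video <- function(path, um_per_px = NULL, fps = NULL) {
  to_gray <- function(a, file) {
    if (length(dim(a)) == 3) {
      if (dim(a)[3] >= 3) {
        warning("color input converted to luma: ", file)
        a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      } else a <- a[, , 1]
    }
    if (!is.matrix(a)) stop("unreadable frame: ", file)
    a
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, function(f) {
      a <- tryCatch(
        if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
        else tiff::readTIFF(f),
        error = function(e) stop("unreadable frame: ", f, " (", conditionMessage(e), ")",
                                 call. = FALSE))
      to_gray(a, f)
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray, file = path)
  } else stop("no such file or directory: ", path)
  new_vessel_video(frames, um_per_px = um_per_px, fps = fps)
}

#' Write a video as a directory of zero-padded PNG frames
#'
#' @param video a `vessel_video`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the directory path, invisibly.
#' @export
write_video <- function(video, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(video$frames)
  width <- max(4L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    f <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, i))
    png::writePNG(clamp01(video$frames[[i]]), f)
  }
  invisible(dir)
}

#' Write a binary mask as an 8-bit PNG (255 = vessel)
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG (nonzero = vessel)
#' @param path PNG file.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Export phantom ground truth to plain-text files
#'
#' Writes `offsets`/`speeds` as JSON, the mask as PNG and the centerline as
#' CSV (`segment_id`, `order`, `row`, `col`).
#'
#' @param truth ground-truth list from [render_video()].
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(offsets = unname(as.matrix(truth$offsets)), speeds = truth$speeds),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  write_mask_png(truth$mask, file.path(dir, "mask.png"))
  cl <- do.call(rbind, truth$centerline)
  utils::write.csv(cl[, c("segment_id", "order", "row", "col")],
                   file.path(dir, "centerline.csv"), row.names = FALSE)
  invisible(dir)
}
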