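# Frame and video containers. A frame is a calibrated single-channel image;
# a video sequence is an ordered list of frames sharing shape and calibration.

#' Construct a single calibrated ultrasound frame
#'
#' @param pixels Numeric matrix `pixels[row, col]` of finite, non-negative
#'   intensities (conventionally in `[0, 1]`).
#' @param index Integer frame index, 0-based.
#' @param mm_per_pixel Positive isotropic spatial calibration (mm per pixel).
#' @return An object of class `us_frame`.
#' @export
us_frame <- function(pixels, index = 0L, mm_per_pixel = 1) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("frame must be at least 2x2 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("frame contains non-finite intensities", call. = FALSE)
  if (any(pixels < 0)) stop("frame contains negative intensities", call. = FALSE)
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a positive scalar", call. = FALSE)
  }
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("frame index must be a non-negative integer", call. = FALSE)
  structure(
    list(pixels = pixels, index = index, mm_per_pixel = mm_per_pixel),
    class = "us_frame"
  )
}

#' @export
print.us_frame <- function(x, ...) {
  cat(sprintf(
    "<us_frame #%d: %d x %d px, %.4g mm/px, intensity [%.3g, %.3g]>\n",
    x$index, nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Construct a video sequence from frames
#'
#' @param frames List of [us_frame] objects sharing dimensions and
#'   calibration; indices are (re)assigned consecutively from 0.
#' @param frame_rate Optional positive frame rate in Hz.
#' @return An object of class `us_video`.
#' @export
us_video <- function(frames, frame_rate = NULL) {
  if (length(frames) == 0L) stop("no frames found", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "us_frame"))) {
    stop("all elements must be us_frame objects", call. = FALSE)
  }
  d0 <- dim(frames[[1]]$pixels)
  mpp <- frames[[1]]$mm_per_pixel
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), d0)) {
      stop(sprintf("frame %d has inconsistent dimensions", i - 1L), call. = FALSE)
    }
    if (frames[[i]]$mm_per_pixel != mpp) {
      stop(sprintf("frame %d has inconsistent calibration", i - 1L), call. = FALSE)
    }
    frames[[i]]$index <- i - 1L
  }
  if (!is.null(frame_rate) && (!is.numeric(frame_rate) || frame_rate <= 0)) {
    stop("frame_rate must be positive", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate = frame_rate), class = "us_video")
}

#' @export
length.us_video <- function(x) length(x$frames)

#' @export
print.us_video <- function(x, ...) {
  f <- x$frames[[1]]
  cat(sprintf(
    "<us_video: %d frames, %d x %d px, %.4g mm/px%s>\n",
    length(x$frames), nrow(f$pixels), ncol(f$pixels), f$mm_per_pixel,
    if (is.null(x$frame_rate)) "" else sprintf(", %g Hz", x$frame_rate)
  ))
  invisible(x)
}

# Collapse a possibly multi-channel array read from disk to a single channel
# (channel mean), returning mat[row, col].
as_gray_matrix <- function(a) {
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    # alpha channel (4th) is dropped before averaging
    if (nch == 4L) a <- a[, , 1:3, drop = FALSE]
    a <- apply(a, c(1, 2), mean)
  }
  as.matrix(a)
}

#' Load an ultrasound video from an image-sequence directory
#'
#' Reads an ordered directory of single-channel (or RGB, averaged to gray)
#' PNG/TIFF frames into a calibrated [us_video]. Files are taken in
#' lexicographic order. Intensities are rescaled to `[0, 1]` if the source is
#' 8- or 16-bit (the `png`/`tiff` readers already return `[0, 1]` doubles).
#' Video container files (AVI/MP4/...) are not decoded; extract frames to a
#' directory first (e.g. with ffmpeg) and point `path` at it.
#'
#' @param path Directory containing the frame images.
#' @param mm_per_pixel Positive isotropic calibration (mm per pixel).
#' @param pattern Regular expression selecting frame files.
#' @return A [us_video].
#' @export
load_video <- function(path, mm_per_pixel, pattern = "\\.(png|tif|tiff)$") {
  if (!file.exists(path)) stop(sprintf("path not found: %s", path), call. = FALSE)
  if (!dir.exists(path)) {
    stop(sprintf(
      "'%s' is not a directory; video containers are not decoded, extract frames to a directory of PNG/TIFF images first",
      path
    ), call. = FALSE)
  }
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no frames found in %s", path), call. = FALSE)
  frames <- vector("list", length(files))
  d0 <- NULL
  for (i in seq_along(files)) {
    f <- files[[i]]
    a <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    m <- as_gray_matrix(a)
    if (is.null(d0)) {
      d0 <- dim(m)
    } else if (!identical(dim(m), d0)) {
      stop(sprintf("inconsistent frame size in file %s", basename(f)), call. = FALSE)
    }
    frames[[i]] <- us_frame(m, index = i - 1L, mm_per_pixel = mm_per_pixel)
  }
  us_video(frames)
}

#' Write a video sequence as a directory of PNG frames
#'
#' @param video A [us_video].
#' @param path Output directory (created if missing).
#' @return Invisibly, the file names written.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "us_video"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(video$frames))
  for (i in seq_along(video$frames)) {
    files[i] <- file.path(path, sprintf("frame_%04d.png", i - 1L))
    px <- pmin(pmax(video$frames[[i]]$pixels, 0), 1)
    png::writePNG(px, files[i])
  }
  invisible(files)
}
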