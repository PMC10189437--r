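#' Video stacks
#'
#' A video stack is an ordered list of single-channel grayscale frames
#' (numeric matrices, rows = y, columns = x) together with the acquisition
#' metadata needed downstream: the frame rate and the pixel-to-millimetre
#' conversion factor. All public coordinates in pillartrack are
#' `(x = column, y = row)`, 0-based, with pixel centres at integer
#' coordinates; sub-pixel positions are decimal in this frame.
#'
#' @param frames list of numeric matrices, all of identical dimensions.
#' @param fps frame rate in Hz (> 0).
#' @param pixel_size_mm conversion factor from pixels to millimetres (> 0).
#'
#' @return An object of class `video_stack`: a list with elements `frames`,
#'   `fps` and `pixel_size_mm`.
#' @export
video_stack <- function(frames, fps, pixel_size_mm) {
  if (!is.list(frames) || length(frames) == 0L) {
    abort("no frames")
  }
  frames <- lapply(frames, as_gray_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("shape mismatch: all frames must share one height and width")
  }
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1)))) {
    abort("frame intensities must be finite")
  }
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  stopifnot(is.numeric(pixel_size_mm), length(pixel_size_mm) == 1L, pixel_size_mm > 0)
  structure(
    list(frames = frames, fps = as.numeric(fps), pixel_size_mm = as.numeric(pixel_size_mm)),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<video_stack> %d frames of %d x %d px, %.6g fps, %.6g mm/px\n",
    length(x$frames), d[1], d[2], x$fps, x$pixel_size_mm
  ))
  invisible(x)
}

#' @export
length.video_stack <- function(x) length(x$frames)

#' Collapse an image array to a single grayscale channel
#'
#' RGB(A) input is collapsed by the standard luminance weighting
#' 0.299 R + 0.587 G + 0.114 B; an alpha channel is ignored. Grayscale input
#' is returned unchanged, so the conversion is idempotent.
#'
#' @param img a numeric matrix (grayscale) or a height x width x channels array.
#' @return A numeric matrix.
#' @export
as_gray_frame <- function(img) {
  if (is.matrix(img)) {
    return(img * 1.0)
  }
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] == 1L) {
      return(img[, , 1] * 1.0)
    }
    if (d[3] %in% c(3L, 4L)) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
  }
  abort(sprintf(
    "cannot interpret image with dimensions [%s] as a frame",
    paste(d, collapse = ", ")
  ))
}

#' Read a brightfield video
#'
#' Reads either a multi-page TIFF file or a directory of single-frame images
#' (PNG or TIFF, one frame per file, ordered lexicographically by file name).
#' Frames are converted to grayscale by [as_gray_frame()].
#'
#' @param path path to a multi-page TIFF or to a directory of frames.
#' @inheritParams video_stack
#' @return A [video_stack()].
#' @export
read_video <- function(path, fps, pixel_size_mm) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      abort("no frames")
    }
    frames <- lapply(files, read_frame_file)
  } else {
    if (!file.exists(path)) {
      abort(sprintf("no frames: '%s' does not exist", path))
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) == 0L) {
      abort("no frames")
    }
  }
  video_stack(frames, fps = fps, pixel_size_mm = pixel_size_mm)
}

read_frame_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    abort(sprintf("unsupported frame format '%s'", ext))
  )
  as_gray_frame(img)
}

#' Write a video stack as a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` and quantized to the requested bit
#' depth. The round trip through [read_video()] preserves frame count, shape
#' and quantized intensities.
#'
#' @param video a [video_stack()].
#' @param path output file path (`.tif`).
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frames <- function(video, path, bits_per_sample = 16L) {
  stopifnot(inherits(video, "video_stack"))
  frames <- lapply(video$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Acquisition and pillar calibration
#'
#' Bundles the constants that convert a pixel trajectory into physical units:
#' the pillar bending stiffness (slope of the force-displacement curve of the
#' pillar, mN/mm), the resting inter-pillar distance (mm), the
#' pixel-to-millimetre factor and the frame rate.
#'
#' @param stiffness_mN_per_mm pillar bending stiffness k (mN/mm).
#' @param pixel_size_mm conversion factor a (mm per pixel).
#' @param fps frame rate (Hz).
#' @param rest_distance_mm resting inter-pillar distance L0 (mm); default 3.2.
#' @return An object of class `eht_calibration`.
#' @export
calibration <- function(stiffness_mN_per_mm, pixel_size_mm, fps,
                        rest_distance_mm = 3.2) {
  vals <- c(stiffness_mN_per_mm = stiffness_mN_per_mm,
            pixel_size_mm = pixel_size_mm, fps = fps,
            rest_distance_mm = rest_distance_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("calibration values must all be strictly positive and finite")
  }
  structure(as.list(vals), class = "eht_calibration")
}

#' @export
print.eht_calibration <- function(x, ...) {
  cat(sprintf(
    "<eht_calibration> k = %.4g mN/mm, a = %.6g mm/px, fps = %.4g Hz, L0 = %.4g mm\n",
    x$stiffness_mN_per_mm, x$pixel_size_mm, x$fps, x$rest_distance_mm
  ))
  invisible(x)
}

#' Read a calibration record from a YAML file
#'
#' The file must define `stiffness_mN_per_mm`, `pixel_size_mm` and `fps`;
#' `rest_distance_mm` is optional (default 3.2).
#'
#' @param path path to a YAML file.
#' @return An [calibration()] object.
#' @export
read_calibration <- function(path) {
  vals <- yaml::read_yaml(path)
  required <- c("stiffness_mN_per_mm", "pixel_size_mm", "fps")
  missing <- setdiff(required, names(vals))
  if (length(missing) > 0L) {
    abort(sprintf("malformed calibration: missing %s",
                  paste(missing, collapse = ", ")))
  }
  calibration(
    stiffness_mN_per_mm = as.numeric(vals$stiffness_mN_per_mm),
    pixel_size_mm = as.numeric(vals$pixel_size_mm),
    fps = as.numeric(vals$fps),
    rest_distance_mm = as.numeric(vals$rest_distance_mm %||% 3.2)
  )
}
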