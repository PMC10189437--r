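#' Segmentation label masks
#'
#' A label mask assigns every pixel of a frame to one of four classes:
#' background, inner pillar, outer pillar or tissue. Masks are stored as
#' integer matrices with a `levels` attribute; the integer codes index into
#' [eht_label_levels()].
#'
#' @param labels an integer matrix of codes in `1:4`, or a character matrix
#'   of level names.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels) {
  lv <- eht_label_levels()
  if (is.character(labels)) {
    codes <- match(labels, lv)
    if (anyNA(codes)) {
      abort(sprintf("unknown label name(s): %s",
                    paste(unique(labels[is.na(codes)]), collapse = ", ")))
    }
    labels <- matrix(codes, nrow = nrow(labels), ncol = ncol(labels))
  }
  if (!is.matrix(labels) || !all(labels %in% seq_along(lv))) {
    abort("labels must be a matrix of codes in 1:4 (or level names)")
  }
  storage.mode(labels) <- "integer"
  structure(labels, levels = lv, class = "label_mask")
}

#' @rdname label_mask
#' @export
eht_label_levels <- function() {
  c("background", "inner_pillar", "outer_pillar", "tissue")
}

#' Default label colours
#'
#' The RGB convention for segmentation labels: white background, red inner
#' pillar, green outer pillar, blue tissue.
#'
#' @return A named list of length-3 integer RGB vectors (0-255).
#' @export
eht_label_colors <- function() {
  list(
    background   = c(255L, 255L, 255L),
    inner_pillar = c(255L, 0L, 0L),
    outer_pillar = c(0L, 255L, 0L),
    tissue       = c(0L, 0L, 255L)
  )
}

#' @export
print.label_mask <- function(x, ...) {
  counts <- tabulate(x, nbins = 4L)
  cat(sprintf("<label_mask> %d x %d px (%s)\n", nrow(x), ncol(x),
              paste(sprintf("%s: %d", attr(x, "levels"), counts), collapse = ", ")))
  invisible(x)
}

#' Logical mask for one label class
#'
#' @param mask a [label_mask()].
#' @param class one of `"background"`, `"inner_pillar"`, `"outer_pillar"`,
#'   `"tissue"`.
#' @return A logical matrix.
#' @export
mask_class <- function(mask, class) {
  stopifnot(inherits(mask, "label_mask"))
  code <- match(match.arg(class, eht_label_levels()), eht_label_levels())
  unclass(mask) == code
}

#' Read an RGB-coded label mask
#'
#' Every pixel must exactly match one of the configured class colours
#' (after quantization to 8-bit); any other colour is an error.
#'
#' @param path path to a PNG or TIFF image.
#' @param color_map named list mapping class name to RGB triplet (0-255);
#'   defaults to [eht_label_colors()].
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, color_map = eht_label_colors()) {
  img <- read_frame_raw(path)
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  r <- round(img[, , 1] * 255)
  g <- round(img[, , 2] * 255)
  b <- round(img[, , 3] * 255)
  key <- r * 65536 + g * 256 + b
  lv <- eht_label_levels()
  missing <- setdiff(lv, names(color_map))
  if (length(missing) > 0L) {
    abort(sprintf("color_map must define %s", paste(missing, collapse = ", ")))
  }
  map_keys <- vapply(lv, function(nm) {
    rgb <- color_map[[nm]]
    rgb[1] * 65536 + rgb[2] * 256 + rgb[3]
  }, numeric(1))
  codes <- match(key, map_keys)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    abort(sprintf("unknown label color: RGB (%d, %d, %d)",
                  r[bad], g[bad], b[bad]))
  }
  label_mask(matrix(as.integer(codes), nrow = nrow(r), ncol = ncol(r)))
}

read_frame_raw <- function(file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    abort(sprintf("unsupported image format '%s'", ext))
  )
}

#' Write a label mask as an RGB PNG
#'
#' Inverse of [read_label_mask()] under the same colour map.
#'
#' @inheritParams read_label_mask
#' @param mask a [label_mask()].
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path, color_map = eht_label_colors()) {
  stopifnot(inherits(mask, "label_mask"))
  lv <- eht_label_levels()
  rgb <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (k in seq_along(lv)) {
    sel <- unclass(mask) == k
    col <- color_map[[lv[k]]] / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- col[ch]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
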