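#' Label 8-connected components of a binary mask
#'
#' Components are connected sets of `TRUE` pixels under 8-connectivity
#' (diagonal neighbours join). Implemented as connected components of the
#' pixel adjacency graph.
#'
#' @param bin a logical matrix.
#' @return An integer matrix of the same shape: 0 for background, component
#'   ids `1..k` otherwise (ids ordered by first pixel in column-major order).
#' @export
label_components <- function(bin) {
  stopifnot(is.logical(bin), is.matrix(bin))
  nr <- nrow(bin)
  nc <- ncol(bin)
  fg <- which(bin)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) {
    return(out)
  }
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  # half the 8-neighbourhood; the other half is covered by symmetry
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0)
  to <- integer(0)
  for (off in offsets) {
    rn <- r + off[1]
    cn <- c + off[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- (cn[ok] - 1L) * nr + rn[ok]
    keep <- bin[nb]
    from <- c(from, fg[ok][keep])
    to <- c(to, nb[keep])
  }
  ids <- match(c(from, to), fg)
  g <- igraph::make_graph(edges = rbind(ids[seq_along(from)],
                                        ids[length(from) + seq_along(to)]),
                          n = length(fg), directed = FALSE)
  out[fg] <- as.integer(igraph::components(g)$membership)
  out
}

#' Pillar template
#'
#' A template is a rectangular grayscale patch cropped from the reference
#' frame, together with the 0-based `(x, y)` frame coordinates of its
#' top-left corner and which side (left/right) it belongs to.
#'
#' @param patch numeric matrix (h x w), at least 2 px in each dimension.
#' @param origin length-2 numeric `(x, y)`, 0-based top-left in frame coords.
#' @param side `"left"` or `"right"`.
#' @return An object of class `eht_template`.
#' @export
eht_template <- function(patch, origin, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(is.matrix(patch), length(origin) == 2L)
  if (nrow(patch) < 2L || ncol(patch) < 2L) {
    abort("template too small: patch must be at least 2 x 2 px")
  }
  structure(list(patch = patch, origin = as.numeric(origin), side = side),
            class = "eht_template")
}

#' @export
print.eht_template <- function(x, ...) {
  cat(sprintf("<eht_template> %s, %d x %d px at (%g, %g)\n", x$side,
              ncol(x$patch), nrow(x$patch), x$origin[1], x$origin[2]))
  invisible(x)
}

template_bbox <- function(tpl) {
  # inclusive 0-based (x0, y0, x1, y1)
  c(tpl$origin[1], tpl$origin[2],
    tpl$origin[1] + ncol(tpl$patch) - 1, tpl$origin[2] + nrow(tpl$patch) - 1)
}

#' Extract left/right pillar templates from a segmentation mask
#'
#' Selects the two largest 8-connected components of the target class
#' (robust to small spurious blobs elsewhere in the segmentation) and crops
#' the reference frame at each component's tight bounding box. The component
#' with the smaller centroid x becomes the left template. Ties in size are
#' broken in favour of the smaller centroid x.
#'
#' @param mask a [label_mask()].
#' @param reference_frame numeric matrix, the frame the templates are cut
#'   from (normally frame 1 of the video).
#' @param target_class label class used for the pillars; the outer pillar is
#'   the default because its segmented shape is the more reproducible one.
#' @return A list with elements `left` and `right`, both [eht_template()].
#' @export
extract_pillar_templates <- function(mask, reference_frame,
                                     target_class = "outer_pillar") {
  stopifnot(inherits(mask, "label_mask"), is.matrix(reference_frame))
  if (!all(dim(mask) == dim(reference_frame))) {
    abort("mask and reference frame shapes differ")
  }
  comp <- label_components(mask_class(mask, target_class))
  k <- max(comp)
  if (k < 2L) {
    abort("insufficient pillar components: need at least 2 connected components")
  }
  areas <- tabulate(comp[comp > 0L], nbins = k)
  cx <- vapply(seq_len(k), function(i) {
    mean(((which(comp == i) - 1L) %/% nrow(comp)))   # 0-based column
  }, numeric(1))
  ord <- order(-areas, cx)
  pick <- ord[1:2]
  pick <- pick[order(cx[pick])]   # left first

  tpls <- lapply(seq_along(pick), function(j) {
    i <- pick[j]
    px <- which(comp == i)
    rows <- ((px - 1L) %% nrow(comp)) + 1L
    cols <- ((px - 1L) %/% nrow(comp)) + 1L
    patch <- reference_frame[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
    eht_template(patch, origin = c(min(cols) - 1L, min(rows) - 1L),
                 side = c("left", "right")[j])
  })
  b1 <- template_bbox(tpls[[1]])
  b2 <- template_bbox(tpls[[2]])
  if (b1[3] >= b2[1] && b2[3] >= b1[1] && b1[4] >= b2[2] && b2[4] >= b1[2]) {
    warn("pillar template bounding boxes overlap; both returned")
  }
  list(left = tpls[[1]], right = tpls[[2]])
}

#' Search region for template matching
#'
#' Axis-aligned rectangle of frame pixels in which candidate template
#' placements are scored. Bounds are inclusive, 0-based `(x0, y0, x1, y1)`.
#'
#' @param x0,y0,x1,y1 inclusive 0-based bounds.
#' @return An object of class `search_region`.
#' @export
search_region <- function(x0, y0, x1, y1) {
  stopifnot(x1 >= x0, y1 >= y0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "search_region")
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("<search_region> x in [%d, %d], y in [%d, %d]\n",
              x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Build left/right search regions around the pillar templates
#'
#' Each region is the template bounding box dilated by `margin_px` along the
#' pillar-to-pillar (x) axis and by a smaller fixed transverse margin along
#' y, clipped to the frame. Restricting matching to these regions is what
#' keeps per-frame tracking cheap; the margin need only cover the maximum
#' tip excursion, which for contracting tissues is far below the
#' inter-pillar gap. Regions are additionally clipped so that neither
#' contains the opposite template's initial box.
#'
#' @param left,right [eht_template()] objects from the reference frame.
#' @param frame_shape `c(height, width)` of the video frames (or `dim(frame)`).
#' @param margin_px dilation along x in pixels; default 25% of the
#'   inter-template gap.
#' @param transverse_margin_px dilation along y in pixels (default 8).
#' @return A list with elements `left` and `right`, both [search_region()].
#' @export
build_search_regions <- function(left, right, frame_shape, margin_px = NULL,
                                 transverse_margin_px = 8L) {
  stopifnot(inherits(left, "eht_template"), inherits(right, "eht_template"))
  h <- frame_shape[1]
  w <- frame_shape[2]
  bl <- template_bbox(left)
  br <- template_bbox(right)
  gap <- br[1] - bl[3] - 1
  if (is.null(margin_px)) {
    margin_px <- max(1L, round(0.25 * max(gap, 0)))
  }
  margin_px <- as.integer(margin_px)
  tm <- as.integer(transverse_margin_px)

  dilate <- function(b) {
    search_region(max(0, b[1] - margin_px), max(0, b[2] - tm),
                  min(w - 1, b[3] + margin_px), min(h - 1, b[4] + tm))
  }
  rl <- dilate(bl)
  rr <- dilate(br)
  # never let a region reach into the opposite template's initial box
  if (rl$x1 >= br[1]) {
    warn("left search region reaches the right template; clipping")
    rl$x1 <- as.integer(br[1] - 1)
  }
  if (rr$x0 <= bl[3]) {
    warn("right search region reaches the left template; clipping")
    rr$x0 <- as.integer(bl[3] + 1)
  }
  list(left = rl, right = rr)
}

#' Tissue surface area from a segmentation mask
#'
#' The projected tissue surface area is the pixel area times the number of
#' tissue-class pixels: `area = a^2 * sum(mask == tissue)`.
#'
#' @param mask a [label_mask()].
#' @param pixel_size_mm conversion factor a (mm per pixel).
#' @return Surface area in mm^2 (0 when the tissue class is empty).
#' @export
surface_area <- function(mask, pixel_size_mm) {
  stopifnot(pixel_size_mm > 0)
  pixel_size_mm^2 * sum(mask_class(mask, "tissue"))
}
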