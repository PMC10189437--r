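#' Normalized cross-correlation accumulator
#'
#' Scores every candidate placement of a template inside a search region
#' with the normalized correlation coefficient
#' \deqn{R(x, y) = \frac{\sum T' \, I'}{\sqrt{\sum T'^2 \; \sum I'^2}}}
#' where \eqn{T'} is the mean-subtracted template and \eqn{I'} the
#' mean-subtracted image window, both means taken over the `w * h` template
#' support. A score of 1 is an exact match (up to an affine intensity
#' change); 0 is no correlation. Windows of zero intensity variance score 0
#' so that flat background can never win the argmax.
#'
#' The accumulator is computed only inside the search region, never over
#' the whole frame.
#'
#' @param template an [eht_template()].
#' @param frame numeric matrix, the frame to match against.
#' @param region a [search_region()]; must exceed the template in both axes.
#' @param method `"fft"` (default) computes the correlation sums with a
#'   2-D FFT and the window sums with integral images; `"direct"` scores
#'   every placement by explicit window extraction. Both give the same
#'   scores to well below 1e-8; `"direct"` is the reference path.
#' @return An object of class `accumulator`: list with `scores`
#'   (matrix indexed `[y placement, x placement]`) and `region_origin`
#'   (`(x, y)` frame coordinates of placement index `(0, 0)`).
#' @export
ncc_accumulator <- function(template, frame, region,
                            method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(template, "eht_template"), inherits(region, "search_region"))
  patch <- template$patch
  h <- nrow(patch)
  w <- ncol(patch)
  sub <- frame[(region$y0 + 1):(region$y1 + 1), (region$x0 + 1):(region$x1 + 1),
               drop = FALSE]
  rh <- nrow(sub)
  rw <- ncol(sub)
  ny <- rh - h + 1L
  nx <- rw - w + 1L
  if (ny < 1L || nx < 1L) {
    abort("region too small: search region must exceed the template in both axes")
  }
  if (ny == 1L && nx == 1L && rh == h && rw == w) {
    # degenerate but legal: single placement
  }
  tv <- as.vector(patch)
  tm <- tv - mean(tv)
  den_t <- sum(tm^2)
  wh <- w * h

  if (method == "direct") {
    # im2col: columns of W are flattened windows, placements in (y fastest) order
    base <- as.vector(outer(seq_len(h), (seq_len(w) - 1L) * rh, `+`))
    offs <- as.vector(outer(seq_len(ny) - 1L, (seq_len(nx) - 1L) * rh, `+`))
    W <- sub[outer(base, offs, `+`)]
    dim(W) <- c(wh, length(offs))
    cross <- as.vector(crossprod(tm, W))        # sum(Tm) == 0, window mean cancels
    csum <- .colSums(W, wh, length(offs))
    sq <- .colSums(W * W, wh, length(offs))
  } else {
    # circular cross-correlation, zero-padded to 2-3-5-smooth sizes (fast
    # FFT lengths); exact for all valid placements because neither the
    # template nor any scored window wraps onto the padding
    ph <- stats::nextn(rh, c(2, 3, 5))
    pw <- stats::nextn(rw, c(2, 3, 5))
    spad <- matrix(0, ph, pw)
    spad[seq_len(rh), seq_len(rw)] <- sub
    tpad <- matrix(0, ph, pw)
    tpad[seq_len(h), seq_len(w)] <- tm
    cr <- Re(stats::fft(stats::fft(spad) * Conj(stats::fft(tpad)),
                        inverse = TRUE)) / (ph * pw)
    cross <- as.vector(cr[seq_len(ny), seq_len(nx), drop = FALSE])
    sums <- window_sums(sub, h, w)
    csum <- as.vector(sums$s1)
    sq <- as.vector(sums$s2)
  }

  den_i <- sq - csum^2 / wh
  den_i[den_i < 0] <- 0
  denom <- sqrt(den_t * den_i)
  scores <- ifelse(denom > .Machine$double.eps^0.5 * wh, cross / denom, 0)
  scores <- pmin(pmax(scores, -1), 1)
  dim(scores) <- c(ny, nx)
  structure(list(scores = scores,
                 region_origin = c(region$x0, region$y0)),
            class = "accumulator")
}

window_sums <- function(sub, h, w) {
  # sums and sums of squares of all h x w windows via integral images
  ii <- function(m) {
    # I[i+1, j+1] = sum(m[1:i, 1:j])
    rs <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
    I <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    I[-1L, -1L] <- rs
    I
  }
  rh <- nrow(sub)
  rw <- ncol(sub)
  ny <- rh - h + 1L
  nx <- rw - w + 1L
  win <- function(I) {
    I[(1L + h):(rh + 1L), (1L + w):(rw + 1L), drop = FALSE] -
      I[(1L + h):(rh + 1L), 1L:(rw + 1L - w), drop = FALSE] -
      I[1L:(rh + 1L - h), (1L + w):(rw + 1L), drop = FALSE] +
      I[1L:(rh + 1L - h), 1L:(rw + 1L - w), drop = FALSE]
  }
  list(s1 = win(ii(sub)), s2 = win(ii(sub * sub)))
}

#' @export
print.accumulator <- function(x, ...) {
  cat(sprintf("<accumulator> %d x %d placements at origin (%d, %d), max %.4f\n",
              ncol(x$scores), nrow(x$scores),
              x$region_origin[1], x$region_origin[2],
              suppressWarnings(max(x$scores, na.rm = TRUE))))
  invisible(x)
}

#' Best integer-pixel match in an accumulator
#'
#' Returns the placement with the highest score. Ties are broken by the
#' smallest y, then the smallest x.
#'
#' @param acc an accumulator from [ncc_accumulator()].
#' @return A list with `x`, `y` (0-based frame coordinates of the placement
#'   top-left) and `score`.
#' @export
best_integer_match <- function(acc) {
  s <- acc$scores
  if (length(s) == 0L || !any(is.finite(s))) {
    abort("no valid placement: accumulator has no finite entries")
  }
  m <- max(s[is.finite(s)])
  cand <- which(s == m, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]   # smallest y, then x
  list(x = unname(acc$region_origin[1] + cand[1, 2] - 1L),
       y = unname(acc$region_origin[2] + cand[1, 1] - 1L),
       score = m)
}

#' Dump an accumulator as a normalized 16-bit grayscale image
#'
#' Debug visualization of the correlation field: scores are rescaled to
#' `[0, 1]` (brighter = better match) and written as PNG.
#'
#' @param acc an accumulator from [ncc_accumulator()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_accumulator_image <- function(acc, path) {
  s <- acc$scores
  rng <- range(s[is.finite(s)])
  z <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s * 0
  z[!is.finite(z)] <- 0
  png::writePNG(z, path)
  invisible(path)
}
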