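#' Tensor-product bicubic spline over a grid of scores
#'
#' Builds a smooth, differentiable surface through the samples of a score
#' window by natural cubic splines applied separably: one spline per grid
#' row in x, then one spline across the row values in y. Used to evaluate
#' the correlation field at decimal coordinates between the integer-pixel
#' samples.
#'
#' @param xs,ys grid coordinates (ascending, length >= 4 each).
#' @param z matrix of samples, `z[j, i]` at `(xs[i], ys[j])`.
#' @return A function `f(x, y)` returning the interpolated value.
#' @export
bicubic_spline <- function(xs, ys, z) {
  stopifnot(length(xs) >= 4L, length(ys) >= 4L,
            nrow(z) == length(ys), ncol(z) == length(xs))
  row_splines <- lapply(seq_along(ys), function(j) {
    splinefun(xs, z[j, ], method = "natural")
  })
  function(x, y) {
    col <- vapply(row_splines, function(sf) sf(x), numeric(1))
    splinefun(ys, col, method = "natural")(y)
  }
}

f_grid <- function(xs, ys, scores, gx, gy) {
  # evaluate the tensor-product spline at a small grid in one pass:
  # row splines at all gx, then column splines at all gy
  z <- scores[ys + 1L, xs + 1L, drop = FALSE]
  rv <- vapply(seq_along(ys),
               function(j) splinefun(xs, z[j, ], method = "natural")(gx),
               numeric(length(gx)))           # |gx| x |ys|
  vapply(seq_along(gx),
         function(k) splinefun(ys, rv[k, ], method = "natural")(gy),
         numeric(length(gy)))                 # |gy| x |gx|
}

#' Nelder-Mead minimization with a positional stopping rule
#'
#' Small derivative-free simplex minimizer whose convergence criterion is
#' the simplex diameter: iteration stops once every vertex lies within
#' `tol` of the best vertex (in the max-norm of the coordinates). This makes
#' the tolerance a length in the units of the search space - here pixels -
#' matching the sub-pixel refinement threshold of the tracker.
#'
#' @param fn objective to minimize, taking a numeric vector.
#' @param x0 starting point.
#' @param step initial simplex edge length (same units as `x0`).
#' @param tol positional convergence tolerance.
#' @param maxeval cap on objective evaluations.
#' @return List with `x` (argmin), `value`, and `neval`.
#' @export
nm_minimize <- function(fn, x0, step = 0.25, tol = 1e-4, maxeval = 500L) {
  n <- length(x0)
  verts <- matrix(rep(x0, n + 1L), ncol = n, byrow = TRUE)
  for (i in seq_len(n)) verts[i + 1L, i] <- verts[i + 1L, i] + step
  fv <- apply(verts, 1L, fn)
  neval <- n + 1L
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5

  repeat {
    ord <- order(fv)
    verts <- verts[ord, , drop = FALSE]
    fv <- fv[ord]
    diam <- max(abs(sweep(verts[-1L, , drop = FALSE], 2L, verts[1L, ])))
    if (diam < tol || neval >= maxeval) break

    centroid <- colMeans(verts[-(n + 1L), , drop = FALSE])
    xr <- centroid + alpha * (centroid - verts[n + 1L, ])
    fr <- fn(xr); neval <- neval + 1L
    if (fr < fv[1L]) {
      xe <- centroid + gamma * (xr - centroid)
      fe <- fn(xe); neval <- neval + 1L
      if (fe < fr) { verts[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { verts[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      verts[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {
        xc <- centroid + rho * (xr - centroid)
      } else {
        xc <- centroid + rho * (verts[n + 1L, ] - centroid)
      }
      fc <- fn(xc); neval <- neval + 1L
      if (fc < min(fr, fv[n + 1L])) {
        verts[n + 1L, ] <- xc; fv[n + 1L] <- fc
      } else {
        for (i in 2:(n + 1L)) {
          verts[i, ] <- verts[1L, ] + sigma * (verts[i, ] - verts[1L, ])
          fv[i] <- fn(verts[i, ]); neval <- neval + 1L
        }
      }
    }
  }
  ord <- order(fv)
  list(x = verts[ord[1L], ], value = fv[ord[1L]], neval = neval)
}

#' Refine an integer match to sub-pixel precision
#'
#' Fits a bicubic spline to the `window x window` neighbourhood of the
#' correlation peak and maximizes it (by minimizing its negation) with
#' Nelder-Mead started at the integer peak. The true continuous peak lies
#' within half a pixel of the integer argmax, so the search is confined to
#' one pixel around it; the default positional convergence threshold is
#' 0.0001 px.
#'
#' If the integer peak sits on the accumulator border, or the clipped
#' window leaves fewer than 4 spline knots in an axis, refinement is not
#' possible and the integer match is returned with flag `"border_peak"`.
#'
#' @param acc an accumulator from [ncc_accumulator()].
#' @param peak integer match from [best_integer_match()].
#' @param window odd window size >= 5 (accumulator samples per axis).
#' @param tol Nelder-Mead positional tolerance in pixels.
#' @return List with decimal `x`, `y` (frame coordinates), interpolated
#'   `score`, and `flag` (`"ok"` or `"border_peak"`).
#' @export
refine_subpixel <- function(acc, peak, window = 7L, tol = 1e-4) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L) {
    abort("window must be odd and >= 5")
  }
  s <- acc$scores
  ny <- nrow(s)
  nx <- ncol(s)
  pi <- peak$x - acc$region_origin[1]   # 0-based accumulator indices
  pj <- peak$y - acc$region_origin[2]

  fallback <- list(x = as.numeric(peak$x), y = as.numeric(peak$y),
                   score = peak$score, flag = "border_peak")
  if (pi <= 0L || pi >= nx - 1L || pj <= 0L || pj >= ny - 1L) {
    return(fallback)
  }
  half <- window %/% 2L
  xs <- max(0L, pi - half):min(nx - 1L, pi + half)
  ys <- max(0L, pj - half):min(ny - 1L, pj + half)
  if (length(xs) < 4L || length(ys) < 4L) {
    return(fallback)
  }
  f <- bicubic_spline(xs, ys, s[ys + 1L, xs + 1L, drop = FALSE])

  # the continuous peak lies within half a pixel of the noise-free integer
  # argmax; under noise the observed argmax can be one sample off, so the
  # search covers the inner part of the window (spline knots at the window
  # border are kept as support only)
  lo <- c(max(min(xs), pi - 2.5), max(min(ys), pj - 2.5))
  hi <- c(min(max(xs), pi + 2.5), min(max(ys), pj + 2.5))
  obj <- function(p) {
    p <- pmin(pmax(p, lo), hi)
    -f(p[1], p[2])
  }
  # coarse scan of the interpolated surface, then simplex refinement from
  # the best coarse point (start order keeps the integer peak on ties)
  offs <- c(0, -1.5, -1, -0.5, 0.5, 1, 1.5)
  gxu <- pmin(pmax(pi + offs, lo[1]), hi[1])
  gyu <- pmin(pmax(pj + offs, lo[2]), hi[2])
  gv <- f_grid(xs, ys, s, gxu, gyu)       # |gyu| x |gxu| values
  b <- arrayInd(which.max(gv), dim(gv))
  opt <- nm_minimize(obj, c(gxu[b[2]], gyu[b[1]]), step = 0.25, tol = tol)
  p <- pmin(pmax(opt$x, lo), hi)
  score <- f(p[1], p[2])
  if (!is.finite(score) || score < peak$score) {
    # refinement must never degrade the match
    return(list(x = as.numeric(peak$x), y = as.numeric(peak$y),
                score = peak$score, flag = "ok"))
  }
  list(x = acc$region_origin[1] + p[1],
       y = acc$region_origin[2] + p[2],
       score = score, flag = "ok")
}
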