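acc_from_matrix <- function(scores, origin = c(0, 0)) {
  structure(list(scores = scores, region_origin = origin),
            class = "accumulator")
}

test_that("refinement recovers the maximum of a sampled quadratic surface", {
  f <- function(x, y) 1 - ((x - 7.35)^2 + (y - 3.6)^2) / 100
  scores <- outer(0:8, 0:14, function(y, x) f(x, y))
  acc <- acc_from_matrix(scores)
  peak <- best_integer_match(acc)
  expect_equal(c(peak$x, peak$y), c(7, 4))
  ref <- refine_subpixel(acc, peak)
  expect_equal(ref$flag, "ok")
  expect_lt(abs(ref$x - 7.35), 0.02)
  expect_lt(abs(ref$y - 3.6), 0.02)
  expect_gte(ref$score, peak$score - 1e-9)
})

test_that("a symmetric integer-centred peak refines to exactly the integer", {
  f <- function(x, y) exp(-((x - 7)^2 + (y - 3)^2) / 6)
  scores <- outer(0:6, 0:14, function(y, x) f(x, y))
  acc <- acc_from_matrix(scores)
  peak <- best_integer_match(acc)
  ref <- refine_subpixel(acc, peak)
  expect_lt(abs(ref$x - 7), 1e-3)
  expect_lt(abs(ref$y - 3), 1e-3)
})

test_that("a half-pixel image shift is recovered and matches a dense grid search", {
  patch <- textured_patch(40, 40, seed = 12)
  frame <- matrix(0.5, 80, 100)
  frame[21:60, 31:70] <- patch
  shifted <- shift_image_x(frame, 0.5)
  tpl <- eht_template(patch[6:35, 6:35], origin = c(35, 25), side = "left")
  reg <- search_region(25, 17, 80, 62)
  acc <- ncc_accumulator(tpl, shifted, reg)
  peak <- best_integer_match(acc)
  ref <- refine_subpixel(acc, peak)
  expect_lt(abs((ref$x - 35) - 0.5), 0.1)

  # oracle: dense 0.001-px grid search over the same spline surface
  s <- acc$scores
  pi <- peak$x - acc$region_origin[1]
  pj <- peak$y - acc$region_origin[2]
  xs <- (pi - 3):(pi + 3)
  ys <- (pj - 3):(pj + 3)
  spl <- bicubic_spline(xs, ys, s[ys + 1, xs + 1])
  gx <- seq(pi - 1, pi + 1, by = 0.001)
  vals <- vapply(gx, function(x) spl(x, ref$y - acc$region_origin[2]), numeric(1))
  expect_lt(abs((ref$x - acc$region_origin[1]) - gx[which.max(vals)]), 0.005)
})

test_that("programmatic sub-pixel shifts are recovered within 0.05 px at zero noise", {
  patch <- textured_patch(46, 46, seed = 13, sigma = 1.2)
  frame <- matrix(0.5, 90, 110)
  frame[23:68, 33:78] <- patch
  tpl <- eht_template(patch[9:38, 9:38], origin = c(40, 30), side = "left")
  reg <- search_region(30, 22, 85, 66)
  for (delta in seq(0.1, 0.9, by = 0.1)) {
    shifted <- shift_image_x(frame, delta)
    acc <- ncc_accumulator(tpl, shifted, reg)
    ref <- refine_subpixel(acc, best_integer_match(acc))
    expect_lt(abs((ref$x - 40) - delta), 0.05)
  }
})

test_that("refinement never degrades the integer match score", {
  set.seed(21)
  for (k in 1:10) {
    scores <- matrix(runif(11 * 13, -0.2, 0.8), 11, 13)
    scores <- gaussian_blur_ref(scores, 0.8)
    acc <- acc_from_matrix(scores)
    peak <- best_integer_match(acc)
    ref <- refine_subpixel(acc, peak)
    expect_gte(ref$score, peak$score - 1e-9)
  }
})

test_that("border peaks fall back to the integer match with a flag", {
  scores <- matrix(0.1, 6, 8)
  scores[1, 4] <- 0.9                     # peak on the accumulator border
  acc <- acc_from_matrix(scores, origin = c(10, 20))
  peak <- best_integer_match(acc)
  ref <- refine_subpixel(acc, peak)
  expect_equal(ref$flag, "border_peak")
  expect_equal(ref$x, peak$x)
  expect_equal(ref$y, peak$y)
  expect_error(refine_subpixel(acc, peak, window = 4), "odd")
  expect_error(refine_subpixel(acc, peak, window = 3), "odd|>= 5")
})

test_that("the simplex minimizer honours its positional tolerance", {
  fn <- function(p) (p[1] - 0.31)^2 + 2 * (p[2] + 0.47)^2 + 0.3 * p[1] * p[2]
  opt <- nm_minimize(fn, c(0, 0), step = 0.25, tol = 1e-6)
  # analytic minimum of the quadratic: solve the gradient system
  A <- matrix(c(2, 0.3, 0.3, 4), 2)
  b <- c(2 * 0.31, -4 * 0.47 - 0)
  xstar <- solve(A, c(0.62, -1.88))
  expect_lt(max(abs(opt$x - xstar)), 1e-4)
})
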