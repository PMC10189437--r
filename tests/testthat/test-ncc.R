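test_that("an exact template copy scores 1.0 at its location", {
  frame <- textured_patch(60, 80, seed = 2)
  tpl <- eht_template(frame[21:40, 31:55], origin = c(30, 20), side = "left")
  reg <- search_region(20, 12, 68, 50)
  for (m in c("fft", "direct")) {
    acc <- ncc_accumulator(tpl, frame, reg, method = m)
    best <- best_integer_match(acc)
    expect_equal(best$x, 30)
    expect_equal(best$y, 20)
    expect_equal(best$score, 1, tolerance = 1e-12)
  }
})

test_that("NCC is invariant to affine intensity rescaling of the image", {
  frame <- textured_patch(50, 60, seed = 3)
  tpl <- eht_template(frame[11:30, 16:40], origin = c(15, 10), side = "left")
  rescaled <- 2 * frame + 10
  reg <- search_region(8, 4, 52, 40)
  acc <- ncc_accumulator(tpl, rescaled, reg)
  best <- best_integer_match(acc)
  expect_equal(c(best$x, best$y), c(15, 10))
  expect_equal(best$score, 1, tolerance = 1e-12)
})

test_that("accumulator entries equal the sliding-window Pearson oracle", {
  set.seed(9)
  # 3x3 template over a 5x5 region: all nine placements
  frame <- matrix(runif(144), 12, 12)
  tpl <- eht_template(frame[4:6, 5:7], origin = c(4, 3), side = "left")
  reg <- search_region(3, 2, 7, 6)
  oracle <- pearson_oracle(tpl, frame, reg)
  expect_identical(dim(oracle), c(3L, 3L))
  for (m in c("fft", "direct")) {
    acc <- ncc_accumulator(tpl, frame, reg, method = m)
    expect_identical(dim(acc$scores), c(3L, 3L))
    expect_lt(max(abs(acc$scores - oracle)), 1e-10)
  }
  # random instances up to 16x16
  for (k in 1:5) {
    rh <- sample(8:16, 1)
    rw <- sample(8:16, 1)
    th <- sample(3:(rh - 2), 1)
    tw <- sample(3:(rw - 2), 1)
    fr <- matrix(runif(20 * 20), 20, 20)
    tp <- eht_template(fr[2:(1 + th), 2:(1 + tw)], origin = c(1, 1), side = "left")
    rg <- search_region(2, 3, 1 + rw, 2 + rh)
    oracle <- pearson_oracle(tp, fr, rg)
    for (m in c("fft", "direct")) {
      acc <- ncc_accumulator(tp, fr, rg, method = m)
      expect_lt(max(abs(acc$scores - oracle)), 1e-10)
      expect_true(all(abs(acc$scores) <= 1 + 1e-9))
    }
  }
})

test_that("shifting the search region shifts the argmax equally", {
  frame <- textured_patch(70, 90, seed = 5)
  tpl <- eht_template(frame[31:45, 41:60], origin = c(40, 30), side = "left")
  r1 <- search_region(30, 22, 70, 53)
  r2 <- search_region(25, 18, 65, 49)
  b1 <- best_integer_match(ncc_accumulator(tpl, frame, r1))
  b2 <- best_integer_match(ncc_accumulator(tpl, frame, r2))
  expect_equal(c(b1$x, b1$y), c(b2$x, b2$y))   # frame coordinates agree
  a1 <- ncc_accumulator(tpl, frame, r1)
  expect_identical(dim(a1$scores), c(53L - 22L - 15L + 2L, 70L - 30L - 20L + 2L))
})

test_that("zero-variance windows score 0 and never win over texture", {
  frame <- matrix(0.5, 40, 60)
  frame[15:25, 35:50] <- textured_patch(11, 16, seed = 6)
  tpl <- eht_template(frame[15:25, 35:50], origin = c(34, 14), side = "left")
  reg <- search_region(0, 5, 59, 34)
  acc <- ncc_accumulator(tpl, frame, reg)
  expect_equal(acc$scores[1, 1], 0)            # flat corner
  best <- best_integer_match(acc)
  expect_equal(c(best$x, best$y), c(34, 14))
  # a flat template correlates with nothing
  flat <- eht_template(matrix(0.5, 5, 5), origin = c(0, 0), side = "left")
  acc2 <- ncc_accumulator(flat, frame, search_region(0, 0, 20, 20))
  expect_true(all(acc2$scores == 0))
})

test_that("argmax ties break to the smallest y then smallest x", {
  acc <- structure(list(scores = matrix(0.5, 4, 5), region_origin = c(7, 3)),
                   class = "accumulator")
  best <- best_integer_match(acc)
  expect_equal(c(best$x, best$y), c(7, 3))
  s <- matrix(0, 4, 5)
  s[2, 4] <- s[3, 2] <- 0.9                    # tie: (x=3,y=1) wins over (x=1,y=2)
  acc2 <- structure(list(scores = s, region_origin = c(0, 0)), class = "accumulator")
  best2 <- best_integer_match(acc2)
  expect_equal(c(best2$x, best2$y), c(3, 1))
})

test_that("degenerate accumulators are rejected", {
  frame <- matrix(runif(100), 10, 10)
  tpl <- eht_template(frame[1:6, 1:6], origin = c(0, 0), side = "left")
  expect_error(ncc_accumulator(tpl, frame, search_region(0, 0, 4, 4)),
               "region too small")
  nan_acc <- structure(list(scores = matrix(NaN, 3, 3), region_origin = c(0, 0)),
                       class = "accumulator")
  expect_error(best_integer_match(nan_acc), "no valid placement")
})
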