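test_that("the generator is deterministic under a fixed seed", {
  s1 <- tiny_simulation(noise_frac = 0.1, seed = 5, n_frames = 4)
  s2 <- tiny_simulation(noise_frac = 0.1, seed = 5, n_frames = 4)
  expect_identical(s1$video$frames, s2$video$frames)
  s3 <- tiny_simulation(noise_frac = 0.1, seed = 6, n_frames = 4)
  expect_false(identical(s1$video$frames[[1]], s3$video$frames[[1]]))
})

test_that("zero amplitude and zero noise give a static video", {
  sc <- tiny_scene()
  spec <- simulation_spec(sc$background, sc$sprites, sc$pillar_centers,
                          amplitude_px = 0, n_frames = 3, noise_frac = 0)
  sim <- generate_video(spec)
  expect_identical(sim$video$frames[[1]], sim$video$frames[[3]])
  expect_equal(diff(range(sim$truth$distance_px)), 0)
  # rest composite equals the background where sprites were cut from it
  expect_equal(sim$video$frames[[1]], sc$background, tolerance = 1e-12)
})

test_that("ground truth is internally consistent and follows the waveform", {
  sim <- tiny_simulation(noise_frac = 0, n_frames = 60, amplitude_px = 1.5,
                         frequency_hz = 2)
  tr <- sim$truth
  expect_equal(nrow(tr), 60L)
  d <- sqrt((tr$left_x - tr$right_x)^2 + (tr$left_y - tr$right_y)^2)
  expect_equal(d, tr$distance_px, tolerance = 1e-12)
  D0 <- tr$distance_px[1]
  s <- 1.5 * sin(2 * pi * 2 * tr$time_s)
  expect_equal(tr$distance_px, D0 - 2 * s, tolerance = 1e-12)
  # 2 Hz at 100 fps: the waveform repeats every 50 frames
  expect_equal(tr$distance_px[1], tr$distance_px[51], tolerance = 1e-12)
})

test_that("sprites leaving the frame and invalid noise levels are rejected", {
  sc <- tiny_scene()
  expect_error(
    simulation_spec(sc$background, sc$sprites, sc$pillar_centers,
                    amplitude_px = 30, n_frames = 3),
    "excursion exceeds frame"
  )
  expect_error(
    simulation_spec(sc$background, sc$sprites, sc$pillar_centers,
                    noise_frac = 0.3),
    "noise_frac"
  )
})

test_that("MAE and MSE follow their definitions", {
  expect_equal(score_tracker(1:10, 1:10)$mae, 0)
  expect_equal(score_tracker(1:10, 1:10)$mse, 0)
  # alternating +/- 0.3 residuals (already zero-mean after de-meaning)
  truth <- rep(100, 10)
  est <- 100 + rep(c(0.3, -0.3), 5)
  st <- score_tracker(est, truth)
  expect_equal(st$mae, 0.3)
  expect_equal(st$mse, 0.09)
  expect_equal(st$n, 10L)
  # brute-force oracle on random residuals
  set.seed(31)
  x <- rnorm(1000, 50, 2)
  y <- x + rnorm(1000, 0, 0.4)
  st2 <- score_tracker(y, x)
  xd <- x - mean(x)
  yd <- y - mean(y)
  mae_ref <- 0
  mse_ref <- 0
  for (i in seq_along(x)) {
    mae_ref <- mae_ref + abs(yd[i] - xd[i])
    mse_ref <- mse_ref + (yd[i] - xd[i])^2
  }
  expect_equal(st2$mae, mae_ref / 1000, tolerance = 1e-12)
  expect_equal(st2$mse, mse_ref / 1000, tolerance = 1e-12)
  expect_lte(st2$mae, max(abs(st2$residuals)))
  expect_error(score_tracker(1:5, 1:6), "length mismatch")
})

test_that("a constant offset between traces is ignored by de-meaning", {
  truth <- 100 + sin(seq(0, 6, length.out = 50))
  est <- truth + 7.3
  expect_equal(score_tracker(est, truth)$mae, 0, tolerance = 1e-12)
})

test_that("the gaussian noise model is available and differs from uniform", {
  g <- tiny_simulation(noise_frac = 0.1, seed = 2, n_frames = 2,
                       noise_model = "gaussian")
  u <- tiny_simulation(noise_frac = 0.1, seed = 2, n_frames = 2,
                       noise_model = "uniform")
  expect_false(identical(g$video$frames[[1]], u$video$frames[[1]]))
  # uniform noise is amplitude-bounded at noise_frac * dynamic range
  clean <- tiny_simulation(noise_frac = 0, seed = 2, n_frames = 2)
  dyn <- diff(range(vapply(clean$video$frames, range, numeric(2))))
  resid <- u$video$frames[[1]] - clean$video$frames[[1]]
  expect_lte(max(abs(resid)), 0.1 * dyn + 1e-12)
})

test_that("a small noise sweep has the expected shape and error ordering", {
  sc <- tiny_scene()
  spec <- simulation_spec(sc$background, sc$sprites, sc$pillar_centers,
                          n_frames = 40, amplitude_px = 1.5)
  attr(spec, "mask") <- sc$mask
  sweep <- noise_sweep(spec, noise_levels = c(0, 0.15), frequencies = 2,
                       seeds = 1, margin_px = 10)
  expect_s3_class(sweep, "eht_sweep")
  expect_equal(nrow(sweep), 2L)
  expect_named(sweep, c("noise_frac", "frequency_hz", "seed", "mae_px", "mse_px2"))
  expect_lt(sweep$mae_px[sweep$noise_frac == 0], 0.05)  # noiseless sanity floor
  expect_lte(sweep$mae_px[1], sweep$mae_px[2])
})
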