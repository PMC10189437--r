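sine_trajectory <- function(n_s = 10, fps = 100, freq = 1, amp_mm = 0.2,
                            baseline_mm = 0) {
  t <- seq(0, n_s - 1 / fps, by = 1 / fps)
  # contraction dips the displacement below its diastolic baseline
  disp <- baseline_mm - amp_mm * (sin(pi * freq * t))^2
  traj <- tibble::tibble(time_s = t, displacement_mm = disp)
  attr(traj, "fps") <- fps
  traj
}

test_that("a clean 1 Hz sine paced for 10 s yields 10 beats at 1 Hz", {
  traj <- sine_trajectory(n_s = 10, freq = 1)
  beats <- detect_beats(traj, prominence_frac = 0.3)
  expect_equal(nrow(beats), 10L)
  cal <- calibration(1, 0.01, 100)
  m <- contraction_metrics(traj, cal)
  expect_equal(nrow(m$beats), 10L)
  expect_equal(m$beat_rate, 1, tolerance = 0.01)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$n_beats, 10L)
})

test_that("a flat trajectory has no beats", {
  traj <- tibble::tibble(time_s = (0:499) / 100,
                         displacement_mm = rep(0.5, 500))
  attr(traj, "fps") <- 100
  expect_message(beats <- detect_beats(traj), "no beats")
  expect_equal(nrow(beats), 0L)
})

test_that("a half-amplitude noise spike is rejected at high prominence threshold", {
  traj <- sine_trajectory(n_s = 5, freq = 1)
  spike_at <- 101                        # at the diastolic trough after beat 1
  traj$displacement_mm[spike_at] <- traj$displacement_mm[spike_at] - 0.5 * 0.2
  all_peaks <- detect_beats(traj, prominence_frac = 0.05)
  strict <- detect_beats(traj, prominence_frac = 0.6)
  expect_gt(nrow(all_peaks), nrow(strict))
  expect_equal(nrow(strict), 5L)         # the 5 true beats survive
  expect_false(any(abs(strict$i_peak - spike_at) < 3))
})

test_that("force follows the linear-spring pillar model", {
  cal <- calibration(stiffness_mN_per_mm = 1, pixel_size_mm = 0.01, fps = 100)
  traj <- tibble::tibble(time_s = (0:9) / 100,
                         displacement_mm = c(rep(0.5, 5), rep(0.3, 5)))
  out <- force_from_displacement(traj, cal, baseline_mm = 0.5)
  expect_equal(out$force_mN[1], 0)                      # zero shortening
  expect_equal(out$force_mN[10], 1 * 0.2 / 2)           # per-pillar: k * d / 2
  tot <- force_from_displacement(traj, cal, mode = "total", baseline_mm = 0.5)
  expect_equal(tot$force_mN, 2 * out$force_mN)
})

test_that("kinetics of a triangular beat match the closed form", {
  fps <- 100
  up <- seq(0, 1, length.out = 51)        # 0 -> A over 0.5 s
  A <- 0.3
  contraction <- c(rep(0, 20), up, rev(up)[-1], rep(0, 20)) * A
  t <- (seq_along(contraction) - 1) / fps
  beat <- tibble::tibble(i_start = 21L, i_peak = 71L, i_end = 121L,
                         t_start = t[21], t_peak = t[71], t_end = t[121])
  bk <- beat_kinetics(beat, contraction, fps,
                      cal = calibration(2, 0.01, fps), mode = "per_pillar")
  expect_equal(bk$amplitude_mm, A)
  expect_equal(bk$force_mN, 2 * A / 2)
  expect_equal(bk$tc10, 0.05, tolerance = 0.01)
  expect_equal(bk$tc90, 0.45, tolerance = 0.01)
  expect_equal(bk$tr10, 0.05, tolerance = 0.01)   # symmetric beat mirrors
  expect_equal(bk$tr90, 0.45, tolerance = 0.01)
  expect_equal(bk$v_con, A / 0.5, tolerance = 0.05 * A / 0.5)
  expect_equal(bk$v_rel, A / 0.5, tolerance = 0.05 * A / 0.5)
})

test_that("kinetics of a half-sine beat match the analytic crossing times", {
  fps <- 100
  P <- 1                                   # beat duration (s)
  t <- seq(0, P, by = 1 / fps)
  A <- 0.25
  contraction <- c(rep(0, 10), A * sin(pi * t / P), rep(0, 10))
  tt <- (seq_along(contraction) - 1) / fps
  ip <- 10L + which.max(sin(pi * t / P))
  beat <- tibble::tibble(i_start = 11L, i_peak = ip,
                         i_end = 11L + length(t) - 1L,
                         t_start = tt[11], t_peak = tt[ip],
                         t_end = tt[11 + length(t) - 1])
  bk <- beat_kinetics(beat, contraction, fps)
  one_frame <- 1 / fps
  expect_equal(bk$tc10, (P / pi) * asin(0.1), tolerance = one_frame)
  expect_equal(bk$tc90, (P / pi) * asin(0.9), tolerance = one_frame)
  # symmetric beat: relaxation times mirror the contraction times
  expect_equal(bk$tr10, P / 2 - (P / pi) * asin(0.9), tolerance = one_frame)
  expect_equal(bk$tr90, P / 2 - (P / pi) * asin(0.1), tolerance = one_frame)
  expect_lte(bk$tc10, bk$tc90)
  expect_lte(bk$tr10, bk$tr90)
})

test_that("metrics are invariant to a constant displacement offset", {
  cal <- calibration(1.5, 0.01, 100)
  t1 <- sine_trajectory(n_s = 6)
  t2 <- t1
  t2$displacement_mm <- t2$displacement_mm + 0.7
  m1 <- contraction_metrics(t1, cal)
  m2 <- contraction_metrics(t2, cal)
  cols <- c("amplitude_mm", "force_mN", "tc10", "tc90", "tr10", "tr90",
            "v_con", "v_rel")
  expect_equal(m1$beats[cols], m2$beats[cols], tolerance = 1e-12)
  expect_true(all(m1$trajectory$force_mN >= 0))
})

test_that("dose-response summaries are baseline ratios", {
  df <- tibble::tibble(
    condition = rep(c("vehicle", "iso_0.01uM", "iso_10uM"), each = 3),
    force_mN = c(0.30, 0.30, 0.30, 0.36, 0.36, 0.36, 0.24, 0.24, 0.24)
  )
  out <- dose_response_summary(df, baseline = "vehicle")
  expect_equal(out$relative_force[out$condition == "iso_0.01uM"], 1.2)
  expect_equal(out$relative_force[out$condition == "vehicle"], 1)
  # scale invariance
  df2 <- df
  df2$force_mN <- df2$force_mN * 13.7
  out2 <- dose_response_summary(df2, baseline = "vehicle")
  expect_equal(out$relative_force, out2$relative_force)
  df0 <- tibble::tibble(condition = c("a", "b"), force_mN = c(0, 1))
  expect_error(dose_response_summary(df0, baseline = "a"), "zero")
})
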