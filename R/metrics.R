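#' Detect contraction beats in a displacement trajectory
#'
#' Beats are local maxima of the contraction trace (the negated
#' displacement) whose topographic prominence is at least
#' `prominence_frac` times the global amplitude range of the trace. Beat
#' boundaries are placed at the surrounding crossings of the baseline level
#' (the trace median); when two accepted beats run into each other the
#' minimum between them separates the windows.
#'
#' @param traj an `eht_trajectory` tibble (or any data frame with
#'   `time_s` and `displacement_mm` columns).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   global contraction range (default 0.3).
#' @return A tibble with one row per beat: `beat`, `i_start`, `i_peak`,
#'   `i_end` (1-based sample indices), `t_start`, `t_peak`, `t_end` (s) and
#'   `prominence` (mm). Zero rows (with a message) when no beat is found.
#' @export
detect_beats <- function(traj, prominence_frac = 0.3) {
  x <- -traj$displacement_mm          # contraction: positive during a beat
  t <- traj$time_s
  n <- length(x)
  empty <- tibble(beat = integer(), i_start = integer(), i_peak = integer(),
                  i_end = integer(), t_start = numeric(), t_peak = numeric(),
                  t_end = numeric(), prominence = numeric())
  rng <- diff(range(x))
  if (n < 3L || rng == 0) {
    inform("no beats found")
    return(empty)
  }
  # local maxima (first sample of a plateau)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L]]
  if (length(cand) == 0L) {
    inform("no beats found")
    return(empty)
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= prominence_frac * rng
  peaks <- cand[keep]
  prom <- prom[keep]
  if (length(peaks) == 0L) {
    inform("no beats found")
    return(empty)
  }
  # baseline level with a tolerance so that boundary samples exactly at the
  # median stay on the same side under constant offsets of the trace
  b <- median(x) + 1e-9 * rng
  starts <- integer(length(peaks))
  ends <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    lo <- if (k > 1L) peaks[k - 1L] else 1L
    hi <- if (k < length(peaks)) peaks[k + 1L] else n
    below <- which(x[lo:p] <= b) + lo - 1L
    starts[k] <- if (length(below) > 0L) max(below)
                 else lo + which.min(x[lo:p]) - 1L
    below <- which(x[p:hi] <= b) + p - 1L
    ends[k] <- if (length(below) > 0L) min(below)
               else p + which.min(x[p:hi]) - 1L
  }
  tibble(beat = seq_along(peaks),
         i_start = starts, i_peak = peaks, i_end = ends,
         t_start = t[starts], t_peak = t[peaks], t_end = t[ends],
         prominence = prom)
}

peak_prominence <- function(x, i) {
  # topographic prominence: drop to the lowest point before reaching the
  # nearest higher ground (or the trace edge) on each side
  n <- length(x)
  left_min <- x[i]
  j <- i
  while (j > 1L && x[j - 1L] <= x[i]) {
    j <- j - 1L
    left_min <- min(left_min, x[j])
  }
  right_min <- x[i]
  j <- i
  while (j < n && x[j + 1L] <= x[i]) {
    j <- j + 1L
    right_min <- min(right_min, x[j])
  }
  x[i] - max(left_min, right_min)
}

#' Contractile force from the displacement trajectory
#'
#' The pillar is a linear spring: force is stiffness times tip deflection.
#' The trajectory measures the total inter-pillar shortening
#' `contraction = baseline - displacement`; in the default `per_pillar`
#' mode half of it is attributed to each tip, `F = k * contraction / 2`,
#' while `total` reports `F = k * contraction`. The baseline is the median
#' displacement (a robust diastolic estimate) unless supplied.
#'
#' @param traj an `eht_trajectory` (or data frame with `displacement_mm`).
#' @param cal an [calibration()] object (stiffness used).
#' @param mode `"per_pillar"` (default) or `"total"`.
#' @param baseline_mm optional explicit diastolic baseline displacement.
#' @return The input with columns `contraction_mm` and `force_mN` added.
#' @export
force_from_displacement <- function(traj, cal, mode = c("per_pillar", "total"),
                                    baseline_mm = NULL) {
  mode <- match.arg(mode)
  baseline <- baseline_mm %||% median(traj$displacement_mm)
  contraction <- pmax(0, baseline - traj$displacement_mm)
  scale <- if (mode == "per_pillar") 0.5 else 1
  traj$contraction_mm <- contraction
  traj$force_mN <- cal$stiffness_mN_per_mm * contraction * scale
  traj
}

#' Per-beat contraction kinetics
#'
#' Given one beat window on a contraction trace, computes the amplitude,
#' peak force, 10%/90% contraction and relaxation times and the peak
#' contraction/relaxation velocities. Contraction times (TC10/TC90) are
#' the first crossings of 10%/90% of the amplitude measured from the beat
#' start; relaxation times (TR10/TR90) are the first times the trace falls
#' 10%/90% below the peak, measured from the peak. Crossings are located by
#' linear interpolation between samples. Velocities are the extrema of the
#' 5-point-smoothed central-difference derivative of the contraction trace
#' over the rising and falling phases.
#'
#' @param beat one-row beat window (as returned by [detect_beats()]).
#' @param contraction_mm numeric vector, the full contraction trace (mm).
#' @param fps sampling rate (Hz).
#' @param cal an [calibration()] for the force conversion.
#' @param mode force attribution mode, as in [force_from_displacement()].
#' @return A one-row tibble with `t_start`, `t_peak`, `t_end`,
#'   `baseline_mm`, `amplitude_mm`, `force_mN`, `tc10`, `tc90`, `tr10`,
#'   `tr90`, `v_con`, `v_rel`.
#' @export
beat_kinetics <- function(beat, contraction_mm, fps, cal = NULL,
                          mode = c("per_pillar", "total")) {
  mode <- match.arg(mode)
  i0 <- beat$i_start
  ip <- beat$i_peak
  i1 <- beat$i_end
  seg <- contraction_mm[i0:i1] - contraction_mm[i0]
  # beat-local contraction, zero at beat start
  pk <- ip - i0 + 1L
  amp <- seg[pk]
  if (!is.finite(amp) || amp <= 0) {
    return(NULL)
  }
  cross_up <- function(level) {
    idx <- which(seg[1:pk] >= level)
    if (length(idx) == 0L) return(NA_real_)
    i <- idx[1]
    if (i == 1L) return(0)
    frac <- (level - seg[i - 1L]) / (seg[i] - seg[i - 1L])
    (i - 2L + frac) / fps
  }
  cross_down <- function(level) {
    idx <- which(seg[pk:length(seg)] <= level)
    if (length(idx) == 0L) return(NA_real_)
    i <- idx[1]
    if (i == 1L) return(0)
    j <- pk + i - 2L       # sample before the crossing
    frac <- (seg[j] - level) / (seg[j] - seg[j + 1L])
    (i - 2L + frac) / fps
  }
  tc10 <- cross_up(0.1 * amp)
  tc90 <- cross_up(0.9 * amp)
  tr10 <- cross_down(amp - 0.1 * amp)
  tr90 <- cross_down(amp - 0.9 * amp)

  d <- smoothed_derivative(seg, fps)
  v_con <- max(d[1:pk], na.rm = TRUE)
  v_rel <- max(abs(d[pk:length(d)]), na.rm = TRUE)

  k <- if (!is.null(cal)) cal$stiffness_mN_per_mm else NA_real_
  scale <- if (mode == "per_pillar") 0.5 else 1
  tibble(
    t_start = beat$t_start, t_peak = beat$t_peak, t_end = beat$t_end,
    baseline_mm = contraction_mm[i0],
    amplitude_mm = amp,
    force_mN = k * amp * scale,
    tc10 = tc10, tc90 = tc90, tr10 = tr10, tr90 = tr90,
    v_con = v_con, v_rel = v_rel
  )
}

smoothed_derivative <- function(x, fps, k = 5L) {
  n <- length(x)
  xs <- stats::filter(x, rep(1 / k, k), sides = 2)
  xs <- as.numeric(xs)
  # moving average is undefined at the ends; fall back to the raw samples
  xs[is.na(xs)] <- x[is.na(xs)]
  d <- numeric(n)
  if (n >= 3L) {
    d[2:(n - 1L)] <- (xs[3:n] - xs[1:(n - 2L)]) / 2 * fps
    d[1L] <- (xs[2L] - xs[1L]) * fps
    d[n] <- (xs[n] - xs[n - 1L]) * fps
  }
  d
}

#' Full per-beat contractile analysis of a trajectory
#'
#' Detects beats, computes a per-beat diastolic baseline (the median
#' displacement of the preceding inter-beat interval), fills in each beat's
#' kinetics and aggregates the parameters across beats.
#'
#' @inheritParams detect_beats
#' @param cal an [calibration()] object.
#' @param mode force attribution mode, see [force_from_displacement()].
#' @param min_amplitude_mm beats with amplitude below this noise floor are
#'   discarded (default 0: keep all).
#' @return An object of class `eht_metrics`: list with `beats` (tibble, one
#'   row per accepted beat), `beat_rate` (Hz, beats per trace duration),
#'   `n_discarded`, and `trajectory` (the input with force columns added).
#'   [tidy()] returns the beats, [glance()] the across-beat summary.
#' @export
contraction_metrics <- function(traj, cal, prominence_frac = 0.3,
                                mode = c("per_pillar", "total"),
                                min_amplitude_mm = 0) {
  mode <- match.arg(mode)
  fps <- traj_fps(traj)
  windows <- detect_beats(traj, prominence_frac = prominence_frac)
  disp <- traj$displacement_mm
  n <- length(disp)

  beats <- list()
  n_discarded <- 0L
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    prev_end <- if (k > 1L) windows$i_end[k - 1L] else 1L
    inter <- disp[prev_end:w$i_start]
    baseline <- median(inter)
    contraction <- pmax(0, baseline - disp)
    bk <- beat_kinetics(w, contraction, fps, cal = cal, mode = mode)
    if (is.null(bk)) next
    bk$baseline_mm <- baseline
    if (bk$amplitude_mm < min_amplitude_mm) {
      n_discarded <- n_discarded + 1L
      next
    }
    beats[[length(beats) + 1L]] <- bk
  }
  beats <- if (length(beats) > 0L) dplyr::bind_rows(beats, .id = NULL) else
    beat_kinetics_empty()
  if (nrow(beats) > 0L) beats <- dplyr::mutate(beats, beat = dplyr::row_number(),
                                               .before = 1L)

  duration <- n / fps
  traj_f <- force_from_displacement(traj, cal, mode = mode)
  structure(list(
    beats = beats,
    beat_rate = if (duration > 0) nrow(beats) / duration else NA_real_,
    n_discarded = n_discarded,
    mode = mode,
    trajectory = traj_f
  ), class = "eht_metrics")
}

beat_kinetics_empty <- function() {
  tibble(t_start = numeric(), t_peak = numeric(), t_end = numeric(),
         baseline_mm = numeric(), amplitude_mm = numeric(),
         force_mN = numeric(), tc10 = numeric(), tc90 = numeric(),
         tr10 = numeric(), tr90 = numeric(), v_con = numeric(),
         v_rel = numeric())
}

#' @export
print.eht_metrics <- function(x, ...) {
  cat(sprintf("<eht_metrics> %d beat(s) at %.3g Hz, mode = %s\n",
              nrow(x$beats), x$beat_rate, x$mode))
  if (nrow(x$beats) > 0L) {
    cat(sprintf("  mean force %.4g mN, TC90 %.3g s, TR90 %.3g s\n",
                mean(x$beats$force_mN), mean(x$beats$tc90), mean(x$beats$tr90)))
  }
  invisible(x)
}

#' @rdname contraction_metrics
#' @param x an `eht_metrics` object.
#' @param ... unused.
#' @method tidy eht_metrics
#' @export
tidy.eht_metrics <- function(x, ...) {
  x$beats
}

#' @rdname contraction_metrics
#' @method glance eht_metrics
#' @export
glance.eht_metrics <- function(x, ...) {
  b <- x$beats
  pars <- c("amplitude_mm", "force_mN", "tc10", "tc90", "tr10", "tr90",
            "v_con", "v_rel")
  out <- tibble(n_beats = nrow(b), beat_rate_hz = x$beat_rate,
                n_discarded = x$n_discarded)
  for (p in pars) {
    out[[paste0(p, "_mean")]] <- if (nrow(b) > 0L) mean(b[[p]]) else NA_real_
    out[[paste0(p, "_sd")]] <- if (nrow(b) > 1L) sd(b[[p]]) else NA_real_
  }
  out
}

#' @method autoplot eht_metrics
#' @export
autoplot.eht_metrics <- function(object, ...) {
  tr <- object$trajectory
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$force_mN)) +
    ggplot2::geom_line(colour = "#31a354") +
    ggplot2::labs(x = "time (s)", y = "force (mN)", title = "Contractile force") +
    ggplot2::theme_minimal()
  if (nrow(object$beats) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$beats$t_peak,
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' Relative force across conditions (dose-response summary)
#'
#' Divides each condition's mean force by the mean force of a designated
#' baseline condition, e.g. to express the inotropic response to a drug as
#' a relative force.
#'
#' @param data a data frame with one row per observation.
#' @param condition name of the condition column (string).
#' @param force name of the force column (string).
#' @param baseline the value of `condition` to use as baseline.
#' @return A tibble with `condition`, `mean_force`, `relative_force`
#'   (baseline row has relative force 1).
#' @export
dose_response_summary <- function(data, condition = "condition",
                                  force = "force_mN", baseline) {
  stopifnot(condition %in% names(data), force %in% names(data))
  summ <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(condition))),
    mean_force = mean(.data[[force]]), .groups = "drop"
  )
  names(summ)[1] <- "condition"
  if (!baseline %in% summ$condition) {
    abort(sprintf("baseline condition '%s' not present", baseline))
  }
  base <- summ$mean_force[summ$condition == baseline]
  if (base == 0) {
    abort("baseline mean force is zero")
  }
  dplyr::mutate(summ, relative_force = .data$mean_force / base)
}
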