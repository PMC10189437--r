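#' Track both pillars through a video
#'
#' For every frame, each pillar template (fixed from the reference frame,
#' never updated) is matched inside its search region with normalized
#' cross-correlation, the integer peak is refined to decimal coordinates,
#' and the inter-pillar distance is computed between the template anchor
#' points (the template-box centre; with a rigid template any fixed anchor
#' differs from the pillar centroid by a constant that cancels in
#' displacement). The distance in pixels is converted to a displacement in
#' millimetres by `displacement = distance_px * a - L0`, with `a` the
#' pixel size and `L0` the resting inter-pillar distance.
#'
#' Frames where either match score falls below `min_score` are flagged and
#' their positions imputed from the previous frame.
#'
#' @param video a [video_stack()].
#' @param templates list with `left` and `right` [eht_template()]s, from
#'   frame 1 of this video.
#' @param regions list with `left` and `right` [search_region()]s.
#' @param cal an [calibration()] object; its `fps`/`pixel_size_mm` override
#'   the video's when both are present.
#' @param window,tol passed to [refine_subpixel()].
#' @param min_score matches scoring below this are treated as failed
#'   (default 0.3, far below typical valid matches).
#' @param refine if `FALSE`, keep integer-pixel matches (for diagnostics of
#'   the quantization the sub-pixel stage removes).
#' @return A tibble of class `eht_trajectory` with one row per frame:
#'   `frame` (0-based), `time_s`, `left_x/left_y/left_score`,
#'   `right_x/right_y/right_score`, `distance_px`, `displacement_mm`,
#'   `flagged`. Attributes `calibration` and `fps` carry the metadata.
#' @export
track_video <- function(video, templates, regions, cal = NULL,
                        window = 7L, tol = 1e-4, min_score = 0.3,
                        refine = TRUE) {
  stopifnot(inherits(video, "video_stack"))
  fps <- if (!is.null(cal)) cal$fps else video$fps
  a <- if (!is.null(cal)) cal$pixel_size_mm else video$pixel_size_mm
  L0 <- if (!is.null(cal)) cal$rest_distance_mm else 3.2

  n <- length(video$frames)
  sides <- c("left", "right")
  anchors <- lapply(sides, function(s) {
    p <- templates[[s]]$patch
    c((ncol(p) - 1) / 2, (nrow(p) - 1) / 2)
  })
  names(anchors) <- sides

  pos <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, c("left_x", "left_y", "right_x", "right_y")))
  scr <- matrix(NA_real_, n, 2L, dimnames = list(NULL, sides))
  flagged <- logical(n)
  n_warn <- 0L

  for (i in seq_len(n)) {
    frame <- video$frames[[i]]
    for (s in sides) {
      acc <- ncc_accumulator(templates[[s]], frame, regions[[s]])
      peak <- best_integer_match(acc)
      m <- if (refine) refine_subpixel(acc, peak, window = window, tol = tol)
           else list(x = peak$x, y = peak$y, score = peak$score, flag = "ok")
      scr[i, s] <- m$score
      if (m$score < min_score && i > 1L) {
        flagged[i] <- TRUE
        pos[i, paste0(s, "_x")] <- pos[i - 1L, paste0(s, "_x")]
        pos[i, paste0(s, "_y")] <- pos[i - 1L, paste0(s, "_y")]
        n_warn <- n_warn + 1L
      } else {
        if (m$score < min_score) flagged[i] <- TRUE
        pos[i, paste0(s, "_x")] <- m$x + anchors[[s]][1]
        pos[i, paste0(s, "_y")] <- m$y + anchors[[s]][2]
      }
    }
  }
  if (n_warn > 0L) {
    warn(sprintf("%d failed match(es) below min_score = %.2f; positions imputed from previous frame",
                 n_warn, min_score))
  }

  distance_px <- sqrt((pos[, "left_x"] - pos[, "right_x"])^2 +
                      (pos[, "left_y"] - pos[, "right_y"])^2)
  traj <- tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / fps,
    left_x = pos[, "left_x"], left_y = pos[, "left_y"], left_score = scr[, "left"],
    right_x = pos[, "right_x"], right_y = pos[, "right_y"], right_score = scr[, "right"],
    distance_px = distance_px,
    displacement_mm = distance_px * a - L0,
    flagged = flagged
  )
  attr(traj, "fps") <- fps
  attr(traj, "calibration") <- cal
  class(traj) <- c("eht_trajectory", class(traj))
  traj
}

traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) {
    dt <- diff(traj$time_s)
    fps <- 1 / median(dt)
  }
  fps
}

#' @method autoplot eht_trajectory
#' @export
autoplot.eht_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$displacement_mm)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)",
                  title = "Inter-pillar displacement") +
    ggplot2::theme_minimal()
}
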