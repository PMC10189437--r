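#' Write a results folder for analyzed videos
#'
#' Writes, per video, the raw trajectory CSV (`frame, time_s, distance_px,
#' displacement_mm, force_mN`), the per-beat metrics CSV and a contraction
#' plot, plus one `summary.csv` aggregating all analyzed videos. A video
#' with zero detected beats gets a metrics CSV with headers only and is
#' flagged in the summary. Output CSVs are byte-identical across re-runs on
#' identical inputs.
#'
#' @param out_dir output directory (created if needed).
#' @param results named list, one element per video, each a list with
#'   `trajectory` (an `eht_trajectory`) and `metrics` (an `eht_metrics`).
#' @param plots write PNG contraction plots (default `TRUE`).
#' @return The summary tibble, invisibly.
#' @export
write_results <- function(out_dir, results, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create results folder '%s'", out_dir))
  }
  stopifnot(is.list(results), length(names(results)) == length(results))

  summaries <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    traj <- res$metrics$trajectory %||% res$trajectory
    cols <- intersect(c("frame", "time_s", "distance_px", "displacement_mm",
                        "contraction_mm", "force_mN", "flagged"), names(traj))
    readr::write_csv(as_tibble(traj)[, cols],
                     file.path(out_dir, paste0(nm, "_trajectory.csv")))
    beats <- tidy(res$metrics)
    readr::write_csv(beats, file.path(out_dir, paste0(nm, "_metrics.csv")))
    if (isTRUE(plots)) {
      p <- autoplot(res$metrics)
      ggplot2::ggsave(file.path(out_dir, paste0(nm, "_contraction.png")), p,
                      width = 7, height = 4, dpi = 120)
    }
    g <- glance(res$metrics)
    dplyr::bind_cols(
      tibble(video = nm,
             n_frames = nrow(traj),
             n_flagged_frames = sum(traj$flagged %||% FALSE),
             no_beats = nrow(beats) == 0L),
      g
    )
  })
  summary <- dplyr::bind_rows(summaries)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  invisible(summary)
}
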