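#' Analyze a folder of EHT videos into a results folder
#'
#' For every multi-page TIFF in `videos_dir` with a matching RGB label mask
#' (`<stem>.png` or `<stem>.tif` in `masks_dir`), runs the full pipeline:
#' template extraction from the mask and first frame, sub-pixel tracking,
#' per-beat contractile metrics, and output writing via [write_results()].
#' Videos without a mask are skipped with a logged reason; a malformed
#' calibration aborts the run.
#'
#' @param videos_dir directory of multi-page TIFF videos.
#' @param masks_dir directory of label masks (matched by file stem).
#' @param calibration an [calibration()] object or path to a calibration
#'   YAML for [read_calibration()].
#' @param out_dir results folder.
#' @param config named list of tracking options: `window`, `tol`,
#'   `min_score`, `margin_px`, `transverse_margin_px`, `prominence_frac`,
#'   `force_mode`, `plots`.
#' @return A list with `summary` (tibble written to `summary.csv`) and
#'   `log` (character vector of warnings/skips, also written to
#'   `run_log.txt`), invisibly.
#' @export
analyze_videos <- function(videos_dir, masks_dir, calibration, out_dir,
                           config = list()) {
  cal <- if (inherits(calibration, "eht_calibration")) calibration
         else read_calibration(calibration)
  cfg <- utils::modifyList(list(
    window = 7L, tol = 1e-4, min_score = 0.3, margin_px = NULL,
    transverse_margin_px = 8L, prominence_frac = 0.3,
    force_mode = "per_pillar", plots = TRUE
  ), config)

  videos <- sort(list.files(videos_dir, pattern = "\\.(tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
  if (length(videos) == 0L) {
    abort(sprintf("no videos found in '%s'", videos_dir))
  }
  log <- character(0)
  results <- list()
  skipped <- character(0)

  for (vf in videos) {
    stem <- tools::file_path_sans_ext(basename(vf))
    mask_file <- NULL
    for (ext in c(".png", ".tif", ".tiff")) {
      cand <- file.path(masks_dir, paste0(stem, ext))
      if (file.exists(cand)) {
        mask_file <- cand
        break
      }
    }
    if (is.null(mask_file)) {
      msg <- sprintf("skipped %s: no mask found", stem)
      log <- c(log, msg)
      skipped <- c(skipped, stem)
      inform(msg)
      next
    }
    res <- withCallingHandlers({
      video <- read_video(vf, fps = cal$fps, pixel_size_mm = cal$pixel_size_mm)
      mask <- read_label_mask(mask_file)
      tpl <- extract_pillar_templates(mask, video$frames[[1]])
      reg <- build_search_regions(tpl$left, tpl$right, dim(video$frames[[1]]),
                                  margin_px = cfg$margin_px,
                                  transverse_margin_px = cfg$transverse_margin_px)
      traj <- track_video(video, tpl, reg, cal, window = cfg$window,
                          tol = cfg$tol, min_score = cfg$min_score)
      metrics <- contraction_metrics(traj, cal,
                                     prominence_frac = cfg$prominence_frac,
                                     mode = cfg$force_mode)
      list(trajectory = traj, metrics = metrics,
           tissue_area_mm2 = surface_area(mask, cal$pixel_size_mm))
    }, warning = function(w) {
      log <<- c(log, sprintf("%s: %s", stem, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      log <<- c(log, sprintf("%s: %s", stem, trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    })
    results[[stem]] <- res
  }

  summary <- write_results(out_dir, results, plots = cfg$plots)
  if (length(results) > 0L) {
    summary$tissue_area_mm2 <-
      vapply(results[summary$video], `[[`, numeric(1), "tissue_area_mm2")
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  }
  if (length(skipped) > 0L) {
    readr::write_csv(tibble(video = skipped, reason = "no mask found"),
                     file.path(out_dir, "skipped.csv"))
  }
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(summary = summary, log = log, skipped = skipped))
}

#' Verify tracking precision on simulated videos
#'
#' Runs [noise_sweep()] over the configured grid and checks the sweep
#' against the tracker's precision bounds: mean MAE at most 0.1 px for
#' noise up to 20% of dynamic range and at most 0.2 px at 25%.
#'
#' @param config named list of overrides: `noise_levels`, `frequencies`,
#'   `seeds`, `n_frames`, `amplitude_px`, `fps`, plus [track_video()]
#'   options `window`, `tol`.
#' @return A list with `sweep` (the per-run tibble), `bounds` (per-level
#'   mean MAE with its applicable bound and pass flag) and `pass`
#'   (overall logical).
#' @export
verify_tracking <- function(config = list()) {
  cfg <- utils::modifyList(list(
    noise_levels = c(0.05, 0.1, 0.15, 0.2, 0.25),
    frequencies = c(1, 2),
    seeds = 1:3,
    n_frames = 300L,
    amplitude_px = 2,
    fps = 100,
    window = 7L,
    tol = 1e-4,
    margin_px = 20L
  ), config)
  spec <- default_simulation_spec(amplitude_px = cfg$amplitude_px,
                                  fps = cfg$fps, n_frames = cfg$n_frames)
  sweep <- noise_sweep(spec, noise_levels = cfg$noise_levels,
                       frequencies = cfg$frequencies, seeds = cfg$seeds,
                       window = cfg$window, tol = cfg$tol,
                       margin_px = cfg$margin_px)
  bounds <- dplyr::summarise(dplyr::group_by(sweep, .data$noise_frac),
                             mean_mae_px = mean(.data$mae_px), .groups = "drop")
  bounds$bound_px <- ifelse(bounds$noise_frac <= 0.20, 0.1, 0.2)
  bounds$pass <- bounds$mean_mae_px <= bounds$bound_px
  list(sweep = sweep, bounds = bounds, pass = all(bounds$pass))
}
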