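#' Run the full Erk-KTR reconstruction pipeline on a movie
#'
#' Chains the analysis stages: optional translational registration,
#' per-frame nucleus segmentation and annular-ring construction, cell
#' tracking by minimum-cost assignment, C/N ratio extraction with
#' normalization to the frame just prior to stimulation, and per-cell
#' kinetic model fitting.
#'
#' @param movie A [movie_stack()].
#' @param register Estimate and undo a global per-frame translation before
#'   segmentation (use when the stage drifted).
#' @param ring_width_px Cytoplasm ring width in pixels (default 5).
#' @param min_area_px Minimum nucleus area in pixels.
#' @param threshold_method,threshold Passed to [segment_nuclei()].
#' @param max_link_dist_px,max_gap Passed to [link_tracks()].
#' @param background Passed to [measure_cn()].
#' @param variant,control Passed to [fit_cells()].
#' @param min_coverage,exclude_border Passed to [fit_cells()].
#' @return List of class `ktr_result` with `movie` (registered), `offsets`
#'   (or NULL), `masks` (per-frame `cell_masks`), `tracks`, `traces`
#'   (normalized), `fits` (list of `ktr_fit`), and `fit_table`
#'   (data.frame).
#' @export
run_ktr_pipeline <- function(movie, register = FALSE, ring_width_px = 5,
                             min_area_px = 30, threshold_method = "otsu",
                             threshold = NULL, max_link_dist_px = 15,
                             max_gap = 0L, background = "median_outside",
                             variant = "auto", control = fit_control(),
                             min_coverage = 0.8, exclude_border = TRUE) {
  stopifnot(inherits(movie, "movie_stack"))
  offsets <- NULL
  if (register) {
    reg <- register_movie(movie, reference_frame = movie$stimulation_frame)
    movie <- reg$movie
    offsets <- reg$offsets
  }
  masks <- segment_movie(movie, ring_width_px = ring_width_px,
                         min_area_px = min_area_px,
                         threshold_method = threshold_method,
                         threshold = threshold)
  tracks <- link_tracks(masks, max_link_dist_px = max_link_dist_px,
                        max_gap = max_gap)
  traces <- measure_cn(movie, masks, tracks, background = background)
  traces <- normalize_traces(traces, movie$stimulation_frame)
  fits <- fit_cells(traces, variant = variant, control = control,
                    n_frames_total = dim(movie$pixels)[1],
                    min_coverage = min_coverage,
                    exclude_border = exclude_border)
  structure(list(movie = movie, offsets = offsets, masks = masks,
                 tracks = tracks, traces = traces, fits = fits,
                 fit_table = fits_to_df(fits)),
            class = "ktr_result")
}

#' @export
print.ktr_result <- function(x, ...) {
  cat(sprintf(paste0("<ktr_result> %d tracks, %d fitted cells ",
                     "(%d excluded)\n"),
              length(unique(x$tracks$track_id)),
              sum(x$fit_table$converged),
              sum(!x$fit_table$converged)))
  invisible(x)
}

#' Compare fitted parameters of a pipeline run to synthetic ground truth
#'
#' Matches tracks to truth cells by centroid proximity and reports, for
#' every converged fit with an unambiguous truth match, the true and
#' estimated kinetic parameters and their relative errors.
#'
#' @param result A `ktr_result` from [run_ktr_pipeline()].
#' @param truth The `ktr_truth` of the rendered movie.
#' @param tol_px Centroid tolerance for truth matching.
#' @return data.frame with one row per matched fitted cell: `track_id`,
#'   `cell`, `archetype`, true/estimated `k_on`, `t_on`, `R_eq` (and
#'   `k_off`, `t_off` when applicable), relative errors
#'   `rel_err_k_on`, `rel_err_t_on`, `rel_err_R_eq`, the selected and true
#'   `variant`s.
#' @export
evaluate_against_truth <- function(result, truth, tol_px = 5) {
  mt <- match_tracks_to_truth(result$tracks, truth, tol_px = tol_px)
  tab <- result$fit_table
  out <- list()
  for (i in seq_len(nrow(mt$track_cell))) {
    tc <- mt$track_cell[i, ]
    if (!isTRUE(tc$agrees) || is.na(tc$cell)) next
    row <- tab[tab$track_id == tc$track_id, ]
    if (nrow(row) != 1L || !isTRUE(row$converged)) next
    tru <- truth$params[tc$cell, ]
    out[[length(out) + 1L]] <- data.frame(
      track_id = tc$track_id, cell = tc$cell, archetype = tru$archetype,
      variant_true = tru$variant, variant_est = row$variant,
      k_on_true = tru$k_on, k_on_est = row$k_on,
      t_on_true = tru$t_on, t_on_est = row$t_on,
      R_eq_true = tru$R_eq, R_eq_est = row$R_eq,
      k_off_true = tru$k_off, k_off_est = row$k_off,
      t_off_true = tru$t_off, t_off_est = row$t_off,
      rel_err_k_on = abs(row$k_on - tru$k_on) / tru$k_on,
      rel_err_t_on = abs(row$t_on - tru$t_on) / max(tru$t_on, 1),
      rel_err_R_eq = abs(row$R_eq - tru$R_eq) / tru$R_eq)
  }
  do.call(rbind, out)
}
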