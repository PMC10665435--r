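#' Write a movie to a directory as multi-page TIFF plus YAML sidecar
#'
#' Pages are interleaved frame-major: page `(f - 1) * n_channels + c`
#' holds frame `f`, channel `c`. Intensities are stored as 16-bit samples
#' scaled by `scale` (values above `scale` are clipped); the sidecar
#' `movie.yaml` records the scale, pixel size, frame interval, stimulation
#' frame, and channel roles.
#'
#' @param movie A [movie_stack()].
#' @param dir Output directory (created if needed).
#' @param scale Full-scale intensity mapped to 65535.
#' @return Invisibly, the directory.
#' @export
write_movie <- function(movie, dir, scale = 65535) {
  stopifnot(inherits(movie, "movie_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(movie$pixels)
  pages <- vector("list", d[1] * d[2])
  for (f in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      pages[[(f - 1) * d[2] + ch]] <-
        pmin(movie$pixels[f, ch, , ] / scale, 1)
  tiff::writeTIFF(pages, file.path(dir, "movie.tif"),
                  bits.per.sample = 16L)
  yaml::write_yaml(list(
    n_frames = d[1], n_channels = d[2], height = d[3], width = d[4],
    pixel_size_um = movie$pixel_size_um,
    frame_interval_s = movie$frame_interval_s,
    stimulation_frame = movie$stimulation_frame,
    channel_roles = as.list(movie$channel_roles),
    intensity_scale = scale), file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir Directory containing `movie.tif` and `movie.yaml`.
#' @return A [movie_stack()].
#' @export
read_movie <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  pages <- tiff::readTIFF(file.path(dir, "movie.tif"), all = TRUE)
  px <- array(0, dim = c(meta$n_frames, meta$n_channels, meta$height,
                         meta$width))
  for (f in seq_len(meta$n_frames))
    for (ch in seq_len(meta$n_channels))
      px[f, ch, , ] <- pages[[(f - 1) * meta$n_channels + ch]] *
        meta$intensity_scale
  movie_stack(px, pixel_size_um = meta$pixel_size_um,
              frame_interval_s = meta$frame_interval_s,
              stimulation_frame = meta$stimulation_frame,
              channel_roles = unlist(meta$channel_roles))
}

#' Write per-frame label TIFFs and a masks manifest CSV
#'
#' Each frame's nucleus label image goes to `labels_<frame>.tif` (16-bit,
#' label values stored as `label / 65535`); the manifest CSV has one row
#' per (frame, label) with areas, centroid, and border flag.
#'
#' @param masks_list List of per-frame `cell_masks`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_masks <- function(masks_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(masks_list), function(f) {
    m <- masks_list[[f]]
    tiff::writeTIFF(m$labels / 65535,
                    file.path(dir, sprintf("labels_%04d.tif", f)),
                    bits.per.sample = 16L)
    if (nrow(m$info) == 0L) return(NULL)
    cbind(frame = f, m$info)
  }))
  path <- file.path(dir, "masks_manifest.csv")
  if (is.null(manifest))
    manifest <- data.frame(frame = integer(0), label = integer(0),
                           nucleus_area = integer(0), ring_area = integer(0),
                           centroid_y = numeric(0), centroid_x = numeric(0),
                           border = logical(0))
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a track table to CSV
#' @param tracks A `track_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Write traces to a long-format CSV
#' @param traces List of `cn_trace` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces_to_df(traces), path, row.names = FALSE)
  invisible(path)
}

#' Write kinetic fits to CSV
#' @param fits List of `ktr_fit` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(fits_to_df(fits), path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth of a synthetic movie as CSV
#'
#' Per-cell true kinetic parameters go to `truth_params.csv`; per-frame
#' true C/N values and centroids to `truth_traces.csv`.
#'
#' @param truth A `ktr_truth` object.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ktr_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$params, file.path(dir, "truth_params.csv"),
                   row.names = FALSE)
  n_frames <- dim(truth$centroids)[1]
  n_cells <- dim(truth$centroids)[2]
  long <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    data.frame(cell = i, frame = seq_len(n_frames),
               time_s = truth$times_s, cn_true = truth$cn[, i],
               centroid_y = truth$centroids[, i, 1],
               centroid_x = truth$centroids[, i, 2])
  }))
  utils::write.csv(long, file.path(dir, "truth_traces.csv"),
                   row.names = FALSE)
  invisible(dir)
}
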