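#' Construct a C/N trace from vectors
#'
#' Builds the trace container used throughout the package, for fitting
#' ratio time series measured outside the imaging pipeline (or synthesized
#' with [synthesize_traces()]).
#'
#' @param times_s Strictly increasing times in seconds relative to
#'   stimulation.
#' @param cn_raw Raw C/N values (`NA` where undefined).
#' @param cn_norm Normalized C/N values; when NULL the trace can be passed
#'   through [normalize_trace()].
#' @param track_id Integer identifier.
#' @param frame Frame indices (defaults to `seq_along(times_s)`).
#' @param border Whether the cell touches the image border.
#' @return A `cn_trace` object.
#' @export
cn_trace <- function(times_s, cn_raw, cn_norm = NULL, track_id = 1L,
                     frame = seq_along(times_s), border = FALSE) {
  stopifnot(is.numeric(times_s), length(times_s) >= 2,
            all(diff(times_s) > 0), length(cn_raw) == length(times_s))
  if (!is.null(cn_norm)) stopifnot(length(cn_norm) == length(times_s))
  structure(list(track_id = as.integer(track_id), frame = as.integer(frame),
                 times_s = times_s, cn_raw = cn_raw, cn_norm = cn_norm,
                 flags = list(border = border, n_missing = sum(is.na(cn_raw)),
                              n_bad_frames = 0L),
                 exclusion_reason = NULL),
            class = "cn_trace")
}

#' Measure raw C/N mean-intensity-ratio traces for tracked cells
#'
#' For every track and frame, the raw C/N value is the arithmetic mean of
#' the (background-subtracted) reporter channel over the cell's cytoplasm
#' ring divided by the mean over its nucleus. Frames missed by the track,
#' and frames whose nuclear mean is not strictly positive after background
#' subtraction, yield `NA` and are flagged.
#'
#' @param movie A [movie_stack()].
#' @param masks_list Per-frame `cell_masks` from [segment_movie()].
#' @param tracks A `track_table` from [link_tracks()].
#' @param background Background handling for the reporter channel:
#'   `"median_outside"` (default; per-frame median over pixels outside all
#'   nuclei and rings), `"none"`, or a single number subtracted from every
#'   frame.
#' @return List of `cn_trace` objects, one per track: `track_id`, `frame`,
#'   `times_s`, `cn_raw`, `cn_norm` (NULL until [normalize_trace()]), and
#'   `flags` (`border`, `n_missing`, `n_bad_frames`).
#' @export
measure_cn <- function(movie, masks_list, tracks,
                       background = "median_outside") {
  stopifnot(inherits(movie, "movie_stack"), is.list(masks_list))
  if (length(masks_list) != dim(movie$pixels)[1])
    stop("masks_list length must equal the number of frames")
  rep_ch <- movie$channel_roles[["reporter"]]
  times <- movie_times(movie)
  bg <- vapply(seq_along(masks_list), function(f) {
    if (identical(background, "none")) 0
    else if (is.numeric(background)) background
    else estimate_background(movie$pixels[f, rep_ch, , ], masks_list[[f]])
  }, numeric(1))
  # frame-major pass: per-(frame, label) mask means computed once
  cn_tab <- lapply(seq_along(masks_list), function(f) {
    m <- masks_list[[f]]
    if (nrow(m$info) == 0L) return(numeric(0))
    img <- movie$pixels[f, rep_ch, , ] - bg[f]
    nuc_mean <- vapply(split(img[m$labels > 0L], m$labels[m$labels > 0L]),
                       mean, numeric(1))
    ring_mean <- vapply(split(img[m$rings > 0L], m$rings[m$rings > 0L]),
                        mean, numeric(1))
    out <- rep(NA_real_, max(m$info$label))
    for (l in m$info$label) {
      nm <- nuc_mean[as.character(l)]
      rm_ <- ring_mean[as.character(l)]
      if (!is.na(nm) && !is.na(rm_) && nm > 0) out[l] <- rm_ / nm
    }
    out
  })
  lapply(split(seq_len(nrow(tracks)), tracks$track_id), function(ix) {
    rows <- tracks[ix, ]
    cn <- rep(NA_real_, nrow(rows))
    bad <- 0L
    for (k in seq_len(nrow(rows))) {
      if (is.na(rows$label[k])) next
      v <- cn_tab[[rows$frame[k]]][rows$label[k]]
      if (is.na(v)) { bad <- bad + 1L; next }
      cn[k] <- v
    }
    structure(list(track_id = rows$track_id[1], frame = rows$frame,
                   times_s = times[rows$frame], cn_raw = cn, cn_norm = NULL,
                   flags = list(border = any(rows$border %in% TRUE),
                                n_missing = sum(is.na(rows$label)),
                                n_bad_frames = bad),
                   exclusion_reason = NULL),
              class = "cn_trace")
  })
}

#' Normalize a raw C/N trace to the frame just prior to stimulation
#'
#' Divides the raw trace by its value at the reference frame
#' `stimulation_frame - 1`, so `cn_norm` equals exactly 1 there. A trace
#' whose reference value is undefined or non-positive is excluded with an
#' explicit reason instead of being normalized.
#'
#' @param trace A `cn_trace` from [measure_cn()].
#' @param stimulation_frame 1-based index of the first post-stimulation
#'   frame.
#' @return The trace with `cn_norm` filled in, or with
#'   `exclusion_reason` set ( `"reference_frame_not_in_track"` /
#'   `"reference_value_undefined_or_nonpositive"`).
#' @export
normalize_trace <- function(trace, stimulation_frame) {
  stopifnot(inherits(trace, "cn_trace"))
  ref_frame <- stimulation_frame - 1L
  k <- match(ref_frame, trace$frame)
  if (is.na(k)) {
    trace$exclusion_reason <- "reference_frame_not_in_track"
    return(trace)
  }
  ref <- trace$cn_raw[k]
  if (is.na(ref) || ref <= 0) {
    trace$exclusion_reason <- "reference_value_undefined_or_nonpositive"
    return(trace)
  }
  trace$cn_norm <- trace$cn_raw / ref
  trace$cn_norm[k] <- 1
  trace
}

#' Normalize a list of traces
#'
#' @param traces List of `cn_trace` objects.
#' @param stimulation_frame 1-based index of the first post-stimulation
#'   frame.
#' @return List of traces, each passed through [normalize_trace()].
#' @export
normalize_traces <- function(traces, stimulation_frame) {
  lapply(traces, normalize_trace, stimulation_frame = stimulation_frame)
}

#' @export
print.cn_trace <- function(x, ...) {
  cat(sprintf("<cn_trace> track %d: %d frames, %d defined C/N values%s\n",
              x$track_id, length(x$frame), sum(!is.na(x$cn_raw)),
              if (!is.null(x$exclusion_reason))
                paste0(" [excluded: ", x$exclusion_reason, "]") else ""))
  invisible(x)
}

#' Long-format data.frame of a list of C/N traces
#'
#' @param traces List of `cn_trace` objects.
#' @return data.frame with columns `track_id`, `frame`, `time_s`, `cn_raw`,
#'   `cn_norm`, `border`, `excluded`.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(track_id = tr$track_id, frame = tr$frame,
               time_s = tr$times_s, cn_raw = tr$cn_raw,
               cn_norm = if (is.null(tr$cn_norm)) NA_real_ else tr$cn_norm,
               border = tr$flags$border,
               excluded = if (is.null(tr$exclusion_reason)) ""
                          else tr$exclusion_reason)
  }))
}
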