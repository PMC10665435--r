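#' Cyclically shift a matrix
#'
#' Rolls rows down by `dy` and columns right by `dx` (negative values roll
#' the other way), wrapping around the edges.
#'
#' @param m Numeric matrix.
#' @param dy,dx Integer shifts.
#' @return Shifted matrix of the same dimensions.
#' @export
roll_matrix <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- ((seq_len(H) - 1 - dy) %% H) + 1
  ci <- ((seq_len(W) - 1 - dx) %% W) + 1
  m[ri, ci, drop = FALSE]
}

#' Estimate the integer translation between a frame and a reference
#'
#' Finds the cyclic integer shift `(dy, dx)` maximizing the
#' cross-correlation (computed via FFT) such that the frame equals the
#' reference shifted by `(dy, dx)`; the returned `shifted` frame is the
#' input rolled back by that offset, i.e. aligned to the reference.
#'
#' Degenerate inputs (constant frames, or an essentially flat correlation
#' surface) return a zero offset with a warning.
#'
#' @param frame,reference Numeric matrices of identical dimensions.
#' @return List with `offset` (`c(dy, dx)`, signed, wrapped to the smaller
#'   magnitude) and `shifted` (the aligned frame).
#' @export
register_translation <- function(frame, reference) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            all(dim(frame) == dim(reference)))
  H <- nrow(frame); W <- ncol(frame)
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0) {
    warning("degenerate (constant) frame: returning zero offset")
    return(list(offset = c(dy = 0L, dx = 0L), shifted = frame))
  }
  f1 <- stats::fft(reference - mean(reference))
  f2 <- stats::fft(frame - mean(frame))
  cc <- Re(stats::fft(Conj(f1) * f2, inverse = TRUE)) / (H * W)
  if (diff(range(cc)) <= 1e-9 * max(abs(cc), 1)) {
    warning("degenerate correlation surface: returning zero offset")
    return(list(offset = c(dy = 0L, dx = 0L), shifted = frame))
  }
  idx <- which.max(cc)
  dy <- (idx - 1) %% H
  dx <- (idx - 1) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  list(offset = c(dy = as.integer(dy), dx = as.integer(dx)),
       shifted = roll_matrix(frame, -dy, -dx))
}

#' Register all frames of a movie to a reference frame
#'
#' Estimates the translation of each frame's nuclear-dye channel against
#' the reference frame and applies the correcting shift identically to
#' both channels.
#'
#' @param movie A [movie_stack()].
#' @param reference_frame 1-based index of the reference frame.
#' @return List with `movie` (registered) and `offsets` (frames x 2 matrix
#'   of estimated `(dy, dx)` shifts).
#' @export
register_movie <- function(movie, reference_frame = 1L) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$pixels)
  dye <- movie$channel_roles[["nuclear_dye"]]
  ref <- movie$pixels[reference_frame, dye, , ]
  offsets <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  out <- movie$pixels
  for (f in seq_len(d[1])) {
    if (f == reference_frame) next
    reg <- register_translation(movie$pixels[f, dye, , ], ref)
    offsets[f, ] <- reg$offset
    if (any(reg$offset != 0))
      for (ch in seq_len(d[2]))
        out[f, ch, , ] <- roll_matrix(movie$pixels[f, ch, , ],
                                      -reg$offset[1], -reg$offset[2])
  }
  movie$pixels <- out
  list(movie = movie, offsets = offsets)
}

#' Subtract a scalar background from a frame
#'
#' `method = "constant"` subtracts `value`; `method = "percentile"`
#' subtracts the `value`-th percentile of the frame (value in \[0, 100\]).
#' The result is clipped at zero.
#'
#' @param frame Non-negative numeric matrix.
#' @param method `"percentile"` or `"constant"`.
#' @param value Percentile (0-100) or constant to subtract.
#' @return Background-subtracted, non-negative matrix.
#' @export
subtract_background <- function(frame, method = c("percentile", "constant"),
                                value) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame), is.numeric(value), length(value) == 1L)
  b <- if (method == "constant") value else {
    if (value < 0 || value > 100)
      stop("percentile must lie in [0, 100]")
    stats::quantile(frame, value / 100, names = FALSE)
  }
  pmax(frame - b, 0)
}

#' Estimate the background level of a frame outside given masks
#'
#' Median intensity over pixels not covered by any nucleus or ring; the
#' median of Gaussian noise about a flat background is an unbiased
#' estimate of that background.
#'
#' @param frame Numeric matrix.
#' @param masks A `cell_masks` object (see [make_cytoplasm_rings()]), or
#'   NULL to use the whole frame.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(frame, masks = NULL) {
  if (is.null(masks)) return(stats::median(frame))
  free <- masks$labels == 0L & masks$rings == 0L
  if (!any(free)) return(stats::median(frame))
  stats::median(frame[free])
}

#' Segment nuclei from a nuclear-dye frame
#'
#' Thresholds the frame (Otsu or fixed threshold), labels 4-connected
#' foreground components, fills holes, removes components smaller than
#' `min_area_px`, and relabels survivors 1..n in raster (column-major)
#' order of their first pixel.
#'
#' @param dye_frame Numeric matrix (background subtraction beforehand is
#'   optional; thresholding is shift-covariant for the constant method).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold intensity when `threshold_method = "fixed"`.
#' @param min_area_px Minimum component area in pixels.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dye_frame, threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_area_px = 30) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(dye_frame), min_area_px >= 1)
  rng <- range(dye_frame)
  if (threshold_method == "otsu") {
    if (rng[1] == rng[2]) return(matrix(0L, nrow(dye_frame), ncol(dye_frame)))
    threshold <- EBImage::otsu(EBImage::Image(dye_frame), range = rng)
  } else if (is.null(threshold)) {
    stop("threshold must be given for threshold_method = 'fixed'")
  }
  mask <- dye_frame > threshold
  if (!any(mask)) return(matrix(0L, nrow(dye_frame), ncol(dye_frame)))
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::fillHull(lab)
  lab <- matrix(as.integer(round(lab)), nrow(dye_frame))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) return(matrix(0L, nrow(dye_frame), ncol(dye_frame)))
  # relabel 1..n by raster (column-major) order of each component's first px
  first_px <- vapply(keep, function(l) which(lab == l)[1], numeric(1))
  keep <- keep[order(first_px)]
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(dye_frame), ncol(dye_frame))
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

# Disjoint cytoplasm rings from a nucleus label image. For every non-nucleus
# pixel within `ring_width` (exact Euclidean distance to the nearest pixel of
# some nucleus) the pixel joins the ring of its nearest nucleus; exact
# distance ties go to the lower label. Distances are computed per label on a
# cropped window with EBImage's exact Euclidean distance transform.
rings_from_labels <- function(labels, ring_width) {
  stopifnot(is.matrix(labels))
  if (ring_width < 1) stop("ring_width_px must be >= 1")
  H <- nrow(labels); W <- ncol(labels)
  rings <- matrix(0L, H, W)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(rings)
  bestd <- matrix(Inf, H, W)
  pad <- ceiling(ring_width) + 1L
  for (l in ids) {
    idx <- which(labels == l, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(H, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(W, max(idx[, 2]) + pad)
    sub <- labels[r0:r1, c0:c1] == l
    d <- as.matrix(EBImage::distmap(1 - sub, metric = "euclidean"))
    sel <- d > 0 & d <= ring_width
    gd <- bestd[r0:r1, c0:c1]
    upd <- sel & d < gd
    if (any(upd)) {
      gd[upd] <- d[upd]
      bestd[r0:r1, c0:c1] <- gd
      gr <- rings[r0:r1, c0:c1]
      gr[upd] <- l
      rings[r0:r1, c0:c1] <- gr
    }
  }
  rings[labels > 0L] <- 0L
  rings
}

#' Construct disjoint annular cytoplasm rings around segmented nuclei
#'
#' The cytoplasmic region of each cell is the set of non-nucleus pixels
#' whose exact Euclidean distance to that cell's nucleus is at most
#' `ring_width_px` (default 5 px, ~1.1 um at 0.22 um/px). Pixels claimed by
#' more than one nucleus go to the nearest one; exact-distance ties go to
#' the lower label, so rings are pairwise disjoint and never overlap any
#' nucleus.
#'
#' @param label_image Integer nucleus label matrix (0 = background), e.g.
#'   from [segment_nuclei()].
#' @param ring_width_px Ring width in pixels (>= 1).
#' @return An object of class `cell_masks`: list with `labels` (the input),
#'   `rings` (ring label matrix, disjoint from all nuclei), `ring_width_px`,
#'   and `info`, a data.frame with one row per label: `label`,
#'   `nucleus_area`, `ring_area`, `centroid_y`, `centroid_x`, and `border`
#'   (TRUE when the nucleus lies within `ring_width_px` of the image edge,
#'   so its ring may be truncated).
#' @export
make_cytoplasm_rings <- function(label_image, ring_width_px = 5) {
  stopifnot(is.matrix(label_image))
  if (ring_width_px < 1) stop("ring_width_px must be >= 1")
  labels <- matrix(as.integer(label_image), nrow(label_image))
  rings <- rings_from_labels(labels, ring_width_px)
  ids <- sort(unique(labels[labels > 0L]))
  H <- nrow(labels); W <- ncol(labels)
  info <- do.call(rbind, lapply(ids, function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    data.frame(label = l, nucleus_area = nrow(idx),
               ring_area = sum(rings == l),
               centroid_y = mean(idx[, 1]), centroid_x = mean(idx[, 2]),
               border = min(idx[, 1]) <= ring_width_px ||
                 min(idx[, 2]) <= ring_width_px ||
                 max(idx[, 1]) > H - ring_width_px ||
                 max(idx[, 2]) > W - ring_width_px)
  }))
  if (is.null(info))
    info <- data.frame(label = integer(0), nucleus_area = integer(0),
                       ring_area = integer(0), centroid_y = numeric(0),
                       centroid_x = numeric(0), border = logical(0))
  structure(list(labels = labels, rings = rings,
                 ring_width_px = ring_width_px, info = info),
            class = "cell_masks")
}

#' Segment every frame of a movie into nuclei and cytoplasm rings
#'
#' Applies [segment_nuclei()] and [make_cytoplasm_rings()] to the
#' nuclear-dye channel of each frame.
#'
#' @param movie A [movie_stack()].
#' @param ring_width_px Ring width in pixels.
#' @param min_area_px Minimum nucleus area in pixels.
#' @param threshold_method,threshold Passed to [segment_nuclei()].
#' @return List of `cell_masks`, one per frame.
#' @export
segment_movie <- function(movie, ring_width_px = 5, min_area_px = 30,
                          threshold_method = "otsu", threshold = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  dye <- movie$channel_roles[["nuclear_dye"]]
  lapply(seq_len(dim(movie$pixels)[1]), function(f) {
    lab <- segment_nuclei(movie$pixels[f, dye, , ],
                          threshold_method = threshold_method,
                          threshold = threshold, min_area_px = min_area_px)
    make_cytoplasm_rings(lab, ring_width_px)
  })
}
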