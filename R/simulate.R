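#' Population specification for the synthetic-cell generator
#'
#' Describes a population of simulated cells as a mixture of three kinetic
#' archetypes mirroring the in-vitro cell states compared by the pipeline:
#' \describe{
#'   \item{young}{fast, strong monotone response (large `k_on`, short `t_on`,
#'     high `R_eq`);}
#'   \item{mid_old}{slower, weaker monotone response;}
#'   \item{old}{transient response that recovers toward baseline, carrying
#'     the extra recovery parameters `k_off` and `t_off`.}
#' }
#' Per-archetype parameters are drawn uniformly from the ranges in
#' `param_dists` (each range a length-2 numeric `c(lo, hi)`).
#'
#' @param n_cells Number of cells to simulate.
#' @param archetype_mix Named proportions over `young`, `mid_old`, `old`;
#'   must lie in \[0, 1\] and sum to 1 (tolerance 1e-9). Archetypes absent
#'   from the names get proportion 0.
#' @param param_dists Named list of per-archetype sampling ranges. Defaults
#'   give a fast/high response for young cells, a slower/lower one for
#'   mid-old cells, and a transient (recovering) response for old cells,
#'   all within the 30-min observation window.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells,
                            archetype_mix = c(young = 1/3, mid_old = 1/3,
                                              old = 1/3),
                            param_dists = default_param_dists(),
                            seed = 1L) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 0,
            n_cells == round(n_cells))
  arch <- c("young", "mid_old", "old")
  if (is.null(names(archetype_mix)) || !all(names(archetype_mix) %in% arch))
    stop("archetype_mix must be named with a subset of: ",
         paste(arch, collapse = ", "))
  mix <- stats::setNames(numeric(3), arch)
  mix[names(archetype_mix)] <- archetype_mix
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9)
    stop("archetype_mix proportions must lie in [0,1] and sum to 1")
  for (a in arch[mix > 0]) {
    pd <- param_dists[[a]]
    if (is.null(pd)) stop("param_dists missing archetype: ", a)
    need <- c("k_on", "t_on", "R_eq", if (a == "old") c("k_off", "t_off"))
    for (nm in need) {
      rg <- pd[[nm]]
      if (is.null(rg) || length(rg) != 2L || any(!is.finite(rg)) ||
          rg[1] > rg[2])
        stop("param_dists$", a, "$", nm, " must be a finite range c(lo, hi)")
      if (nm %in% c("k_on", "k_off") && rg[1] <= 0)
        stop("rate ranges must be strictly positive (", a, "$", nm, ")")
      if (nm %in% c("t_on", "R_eq") && rg[1] < 0)
        stop(a, "$", nm, " range must be non-negative")
    }
    if (a == "old" && pd$t_off[1] <= pd$t_on[2])
      stop("old$t_off range must lie strictly above the t_on range")
  }
  structure(list(n_cells = as.integer(n_cells), archetype_mix = mix,
                 param_dists = param_dists, seed = as.integer(seed)),
            class = "population_spec")
}

#' Default per-archetype kinetic parameter ranges
#'
#' Rates in 1/s, times in s, `R_eq` dimensionless. Chosen so that responses
#' develop and (for old cells) visibly recover within a 30-minute movie
#' sampled every 15 s: young cells respond within 1-2 min and plateau at
#' 2-3.5x baseline, mid-old cells more slowly and lower, and old cells rise
#' like mid-old cells but switch off at 5-12 min and relax back toward
#' baseline.
#'
#' @return Named list of archetype parameter ranges.
#' @export
default_param_dists <- function() {
  list(
    young   = list(k_on = c(0.015, 0.05), t_on = c(30, 90),
                   R_eq = c(2.0, 3.5)),
    mid_old = list(k_on = c(0.005, 0.02), t_on = c(60, 150),
                   R_eq = c(1.5, 2.5)),
    old     = list(k_on = c(0.005, 0.02), t_on = c(60, 150),
                   R_eq = c(1.8, 3.0), k_off = c(0.002, 0.01),
                   t_off = c(300, 700))
  )
}

#' Draw per-cell true kinetic parameters from a population specification
#'
#' Each cell gets an archetype sampled from `archetype_mix` and kinetic
#' parameters drawn uniformly from that archetype's ranges; old-archetype
#' cells carry the recovery-model parameters (`k_off`, `t_off`), others NA.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return A data.frame with one row per cell: `cell`, `archetype`,
#'   `variant`, `k_on`, `t_on`, `R_eq`, `k_off`, `t_off`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_cells
  withr::with_seed(spec$seed, {
    arch <- if (n > 0)
      sample(names(spec$archetype_mix), n, replace = TRUE,
             prob = spec$archetype_mix)
    else character(0)
    runif_rg <- function(rg) stats::runif(1, rg[1], rg[2])
    if (n == 0L)
      return(data.frame(cell = integer(0), archetype = character(0),
                        variant = character(0), k_on = numeric(0),
                        t_on = numeric(0), R_eq = numeric(0),
                        k_off = numeric(0), t_off = numeric(0)))
    rows <- lapply(seq_len(n), function(i) {
      pd <- spec$param_dists[[arch[i]]]
      old <- arch[i] == "old"
      data.frame(cell = i, archetype = arch[i],
                 variant = if (old) "recovery" else "monotone",
                 k_on = runif_rg(pd$k_on), t_on = runif_rg(pd$t_on),
                 R_eq = runif_rg(pd$R_eq),
                 k_off = if (old) runif_rg(pd$k_off) else NA_real_,
                 t_off = if (old) runif_rg(pd$t_off) else NA_real_)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Noiseless C/N time series for a set of true kinetic parameter sets
#'
#' Evaluates each cell's generating model at the supplied times. Times are
#' seconds relative to stimulation and must be strictly increasing with at
#' least one pre-stimulation time (t < 0); pre-stimulation values are
#' exactly 1 by construction of the models.
#'
#' @param params A data.frame as returned by [sample_population()] (or any
#'   data.frame with columns `variant`, `k_on`, `t_on`, `R_eq` and, for
#'   recovery rows, `k_off`, `t_off`).
#' @param times_s Strictly increasing numeric vector of times (s).
#' @return Numeric matrix, `length(times_s)` rows x `nrow(params)` columns.
#' @export
synthesize_traces <- function(params, times_s) {
  stopifnot(is.data.frame(params), is.numeric(times_s), length(times_s) >= 2)
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (!any(times_s < 0))
    stop("times_s must include at least one pre-stimulation time (t < 0)")
  out <- vapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    kp <- ktr_params(p$variant, k_on = p$k_on, t_on = p$t_on, R_eq = p$R_eq,
                     k_off = if (p$variant == "recovery") p$k_off,
                     t_off = if (p$variant == "recovery") p$t_off)
    eval_kinetic(kp, times_s)
  }, numeric(length(times_s)))
  matrix(out, nrow = length(times_s), ncol = nrow(params))
}

#' Imaging specification for the synthetic movie renderer
#'
#' Defaults follow the study acquisition schedule (one frame every 15 s for
#' 30 min after serum stimulation) plus a short pre-stimulation baseline,
#' and a pixel size of 0.22 um so that a 5-pixel annular ring is ~1.1 um
#' wide.
#'
#' @param frame_interval_s Frame interval (s).
#' @param duration_s Post-stimulation duration (s); the movie has
#'   `duration_s / frame_interval_s + 1` post-stimulation frames (t = 0 at
#'   the stimulation frame).
#' @param n_prestim_frames Number of pre-stimulation baseline frames (>= 1;
#'   the last of them is the normalization reference).
#' @param image_size `c(H, W)` in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param nucleus_radius_px Nucleus radius (px); nuclei are rendered as hard
#'   (non-anti-aliased) disks so pixel-count oracles are exact.
#' @param ring_width_px Width of the cytoplasmic annular ring used for
#'   rendering reporter intensities and for the generation-time separation
#'   constraint (centers at least `2 * (nucleus_radius_px + ring_width_px)`
#'   apart).
#' @param dye_level Nuclear-dye intensity above background on nuclei.
#' @param reporter_nucleus_level Reporter mean intensity above background in
#'   the nucleus; the ring is rendered at `reporter_nucleus_level * C/N` so
#'   that only the ratio is meaningful.
#' @param background_level Additive background in both channels.
#' @param noise_sd SD of additive Gaussian pixel noise (`noise_model =
#'   "gaussian"`); ignored for `"poisson"`, where each pixel is a Poisson
#'   draw with mean equal to its noiseless value.
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param motion_sd_px Per-frame SD of each cell's isotropic random-walk
#'   step (px).
#' @param global_drift_px `c(dy, dx)` deterministic per-frame drift applied
#'   to all cells (for registration tests).
#' @param on_overlap Collision policy when motion would bring two nuclei
#'   into contact: `"reject_step"` (default) resamples the offending
#'   random-walk step, keeping the cell in place after 20 failed
#'   proposals; `"error"` raises instead.
#' @param seed Integer seed controlling placement, motion, and noise.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(frame_interval_s = 15, duration_s = 1800,
                         n_prestim_frames = 4, image_size = c(256, 256),
                         pixel_size_um = 0.22, nucleus_radius_px = 8,
                         ring_width_px = 5, dye_level = 2000,
                         reporter_nucleus_level = 500,
                         background_level = 100, noise_sd = 0,
                         noise_model = c("gaussian", "poisson"),
                         motion_sd_px = 0, global_drift_px = c(0, 0),
                         on_overlap = c("reject_step", "error"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  on_overlap <- match.arg(on_overlap)
  stopifnot(frame_interval_s > 0, duration_s > 0,
            n_prestim_frames >= 1, length(image_size) == 2L,
            all(image_size >= 16), pixel_size_um > 0,
            nucleus_radius_px >= 2, ring_width_px >= 1,
            dye_level > 0, reporter_nucleus_level > 0,
            background_level >= 0, noise_sd >= 0, motion_sd_px >= 0,
            length(global_drift_px) == 2L)
  n_post <- duration_s / frame_interval_s
  if (n_post < 1) stop("duration_s / frame_interval_s must yield >= 2 frames")
  structure(list(frame_interval_s = frame_interval_s,
                 duration_s = duration_s,
                 n_prestim_frames = as.integer(n_prestim_frames),
                 image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 nucleus_radius_px = nucleus_radius_px,
                 ring_width_px = ring_width_px,
                 dye_level = dye_level,
                 reporter_nucleus_level = reporter_nucleus_level,
                 background_level = background_level,
                 noise_sd = noise_sd, noise_model = noise_model,
                 motion_sd_px = motion_sd_px,
                 global_drift_px = as.numeric(global_drift_px),
                 on_overlap = on_overlap, seed = as.integer(seed)),
            class = "imaging_spec")
}

#' Frame times of an imaging specification
#'
#' Seconds relative to stimulation; frame `n_prestim_frames + 1` is the
#' stimulation frame (t = 0).
#'
#' @param imaging An [imaging_spec()].
#' @return Numeric vector of length `n_prestim_frames + duration_s /
#'   frame_interval_s + 1`.
#' @export
frame_times <- function(imaging) {
  stopifnot(inherits(imaging, "imaging_spec"))
  n_post <- as.integer(round(imaging$duration_s / imaging$frame_interval_s))
  n <- imaging$n_prestim_frames + n_post + 1L
  (seq_len(n) - (imaging$n_prestim_frames + 1L)) * imaging$frame_interval_s
}

#' Two-channel time-lapse movie container
#'
#' @param pixels Numeric array `[frames, channels, H, W]`, non-negative.
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_s Frame interval (s).
#' @param stimulation_frame 1-based index of the first post-stimulation
#'   frame; must be >= 2 so that a pre-stimulation reference frame exists.
#' @param channel_roles Named integer mapping, e.g.
#'   `c(nuclear_dye = 1, reporter = 2)`; roles must map to distinct
#'   channels.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(pixels, pixel_size_um, frame_interval_s,
                        stimulation_frame,
                        channel_roles = c(nuclear_dye = 1, reporter = 2)) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L)
  if (dim(pixels)[1] < 2) stop("movie must have >= 2 frames")
  if (stimulation_frame < 2 || stimulation_frame > dim(pixels)[1])
    stop("stimulation_frame must leave >= 1 pre-stimulation frame")
  if (!all(c("nuclear_dye", "reporter") %in% names(channel_roles)))
    stop("channel_roles must name nuclear_dye and reporter")
  if (channel_roles[["nuclear_dye"]] == channel_roles[["reporter"]])
    stop("channel roles must map to distinct channels")
  if (any(channel_roles < 1) || any(channel_roles > dim(pixels)[2]))
    stop("channel_roles out of range")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 stimulation_frame = as.integer(stimulation_frame),
                 channel_roles = channel_roles),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(paste0("<movie_stack> %d frames x %d channels x %dx%d px, ",
                     "dt = %g s, stimulation frame %d\n"),
              d[1], d[2], d[3], d[4], x$frame_interval_s,
              x$stimulation_frame))
  invisible(x)
}

#' Times of a movie's frames relative to stimulation
#' @param movie A [movie_stack()].
#' @return Numeric vector (s), one entry per frame.
#' @export
movie_times <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  (seq_len(dim(movie$pixels)[1]) - movie$stimulation_frame) *
    movie$frame_interval_s
}

# Hard-disk raster: pixels whose integer center lies within radius r of
# (cy, cx). Returns an index matrix (row, col) clipped to the image.
disk_pixels <- function(cy, cx, r, H, W) {
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Number of raster pixels in a hard disk of given radius
#'
#' Counts integer pixel centers within Euclidean distance `r` of an
#' integer-centered disk; used by the analytic noise calibration.
#'
#' @param r Disk radius (px).
#' @return Integer pixel count.
#' @export
disk_pixel_count <- function(r) {
  s <- -ceiling(r):ceiling(r)
  g <- expand.grid(s, s)
  sum(g[[1]]^2 + g[[2]]^2 <= r^2)
}

#' Render a ground-truthed synthetic two-channel movie
#'
#' Renders nuclei as bright hard disks in the nuclear-dye channel and sets
#' reporter intensities so that the ring/nucleus mean-intensity ratio of
#' each cell equals its true C/N value before noise. Cells move by a seeded
#' isotropic random walk plus an optional deterministic global drift;
#' positions are re-drawn if motion would bring two nuclei into contact.
#'
#' @param params Per-cell true kinetic parameters, as from
#'   [sample_population()].
#' @param imaging An [imaging_spec()].
#' @return A list with components `movie` (a [movie_stack()]) and `truth`
#'   (class `ktr_truth`): per-cell parameters, per-frame centroids
#'   (`centroids[frame, cell, c(y, x)]`), true C/N matrix
#'   (`cn[frame, cell]`), per-frame pixel-level nucleus label images
#'   (`label_images`, label = cell index), and the frame times.
#' @export
render_movie <- function(params, imaging) {
  stopifnot(is.data.frame(params), inherits(imaging, "imaging_spec"))
  n_cells <- nrow(params)
  H <- imaging$image_size[1]; W <- imaging$image_size[2]
  r <- imaging$nucleus_radius_px
  w <- imaging$ring_width_px
  times <- frame_times(imaging)
  n_frames <- length(times)
  cn <- if (n_cells > 0) synthesize_traces(params, times) else
    matrix(0, n_frames, 0)

  margin <- r + w + 2
  min_sep <- 2 * (r + w)
  if (n_cells > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1))
    stop("image too small for nucleus radius + ring width")

  withr::with_seed(imaging$seed, {
    centroids <- array(0, dim = c(n_frames, n_cells, 2))
    if (n_cells > 0) {
      drift <- outer(seq_len(n_frames) - 1L, imaging$global_drift_px)
      pos0 <- matrix(0, n_cells, 2)
      placed <- 0L
      for (tries in seq_len(50000)) {
        cand <- c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin))
        if (placed == 0L ||
            min(sqrt(colSums((t(pos0[seq_len(placed), , drop = FALSE]) -
                              cand)^2))) >= min_sep) {
          placed <- placed + 1L
          pos0[placed, ] <- cand
          if (placed == n_cells) break
        }
      }
      if (placed < n_cells)
        stop("could not place ", n_cells, " cells at separation ",
             min_sep, " px in a ", H, "x", W, " field")
      # hard-core random walk: nucleus centers never come closer than
      # 2r + 4 px (nuclei stay separable); offending steps are resampled,
      # drift (common to all cells) does not change pairwise distances
      touch <- 2 * r + 4
      centroids[1, , ] <- pos0
      pos <- pos0
      if (imaging$motion_sd_px > 0) {
        for (f in seq_len(n_frames)[-1]) {
          for (i in seq_len(n_cells)) {
            accepted <- FALSE
            for (k in seq_len(20)) {
              cand <- pos[i, ] + stats::rnorm(2, 0, imaging$motion_sd_px)
              clear <- n_cells == 1 ||
                min(sqrt(colSums((t(pos[-i, , drop = FALSE]) - cand)^2))) >=
                  touch
              if (clear) { pos[i, ] <- cand; accepted <- TRUE; break }
              if (imaging$on_overlap == "error")
                stop("cell motion produced overlapping nuclei")
            }
            # if no proposal clears, the cell pauses this frame
          }
          centroids[f, , ] <- pos
        }
      } else {
        for (f in seq_len(n_frames)[-1]) centroids[f, , ] <- pos0
      }
      centroids[, , 1] <- centroids[, , 1] + drift[, 1]
      centroids[, , 2] <- centroids[, , 2] + drift[, 2]
    }

    pixels <- array(0, dim = c(n_frames, 2, H, W))
    label_images <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      labels <- matrix(0L, H, W)
      for (i in seq_len(n_cells)) {
        px <- disk_pixels(centroids[f, i, 1], centroids[f, i, 2], r, H, W)
        labels[px] <- i
      }
      label_images[[f]] <- labels
      rings <- rings_from_labels(labels, w)
      dye <- matrix(imaging$background_level, H, W)
      dye[labels > 0] <- dye[labels > 0] + imaging$dye_level
      rep_ch <- matrix(imaging$background_level, H, W)
      rep_ch[labels > 0] <- rep_ch[labels > 0] +
        imaging$reporter_nucleus_level
      if (n_cells > 0) {
        ring_idx <- which(rings > 0)
        if (length(ring_idx))
          rep_ch[ring_idx] <- rep_ch[ring_idx] +
            imaging$reporter_nucleus_level * cn[f, rings[ring_idx]]
      }
      if (imaging$noise_model == "gaussian" && imaging$noise_sd > 0) {
        dye <- dye + stats::rnorm(H * W, 0, imaging$noise_sd)
        rep_ch <- rep_ch + stats::rnorm(H * W, 0, imaging$noise_sd)
      } else if (imaging$noise_model == "poisson") {
        dye <- matrix(stats::rpois(H * W, dye), H, W)
        rep_ch <- matrix(stats::rpois(H * W, rep_ch), H, W)
      }
      pixels[f, 1, , ] <- pmax(dye, 0)
      pixels[f, 2, , ] <- pmax(rep_ch, 0)
    }
  })

  movie <- movie_stack(pixels, pixel_size_um = imaging$pixel_size_um,
                       frame_interval_s = imaging$frame_interval_s,
                       stimulation_frame = imaging$n_prestim_frames + 1L,
                       channel_roles = c(nuclear_dye = 1, reporter = 2))
  truth <- structure(list(params = params, centroids = centroids, cn = cn,
                          label_images = label_images, times_s = times,
                          imaging = imaging),
                     class = "ktr_truth")
  list(movie = movie, truth = truth)
}

#' Sample a population and render its movie in one call
#'
#' @param pop A [population_spec()].
#' @param imaging An [imaging_spec()].
#' @return As [render_movie()].
#' @export
simulate_movie <- function(pop, imaging) {
  render_movie(sample_population(pop), imaging)
}

#' Pixel noise SD that yields a target C/N trace noise SD
#'
#' Analytic calibration under the additive Gaussian pixel-noise model: the
#' variance of a mask mean is `noise_sd^2 / n_pixels`, and the normalized
#' C/N ratio propagates the relative variances of the ring mean, the
#' nucleus mean, and the reference-frame ratio. Discretized hard-disk pixel
#' counts are used, so the calibration is exact up to the first-order delta
#' approximation of the ratio.
#'
#' @param target_trace_sd Desired SD of `cn_norm` in normalized units.
#' @param imaging An [imaging_spec()] (geometry and reporter level).
#' @param cn_ref Representative C/N value at which to calibrate.
#' @return Pixel noise SD (intensity units).
#' @export
noise_sd_for_trace_sd <- function(target_trace_sd, imaging, cn_ref = 2) {
  stopifnot(inherits(imaging, "imaging_spec"), target_trace_sd > 0)
  r <- imaging$nucleus_radius_px; w <- imaging$ring_width_px
  n_nuc <- disk_pixel_count(r)
  n_ring <- disk_pixel_count(r + w) - n_nuc
  In <- imaging$reporter_nucleus_level
  relvar_per_sigma2 <- 1 / (n_ring * (In * cn_ref)^2) + 1 / (n_nuc * In^2) +
    1 / (n_ring * In^2) + 1 / (n_nuc * In^2)
  sqrt(target_trace_sd^2 / (cn_ref^2 * relvar_per_sigma2))
}
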