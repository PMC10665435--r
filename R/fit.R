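#' Control settings for kinetic model fitting
#'
#' @param k_on_starts Multi-start grid of initial `k_on` values (1/s).
#' @param k_off_starts Multi-start grid of initial `k_off` values (1/s).
#' @param n_ton_knots Number of equally spaced `t_on` initial values over
#'   the first half of the observed post-stimulation window.
#' @param k_min,k_max Box bounds on both rates (1/s); the defaults cover
#'   the 30-min acquisition window.
#' @param R_min,R_max Box bounds on `R_eq`.
#' @param decline_frac Variant selection: the recovery model is considered
#'   only when the trace's post-peak decline exceeds this fraction of its
#'   rise.
#' @param sse_improvement Variant selection: the recovery model must reduce
#'   the SSE by at least this fraction over the monotone fit.
#' @param flat_tol Minimum rise (normalized units) below which a trace is
#'   declared unidentifiable (no response to fit).
#' @param min_points Minimum number of defined post-stimulation points.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(k_on_starts = c(1e-3, 1e-2, 1e-1),
                        k_off_starts = c(1e-3, 1e-2),
                        n_ton_knots = 5L,
                        k_min = 1e-5, k_max = 1,
                        R_min = 0.1, R_max = 10,
                        decline_frac = 0.25, sse_improvement = 0.10,
                        flat_tol = 0.02, min_points = 8L) {
  structure(list(k_on_starts = k_on_starts, k_off_starts = k_off_starts,
                 n_ton_knots = as.integer(n_ton_knots),
                 k_min = k_min, k_max = k_max, R_min = R_min, R_max = R_max,
                 decline_frac = decline_frac,
                 sse_improvement = sse_improvement,
                 flat_tol = flat_tol, min_points = as.integer(min_points)),
            class = "fit_control")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# residual helpers; par vectors are on the natural scale
resid_monotone <- function(par, t, y) {
  r <- ifelse(t <= par[2], 1,
              par[3] + (1 - par[3]) * exp(-par[1] * (t - par[2])))
  y - r
}

resid_recovery <- function(par, t, y) {
  # par = (k_on, t_on, R_eq, k_off, dt_off); t_off = t_on + dt_off
  t_off <- par[2] + par[5]
  r <- rep(1, length(t))
  mid <- t > par[2] & t <= t_off
  r[mid] <- par[3] + (1 - par[3]) * exp(-par[1] * (t[mid] - par[2]))
  r_off <- par[3] + (1 - par[3]) * exp(-par[1] * par[5])
  late <- t > t_off
  r[late] <- 1 + (r_off - 1) * exp(-par[4] * (t[late] - t_off))
  y - r
}

run_starts <- function(fn, starts, lower, upper, t, y) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = fn, t = t, y = y,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    sse <- sum(fit$fvec^2)
    if (!is.finite(sse)) next
    if (is.null(best) || sse < best$sse * (1 - 1e-12) ||
        (abs(sse - best$sse) <= 1e-12 * max(best$sse, 1) &&
         fit$par[1] < best$par[1]))
      best <- list(par = fit$par, sse = sse)
  }
  best
}

#' Fit the piecewise exponential kinetic models to a normalized C/N trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) with multi-start initialization: `t_on` on a grid over the
#' observed times, `k_on` over `control$k_on_starts`, `R_eq` from the
#' trace's tail mean. Pre-stimulation points are included (they constrain
#' the baseline at 1). With `variant = "auto"` both models are fitted and
#' [select_variant()] chooses between them.
#'
#' Traces with no discernible rise (below `flat_tol` or within ~3 SD of the
#' point-to-point noise) are returned unfitted with an `unidentifiable`
#' flag; excluded traces (no reference frame) and traces with fewer than
#' `min_points` defined post-stimulation points are returned with an
#' exclusion reason.
#'
#' @param trace A normalized `cn_trace` (see [normalize_trace()]).
#' @param variant `"auto"`, `"monotone"`, or `"recovery"`.
#' @param control A [fit_control()].
#' @return Object of class `ktr_fit`: `track_id`, `variant`, `params`
#'   ([ktr_params()] or NULL), `sse`, `rmse`, `n_points`, `converged`,
#'   `flags`, `exclusion_reason`, and the candidate SSEs
#'   (`sse_monotone`, `sse_recovery`).
#' @export
fit_trace <- function(trace, variant = c("auto", "monotone", "recovery"),
                      control = fit_control()) {
  variant <- match.arg(variant)
  stopifnot(inherits(trace, "cn_trace"))
  base <- list(track_id = trace$track_id, variant = NA_character_,
               params = NULL, sse = NA_real_, rmse = NA_real_,
               n_points = 0L, converged = FALSE,
               flags = list(unidentifiable = FALSE,
                            border = isTRUE(trace$flags$border)),
               exclusion_reason = NULL,
               sse_monotone = NA_real_, sse_recovery = NA_real_)
  class(base) <- "ktr_fit"
  if (!is.null(trace$exclusion_reason)) {
    base$exclusion_reason <- trace$exclusion_reason
    return(base)
  }
  if (is.null(trace$cn_norm)) {
    base$exclusion_reason <- "trace_not_normalized"
    return(base)
  }
  ok <- !is.na(trace$cn_norm)
  t <- trace$times_s[ok]
  y <- trace$cn_norm[ok]
  base$n_points <- length(y)
  if (sum(t >= 0) < control$min_points) {
    base$exclusion_reason <- "too_few_points"
    return(base)
  }
  post <- t >= 0
  rise_hat <- stats::quantile(y[post], 0.9, names = FALSE) - 1
  noise_hat <- if (length(y) > 2) stats::mad(diff(y)) / sqrt(2) else 0
  if (rise_hat < max(control$flat_tol, 3 * noise_hat)) {
    base$variant <- "monotone"
    base$flags$unidentifiable <- TRUE
    base$exclusion_reason <- "flat_or_pure_noise_trace"
    return(base)
  }

  t_max <- max(t)
  tail_mean <- mean(y[t >= stats::quantile(t[post], 0.9, names = FALSE)])
  R0 <- clamp(tail_mean, control$R_min, control$R_max)
  ton_knots <- seq(0, t_max / 2, length.out = control$n_ton_knots)

  fit_mono <- NULL
  if (variant != "recovery") {
    starts <- list()
    for (k0 in control$k_on_starts)
      for (t0 in ton_knots)
        starts[[length(starts) + 1L]] <- c(k0, t0, R0)
    fit_mono <- run_starts(resid_monotone, starts,
                           lower = c(control$k_min, 0, control$R_min),
                           upper = c(control$k_max, t_max, control$R_max),
                           t = t, y = y)
  }

  fit_recov <- NULL
  if (variant != "monotone") {
    i_peak <- which.max(y)
    t_peak <- max(t[i_peak], 1)
    peak <- y[i_peak]
    Rr0 <- clamp(max(peak, 1.05), control$R_min, control$R_max)
    starts <- list()
    for (k0 in control$k_on_starts)
      for (t0 in seq(0, t_peak, length.out = 3))
        for (koff0 in control$k_off_starts)
          for (toff0 in unique(c(t_peak, (t_peak + t_max) / 2)))
            starts[[length(starts) + 1L]] <-
              c(k0, t0, Rr0, koff0, max(toff0 - t0, 1))
    fit_recov <- run_starts(resid_recovery, starts,
                            lower = c(control$k_min, 0, control$R_min,
                                      control$k_min, 1),
                            upper = c(control$k_max, t_max, control$R_max,
                                      control$k_max, t_max),
                            t = t, y = y)
  }

  mk_fit <- function(v, f) {
    out <- base
    out$variant <- v
    out$converged <- !is.null(f)
    if (is.null(f)) {
      out$exclusion_reason <- "no_start_converged"
      return(out)
    }
    out$sse <- f$sse
    out$rmse <- sqrt(f$sse / length(y))
    out$params <- if (v == "monotone")
      ktr_params("monotone", k_on = f$par[1], t_on = f$par[2],
                 R_eq = f$par[3])
    else
      ktr_params("recovery", k_on = f$par[1], t_on = f$par[2],
                 R_eq = f$par[3], k_off = f$par[4],
                 t_off = f$par[2] + f$par[5])
    out$sse_monotone <- if (!is.null(fit_mono)) fit_mono$sse else NA_real_
    out$sse_recovery <- if (!is.null(fit_recov)) fit_recov$sse else NA_real_
    out
  }

  if (variant == "monotone") return(mk_fit("monotone", fit_mono))
  if (variant == "recovery") return(mk_fit("recovery", fit_recov))
  chosen <- select_variant(trace, mk_fit("monotone", fit_mono),
                           mk_fit("recovery", fit_recov),
                           decline_frac = control$decline_frac,
                           sse_improvement = control$sse_improvement)
  if (chosen == "recovery") mk_fit("recovery", fit_recov)
  else mk_fit("monotone", fit_mono)
}

#' Choose between the monotone and recovery model for a trace
#'
#' The recovery variant is selected iff (a) the trace's post-peak decline
#' exceeds `decline_frac` of its rise, and (b) the recovery fit reduces the
#' SSE by at least `sse_improvement` relative to the monotone fit.
#' Otherwise the monotone variant is kept.
#'
#' @param trace A normalized `cn_trace`.
#' @param fit_mono,fit_recov Candidate `ktr_fit` objects.
#' @param decline_frac,sse_improvement Selection thresholds (see
#'   [fit_control()]).
#' @return `"monotone"` or `"recovery"`.
#' @export
select_variant <- function(trace, fit_mono, fit_recov,
                           decline_frac = 0.25, sse_improvement = 0.10) {
  ok <- !is.na(trace$cn_norm)
  y <- trace$cn_norm[ok]
  i_peak <- which.max(y)
  rise <- y[i_peak] - 1
  if (rise <= 0) return("monotone")
  tail_val <- mean(utils::tail(y, 3))
  decline <- y[i_peak] - tail_val
  if (decline <= decline_frac * rise) return("monotone")
  if (!isTRUE(fit_recov$converged) || !isTRUE(fit_mono$converged))
    return(if (isTRUE(fit_recov$converged)) "recovery" else "monotone")
  if (fit_recov$sse <= (1 - sse_improvement) * fit_mono$sse) "recovery"
  else "monotone"
}

#' Fit kinetic models to a list of traces with the standard filters
#'
#' Traces are fitted only when they are normalized, span at least
#' `min_coverage` of the movie's frames, and (by default) do not touch the
#' image border; others are returned with an exclusion reason.
#'
#' @param traces List of normalized `cn_trace` objects.
#' @param variant Passed to [fit_trace()].
#' @param control A [fit_control()].
#' @param n_frames_total Total frame count of the movie (inferred from the
#'   traces when NULL).
#' @param min_coverage Minimum fraction of frames with a defined C/N value.
#' @param exclude_border Drop traces from border-touching cells.
#' @return List of `ktr_fit` objects (one per trace, in input order).
#' @export
fit_cells <- function(traces, variant = "auto", control = fit_control(),
                      n_frames_total = NULL, min_coverage = 0.8,
                      exclude_border = TRUE) {
  if (is.null(n_frames_total))
    n_frames_total <- max(vapply(traces, function(tr) max(tr$frame),
                                 numeric(1)))
  lapply(traces, function(tr) {
    skip <- NULL
    if (exclude_border && isTRUE(tr$flags$border))
      skip <- "border_cell"
    else if (is.null(tr$exclusion_reason) &&
             sum(!is.na(tr$cn_raw)) < min_coverage * n_frames_total)
      skip <- "insufficient_frame_coverage"
    if (!is.null(skip)) {
      out <- list(track_id = tr$track_id, variant = NA_character_,
                  params = NULL, sse = NA_real_, rmse = NA_real_,
                  n_points = sum(!is.na(tr$cn_raw)), converged = FALSE,
                  flags = list(unidentifiable = FALSE,
                               border = isTRUE(tr$flags$border)),
                  exclusion_reason = skip,
                  sse_monotone = NA_real_, sse_recovery = NA_real_)
      class(out) <- "ktr_fit"
      return(out)
    }
    fit_trace(tr, variant = variant, control = control)
  })
}

#' @export
print.ktr_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<ktr_fit> track %s: not fitted (%s)\n", x$track_id,
                if (is.null(x$exclusion_reason)) "not converged"
                else x$exclusion_reason))
  } else {
    cat(sprintf("<ktr_fit> track %s: %s, sse %.4g, rmse %.4g (%d points)\n",
                x$track_id, x$variant, x$sse, x$rmse, x$n_points))
    print(x$params)
  }
  invisible(x)
}

#' Tabulate a list of kinetic fits
#'
#' @param fits List of `ktr_fit` objects.
#' @return data.frame with columns `track_id`, `variant`, `k_on`, `t_on`,
#'   `R_eq`, `k_off`, `t_off`, `sse`, `rmse`, `n_points`, `converged`,
#'   `unidentifiable`, `excluded`.
#' @export
fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    p <- f$params
    data.frame(track_id = f$track_id, variant = f$variant,
               k_on = if (is.null(p)) NA_real_ else p$k_on,
               t_on = if (is.null(p)) NA_real_ else p$t_on,
               R_eq = if (is.null(p)) NA_real_ else p$R_eq,
               k_off = if (is.null(p) || is.null(p$k_off)) NA_real_
                       else p$k_off,
               t_off = if (is.null(p) || is.null(p$t_off)) NA_real_
                       else p$t_off,
               sse = f$sse, rmse = f$rmse, n_points = f$n_points,
               converged = f$converged,
               unidentifiable = isTRUE(f$flags$unidentifiable),
               excluded = if (is.null(f$exclusion_reason)) ""
                          else f$exclusion_reason)
  }))
}
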