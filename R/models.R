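#' Kinetic parameter set for the piecewise exponential C/N models
#'
#' Bundles and validates the parameters of the two piecewise exponential
#' models used to describe normalized cytoplasm-to-nucleus (C/N) reporter
#' ratio traces after stimulation.
#'
#' The `"monotone"` variant describes a delayed monotone approach to an
#' equilibrium ratio:
#' \deqn{r(t) = 1 \quad (t \le t_{on}); \qquad
#'       r(t) = R_{eq} + (1 - R_{eq}) e^{-k_{on}(t - t_{on})} \quad (t > t_{on})}
#'
#' The `"recovery"` variant extends it with a return toward baseline after a
#' switch-off time \eqn{t_{off}}:
#' \deqn{r(t) = 1 + (r(t_{off}) - 1) e^{-k_{off}(t - t_{off})} \quad (t > t_{off})}
#' where \eqn{r(t_{off})} is the value of the monotone piece at \eqn{t_{off}},
#' so continuity at the breakpoint is structural, not fitted.
#'
#' @param variant `"monotone"` or `"recovery"`.
#' @param k_on Trans-localization rate (1/s), > 0.
#' @param t_on Onset time delay (s), >= 0. Time is measured relative to the
#'   stimulation event (t = 0 at the first post-stimulation frame).
#' @param R_eq Equilibrium C/N ratio (dimensionless), > 0.
#' @param k_off Recovery rate (1/s), > 0; recovery variant only.
#' @param t_off Switch-off time (s), > `t_on`; recovery variant only.
#' @return An object of class `ktr_params` (a named list).
#' @examples
#' p <- ktr_params("monotone", k_on = 0.02, t_on = 100, R_eq = 3)
#' eval_monotone(p, c(50, 100 + log(2) / 0.02))
#' @export
ktr_params <- function(variant = c("monotone", "recovery"),
                       k_on, t_on, R_eq, k_off = NULL, t_off = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(k_on), length(k_on) == 1L, is.finite(k_on),
            is.numeric(t_on), length(t_on) == 1L, is.finite(t_on),
            is.numeric(R_eq), length(R_eq) == 1L, is.finite(R_eq))
  if (k_on <= 0) stop("k_on must be > 0")
  if (t_on < 0) stop("t_on must be >= 0")
  if (R_eq <= 0) stop("R_eq must be > 0")
  if (variant == "recovery") {
    stopifnot(is.numeric(k_off), length(k_off) == 1L, is.finite(k_off),
              is.numeric(t_off), length(t_off) == 1L, is.finite(t_off))
    if (k_off <= 0) stop("k_off must be > 0")
    if (t_off <= t_on) stop("t_off must be > t_on")
  } else {
    k_off <- NULL
    t_off <- NULL
  }
  structure(list(variant = variant, k_on = k_on, t_on = t_on, R_eq = R_eq,
                 k_off = k_off, t_off = t_off),
            class = "ktr_params")
}

#' @export
print.ktr_params <- function(x, ...) {
  cat("<ktr_params> variant:", x$variant, "\n")
  cat(sprintf("  k_on = %g 1/s, t_on = %g s, R_eq = %g\n",
              x$k_on, x$t_on, x$R_eq))
  if (x$variant == "recovery")
    cat(sprintf("  k_off = %g 1/s, t_off = %g s\n", x$k_off, x$t_off))
  invisible(x)
}

#' Evaluate the monotone piecewise exponential C/N model
#'
#' @param params A [ktr_params()] object (variant may be either; only
#'   `k_on`, `t_on`, `R_eq` are used).
#' @param t Numeric vector of times in seconds relative to stimulation.
#' @return Numeric vector of model C/N values; exactly 1 for `t <= t_on`.
#' @seealso [eval_recovery()]
#' @export
eval_monotone <- function(params, t) {
  stopifnot(inherits(params, "ktr_params"), is.numeric(t))
  r <- rep(1, length(t))
  post <- t > params$t_on
  r[post] <- params$R_eq +
    (1 - params$R_eq) * exp(-params$k_on * (t[post] - params$t_on))
  r
}

#' Evaluate the recovery (transient) piecewise exponential C/N model
#'
#' Equals the monotone model on `(t_on, t_off]` and decays back toward 1
#' with rate `k_off` afterwards, starting from the monotone value at
#' `t_off` (continuity at `t_off` is built in).
#'
#' @inheritParams eval_monotone
#' @return Numeric vector of model C/N values.
#' @export
eval_recovery <- function(params, t) {
  stopifnot(inherits(params, "ktr_params"), is.numeric(t))
  if (params$variant != "recovery")
    stop("params must be a recovery-variant ktr_params")
  r <- rep(1, length(t))
  mid <- t > params$t_on & t <= params$t_off
  r[mid] <- params$R_eq +
    (1 - params$R_eq) * exp(-params$k_on * (t[mid] - params$t_on))
  r_off <- params$R_eq +
    (1 - params$R_eq) * exp(-params$k_on * (params$t_off - params$t_on))
  late <- t > params$t_off
  r[late] <- 1 + (r_off - 1) * exp(-params$k_off * (t[late] - params$t_off))
  r
}

#' Evaluate a kinetic model by its variant
#'
#' Dispatches to [eval_monotone()] or [eval_recovery()] according to
#' `params$variant`.
#'
#' @inheritParams eval_monotone
#' @return Numeric vector of model C/N values.
#' @export
eval_kinetic <- function(params, t) {
  if (params$variant == "recovery") eval_recovery(params, t)
  else eval_monotone(params, t)
}
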