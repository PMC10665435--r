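#' Classify cell status from doubling time and SA-beta-Gal positivity
#'
#' Applies the printed in-vitro bands: young = 1-2 days doubling time (DT)
#' and < 1% SA-beta-Gal-positive cells; mid-old = 5-7 days DT and < 5%;
#' old = > 14 days DT and > 65%. DT bands are closed as printed
#' (`[1, 2]`, `[5, 7]`, `(14, Inf)`); the SA-beta-Gal inequalities are
#' strict. Inputs falling in none of the bands (e.g. DT between 2 and
#' 5 days) are `unclassified`, so every valid input maps to exactly one
#' status.
#'
#' @param dt_days Doubling time in days (> 0); vectorized.
#' @param sabgal_pct Percent SA-beta-Gal-positive cells in \[0, 100\];
#'   vectorized (recycled against `dt_days`).
#' @return Character vector in
#'   `c("young", "mid_old", "old", "unclassified")`.
#' @export
classify_cell_status <- function(dt_days, sabgal_pct) {
  n <- max(length(dt_days), length(sabgal_pct))
  dt_days <- rep_len(dt_days, n)
  sabgal_pct <- rep_len(sabgal_pct, n)
  if (any(!is.finite(dt_days)) || any(dt_days <= 0))
    stop("dt_days must be finite and > 0")
  if (any(!is.finite(sabgal_pct)) || any(sabgal_pct < 0) ||
      any(sabgal_pct > 100))
    stop("sabgal_pct must lie in [0, 100]")
  status <- rep("unclassified", n)
  status[dt_days >= 1 & dt_days <= 2 & sabgal_pct < 1] <- "young"
  status[dt_days >= 5 & dt_days <= 7 & sabgal_pct < 5] <- "mid_old"
  status[dt_days > 14 & sabgal_pct > 65] <- "old"
  status
}

#' One-tailed Mann-Whitney U test
#'
#' The U statistic counts pairs with `x > y` (ties count 1/2). The p value
#' is exact -- computed by full enumeration of the
#' `choose(n1 + n2, n1)` rank arrangements -- when `n1 + n2 <= 12` and
#' there are no ties; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' `alternative = "less"` tests whether `x` is stochastically smaller than
#' `y` (small U); `"greater"` the reverse.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"less"` or `"greater"`.
#' @param exact_max Largest `n1 + n2` for which the exact enumeration is
#'   used (no ties only).
#' @return List with `U`, `p`, `method` (`"exact"` or `"normal"`), and
#'   `alternative`.
#' @export
mann_whitney_one_tailed <- function(x, y,
                                    alternative = c("less", "greater"),
                                    exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && N <= exact_max) {
    arrangements <- utils::combn(N, n1)
    u_all <- colSums(matrix(seq_len(N)[arrangements], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p <- if (alternative == "less") mean(u_all <= U) else mean(u_all >= U)
    return(list(U = U, p = p, method = "exact",
                alternative = alternative))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)  # all values identical
    return(list(U = U, p = 1, method = "normal",
                alternative = alternative))
  z <- if (alternative == "less") (U - mu + 0.5) / sqrt(sigma2)
       else (U - mu - 0.5) / sqrt(sigma2)
  p <- if (alternative == "less") stats::pnorm(z)
       else stats::pnorm(z, lower.tail = FALSE)
  list(U = U, p = min(max(p, .Machine$double.xmin), 1), method = "normal",
       alternative = alternative)
}

#' Two-tailed Student's t test (equal variances)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`,
#' `two.sided`; provided for samples that pass a normality check, matching
#' the reporting convention mean +/- SD.
#'
#' @param x,y Numeric samples (length >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
student_t_two_tailed <- function(x, y) {
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare kinetic parameters between cell-status groups
#'
#' For each parameter and each pair of groups, reports group sizes, mean
#' +/- SD per group, the Mann-Whitney U statistic, and the one-tailed p
#' value. The direction of the one-sided alternative must be declared by
#' the caller (there is no automatic choice); `alternative = "less"` tests
#' that the first group of the pair is stochastically smaller. No
#' multiple-testing correction is applied; each row is a per-comparison p
#' value.
#'
#' @param fits data.frame of fitted parameters (e.g. [fits_to_df()]) with a
#'   `status` column added; only rows with `converged == TRUE` enter.
#' @param parameters Character vector of parameter columns to compare.
#' @param alternative Single direction applied to every pair, or a named
#'   vector like `c("young.vs.old" = "greater")` keyed by
#'   `"<group1>.vs.<group2>"` (missing keys fall back to `"less"`).
#' @param min_n Minimum converged fits per group; pairs below it are
#'   skipped with a reason.
#' @return data.frame with one row per (parameter, group pair):
#'   `parameter`, `group1`, `group2`, `n1`, `n2`, `mean1`, `sd1`, `mean2`,
#'   `sd2`, `U`, `p`, `alternative`, `method`, `skipped`.
#' @export
compare_groups <- function(fits, parameters = c("k_on", "t_on", "R_eq"),
                           alternative = "less", min_n = 2L) {
  stopifnot(is.data.frame(fits), "status" %in% names(fits))
  fits <- fits[order(fits$status), , drop = FALSE]
  groups <- sort(unique(as.character(fits$status)))
  if (length(groups) < 2L)
    return(data.frame(parameter = character(0), group1 = character(0),
                      group2 = character(0), n1 = integer(0),
                      n2 = integer(0), mean1 = numeric(0), sd1 = numeric(0),
                      mean2 = numeric(0), sd2 = numeric(0), U = numeric(0),
                      p = numeric(0), alternative = character(0),
                      method = character(0), skipped = character(0)))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (param in parameters) {
    for (pr in pairs) {
      g1 <- pr[1]; g2 <- pr[2]
      key <- paste0(g1, ".vs.", g2)
      alt <- if (length(alternative) == 1L && is.null(names(alternative)))
        alternative
      else if (key %in% names(alternative)) alternative[[key]]
      else "less"
      x <- fits[[param]][fits$status == g1 & fits$converged %in% TRUE]
      y <- fits[[param]][fits$status == g2 & fits$converged %in% TRUE]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      skipped <- ""
      U <- NA_real_; p <- NA_real_; method <- NA_character_
      if (length(x) < min_n || length(y) < min_n) {
        skipped <- "insufficient_group_size"
      } else {
        mw <- mann_whitney_one_tailed(x, y, alternative = alt)
        U <- mw$U; p <- mw$p; method <- mw$method
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, group1 = g1, group2 = g2,
        n1 = length(x), n2 = length(y),
        mean1 = if (length(x)) mean(x) else NA_real_,
        sd1 = if (length(x) > 1) stats::sd(x) else NA_real_,
        mean2 = if (length(y)) mean(y) else NA_real_,
        sd2 = if (length(y) > 1) stats::sd(y) else NA_real_,
        U = U, p = p, alternative = alt, method = method,
        skipped = skipped)
    }
  }
  do.call(rbind, rows)
}

#' Write a group-comparison report as CSV and JSON
#'
#' The JSON sidecar records the comparisons plus metadata noting that p
#' values are per-comparison (no multiple-testing correction).
#'
#' @param comparisons data.frame from [compare_groups()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.csv` and `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_comparison_report <- function(comparisons, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  utils::write.csv(comparisons, csv, row.names = FALSE)
  jsonlite::write_json(
    list(metadata = list(
           test = "one-tailed Mann-Whitney U",
           note = "per-comparison p values; no multiple-testing correction",
           summary_statistic = "mean +/- SD"),
         comparisons = comparisons),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}
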