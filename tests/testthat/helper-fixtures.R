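# Shared fixture builders. Everything is generated in code; no files.

# A small, fast synthetic experiment used by several module tests.
small_sim <- function(n_cells = 5, seed = 3, noise_sd = 0, motion_sd = 0,
                      mix = c(young = 0.6, old = 0.4),
                      image_size = c(192, 192), drift = c(0, 0)) {
  pop <- population_spec(n_cells, mix, seed = seed)
  img <- imaging_spec(image_size = image_size, noise_sd = noise_sd,
                      motion_sd_px = motion_sd, global_drift_px = drift,
                      seed = seed)
  simulate_movie(pop, img)
}

# Noiseless normalized trace for given parameters on the standard schedule
# (4 prestim frames, then every 15 s for 30 min).
model_trace <- function(variant, k_on, t_on, R_eq, k_off = NULL,
                        t_off = NULL, noise_sd = 0, seed = 1) {
  times <- seq(-60, 1800, by = 15)
  p <- ktr_params(variant, k_on = k_on, t_on = t_on, R_eq = R_eq,
                  k_off = k_off, t_off = t_off)
  y <- eval_kinetic(p, times)
  if (noise_sd > 0)
    y <- withr::with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  cn_trace(times, cn_raw = y, cn_norm = y)
}

# Brute-force annular ring oracle: every non-nucleus pixel whose exact
# Euclidean distance to the nearest nucleus pixel of any label is <= width
# joins the ring of the nearest label (ties -> lower label).
brute_force_rings <- function(labels, width) {
  H <- nrow(labels); W <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  px <- lapply(ids, function(l) which(labels == l, arr.ind = TRUE))
  rings <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (labels[i, j] > 0) next
    bd <- Inf; bl <- 0L
    for (k in seq_along(ids)) {
      d <- sqrt(min((i - px[[k]][, 1])^2 + (j - px[[k]][, 2])^2))
      if (d < bd) { bd <- d; bl <- ids[k] }
    }
    if (bd <= width) rings[i, j] <- bl
  }
  rings
}

# Exhaustive assignment oracle: minimum total cost over all row->column
# injections of the zero-padded square matrix, with forbidden entries as a
# large penalty (same semantics as solve_assignment: maximum cardinality
# among allowed links first, then minimum cost).
perms <- local({
  cache <- list()
  gen <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  function(v) {
    key <- paste(v, collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <<- gen(v)
    cache[[key]]
  }
})

brute_force_assignment_cost <- function(cost) {
  m <- nrow(cost); k <- ncol(cost)
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0) return(0)
  n <- max(m, k)
  big <- (max(finite) + 1) * (n + 1)
  sq <- matrix(0, n, n)
  sq[seq_len(m), seq_len(k)] <- ifelse(is.finite(cost), cost, big)
  best <- Inf
  for (p in perms(seq_len(n))) {
    tot <- sum(sq[cbind(seq_len(n), p)])
    # total allowed cost of the induced matching (drop dummies + forbidden)
    real <- seq_len(m)[p[seq_len(m)] <= k]
    cc <- cost[cbind(real, p[real])]
    tot_real <- sum(cc[is.finite(cc)]) +
      big * sum(!is.finite(cc))
    if (tot_real < best) best <- tot_real
  }
  best
}

# Matching cost of solve_assignment under the same big-M accounting.
solver_cost_bigM <- function(cost) {
  m <- nrow(cost); k <- ncol(cost)
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0) return(0)
  n <- max(m, k)
  big <- (max(finite) + 1) * (n + 1)
  sol <- solve_assignment(cost)
  sol$total_cost + big * (m - nrow(sol$matches) - max(m - k, 0))
}
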