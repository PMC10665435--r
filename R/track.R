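#' Gated Euclidean-distance cost matrix between two centroid sets
#'
#' Cost is the centroid-to-centroid Euclidean distance; pairs farther apart
#' than `max_link_dist_px` are forbidden (`Inf`), which downstream turns
#' into a track end plus a new birth.
#'
#' @param centroids_t,centroids_t1 Matrices with columns `(y, x)` (possibly
#'   0 rows).
#' @param max_link_dist_px Gating distance in pixels (`Inf` to disable).
#' @return Numeric matrix `nrow(centroids_t) x nrow(centroids_t1)` with
#'   `Inf` marking forbidden links.
#' @export
build_cost_matrix <- function(centroids_t, centroids_t1,
                              max_link_dist_px = 15) {
  a <- as.matrix(centroids_t); b <- as.matrix(centroids_t1)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), nrow(a), nrow(b)))
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  d[d > max_link_dist_px] <- Inf
  d
}

# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. cost: n x n finite matrix. Returns for each row
# the assigned column. O(n^3); the inner column scan is vectorized.
lap_square <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)           # row potentials, index shift +1
  v <- numeric(n + 1L)           # col potentials; position 1 = virtual col 0
  p <- integer(n + 1L)           # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])          # candidate real columns
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free + 1L])]
      delta <- minv[j1 + 1L]
      iu <- which(used)
      u[p[iu] + 1L] <- u[p[iu] + 1L] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) assign_row[p[j + 1L]] <- j
  assign_row
}

#' Solve the minimum-cost assignment problem (Munkres/Hungarian)
#'
#' Finds a matching between rows and columns of a rectangular cost matrix
#' that has maximum cardinality among matchings avoiding forbidden (`Inf`
#' or `NA`) entries and, among those, minimum total cost. Implemented as a
#' shortest-augmenting-path (Jonker-Volgenant) solver on a square matrix
#' padded with zero-cost dummies, with forbidden entries encoded as a
#' large penalty that is never part of a reported match.
#'
#' @param cost_matrix Numeric matrix; `Inf`/`NA` entries are forbidden.
#' @return List with `matches` (data.frame `row`, `col`, `cost`),
#'   `unmatched_rows`, `unmatched_cols`, and `total_cost` (sum over
#'   matches; 0 for an empty matching).
#' @export
solve_assignment <- function(cost_matrix) {
  stopifnot(is.matrix(cost_matrix))
  m <- nrow(cost_matrix); k <- ncol(cost_matrix)
  empty <- list(matches = data.frame(row = integer(0), col = integer(0),
                                     cost = numeric(0)),
                unmatched_rows = seq_len(m), unmatched_cols = seq_len(k),
                total_cost = 0)
  if (m == 0L || k == 0L) return(empty)
  cost <- cost_matrix
  cost[is.na(cost)] <- Inf
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0L) return(empty)
  if (any(finite < 0)) stop("costs must be non-negative")
  n <- max(m, k)
  big <- (max(finite) + 1) * (n + 1)
  sq <- matrix(0, n, n)           # dummy rows/cols cost 0
  sq[seq_len(m), seq_len(k)] <- ifelse(is.finite(cost), cost, big)
  assign_row <- lap_square(sq)
  rows <- seq_len(m)
  cols <- assign_row[rows]
  ok <- cols <= k & is.finite(cost[cbind(rows, pmin(cols, k))])
  matches <- data.frame(row = rows[ok], col = cols[ok],
                        cost = cost[cbind(rows[ok], cols[ok])])
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(m), matches$row),
       unmatched_cols = setdiff(seq_len(k), matches$col),
       total_cost = sum(matches$cost))
}

#' Link per-frame detections into cell tracks
#'
#' Greedy-over-frames global-over-detections linking: at every frame the
#' set of active tracks (represented by their last known centroid) is
#' matched to the frame's detections by [solve_assignment()] on the gated
#' distance cost. Matched tracks extend (interior frames missed during a
#' gap are recorded with label `NA`); tracks unseen for more than `max_gap`
#' consecutive frames are closed; unmatched detections found new tracks.
#' Track ids are renumbered densely from 1 in order of birth (ties by first
#' label).
#'
#' @param masks_list List of `cell_masks`, one per frame (see
#'   [segment_movie()]).
#' @param max_link_dist_px Gating distance passed to [build_cost_matrix()].
#' @param max_gap Maximum number of consecutive missed frames an active
#'   track may survive (0 = none).
#' @return A data.frame of class `track_table`: `track_id`, `frame`,
#'   `label` (`NA` for an interior missed frame), `centroid_y`,
#'   `centroid_x`, `border`.
#' @export
link_tracks <- function(masks_list, max_link_dist_px = 15, max_gap = 0L) {
  stopifnot(is.list(masks_list), length(masks_list) >= 1L, max_gap >= 0L)
  active <- list()   # each: id, y, x, missed, rows(list of row dfs)
  done <- list()
  next_id <- 1L
  for (f in seq_along(masks_list)) {
    info <- masks_list[[f]]$info
    nd <- nrow(info)
    na <- length(active)
    matched_det <- integer(0)
    if (na > 0L && nd > 0L) {
      act_xy <- t(vapply(active, function(a) c(a$y, a$x), numeric(2)))
      cm <- build_cost_matrix(act_xy,
                              cbind(info$centroid_y, info$centroid_x),
                              max_link_dist_px)
      sol <- solve_assignment(cm)
      matched_act <- sol$matches$row
      matched_det <- sol$matches$col
      for (k in seq_along(matched_act)) {
        a <- active[[matched_act[k]]]
        j <- matched_det[k]
        if (a$missed > 0L) {
          gap_frames <- (f - a$missed):(f - 1L)
          a$rows[[length(a$rows) + 1L]] <-
            data.frame(frame = gap_frames, label = NA_integer_,
                       centroid_y = NA_real_, centroid_x = NA_real_,
                       border = NA)
        }
        a$rows[[length(a$rows) + 1L]] <-
          data.frame(frame = f, label = info$label[j],
                     centroid_y = info$centroid_y[j],
                     centroid_x = info$centroid_x[j],
                     border = info$border[j])
        a$y <- info$centroid_y[j]; a$x <- info$centroid_x[j]
        a$missed <- 0L
        active[[matched_act[k]]] <- a
      }
      survivors <- rep(TRUE, na)
      for (ai in setdiff(seq_len(na), matched_act)) {
        a <- active[[ai]]
        a$missed <- a$missed + 1L
        if (a$missed > max_gap) {
          done[[length(done) + 1L]] <- a
          survivors[ai] <- FALSE
        } else active[[ai]] <- a
      }
      active <- active[survivors]
    } else if (na > 0L) {
      survivors <- rep(TRUE, na)
      for (ai in seq_len(na)) {
        a <- active[[ai]]
        a$missed <- a$missed + 1L
        if (a$missed > max_gap) {
          done[[length(done) + 1L]] <- a
          survivors[ai] <- FALSE
        } else active[[ai]] <- a
      }
      active <- active[survivors]
    }
    for (j in setdiff(seq_len(nd), matched_det)) {
      active[[length(active) + 1L]] <-
        list(id = next_id, y = info$centroid_y[j], x = info$centroid_x[j],
             missed = 0L,
             rows = list(data.frame(frame = f, label = info$label[j],
                                    centroid_y = info$centroid_y[j],
                                    centroid_x = info$centroid_x[j],
                                    border = info$border[j])))
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  if (length(done) == 0L)
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                label = integer(0), centroid_y = numeric(0),
                                centroid_x = numeric(0), border = logical(0)),
                     class = c("track_table", "data.frame")))
  tabs <- lapply(done, function(a) {
    df <- do.call(rbind, a$rows)
    df$track_id <- a$id
    df
  })
  tab <- do.call(rbind, tabs)
  # dense ids in birth order
  birth <- vapply(split(tab$frame, tab$track_id), min, numeric(1))
  order_ids <- as.integer(names(sort(birth)))
  remap <- integer(max(order_ids))
  remap[order_ids] <- seq_along(order_ids)
  tab$track_id <- remap[tab$track_id]
  tab <- tab[order(tab$track_id, tab$frame),
             c("track_id", "frame", "label", "centroid_y", "centroid_x",
               "border")]
  rownames(tab) <- NULL
  structure(tab, class = c("track_table", "data.frame"))
}

#' Segment-and-track convenience wrapper
#'
#' @param masks_list List of per-frame `cell_masks`.
#' @inheritParams link_tracks
#' @return A `track_table` (see [link_tracks()]).
#' @export
track_cells <- function(masks_list, max_link_dist_px = 15, max_gap = 0L) {
  link_tracks(masks_list, max_link_dist_px = max_link_dist_px,
              max_gap = max_gap)
}

#' Match tracks to ground-truth cells of a synthetic movie
#'
#' For every track and frame, finds the nearest ground-truth cell centroid;
#' a track agrees with the truth when every observed frame maps to the same
#' truth cell within `tol_px` and that cell is claimed by no other track
#' over those frames.
#'
#' @param tracks A `track_table`.
#' @param truth A `ktr_truth` object (from [render_movie()]).
#' @param tol_px Maximum centroid distance for a truth match.
#' @return List with `track_cell` (data.frame `track_id`, `cell`, `agrees`,
#'   `n_frames`) and `agreement`, the fraction of truth cells covered by
#'   exactly one full-length agreeing track.
#' @export
match_tracks_to_truth <- function(tracks, truth, tol_px = 5) {
  stopifnot(inherits(truth, "ktr_truth"))
  n_frames <- dim(truth$centroids)[1]
  n_cells <- dim(truth$centroids)[2]
  per_track <- lapply(split(seq_len(nrow(tracks)), tracks$track_id),
                      function(ix) {
    rows <- tracks[ix, ]
    obs <- !is.na(rows$label)
    cells <- rep(NA_integer_, nrow(rows))
    okdist <- rep(FALSE, nrow(rows))
    for (k in which(obs)) {
      d <- sqrt((truth$centroids[rows$frame[k], , 1] - rows$centroid_y[k])^2 +
                (truth$centroids[rows$frame[k], , 2] - rows$centroid_x[k])^2)
      cells[k] <- which.min(d)
      okdist[k] <- min(d) <= tol_px
    }
    u <- unique(cells[obs])
    data.frame(track_id = rows$track_id[1],
               cell = if (length(u) == 1L) u else NA_integer_,
               agrees = length(u) == 1L && all(okdist[obs]),
               n_frames = sum(obs))
  })
  track_cell <- do.call(rbind, per_track)
  full <- track_cell[track_cell$agrees & !is.na(track_cell$cell) &
                       track_cell$n_frames == n_frames, ]
  claims <- table(full$cell)
  covered <- sum(claims == 1L)
  list(track_cell = track_cell,
       agreement = if (n_cells == 0) 1 else covered / n_cells)
}
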