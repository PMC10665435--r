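test_that("cost matrix is the gated Euclidean distance", {
  cm <- build_cost_matrix(cbind(0, 0), cbind(3, 4), max_link_dist_px = 15)
  expect_equal(cm, matrix(5, 1, 1))
  # beyond the gate -> forbidden
  expect_identical(build_cost_matrix(cbind(0, 0), cbind(3, 4), 4.9)[1, 1],
                   Inf)
  # 3x3 grid shifted by (1, 0): diagonal costs all 1
  g <- as.matrix(expand.grid(y = c(0, 10, 20), x = c(0, 10, 20)))
  cm3 <- build_cost_matrix(g, g + cbind(rep(1, 9), 0), 15)
  expect_equal(unname(diag(cm3)), rep(1, 9))
  expect_identical(dim(build_cost_matrix(g[0, ], g, 15)), c(0L, 9L))
})

test_that("assignment solver reproduces hand-checked optima", {
  s1 <- solve_assignment(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(s1$matches$col[order(s1$matches$row)], c(1, 2))
  expect_equal(s1$total_cost, 0)
  s2 <- solve_assignment(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(s2$matches$col[order(s2$matches$row)], c(2, 1))
  expect_equal(s2$total_cost, 2)
  # all-forbidden -> empty matching, no error
  s3 <- solve_assignment(matrix(Inf, 2, 3))
  expect_identical(nrow(s3$matches), 0L)
  expect_identical(s3$unmatched_rows, 1:2)
  expect_identical(s3$unmatched_cols, 1:3)
})

test_that("assignment solver matches the brute-force oracle", {
  withr::with_seed(42, {
    for (rep in 1:120) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      cost <- matrix(stats::runif(n * m, 0, 100), n, m)
      if (rep %% 2 == 0)
        cost[stats::runif(n * m) < 0.3] <- Inf
      expect_equal(solver_cost_bigM(cost),
                   brute_force_assignment_cost(cost), tolerance = 1e-9)
    }
  })
})

# minimal per-frame cell_masks stand-in for link_tracks
fake_masks <- function(centroid_list) {
  lapply(centroid_list, function(cm) {
    info <- if (is.null(cm) || nrow(cm) == 0)
      data.frame(label = integer(0), nucleus_area = integer(0),
                 ring_area = integer(0), centroid_y = numeric(0),
                 centroid_x = numeric(0), border = logical(0))
    else
      data.frame(label = seq_len(nrow(cm)), nucleus_area = 50L,
                 ring_area = 80L, centroid_y = cm[, 1], centroid_x = cm[, 2],
                 border = FALSE)
    list(info = info)
  })
}

test_that("gap handling closes or bridges tracks as configured", {
  frames <- list(cbind(10, 10), cbind(10, 10), NULL, cbind(10, 10))
  bridged <- link_tracks(fake_masks(frames), max_gap = 1)
  expect_identical(length(unique(bridged$track_id)), 1L)
  expect_identical(bridged$frame, 1:4)
  expect_true(is.na(bridged$label[3]))   # one interior MISSING frame
  split2 <- link_tracks(fake_masks(frames), max_gap = 0)
  expect_identical(length(unique(split2$track_id)), 2L)
  expect_true(all(!is.na(split2$label)))
  # beyond-gate jump = track end + new birth
  jump <- link_tracks(fake_masks(list(cbind(10, 10), cbind(80, 80))),
                      max_link_dist_px = 15)
  expect_identical(length(unique(jump$track_id)), 2L)
})

test_that("track ids are dense in birth order and composition is stable", {
  frames <- list(cbind(c(10, 50), c(10, 50)),
                 cbind(c(11, 51), c(10, 50)),
                 cbind(c(12, 52, 90), c(10, 50, 90)))
  tt <- link_tracks(fake_masks(frames))
  expect_identical(sort(unique(tt$track_id)), 1:3)
  expect_identical(min(tt$frame[tt$track_id == 3]), 3L)
  # permuting detection order within frames changes ids only
  frames_perm <- list(cbind(c(50, 10), c(50, 10)),
                      cbind(c(51, 11), c(50, 10)),
                      cbind(c(90, 52, 12), c(90, 50, 10)))
  tp <- link_tracks(fake_masks(frames_perm))
  sig <- function(df) {
    paths <- lapply(split(df, df$track_id), function(x)
      paste(x$frame, round(x$centroid_y, 6), round(x$centroid_x, 6),
            collapse = ";"))
    sort(unlist(paths))
  }
  expect_identical(unname(sig(tt)), unname(sig(tp)))
})

test_that("tracking a stationary noiseless movie matches the ground truth", {
  sim <- small_sim(n_cells = 8, seed = 31, image_size = c(192, 192))
  masks <- segment_movie(sim$movie)
  tracks <- link_tracks(masks)
  expect_identical(length(unique(tracks$track_id)), 8L)
  expect_true(all(table(tracks$track_id) == 125))
  mt <- match_tracks_to_truth(tracks, sim$truth)
  expect_equal(mt$agreement, 1)
})

test_that("tracking tolerates motion well below the nearest-neighbor gap", {
  sim <- small_sim(n_cells = 6, seed = 37, image_size = c(192, 192),
                   motion_sd = 0.8, noise_sd = 20)
  masks <- segment_movie(sim$movie)
  tracks <- link_tracks(masks)
  mt <- match_tracks_to_truth(tracks, sim$truth)
  expect_equal(mt$agreement, 1)
})
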