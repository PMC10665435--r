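test_that("translation registration recovers cyclic shifts", {
  withr::with_seed(4, {
    ref <- matrix(stats::runif(64 * 64), 64, 64)
    ref[20:30, 35:45] <- ref[20:30, 35:45] + 5   # a bright structure
  })
  for (s in list(c(3, -2), c(0, 0), c(-7, 11))) {
    frame <- roll_matrix(ref, s[1], s[2])
    reg <- register_translation(frame, ref)
    expect_identical(unname(reg$offset), as.integer(s))
    expect_equal(reg$shifted, ref)
  }
  expect_warning(reg0 <- register_translation(matrix(1, 8, 8),
                                              matrix(1, 8, 8)),
                 "degenerate")
  expect_identical(unname(reg0$offset), c(0L, 0L))
})

test_that("registration of a drifting movie undoes the drift for tracking", {
  sim <- small_sim(n_cells = 3, seed = 21, image_size = c(160, 160),
                   drift = c(0.1, -0.1))
  reg <- register_movie(sim$movie, reference_frame = 1)
  # estimated offsets follow the cumulative drift within rounding
  f <- 101
  expect_true(all(abs(reg$offsets[f, ] - (f - 1) * c(0.1, -0.1)) <= 1))
  res <- run_ktr_pipeline(reg$movie, max_link_dist_px = 5)
  expect_identical(length(unique(res$tracks$track_id)), 3L)
})

test_that("background subtraction matches its definition and clips at zero", {
  fr <- matrix(25, 10, 10)
  expect_equal(subtract_background(fr, "constant", 10),
               matrix(15, 10, 10))
  expect_equal(subtract_background(fr, "constant", 100),
               matrix(0, 10, 10))
  fr2 <- matrix(0, 10, 10); fr2[1, 1:10] <- 50   # 10% signal, 90% zeros
  expect_equal(subtract_background(fr2, "percentile", 50), fr2)
  expect_error(subtract_background(fr, "percentile", 150), "\\[0, 100\\]")
})

test_that("nucleus segmentation recovers hard disks and filters by area", {
  H <- 120
  frame <- matrix(100, H, H)
  centers <- list(c(25, 30), c(60, 85), c(95, 40))
  for (cc in centers)
    for (i in 1:H) {
      j <- which((i - cc[1])^2 + (seq_len(H) - cc[2])^2 <= 64)
      frame[i, j] <- 2100
    }
  withr::with_seed(8, noisy <- frame + stats::rnorm(H * H, 0, 20))
  lab <- segment_nuclei(noisy, min_area_px = 30)
  expect_identical(max(lab), 3L)
  true_area <- sum(outer((-8:8)^2, (-8:8)^2, "+") <= 64)
  for (l in 1:3)
    expect_lt(abs(sum(lab == l) - true_area) / true_area, 0.10)
  # labels are 1..n in raster (column-major) order of first pixel
  first <- vapply(1:3, function(l) which(lab == l)[1], numeric(1))
  expect_true(all(diff(first) > 0))

  expect_identical(max(segment_nuclei(matrix(100, 50, 50))), 0L)

  # a component of area min_area_px - 1 is removed
  small <- matrix(0, 40, 40); small[10:12, 10:14] <- 100   # 15 px
  expect_identical(max(segment_nuclei(small, threshold_method = "fixed",
                                      threshold = 50, min_area_px = 16)), 0L)
  expect_identical(max(segment_nuclei(small, threshold_method = "fixed",
                                      threshold = 50, min_area_px = 15)), 1L)
})

test_that("segmentation label count is invariant to constant background", {
  sim <- small_sim(n_cells = 4, seed = 13, image_size = c(128, 128),
                   noise_sd = 20)
  fr <- sim$movie$pixels[1, 1, , ]
  lab0 <- segment_nuclei(subtract_background(fr, "constant", 0))
  lab1 <- segment_nuclei(subtract_background(fr + 500, "constant", 500))
  expect_identical(max(lab0), max(lab1))
})

test_that("cytoplasm rings match the brute-force Euclidean annulus oracle", {
  for (r0 in c(8, 10)) {
    H <- 2 * (r0 + 5) + 11
    lab <- matrix(0L, H, H)
    cy <- (H + 1) / 2
    for (i in seq_len(H)) {
      j <- which((i - cy)^2 + (seq_len(H) - cy)^2 <= r0^2)
      lab[i, j] <- 1L
    }
    masks <- make_cytoplasm_rings(lab, ring_width_px = 5)
    oracle <- brute_force_rings(lab, 5)
    expect_identical(masks$rings, oracle)
    # area within 5% of the continuous annulus pi*((r0+5)^2 - r0^2)
    expect_lt(abs(sum(masks$rings == 1) - pi * ((r0 + 5)^2 - r0^2)) /
                (pi * ((r0 + 5)^2 - r0^2)), 0.05)
    # definitional invariants
    expect_true(all(masks$rings[lab > 0] == 0))
    expect_false(masks$info$border)
  }
})

test_that("rings of nearby nuclei are disjoint with nearest-nucleus ties", {
  lab <- matrix(0L, 60, 110)
  for (i in 1:60) {
    lab[i, which((i - 30)^2 + (seq_len(110) - 30)^2 <= 100)] <- 1L
    lab[i, which((i - 30)^2 + (seq_len(110) - 80)^2 <= 100)] <- 2L
  }
  masks <- make_cytoplasm_rings(lab, ring_width_px = 5)
  expect_identical(masks$rings, brute_force_rings(lab, 5))
  # 50 px apart: rings cannot touch; each matches the single-disk result
  single <- make_cytoplasm_rings(
    matrix(as.integer(lab == 1), 60, 110), ring_width_px = 5)
  expect_identical(sum(masks$rings == 1), sum(single$rings == 1))
  expect_identical(sum(masks$rings == 1), sum(masks$rings == 2))

  # contested pixels between close nuclei: still disjoint, oracle-exact
  lab2 <- matrix(0L, 50, 70)
  for (i in 1:50) {
    lab2[i, which((i - 25)^2 + (seq_len(70) - 22)^2 <= 64)] <- 1L
    lab2[i, which((i - 25)^2 + (seq_len(70) - 45)^2 <= 64)] <- 2L
  }
  masks2 <- make_cytoplasm_rings(lab2, ring_width_px = 5)
  expect_identical(masks2$rings, brute_force_rings(lab2, 5))
  expect_true(all(masks2$rings[lab2 > 0] == 0))

  expect_error(make_cytoplasm_rings(lab2, ring_width_px = 0), ">= 1")
})

test_that("ring area grows monotonically with ring width", {
  lab <- matrix(0L, 60, 60)
  for (i in 1:60)
    lab[i, which((i - 30)^2 + (seq_len(60) - 30)^2 <= 81)] <- 1L
  areas <- vapply(1:8, function(w)
    sum(make_cytoplasm_rings(lab, w)$rings == 1), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("segmentation recovers the generator's labels up to permutation", {
  sim <- small_sim(n_cells = 6, seed = 17, image_size = c(160, 160))
  for (f in c(1, 63, 125)) {
    lab <- segment_nuclei(sim$movie$pixels[f, 1, , ])
    truth_lab <- sim$truth$label_images[[f]]
    expect_identical(max(lab), 6L)
    # same foreground, and a one-to-one label correspondence
    expect_identical(lab > 0, truth_lab > 0)
    tab <- table(lab[lab > 0], truth_lab[lab > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})
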