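test_that("population sampling is seeded, mixed, and validated", {
  spec <- population_spec(10, c(young = 1), seed = 7)
  expect_identical(sample_population(spec), sample_population(spec))

  # archetype fraction within 3 binomial SDs of the mixing proportion
  spec2 <- population_spec(1000, c(young = 0.5, old = 0.5), seed = 1)
  pp <- sample_population(spec2)
  frac_old <- mean(pp$archetype == "old")
  expect_lt(abs(frac_old - 0.5), 3 * sqrt(0.25 / 1000))
  # old cells (and only old cells) carry recovery parameters
  expect_true(all(is.finite(pp$k_off[pp$archetype == "old"])))
  expect_true(all(is.na(pp$k_off[pp$archetype != "old"])))

  expect_error(population_spec(10, c(young = 0.5, old = 0.4)), "sum to 1")
  expect_error(population_spec(10, c(young = 1),
                               param_dists = list(young = list(
                                 k_on = c(0, 1), t_on = c(0, 1),
                                 R_eq = c(1, 2)))),
               "strictly positive")
})

test_that("synthesized traces obey the generating models exactly", {
  spec <- population_spec(30, seed = 11)
  pp <- sample_population(spec)
  times <- seq(-60, 1800, by = 15)
  tr <- synthesize_traces(pp, times)
  # pre-stimulation values exactly 1 for every cell and archetype
  expect_true(all(tr[times < 0, ] == 1))
  expect_true(all(tr[times == 0, ] == 1))  # t_on > 0 for all archetypes
  for (i in seq_len(nrow(pp))) {
    p <- ktr_params(pp$variant[i], k_on = pp$k_on[i], t_on = pp$t_on[i],
                    R_eq = pp$R_eq[i],
                    k_off = if (pp$variant[i] == "recovery") pp$k_off[i],
                    t_off = if (pp$variant[i] == "recovery") pp$t_off[i])
    expect_identical(tr[, i], eval_kinetic(p, times))
  }
  # shape: monotone archetypes non-decreasing toward R_eq (R_eq > 1 here);
  # recovery attains its maximum at t_off and decays toward 1 afterwards
  for (i in which(pp$variant == "monotone")) {
    expect_true(all(diff(tr[, i]) >= 0))
    # approaches R_eq: closer at the end than mid-movie
    expect_lt(abs(tr[length(times), i] - pp$R_eq[i]),
              abs(tr[times == 300, i] - pp$R_eq[i]) + 1e-15)
  }
  for (i in which(pp$variant == "recovery")) {
    post_off <- which(times > pp$t_off[i])
    expect_true(all(diff(tr[post_off, i]) <= 0))
    # discrete argmax brackets t_off (the frame just after t_off can still
    # exceed the frame just before when t_off falls between samples)
    k_off_frame <- max(which(times <= pp$t_off[i]))
    expect_true(which.max(tr[, i]) %in% c(k_off_frame, k_off_frame + 1L))
  }
  expect_error(synthesize_traces(pp, seq(0, 100, 10)), "pre-stimulation")
})

test_that("rendered single cell reproduces its true C/N from raw pixels", {
  pop <- population_spec(1, c(mid_old = 1), seed = 5)
  img <- imaging_spec(image_size = c(96, 96), noise_sd = 0, seed = 5)
  sim <- render_movie(sample_population(pop), img)
  truth <- sim$truth
  # direct pixel-count oracle on raw rendered frames, no segmentation
  for (f in c(1, 5, 40, 125)) {
    labels <- truth$label_images[[f]]
    nuc <- labels == 1
    rep_ch <- sim$movie$pixels[f, 2, , ] - img$background_level
    ring_px <- brute_force_rings(labels, img$ring_width_px) == 1
    ratio <- mean(rep_ch[ring_px]) / mean(rep_ch[nuc])
    expect_equal(ratio, truth$cn[f, 1], tolerance = 0.01)
  }
})

test_that("rendering is seeded and intensity-linear and handles empty fields", {
  pop <- population_spec(3, c(young = 1), seed = 9)
  img <- imaging_spec(image_size = c(128, 128), noise_sd = 25,
                      motion_sd_px = 0.5, seed = 9)
  a <- simulate_movie(pop, img)
  b <- simulate_movie(pop, img)
  expect_identical(a$movie$pixels, b$movie$pixels)
  expect_identical(a$truth$centroids, b$truth$centroids)

  # doubling both channel gains leaves the measured C/N unchanged
  img0 <- imaging_spec(image_size = c(96, 96), seed = 2)
  img2 <- imaging_spec(image_size = c(96, 96), dye_level = 2 * img0$dye_level,
                       reporter_nucleus_level =
                         2 * img0$reporter_nucleus_level,
                       background_level = 2 * img0$background_level, seed = 2)
  pop1 <- population_spec(1, c(young = 1), seed = 2)
  s0 <- simulate_movie(pop1, img0); s2 <- simulate_movie(pop1, img2)
  f <- 60
  lab <- s0$truth$label_images[[f]]
  ring <- brute_force_rings(lab, 5) == 1
  r0 <- mean((s0$movie$pixels[f, 2, , ] - img0$background_level)[ring]) /
    mean((s0$movie$pixels[f, 2, , ] - img0$background_level)[lab == 1])
  r2 <- mean((s2$movie$pixels[f, 2, , ] - img2$background_level)[ring]) /
    mean((s2$movie$pixels[f, 2, , ] - img2$background_level)[lab == 1])
  expect_equal(r0, r2, tolerance = 1e-12)

  # zero cells: pure background, downstream finds no nuclei
  empty <- render_movie(sample_population(population_spec(0, seed = 1)),
                        imaging_spec(image_size = c(64, 64), seed = 1))
  lab <- segment_nuclei(empty$movie$pixels[1, 1, , ])
  expect_identical(max(lab), 0L)
})
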