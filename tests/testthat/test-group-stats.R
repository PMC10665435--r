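test_that("cell-status bands reproduce the printed definitions", {
  expect_identical(classify_cell_status(1.5, 0.5), "young")
  expect_identical(classify_cell_status(6, 3), "mid_old")
  expect_identical(classify_cell_status(20, 80), "old")
  expect_identical(classify_cell_status(10, 20), "unclassified")
  # boundary probes: DT bands closed as printed, SA-b-Gal strict
  expect_identical(classify_cell_status(c(1, 2, 2.01, 5, 7, 14, 14.01),
                                        c(0.9, 0.9, 0.9, 4.9, 4.9, 70, 70)),
                   c("young", "young", "unclassified", "mid_old", "mid_old",
                     "unclassified", "old"))
  expect_identical(classify_cell_status(1.5, 1), "unclassified")
  expect_identical(classify_cell_status(6, 5), "unclassified")
  expect_identical(classify_cell_status(20, 65), "unclassified")
  expect_error(classify_cell_status(0, 10), "dt_days")
  expect_error(classify_cell_status(2, 101), "sabgal")
})

test_that("every valid input maps to exactly one status", {
  withr::with_seed(5, {
    dt <- stats::runif(500, 0.1, 30)
    sg <- stats::runif(500, 0, 100)
  })
  st <- classify_cell_status(dt, sg)
  expect_true(all(st %in% c("young", "mid_old", "old", "unclassified")))
  expect_identical(length(st), 500L)
  # the three bands are disjoint by construction of the DT intervals
  expect_true(all(st[dt > 2 & dt < 5] == "unclassified"))
  expect_true(all(st[dt > 7 & dt <= 14] == "unclassified"))
})

test_that("exact Mann-Whitney p matches hand enumeration on the textbook case", {
  mw <- mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")
  expect_identical(mw$method, "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / choose(6, 3))   # 1/20 = 0.05
  # identical samples with ties: p >= 0.5 under either one-sided alternative
  x <- c(1, 2, 2, 3)
  expect_gte(mann_whitney_one_tailed(x, x, "less")$p, 0.5)
  expect_gte(mann_whitney_one_tailed(x, x, "greater")$p, 0.5)
  expect_error(mann_whitney_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals full enumeration for all no-tie cases up to n=10", {
  # independent enumeration over rank subsets, written against the
  # definition rather than the implementation
  enum_p <- function(x, y, alt) {
    n1 <- length(x); N <- n1 + length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    subsets <- utils::combn(N, n1)
    u_all <- apply(subsets, 2, sum) - n1 * (n1 + 1) / 2
    if (alt == "less") mean(u_all <= U) else mean(u_all >= U)
  }
  withr::with_seed(11, {
    for (rep in 1:40) {
      n1 <- sample(2:7, 1); n2 <- sample(2:(10 - n1), 1)
      x <- stats::rnorm(n1); y <- stats::rnorm(n2)
      for (alt in c("less", "greater")) {
        mw <- mann_whitney_one_tailed(x, y, alt)
        expect_identical(mw$method, "exact")
        expect_equal(mw$p, enum_p(x, y, alt))
        # cross-check against the standard implementation
        expect_equal(mw$p,
                     stats::wilcox.test(x, y, alternative = alt,
                                        exact = TRUE)$p.value)
      }
    }
  })
})

test_that("normal approximation agrees with the exact p for n1=n2=6", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      x <- stats::rnorm(6); y <- stats::rnorm(6, 0.5)
      exact <- mann_whitney_one_tailed(x, y, "less")$p
      approx <- mann_whitney_one_tailed(x, y, "less", exact_max = 0L)$p
      expect_lt(abs(exact - approx), 0.02)
    }
  })
})

test_that("group comparisons detect a generator-set k_on effect", {
  withr::with_seed(17, {
    fits <- data.frame(
      status = rep(c("young", "old"), each = 20),
      k_on = c(stats::rlnorm(20, log(0.03), 0.3),
               stats::rlnorm(20, log(0.008), 0.3)),
      t_on = c(stats::rnorm(20, 60, 15), stats::rnorm(20, 120, 25)),
      R_eq = stats::rlnorm(40, log(2.2), 0.2),
      converged = TRUE)
  })
  cmp <- compare_groups(fits, parameters = c("k_on", "t_on", "R_eq"),
                        alternative = c("old.vs.young" = "less"))
  k_row <- cmp[cmp$parameter == "k_on", ]
  expect_identical(k_row$group1, "old")   # alphabetical pair order
  expect_lt(k_row$p, 0.05)
  expect_true(all(cmp$U >= 0 & cmp$U <= 400))
  expect_identical(names(cmp)[6:9], c("mean1", "sd1", "mean2", "sd2"))
  # mean +/- SD reported per group
  expect_equal(k_row$mean1, mean(fits$k_on[fits$status == "old"]))
  expect_equal(k_row$sd2, stats::sd(fits$k_on[fits$status == "young"]))

  # row order invariance
  cmp_perm <- compare_groups(fits[sample(nrow(fits)), ],
                             parameters = "k_on",
                             alternative = c("old.vs.young" = "less"))
  expect_equal(cmp_perm$p, k_row$p)
  expect_equal(cmp_perm$U, k_row$U)

  # single group -> no comparisons
  expect_identical(nrow(compare_groups(fits[fits$status == "old", ],
                                       parameters = "k_on")), 0L)
  # insufficient group size -> skipped with reason
  few <- rbind(fits[1:20, ], fits[21, ])
  cmp_few <- compare_groups(few, parameters = "k_on", min_n = 2)
  expect_identical(cmp_few$skipped, "insufficient_group_size")
})

test_that("two-tailed Student t wrapper matches the classical test", {
  withr::with_seed(19, { x <- stats::rnorm(12); y <- stats::rnorm(12, 1) })
  st <- student_t_two_tailed(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(st$t, unname(ref$statistic))
  expect_equal(st$p, ref$p.value)
  expect_identical(st$df, 22)
})

test_that("comparison reports round-trip through CSV and JSON", {
  fits <- data.frame(status = rep(c("young", "old"), each = 5),
                     k_on = c(rep(0.03, 5), rep(0.01, 5)) +
                       seq(0, 0.009, by = 0.001),
                     converged = TRUE)
  cmp <- compare_groups(fits, parameters = "k_on")
  paths <- write_comparison_report(cmp, file.path(withr::local_tempdir(),
                                                  "cmp"))
  back <- utils::read.csv(paths[1])
  expect_equal(back$p, cmp$p)
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_match(js$metadata$note, "no multiple-testing correction")
  expect_equal(js$comparisons$U, cmp$U)
})
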