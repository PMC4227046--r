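test_that("group summaries follow the mean/SD/range/N layout", {
  tab <- tibble::tibble(genotype = c("WT", "WT", "mSOD1"),
                        pattern = "immediate",
                        rheobase = c(0.5, 0.7, NA))
  s <- summarize_population(tab, c("genotype", "pattern"),
                            properties = "rheobase")
  wt <- s[s$genotype == "WT", ]
  expect_equal(wt$mean, 0.6)
  expect_equal(wt$n, 2L)
  single <- s[s$genotype == "mSOD1", ]
  expect_equal(single$n, 0L)          # missing value not counted
  s1 <- summarize_population(tab[1, ], c("genotype", "pattern"),
                             properties = "rheobase")
  expect_equal(s1$sd, 0)              # degenerate single-row group
  expect_equal(s1$min, s1$max)
  expect_error(summarize_population(tab[0, ], "genotype"), "empty")
})

test_that("Mann-Whitney p-values match exact enumeration for small samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-9)
  expect_equal(mw_enumerate(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-9)
  withr::with_seed(51, {
    for (k in 1:8) {
      a <- rnorm(sample(3:10, 1))
      b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
      expect_equal(mann_whitney(a, b), mw_enumerate(a, b), tolerance = 1e-9)
    }
  })
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  p <- fisher_exact(13, 2, 3, 8)
  expect_equal(p, fisher_enumerate(13, 2, 3, 8), tolerance = 1e-9)
  expect_lt(abs(p - 0.003), 0.0015)   # the MMO-prevalence contingency
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(63, 31, 31, 18),
               fisher_enumerate(63, 31, 31, 18), tolerance = 1e-9)
  withr::with_seed(52, {
    for (k in 1:40) {
      n <- sample(4:30, 1)
      cts <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
      if (any(cts[1] + cts[2] == 0, cts[3] + cts[4] == 0,
              cts[1] + cts[3] == 0, cts[2] + cts[4] == 0)) next
      expect_equal(fisher_exact(cts[1], cts[2], cts[3], cts[4]),
                   fisher_enumerate(cts[1], cts[2], cts[3], cts[4]),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact(0, 0, 2, 3), "margin")
})

test_that("Kolmogorov-Smirnov separates shrunken dendritic path pools", {
  same <- ks_test(1:20, 1:20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(ks_test(rnorm(50), rnorm(50) + 100)$statistic, 1)

  # WT vs mSOD1 immediate trees (printed tree counts): pooled tip-to-soma
  # paths should differ strongly
  wt <- unlist(lapply(1:10, function(i) {
    compute_metrics(apply_slice_filter(generate_tree(
      tree_spec("WT", "immediate"), seed = 600 + i)))$dendritic_paths
  }))
  mut <- unlist(lapply(1:5, function(i) {
    compute_metrics(apply_slice_filter(generate_tree(
      tree_spec("mSOD1", "immediate"), seed = 700 + i)))$dendritic_paths
  }))
  expect_gt(length(wt), 200)
  expect_gt(length(mut), 100)
  expect_lt(ks_test(wt, mut)$p.value, 1e-3)
  expect_lt(mean(mut), mean(wt))
})

test_that("the zero-intercept slope is exact on constructed data", {
  g <- c(10, 30, 50, 80)
  fit <- zero_intercept_fit(g, 0.022 * g)
  expect_equal(fit$slope_mv, 22, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 4), tolerance = 1e-12)
  expect_equal(zero_intercept_fit(50, 1.1)$slope_mv, 22, tolerance = 1e-12)
  expect_error(zero_intercept_fit(c(0, 0), c(1, 2)), "degenerate")

  withr::with_seed(53, {
    g2 <- runif(200, 5, 150)
    i2 <- 0.02 * g2 + rnorm(200, 0, 0.2)
    fit2 <- zero_intercept_fit(g2, i2)
    expect_lt(abs(fit2$slope - grid_slope(g2, i2)), 1e-6)
  })
})

test_that("U equals the G^2-weighted mean of the per-cell delta-V", {
  withr::with_seed(54, {
    g <- runif(80, 10, 120)
    dv <- runif(80, 10, 35)          # heterogeneous thresholds, mV
    i <- g * dv / 1000
    fit <- zero_intercept_fit(g, i)
    expect_equal(fit$slope_mv, sum(g^2 * dv) / sum(g^2), tolerance = 1e-9)
    # homogeneous delta-V: U recovers it exactly
    fit0 <- zero_intercept_fit(g, g * 0.021)
    expect_equal(fit0$slope_mv, 21, tolerance = 1e-12)
  })
})

test_that("slope comparison separates the printed immediate-firing slopes", {
  # synthetic analog of the immediate-firing rheobase-conductance plots:
  # WT slope 22 mV (n = 29) vs mutant slope 15 mV (n = 16)
  withr::with_seed(55, {
    ga <- runif(29, 6, 98); ia <- 0.022 * ga + rnorm(29, 0, 0.12)
    gb <- runif(16, 6, 62); ib <- 0.015 * gb + rnorm(16, 0, 0.08)
    cs <- compare_slopes(ga, ia, gb, ib)
    expect_lt(cs$t_p, 0.05)
    expect_lt(cs$chow_p, 0.05)
    expect_gt(cs$shapiro_p_a, 0.01)
  })
  # an exact copy of the group: no slope break at all
  withr::with_seed(56, {
    g <- runif(20, 10, 100); i <- 0.02 * g + rnorm(20, 0, 0.1)
    cs0 <- compare_slopes(g, i, g, i)
    expect_lt(cs0$chow_f, 1e-20)
    expect_gt(cs0$chow_p, 0.999)
    expect_equal(cs0$t_stat, 0, tolerance = 1e-12)
  })
  expect_error(compare_slopes(1:2, 1:2, 1:5, 1:5), "3 points")
})

test_that("rank-based tests are invariant to common monotone transforms", {
  withr::with_seed(57, {
    a <- rnorm(12); b <- rnorm(15, 0.5)
    f <- function(x) exp(x)   # strictly increasing
    expect_equal(mann_whitney(a, b), mann_whitney(f(a), f(b)), tolerance = 1e-12)
    ks1 <- ks_test(a, b); ks2 <- ks_test(f(a), f(b))
    expect_equal(ks1$statistic, ks2$statistic, tolerance = 1e-12)
    # and to sample reordering
    expect_equal(mann_whitney(sample(a), sample(b)), mann_whitney(a, b),
                 tolerance = 1e-12)
  })
})

test_that("group comparison reports the table layout", {
  cells <- dplyr::bind_rows(
    sample_population(group_spec("WT", "immediate"), 12, seed = 58),
    sample_population(group_spec("mSOD1", "immediate"), 12, seed = 59))
  rep_ <- compare_groups(cells, compare = "genotype", within = "pattern",
                         properties = c("rheobase_true", "g_in"))
  expect_equal(nrow(rep_), 2L)
  expect_true(all(c("mean_a", "mean_b", "p.value") %in% names(rep_)))
  expect_true(all(rep_$p.value >= 0 & rep_$p.value <= 1))
})
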