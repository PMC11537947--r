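test_that("latency classification partitions every trial once", {
  expect_equal(as.character(classify_saccades(60, "marmoset")), "express")
  expect_equal(as.character(classify_saccades(80, "marmoset")), "regular")
  expect_equal(as.character(classify_saccades(40, "marmoset")), "anticipatory")
  expect_equal(as.character(classify_saccades(-15, "marmoset")), "anticipatory")
  expect_equal(as.character(classify_saccades(80, "human")), "express")
  expect_equal(as.character(classify_saccades(100, "human")), "regular")
  set.seed(3)
  srt <- c(sample(-50:400, 500, replace = TRUE), NA)
  cls <- classify_saccades(srt, "marmoset")
  expect_false(any(is.na(cls)))
  expect_equal(length(cls), length(srt))
  # boundary cases: [50, 75) is express for marmosets
  expect_equal(as.character(classify_saccades(c(50, 74, 75), "marmoset")),
               c("express", "express", "regular"))
})

test_that("histogram proportions sum to one and match direct counts", {
  hp <- histogram_proportions(100, histogram_spec())
  expect_equal(sum(hp$proportion), 1)
  expect_equal(hp$proportion[hp$bin_left == 96], 1)   # single value
  hp2 <- histogram_proportions(c(10, 20), histogram_spec())
  expect_equal(sort(hp2$proportion[hp2$count > 0]), c(0.5, 0.5))
  # uniform grid of values gives a flat histogram
  v <- seq(0.5, 449.5, by = 1)
  hp3 <- histogram_proportions(v, histogram_spec())
  expect_true(all(hp3$count == 6))
  expect_error(histogram_proportions(NA_real_), "empty")
  # values outside the default range extend the binning
  hp4 <- histogram_proportions(c(-20, 500), histogram_spec())
  expect_equal(sum(hp4$proportion), 1)
})

test_that("binned CDF differences recover the histogram", {
  set.seed(8)
  v <- stats::rlnorm(400, 4.5, 0.5)
  spec <- histogram_spec()
  hp <- histogram_proportions(v, spec)
  cdf <- srt_cdf(v)
  binned_cdf <- cdf(hp$bin_right - 1e-9)
  expect_equal(diff(c(0, binned_cdf)), hp$proportion, tolerance = 1e-12)
  expect_true(all(diff(cdf(sort(v))) >= 0))
  expect_equal(cdf(max(v)), 1)
})

test_that("R-squared and MSE match hand-computed values", {
  expect_equal(r_squared(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1)
  o <- c(0.2, 0.3, 0.5)
  expect_equal(r_squared(o, rep(mean(o), 3)), 0)
  expect_equal(r_squared(o, c(0.25, 0.25, 0.5)), 0.8929, tolerance = 1e-3)
  # hand computation: SSres = 0.005, SStot = 0.04667
  expect_equal(r_squared(o, c(0.25, 0.25, 0.5)), 1 - 0.005 / (0.14 / 3))
  expect_equal(mse(c(0.5, 0.5), c(0.4, 0.6)), 0.01)
  expect_equal(mse(c(0.4, 0.6), c(0.5, 0.5)), 0.01)   # symmetric
  expect_equal(mse(o, o), 0)
  # R^2 <= 1 always, with equality only for identical vectors
  set.seed(4)
  for (k in 1:20) {
    a <- stats::runif(10); b <- stats::runif(10)
    expect_lte(r_squared(a, b), 1)
    if (!isTRUE(all.equal(a, b))) expect_lt(r_squared(a, b), 1)
  }
})

test_that("Wasserstein distance has its closed-form and metric properties", {
  expect_equal(wasserstein_1d(c(5, 9, 13), c(5, 9, 13)), 0)
  expect_equal(wasserstein_1d(0, 5), 5)          # point masses
  set.seed(12)
  v <- stats::rlnorm(300, 4.8, 0.4)
  expect_equal(wasserstein_1d(v, v + 13), 13)    # translation property
  # metric properties against the brute-force transport oracle
  for (k in 1:12) {
    a <- stats::runif(sample(3:9, 1), 0, 100)
    b <- stats::runif(sample(3:9, 1), 0, 100)
    cc <- stats::runif(sample(3:9, 1), 0, 100)
    expect_equal(wasserstein_1d(a, b), oracle_wasserstein(a, b),
                 tolerance = 1e-10)
    expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))
    expect_lte(wasserstein_1d(a, cc),
               wasserstein_1d(a, b) + wasserstein_1d(b, cc) + 1e-12)
  }
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
})

test_that("quantiles use linear interpolation and rank-sum tests are exact when small", {
  expect_equal(unname(quantile_table(c(1, 2, 3), 0.5)), 2)
  v <- c(10, 20, 30, 40)
  expect_equal(unname(quantile_table(v, 0.5)), 25)  # type-7 interpolation
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$p_value, 1 / 3)                   # 2 of 6 arrangements
  expect_match(rs$method, "exact")
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)                     # maximal, tied case
  # identical large samples: approximation path, p ~ 1
  big <- rank_sum_test(rep(1:20, 2), rep(1:20, 2))
  expect_match(big$method, "approximation")
  expect_gt(big$p_value, 0.9)
  # agreement with the standard exact test on a no-ties case
  set.seed(21)
  a <- stats::runif(8); b <- stats::runif(7) + 0.3
  ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(rank_sum_test(a, b)$p_value, ref, tolerance = 1e-12)
})

test_that("tail fractions count strict exceedances", {
  expect_equal(fraction_exceeding(c(100, 300), 250), 0.5)
  expect_equal(fraction_exceeding(c(100, 200), 250), 0)
  expect_equal(fraction_exceeding(c(100, 250, 300), 250), 1 / 3)
  expect_error(fraction_exceeding(numeric(0), 250), "empty")
})

test_that("the anticipatory boundary is recovered from landing-point labels", {
  # errant saccades concentrated below 60 ms, correct ones above
  set.seed(31)
  n_err <- 300; n_corr <- 2000
  srt <- c(stats::runif(n_err, 20, 60), stats::runif(n_corr, 61, 200))
  correct <- c(rep(FALSE, n_err), rep(TRUE, n_corr))
  est <- estimate_anticipatory_boundary(srt, correct)
  expect_equal(est$flag, "ok")
  expect_lte(abs(est$boundary_ms - 60), 6)       # within one bin
  # all-correct sample: flagged, boundary at the sample minimum's bin
  est2 <- estimate_anticipatory_boundary(c(80, 90, 100), rep(TRUE, 3))
  expect_equal(est2$flag, "no_errant")
  expect_equal(est2$boundary_ms, 78)
  expect_error(estimate_anticipatory_boundary(numeric(0), logical(0)),
               "empty")
})

test_that("the comparison report is coherent and self-comparison is perfect", {
  set.seed(14)
  obs <- stats::rlnorm(600, 4.8, 0.35)
  rep_self <- compare_srt_distributions(obs, obs)
  expect_equal(rep_self$r_squared, 1)
  expect_equal(rep_self$mse, 0)
  expect_equal(rep_self$wasserstein_ms, 0)
  mod <- obs + 20
  rep2 <- compare_srt_distributions(obs, mod)
  expect_equal(sum(rep2$bins$observed), 1, tolerance = 1e-9)
  expect_equal(sum(rep2$bins$model), 1, tolerance = 1e-9)
  expect_equal(rep2$wasserstein_ms, 20, tolerance = 1e-9)
  expect_true(all(diff(rep2$bins$observed_cdf) >= 0))
  expect_lt(rep2$rank_sum$p_value, 0.05)
  expect_lt(rep2$r_squared, 1)
})
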