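test_that("binning counts lengths into half-open delta intervals", {
  d <- bin_lengths(c(0.5, 1.5, 1.6, 2.5), delta = 1, origin = 0)
  expect_equal(d$counts, c(1, 2, 1))
  expect_equal(d$phi, c(0.5, 1, 0.5))
  expect_equal(d$centers, c(0.5, 1.5, 2.5))
  expect_equal(sum(d$counts), d$n)
  # a bin boundary value lands in the upper bin
  expect_equal(bin_lengths(c(0.5, 1.0), delta = 1)$counts, c(1, 1))
  # all in one bin
  expect_equal(bin_lengths(c(2.1, 2.2), delta = 1)$phi, c(0, 0, 1))
  # halving delta preserves the count total
  x <- runif(500, 0, 5)
  expect_equal(sum(bin_lengths(x, 0.5)$counts), 500)
  expect_equal(max(bin_lengths(x, 0.5)$phi), 1)
  expect_error(bin_lengths(numeric(0)), "empty")
  expect_error(bin_lengths(c(0.2, 3), origin = 1), "origin")
})

test_that("widths of the triangular curve match hand interpolation", {
  d <- bin_lengths(c(0.5, 1.5, 1.5, 2.5), delta = 1)
  # phi = (0.5, 1, 0.5) at centers (0.5, 1.5, 2.5), zero-padded one delta out
  expect_equal(width_at_fraction(d, 0.5), 2.0)
  expect_equal(width_at_fraction(d, 0.75), 1.0)
  w <- widths(d)
  expect_equal(unname(w["width_50"]), 2.0)
  expect_equal(unname(w["width_66"]), 1.36)
  expect_equal(unname(w["width_75"]), 1.0)
  expect_error(width_at_fraction(d, 1.2))
})

test_that("width is monotone non-increasing in the fraction", {
  for (seed in 1:20) {
    x <- local({set.seed(seed); rnorm(300, 3, runif(1, 0.2, 1))})
    x <- x[x > 0]
    d <- bin_lengths(x, delta = 0.5)
    fr <- seq(0.1, 0.9, by = 0.1)
    w <- vapply(fr, function(f) width_at_fraction(d, f), numeric(1))
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0))
  }
})

test_that("widths are invariant to rescaling the counts", {
  x <- local({set.seed(42); rnorm(400, 3, 0.6)})
  d1 <- bin_lengths(x, 0.5)
  d3 <- bin_lengths(rep(x, 3), 0.5)  # every count tripled
  expect_equal(widths(d1), widths(d3))
})

test_that("Gaussian samples recover the closed-form fractional widths", {
  # moderate bins (many counts per bin) keep the unit-max normalization
  # noise small; single-draw accuracy here is a few percent
  x <- local({set.seed(99); rnorm(1e5, 10, 1)})
  d <- bin_lengths(x, delta = 0.25)
  for (f in c(0.5, 0.66, 0.75))
    expect_lt(abs(width_at_fraction(d, f) / gaussian_width(f) - 1), 0.05)
  # averaging over draws removes the sampling noise
  mean_err <- rowMeans(sapply(1:5, function(s) {
    xi <- local({set.seed(300 + s); rnorm(1e5, 10, 1)})
    di <- bin_lengths(xi, delta = 0.25)
    vapply(c(0.5, 0.66, 0.75), function(f)
      width_at_fraction(di, f) / gaussian_width(f) - 1, numeric(1))
  }))
  expect_true(all(abs(mean_err) < 0.025))
})

test_that("replicate width summaries average per-replicate curves", {
  s <- length_sample(rep(c(1.5, 2.5, 2.5, 3.5), 3),
                     replicate = rep(1:3, each = 4))
  rs <- replicate_width_summary(s, delta = 1)
  expect_equal(rs$sd_width_mm, rep(0, 3))        # identical replicates
  expect_equal(rs$n_replicates, rep(3, 3))
  one <- replicate_width_summary(list(c(1.5, 2.5, 2.5, 3.5)), delta = 1)
  expect_true(all(is.na(one$sd_width_mm)))       # no SD from one replicate
  expect_false(any(is.na(one$mean_width_mm)))
})

test_that("cv is the n-1 sample SD over the mean and is scale invariant", {
  expect_equal(cv(c(1, 2, 3)), 0.5)
  expect_equal(cv(rep(4, 10)), 0)
  for (seed in 1:10) {
    x <- local({set.seed(seed); runif(50, 1, 5)})
    c1 <- cv(x)
    expect_equal(cv(3.7 * x), c1)
    expect_equal(cv(0.01 * x), c1)
  }
  expect_error(cv(c(-3, 1)), "mean")
  expect_error(cv(2))
})

test_that("McKay CI matches its chi-square-quantile formula", {
  ci <- mckay_ci(0.24, 1037, level = 0.90)
  expect_equal(ci$ci_low, 0.2311997, tolerance = 1e-5)
  expect_equal(ci$ci_high, 0.2495746, tolerance = 1e-5)
  ci2 <- mckay_ci(0.27, 1176, level = 0.90)
  expect_equal(ci2$ci_low, 0.2605527, tolerance = 1e-5)
  expect_equal(ci2$ci_high, 0.2802416, tolerance = 1e-5)
  # contains the point estimate; narrows monotonically with n
  widths_by_n <- vapply(c(10, 100, 1000, 10000), function(n) {
    c <- mckay_ci(0.3, n, 0.90)
    expect_lte(c$ci_low, 0.3); expect_gte(c$ci_high, 0.3)
    c$ci_high - c$ci_low
  }, numeric(1))
  expect_true(all(diff(widths_by_n) < 0))
  # vanishing level collapses the interval onto the CV
  c0 <- mckay_ci(0.3, 5000, level = 1e-9)
  expect_equal(c0$ci_low, 0.3, tolerance = 1e-3)
  expect_equal(c0$ci_high, 0.3, tolerance = 1e-3)
  # huge CV at tiny n makes the radicand non-positive
  expect_error(mckay_ci(5, 2, 0.90), "McKay")
})

test_that("pooled t test matches the hand-computed oracle", {
  r <- ttest_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  same <- ttest_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_error(ttest_two_sample(c(1, 1), c(2, 2)), "unbounded")
  # Welch uses fractional df when variances differ
  a <- c(1, 2, 3, 4); b <- c(10, 30, 50, 70, 90)
  expect_lt(ttest_two_sample(a, b, welch = TRUE)$df,
            ttest_two_sample(a, b)$df)
})

test_that("yield extrapolation divides by sampled fraction and weight", {
  y <- yield_per_gfw(150, 0.15, 2.0)
  expect_equal(y$embryos_per_gfw, 500)
  expect_equal(yield_per_gfw(80, 1, 2)$embryos_per_gfw, 40)
  # harvesting 15% vs 75% of the same vessel: 5x extrapolation asymmetry
  expect_equal(yield_per_gfw(100, 0.15, 1)$embryos_per_gfw /
                 yield_per_gfw(100, 0.75, 1)$embryos_per_gfw, 5)
  expect_error(yield_per_gfw(10, 0, 1), "fraction")
  expect_error(yield_per_gfw(10, 0.5, 0), "weight")
})

test_that("germination rates report integer percentages of collected", {
  r <- germination_rates(germination_record(10, 10, 10))
  expect_equal(c(r$pct_started, r$pct_rooted), c(100, 100))
  expect_error(germination_rates(germination_record(0, 0, 0)), "undefined")
  expect_error(germination_record(10, 5, 7))  # rooted > started
})

test_that("normality check warns on clearly non-normal lengths, not gates", {
  skewed <- exp(local({set.seed(1); rnorm(500)}))
  expect_warning(check_normality(skewed), "normality")
  normal <- local({set.seed(2); rnorm(500, 3, 0.5)})
  expect_silent(p <- check_normality(normal))
})
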