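#' Bin embryo lengths into the normalized distribution function
#'
#' Counts lengths in half-open intervals `[origin + k*delta,
#' origin + (k+1)*delta)` and normalizes the counts to unit maximum, giving
#' the normalized length-distribution curve phi evaluated at the bin
#' centers. Any positive rescaling of the counts leaves all
#' fraction-of-maximum widths unchanged, so unit-maximum normalization is
#' the natural (and consequence-free) convention.
#'
#' @param sample A `length_sample`, data frame with a `length_mm` column, or
#'   numeric vector of lengths (mm).
#' @param delta Bin width, mm; positive. The classical choice for mature
#'   spruce embryos is 1 mm (intervals 0-1, 1-2, ... 4-5 mm); 0.5 mm gives
#'   better resolution of the curve.
#' @param origin Left edge of the first bin, mm. Default 0.
#' @return An object of class `binned_distribution`: list with `delta`,
#'   `origin`, `breaks`, `counts`, `centers`, `phi`, `n`.
#' @examples
#' d <- bin_lengths(c(0.5, 1.5, 1.6, 2.5), delta = 1)
#' d$counts  # 1 2 1
#' d$phi     # 0.5 1.0 0.5
#' @export
bin_lengths <- function(sample, delta = 1, origin = 0) {
  if (is.data.frame(sample)) sample <- sample$length_mm
  stopifnot(is.numeric(delta), delta > 0)
  if (length(sample) == 0) stop("cannot bin an empty length sample")
  if (any(sample < origin))
    stop("lengths below the bin origin (", origin, " mm)")
  k <- floor((max(sample) - origin) / delta) + 1L
  breaks <- origin + delta * (0:k)
  counts <- tabulate(findInterval(sample, breaks,
                                  rightmost.closed = FALSE), nbins = k)
  structure(list(delta = delta, origin = origin, breaks = breaks,
                 counts = counts,
                 centers = origin + delta * (seq_len(k) - 0.5),
                 phi = counts / max(counts),
                 n = length(sample)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat("Binned length distribution: n =", x$n, ", delta =", x$delta,
      "mm, origin =", x$origin, "mm\n")
  print(data.frame(center_mm = x$centers, count = x$counts,
                   phi = round(x$phi, 3)))
  invisible(x)
}

#' Full width of the normalized distribution at a fraction of maximum
#'
#' The curve is phi linearly interpolated between successive bin centers
#' and taken as zero one bin width beyond each end. The width at level `f`
#' is the distance between the outermost crossings of that level, so for a
#' unimodal curve it is the usual full width (f = 0.5 gives the FWHM) and
#' for a multimodal curve the conservative, envelope-spanning width.
#'
#' @param dist A `binned_distribution` from [bin_lengths()].
#' @param f Fraction of maximum, strictly between 0 and 1.
#' @return Width in mm.
#' @examples
#' d <- bin_lengths(rep(1:3, c(1, 2, 1)), delta = 1, origin = 0.0)
#' width_at_fraction(bin_lengths(c(0.5, 1.5, 1.5, 2.5, 2.5, 2.5, 2.5,
#'                                 3.5, 3.5, 4.5), delta = 1), 0.5)
#' @export
width_at_fraction <- function(dist, f) {
  stopifnot(inherits(dist, "binned_distribution"),
            is.numeric(f), f > 0, f < 1)
  if (all(dist$counts == 0)) stop("all-zero distribution has no width")
  xs <- c(dist$centers[1] - dist$delta, dist$centers,
          dist$centers[length(dist$centers)] + dist$delta)
  ys <- c(0, dist$phi, 0)
  ge <- ys >= f
  j1 <- which(ge)[1]
  j2 <- which(ge)[sum(ge)]
  left <- xs[j1 - 1] + (f - ys[j1 - 1]) / (ys[j1] - ys[j1 - 1]) *
    (xs[j1] - xs[j1 - 1])
  right <- xs[j2] + (ys[j2] - f) / (ys[j2] - ys[j2 + 1]) *
    (xs[j2 + 1] - xs[j2])
  right - left
}

#' Widths at 50, 66 and 75% of maximum
#'
#' Applies [width_at_fraction()] at the three standard levels; the result
#' is monotone non-increasing in the level. Smaller widths indicate a more
#' synchronized (more uniform in length) embryo population.
#'
#' @param dist A `binned_distribution`.
#' @param fractions Levels at which to evaluate; default `c(0.50, 0.66,
#'   0.75)`.
#' @return A `width_set`: named numeric vector `width_50, width_66,
#'   width_75` (names follow the requested fractions), mm.
#' @export
widths <- function(dist, fractions = c(0.50, 0.66, 0.75)) {
  w <- vapply(fractions, function(f) width_at_fraction(dist, f), numeric(1))
  names(w) <- paste0("width_", sub("^0\\.", "", sprintf("%.2f", fractions)))
  structure(w, class = c("width_set", "numeric"))
}

#' Per-replicate width summary
#'
#' Computes the width set for each replicate's own normalized distribution,
#' then the across-replicate mean and sample SD (n-1) per fraction — the
#' summary reported for replicated bioreactor or plate experiments. With a
#' single replicate the SD is `NA`.
#'
#' @param samples A `length_sample` with a `replicate` column (split
#'   internally), or a list of `length_sample`s / numeric vectors.
#' @param delta,origin Passed to [bin_lengths()].
#' @param fractions Passed to [widths()].
#' @return Data frame with columns `fraction`, `mean_width_mm`,
#'   `sd_width_mm`, `n_replicates`.
#' @export
replicate_width_summary <- function(samples, delta = 1, origin = 0,
                                    fractions = c(0.50, 0.66, 0.75)) {
  if (is.data.frame(samples))
    samples <- split(samples$length_mm, samples$replicate)
  stopifnot(length(samples) >= 1)
  W <- t(vapply(samples, function(s)
    as.numeric(widths(bin_lengths(s, delta, origin), fractions)),
    numeric(length(fractions))))
  data.frame(fraction = fractions,
             mean_width_mm = colMeans(W),
             sd_width_mm = if (nrow(W) >= 2) apply(W, 2, sd)
                           else rep(NA_real_, length(fractions)),
             n_replicates = nrow(W))
}

#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) divided by the sample mean: the scale-free
#' spread of embryo lengths (or of per-vessel yields). Requires a positive
#' mean and at least two values.
#'
#' @param values Numeric vector, n >= 2.
#' @return CV, dimensionless.
#' @examples
#' cv(c(1, 2, 3))  # 0.5
#' @export
cv <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  if (m <= 0) stop("CV is undefined for non-positive mean (", m, ")")
  sd(values) / m
}

#' McKay confidence interval for a coefficient of variation
#'
#' Chi-square-quantile approximation for a CI on a normal population CV.
#' With `K` the sample CV, `v = n - 1`, and `u` a chi-square quantile with
#' `v` degrees of freedom, each limit is
#' `K / sqrt((u / v) * (1 + K^2) - K^2)`, using the upper-tail quantile
#' `qchisq(1 - alpha/2, v)` for the lower limit and the lower-tail quantile
#' for the upper limit. The interval always contains `K` and narrows as `n`
#' grows.
#'
#' @param cv Sample coefficient of variation, positive.
#' @param n Sample size, >= 2.
#' @param level Confidence level, e.g. 0.90.
#' @return An object of class `cv_estimate`: list with `cv`, `n`, `level`,
#'   `ci_low`, `ci_high`.
#' @examples
#' mckay_ci(0.24, 1037, level = 0.90)
#' @export
mckay_ci <- function(cv, n, level = 0.90) {
  stopifnot(is.numeric(cv), cv > 0, n >= 2, level > 0, level < 1)
  v <- n - 1
  alpha <- 1 - level
  limit <- function(u) {
    rad <- (u / v) * (1 + cv^2) - cv^2
    if (rad <= 0)
      stop("McKay interval undefined: (u/v)(1+K^2) - K^2 <= 0 ",
           "(CV too large for this sample size)")
    cv / sqrt(rad)
  }
  structure(list(cv = cv, n = as.integer(n), level = level,
                 ci_low = limit(qchisq(1 - alpha / 2, v)),
                 ci_high = limit(qchisq(alpha / 2, v))),
            class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("CV %.4f (n = %d), %d%% CI [%.4f, %.4f] (McKay)\n",
              x$cv, x$n, round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Independent two-sample t test
#'
#' Student's pooled-variance two-sample t test (two-sided), the classical
#' default for comparing dispersed vs non-dispersed groups; Welch's
#' unequal-variance variant is available via `welch = TRUE`. Degenerate
#' zero-variance input is handled explicitly: identical constant groups
#' give `t = 0, p = 1`; constant groups with unequal means have no finite
#' t statistic and are an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's test instead of pooled variance.
#' @return List with `t`, `df`, `p`.
#' @examples
#' ttest_two_sample(c(1, 2, 3), c(4, 5, 6))
#' @export
ttest_two_sample <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means: ",
         "t statistic is unbounded")
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Extrapolated embryo yield per gram fresh weight
#'
#' Only a fraction of the mature embryos in a vessel is harvested and
#' counted; the total is extrapolated by dividing by the sampled fraction
#' (itself estimated from tissue areas, see [estimate_coverage()]) and
#' normalized by the starting fresh weight of tissue.
#'
#' @param harvested_count Number of embryos actually harvested and counted.
#' @param sampled_fraction Fraction of the vessel's embryos harvested, in
#'   `(0, 1]`.
#' @param initial_fw_g Starting fresh weight of tissue, grams; positive.
#' @return A `yield_stats` list: `harvested_count`, `sampled_fraction`,
#'   `initial_fw_g`, `embryos_per_gfw`.
#' @examples
#' yield_per_gfw(150, 0.15, 2.0)$embryos_per_gfw  # 500
#' @export
yield_per_gfw <- function(harvested_count, sampled_fraction, initial_fw_g) {
  if (!is.numeric(sampled_fraction) || sampled_fraction <= 0 ||
      sampled_fraction > 1)
    stop("sampled_fraction must be in (0, 1]")
  if (!is.numeric(initial_fw_g) || initial_fw_g <= 0)
    stop("initial fresh weight must be positive")
  stopifnot(harvested_count >= 0)
  structure(list(harvested_count = harvested_count,
                 sampled_fraction = sampled_fraction,
                 initial_fw_g = initial_fw_g,
                 embryos_per_gfw =
                   harvested_count / sampled_fraction / initial_fw_g),
            class = "yield_stats")
}

#' Germination percentages for a treatment group
#'
#' Percent of collected embryos that started germination, and percent that
#' developed a root of at least 1 cm, rounded to integer percent for
#' reporting (raw proportions are also returned).
#'
#' @param rec A `germination_record`, or the collected count (with
#'   `started` and `rooted` supplied).
#' @param started,rooted Counts, used when `rec` is numeric.
#' @return List with `pct_started`, `pct_rooted` (integer percent) and
#'   `prop_started`, `prop_rooted` (raw proportions).
#' @examples
#' germination_rates(germination_record(1006, 865, 748))  # 86%, 74%
#' @export
germination_rates <- function(rec, started = NULL, rooted = NULL) {
  if (is.numeric(rec)) rec <- germination_record(rec, started, rooted)
  stopifnot(inherits(rec, "germination_record"))
  if (rec$collected == 0)
    stop("germination rate undefined: no embryos collected")
  list(pct_started = round(100 * rec$started / rec$collected),
       pct_rooted = round(100 * rec$rooted / rec$collected),
       prop_started = rec$started / rec$collected,
       prop_rooted = rec$rooted / rec$collected)
}

#' Optional normality diagnostic for a length sample
#'
#' Shapiro-Wilk test on (at most 5000) lengths, reported as a warning when
#' p < `alpha`; never a gate — binned widths and CVs are computed
#' regardless.
#'
#' @param sample `length_sample` or numeric vector.
#' @param alpha Warning threshold; default 0.01.
#' @return The shapiro.test p value, invisibly (`NA` if n < 3).
#' @export
check_normality <- function(sample, alpha = 0.01) {
  if (is.data.frame(sample)) sample <- sample$length_mm
  if (length(sample) < 3 || sd(sample) == 0) return(invisible(NA_real_))
  if (length(sample) > 5000) sample <- sample[seq_len(5000)]
  p <- shapiro.test(sample)$p.value
  if (p < alpha)
    warning(sprintf(
      "lengths deviate from normality (Shapiro-Wilk p = %.2g)", p))
  invisible(p)
}
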