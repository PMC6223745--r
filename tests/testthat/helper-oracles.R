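# Closed-form moments of a normal truncated to (low, high]; independent
# oracle for the rejection sampler.
truncnorm_sd <- function(mean, sd, low = 0, high = Inf) {
  a <- (low - mean) / sd
  b <- (high - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- if (is.finite(b)) dnorm(b) else 0
  bdb <- if (is.finite(b)) b * db else 0
  m1 <- (da - db) / Z
  v <- 1 + (a * da - bdb) / Z - m1^2
  sd * sqrt(v)
}

# Full width of a unit-SD Gaussian density at fraction f of its maximum.
gaussian_width <- function(f, sigma = 1) 2 * sigma * sqrt(2 * log(1 / f))

# Filled-disc binary matrix, diameter d px, centered.
disc_matrix <- function(d, pad = 6L) {
  n <- ceiling(d) + 2L * pad
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), n), n)
  (xs - c0)^2 + (t(xs) - c0)^2 <= (d / 2)^2
}

# Match measured particles to ground-truth rows by nearest centroid.
match_to_truth <- function(measured, truth) {
  idx <- vapply(seq_len(nrow(measured)), function(i) {
    which.min((truth$cx_px - measured$cx_px[i])^2 +
              (truth$cy_px - measured$cy_px[i])^2)
  }, integer(1))
  stopifnot(!anyDuplicated(idx))
  truth[idx, , drop = FALSE]
}
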