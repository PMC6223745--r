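test_that("binarize handles fixed and Otsu thresholds", {
  m <- matrix(c(0, 0, 255, 255, 0, 255), 2, 3)
  expect_identical(binarize(m, "fixed", threshold = 128), m > 128)
  two_level <- matrix(rep(c(40, 200), each = 50), 10, 10)
  bw <- binarize(two_level, "otsu")
  expect_identical(bw, two_level > 40)  # threshold strictly between levels
  expect_error(binarize(matrix(7, 5, 5), "otsu"), "constant")
  # logical input passes through untouched
  expect_identical(binarize(m > 128), m > 128)
})

test_that("Otsu on a rendered plate recovers the rendered mask exactly", {
  ps <- plate_image_spec(600, 600, mm_per_px = 0.02)
  r <- render_plate_image(ps, c(2, 3, 4), seed = 4)
  gray <- r$image * 200 + 20  # foreground 220, background 20
  expect_identical(unname(binarize(gray, "otsu")), r$image == 1L)
})

test_that("labeling uses 8-connectivity with deterministic ordering", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:3] <- TRUE          # square A
  m[8:9, 8:9] <- TRUE          # square B, disjoint
  expect_length(label_particles(m, min_pixels = 1), 2)
  # corner-touching squares merge under 8-connectivity
  m2 <- matrix(FALSE, 12, 12)
  m2[2:3, 2:3] <- TRUE
  m2[4:5, 4:5] <- TRUE
  expect_length(label_particles(m2, min_pixels = 1), 1)
  # ordering: top-most first, then left-most
  m3 <- matrix(FALSE, 20, 20)
  m3[10:11, 2:3] <- TRUE   # left, lower
  m3[2:3, 15:16] <- TRUE   # top, right
  m3[2:3, 5:6] <- TRUE     # top, left
  p <- label_particles(m3, min_pixels = 1)
  firsts <- t(vapply(p, function(q) q[1, ], c(x = 0L, y = 0L)))
  expect_equal(unname(firsts[, "y"]), c(2L, 2L, 10L))
  expect_equal(unname(firsts[1, "x"]), 5L)
  # min_pixels filters debris; with 0 every foreground pixel is accounted for
  m4 <- m
  m4[6, 6] <- TRUE  # 1-px speck
  expect_length(label_particles(m4, min_pixels = 4), 2)
  all_px <- sum(vapply(label_particles(m4, min_pixels = 0), nrow,
                       integer(1)))
  expect_equal(all_px, sum(m4))
  expect_length(label_particles(matrix(FALSE, 5, 5)), 0)
})

test_that("moment ellipse of a disc recovers its diameter", {
  for (d in c(21, 40, 75)) {
    meas <- measure_particle(label_particles(disc_matrix(d),
                                             min_pixels = 1)[[1]], 1)
    expect_lt(abs(meas$major_mm / d - 1), 0.02)
    expect_lt(abs(meas$minor_mm / d - 1), 0.02)
  }
})

test_that("measurement agrees with EBImage's moment features", {
  ps <- plate_image_spec(800, 800, mm_per_px = 0.02,
                         aspect_ratio_sd = 0.05)
  r <- render_plate_image(ps, c(2.2, 3.1, 4.5), seed = 12)
  ours <- measure_all(r$image, 1)  # mm_per_px 1: stay in pixel units
  ref <- EBImage::computeFeatures.moment(EBImage::bwlabel(r$image * 1.0))
  expect_equal(sort(ours$major_mm), sort(unname(ref[, "m.majoraxis"])),
               tolerance = 1e-6)
})

test_that("measurement is invariant to rotation and translation", {
  ps <- plate_image_spec(700, 700, mm_per_px = 0.02,
                         aspect_ratio_mean = 0.35, aspect_ratio_sd = 0)
  majors <- vapply(1:8, function(s) {
    r <- render_plate_image(ps, 3.5, seed = s)  # new orientation + position
    measure_all(r$image, 0.02)$major_mm
  }, numeric(1))
  expect_true(all(abs(majors / 3.5 - 1) < 0.02))
})

test_that("calibration scales lengths linearly and areas quadratically", {
  px <- label_particles(disc_matrix(31), min_pixels = 1)[[1]]
  m1 <- measure_particle(px, 0.01)
  m2 <- measure_particle(px, 0.02)
  expect_equal(m2$major_mm, 2 * m1$major_mm)
  expect_equal(m2$minor_mm, 2 * m1$minor_mm)
  expect_equal(m2$area_mm2, 4 * m1$area_mm2)
  expect_equal(m1$area_mm2, m1$pixel_count * 0.01^2)
})

test_that("a single pixel yields degenerate zero axes, not an error", {
  m <- measure_particle(cbind(x = 5L, y = 5L), 0.02)
  expect_equal(m$major_mm, 0)
  expect_equal(m$minor_mm, 0)
  expect_equal(m$pixel_count, 1)
})

test_that("coverage fraction is the sampled/total area ratio", {
  expect_equal(estimate_coverage(15, 100, 1)$fraction, 0.15)
  expect_equal(estimate_coverage(59, 100, 1)$fraction, 0.59)
  expect_equal(estimate_coverage(100, 100, 0.02)$fraction, 1.0)
  expect_error(estimate_coverage(0, 0, 1), "positive")
  expect_error(estimate_coverage(101, 100, 1))
})

test_that("area histograms summarize replicates with SD across them", {
  edges <- seq(0, 1, by = 0.2)
  h1 <- area_histogram(list(c(0.05, 0.1, 0.15)), edges)
  expect_equal(h1$mean_fraction, c(1, 0, 0, 0, 0))
  expect_true(all(is.na(h1$sd_fraction)))
  rep3 <- list(c(0.1, 0.3, 0.5), c(0.1, 0.3, 0.5), c(0.1, 0.3, 0.5))
  h3 <- area_histogram(rep3, edges)
  expect_equal(h3$sd_fraction, rep(0, 5))
  expect_equal(rowSums(h3$fractions), rep(1, 3))
  expect_warning(area_histogram(list(c(0.1), numeric(0)), edges), "empty")
  # calibrated synthetic areas put ~80% of mass at or below 0.2 mm^2
  a <- sample_aggregate_areas(
    aggregate_size_spec(n_aggregates = 2e4,
                        target_fraction_leq = c(0.2, 0.80)), seed = 8)
  h <- area_histogram(list(a[a <= 1.0]), seq(0, 1, by = 0.1))
  expect_lt(abs(sum(h$mean_fraction[1:2]) * mean(a <= 1.0) - 0.80), 0.02)
})

test_that("plate images survive a PNG write/read round trip", {
  ps <- plate_image_spec(300, 300, mm_per_px = 0.02)
  r <- render_plate_image(ps, c(2, 3), seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(r$image, path)
  back <- read_image(path)
  expect_identical(unname(back > 0.5), r$image == 1L)
  m <- measure_all(back, 0.02, method = "fixed", threshold = 0.5)
  expect_equal(nrow(m), 2)
})
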