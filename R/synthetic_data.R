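#' Specification of a synthetic embryo-length population
#'
#' Describes one treatment group as a truncated-normal length population
#' with optional replicate-level variation. Mature conifer somatic embryos
#' in a culture are close to normally distributed in length; negative
#' lengths being physically impossible, the normal is truncated at
#' `truncation_low` (default 0 mm).
#'
#' @param mean_length Population mean length, mm. Must be positive.
#' @param sd_length Population SD of length, mm (within a replicate).
#' @param n_embryos Embryos per replicate.
#' @param n_replicates Number of replicates (bioreactors or plates).
#' @param between_replicate_sd SD (mm) of the normal perturbation applied to
#'   each replicate's mean, modelling between-vessel variation. Default 0.
#' @param truncation_low,truncation_high Support bounds, mm; lengths are kept
#'   in `(truncation_low, truncation_high]`. `truncation_high = Inf` by
#'   default.
#' @param label Treatment label carried into the sample.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(3.05, 0.74, n_embryos = 173, n_replicates = 6,
#'                 label = "dispersed")
#' @export
population_spec <- function(mean_length, sd_length, n_embryos,
                            n_replicates = 1L, between_replicate_sd = 0,
                            truncation_low = 0, truncation_high = Inf,
                            label = "group") {
  stopifnot(is.numeric(mean_length), mean_length > 0,
            is.numeric(sd_length), sd_length >= 0,
            n_embryos >= 1, n_replicates >= 1,
            between_replicate_sd >= 0,
            truncation_low < mean_length,
            truncation_high > truncation_low)
  structure(list(mean_length = mean_length, sd_length = sd_length,
                 n_embryos = as.integer(n_embryos),
                 n_replicates = as.integer(n_replicates),
                 between_replicate_sd = between_replicate_sd,
                 truncation_low = truncation_low,
                 truncation_high = truncation_high,
                 label = as.character(label)),
            class = "population_spec")
}

# Truncated-normal draws by rejection; errors out rather than looping
# forever when the truncation window holds almost no mass.
rtruncnorm_reject <- function(n, mean, sd, low, high, max_rounds = 1000L) {
  if (sd == 0) {
    if (mean <= low || mean > high)
      stop("degenerate population: zero SD with mean outside (",
           low, ", ", high, "]")
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > low & x <= high])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncation (", low, ", ", high, "] removes nearly all mass of N(",
       mean, ", ", sd, "^2): rejection sampling failed after ",
       max_rounds, " rounds")
}

#' Sample an embryo-length population
#'
#' Draws `n_replicates * n_embryos` lengths. Each replicate's mean is first
#' shifted by a normal perturbation with SD `between_replicate_sd`, then
#' lengths are drawn from a normal with that mean and `sd_length`, truncated
#' to the spec's support by rejection sampling. Bit-reproducible for a fixed
#' seed.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A `length_sample`: a data frame with columns `replicate`
#'   (integer), `treatment` (character) and `length_mm` (numeric).
#' @examples
#' s <- sample_lengths(population_spec(3.05, 0.74, 100), seed = 1)
#' mean(s$length_mm)
#' @export
sample_lengths <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    reps <- lapply(seq_len(spec$n_replicates), function(r) {
      mu_r <- spec$mean_length +
        if (spec$between_replicate_sd > 0) rnorm(1, 0, spec$between_replicate_sd) else 0
      rtruncnorm_reject(spec$n_embryos, mu_r, spec$sd_length,
                        spec$truncation_low, spec$truncation_high)
    })
    out <- data.frame(
      replicate = rep(seq_len(spec$n_replicates), each = spec$n_embryos),
      treatment = spec$label,
      length_mm = unlist(reps))
    class(out) <- c("length_sample", "data.frame")
    out
  })
}

#' Construct a length sample from raw values
#'
#' @param lengths Numeric vector of lengths, mm; all positive.
#' @param replicate Integer replicate ids (recycled).
#' @param treatment Treatment label (recycled).
#' @return A `length_sample` data frame.
#' @export
length_sample <- function(lengths, replicate = 1L, treatment = "group") {
  stopifnot(is.numeric(lengths), all(lengths > 0))
  out <- data.frame(replicate = as.integer(replicate), treatment = treatment,
                    length_mm = as.numeric(lengths))
  class(out) <- c("length_sample", "data.frame")
  out
}

#' Specification of a rendered synthetic plate image
#'
#' Geometry and sampling parameters for rendering embryos as filled
#' ellipses on a binary plate image. Defaults correspond to a DSLR photo
#' of a 9-cm Petri plate (0.02 mm per pixel) and to the elongated shape of
#' mature spruce somatic embryos (minor/major axis ratio about 0.35).
#'
#' @param image_height_px,image_width_px Image dimensions, pixels (>= 64).
#' @param mm_per_px Calibration, mm per pixel.
#' @param aspect_ratio_mean,aspect_ratio_sd Mean and SD of the minor/major
#'   axis ratio of rendered ellipses; must satisfy `0 < mean < 1`.
#' @param max_placement_attempts Rejection-sampling bound per embryo when
#'   placing without overlap.
#' @param allow_touching If `FALSE` (default) embryos are placed so that no
#'   two are 8-adjacent, guaranteeing one connected component per embryo.
#' @return An object of class `plate_image_spec`.
#' @export
plate_image_spec <- function(image_height_px = 1024L, image_width_px = 1024L,
                             mm_per_px = 0.02,
                             aspect_ratio_mean = 0.35, aspect_ratio_sd = 0.05,
                             max_placement_attempts = 200L,
                             allow_touching = FALSE) {
  stopifnot(image_height_px >= 64, image_width_px >= 64,
            is.numeric(mm_per_px), mm_per_px > 0, is.finite(mm_per_px),
            aspect_ratio_mean > 0, aspect_ratio_mean < 1,
            aspect_ratio_sd >= 0, max_placement_attempts >= 1)
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 mm_per_px = mm_per_px,
                 aspect_ratio_mean = aspect_ratio_mean,
                 aspect_ratio_sd = aspect_ratio_sd,
                 max_placement_attempts = as.integer(max_placement_attempts),
                 allow_touching = isTRUE(allow_touching)),
            class = "plate_image_spec")
}

# Pixel centers inside an ellipse at (cx, cy), semi-axes a, b px, angle
# theta (image frame: x = column, y = row, y increasing downward).
ellipse_pixels <- function(cx, cy, a, b, theta, H, W) {
  x0 <- max(1L, floor(cx - a)); x1 <- min(W, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(H, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(cbind(x = integer(0), y = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(x = xs[keep[, 2]], y = ys[keep[, 1]])
}

#' Render embryos as a binary plate image with ground truth
#'
#' Each length becomes a filled ellipse whose major axis spans
#' `length / mm_per_px` pixels, at a uniformly random orientation and
#' position. Unless `spec$allow_touching`, placement is retried (up to
#' `max_placement_attempts` per embryo) until the new ellipse shares no
#' pixel, and is not even diagonally adjacent, with previously placed ones,
#' so the rendered component count equals the embryo count.
#'
#' @param spec A [plate_image_spec()].
#' @param lengths A `length_sample` or numeric vector of lengths, mm. Every
#'   length must span at least 4 pixels at `spec$mm_per_px`.
#' @param seed Integer seed.
#' @return A list with `image` (integer matrix, 0 background / 1 foreground,
#'   rows = y) and `truth`, a data frame with one row per rendered embryo:
#'   `id, cx_px, cy_px, theta_rad, major_mm, area_mm2` (`area_mm2` is the
#'   continuous ellipse area pi*a*b).
#' @export
render_plate_image <- function(spec, lengths, seed) {
  stopifnot(inherits(spec, "plate_image_spec"))
  if (is.data.frame(lengths)) lengths <- lengths$length_mm
  stopifnot(is.numeric(lengths))
  H <- spec$image_height_px; W <- spec$image_width_px
  empty_truth <- data.frame(id = integer(0), cx_px = numeric(0),
                            cy_px = numeric(0), theta_rad = numeric(0),
                            major_mm = numeric(0), area_mm2 = numeric(0))
  img <- matrix(0L, H, W)
  if (length(lengths) == 0)
    return(list(image = img, truth = empty_truth))
  if (any(lengths / spec$mm_per_px < 4))
    stop("every embryo must span >= 4 px; smallest spans ",
         round(min(lengths) / spec$mm_per_px, 2), " px at ",
         spec$mm_per_px, " mm/px")
  with_seed(seed, {
    mask <- matrix(FALSE, H, W)
    rows <- vector("list", length(lengths))
    for (i in seq_along(lengths)) {
      a <- lengths[i] / spec$mm_per_px / 2
      ar <- spec$aspect_ratio_mean
      if (spec$aspect_ratio_sd > 0) {
        repeat {
          ar <- rnorm(1, spec$aspect_ratio_mean, spec$aspect_ratio_sd)
          if (ar > 0.05 && ar < 0.95) break
        }
      }
      b <- a * ar
      placed <- FALSE
      for (att in seq_len(spec$max_placement_attempts)) {
        theta <- runif(1, 0, pi)
        cx <- runif(1, a + 2, W - a - 1)
        cy <- runif(1, a + 2, H - a - 1)
        px <- ellipse_pixels(cx, cy, a, b, theta, H, W)
        if (nrow(px) == 0) next
        if (!spec$allow_touching) {
          # grow candidate by its 8-neighbourhood: a hit means overlap OR touch
          nx <- rep(px[, 1], 9L) + rep(c(-1L, 0L, 1L), each = 3L * nrow(px))
          ny <- rep(px[, 2], 9L) + rep(rep(c(-1L, 0L, 1L), each = nrow(px)), 3L)
          ok <- nx >= 1L & nx <= W & ny >= 1L & ny <= H
          if (any(mask[cbind(ny[ok], nx[ok])])) next
        }
        mask[cbind(px[, 2], px[, 1])] <- TRUE
        rows[[i]] <- data.frame(
          id = i, cx_px = cx, cy_px = cy, theta_rad = theta,
          major_mm = lengths[i],
          area_mm2 = pi * a * b * spec$mm_per_px^2)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place embryo ", i, " of ", length(lengths),
             " without touching after ", spec$max_placement_attempts,
             " attempts (", i - 1L, " placed); enlarge the image or set ",
             "allow_touching = TRUE")
    }
    img[mask] <- 1L
    list(image = img, truth = do.call(rbind, rows))
  })
}

#' Specification of a dispersed-aggregate area distribution
#'
#' Areas of dispersed pro-embryogenic mass (PEM) aggregates are modelled as
#' log-normal: right-skewed with positive support. When `target_fraction_leq`
#' is supplied, `log_mean` is calibrated by quantile matching so that the
#' population fraction of areas at or below the threshold equals the target
#' (with `log_sd` held fixed).
#'
#' @param log_mean,log_sd Parameters of the log-normal on the mm^2 scale.
#'   `log_mean` may be `NA` if calibrated.
#' @param n_aggregates Number of aggregates per sample (the field-typical
#'   count is several hundred per plated sample).
#' @param target_fraction_leq Optional calibration pair
#'   `c(threshold_mm2, fraction)`.
#' @return An object of class `aggregate_size_spec` with `log_mean` resolved.
#' @examples
#' aggregate_size_spec(n_aggregates = 651,
#'                     target_fraction_leq = c(0.2, 0.80))
#' @export
aggregate_size_spec <- function(log_mean = NA, log_sd = 1.0,
                                n_aggregates = 651L,
                                target_fraction_leq = NULL) {
  stopifnot(n_aggregates >= 1, is.numeric(log_sd), log_sd >= 0)
  if (!is.null(target_fraction_leq)) {
    stopifnot(length(target_fraction_leq) == 2)
    thr <- target_fraction_leq[1]; frac <- target_fraction_leq[2]
    stopifnot(thr > 0, frac >= 0, frac <= 1)
    if ((frac <= 0 || frac >= 1) && log_sd > 0)
      stop("infeasible calibration: a log-normal with positive log_sd ",
           "cannot put fraction ", frac, " of its mass at or below a ",
           "finite threshold")
    log_mean <- log(thr) - log_sd * qnorm(frac)
  }
  stopifnot(is.numeric(log_mean), is.finite(log_mean))
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 n_aggregates = as.integer(n_aggregates),
                 target_fraction_leq = target_fraction_leq),
            class = "aggregate_size_spec")
}

#' Sample dispersed-aggregate areas (mm^2)
#'
#' @param spec An [aggregate_size_spec()].
#' @param seed Integer seed.
#' @return Numeric vector of `n_aggregates` areas in mm^2.
#' @export
sample_aggregate_areas <- function(spec, seed) {
  stopifnot(inherits(spec, "aggregate_size_spec"))
  with_seed(seed, exp(rnorm(spec$n_aggregates, spec$log_mean, spec$log_sd)))
}

#' Specification of germination outcome probabilities
#'
#' @param p_start Probability that a collected mature embryo starts
#'   germination.
#' @param p_root_given_start Probability that a started embryo develops a
#'   root of at least 1 cm, given it started.
#' @return An object of class `germination_spec`.
#' @export
germination_spec <- function(p_start, p_root_given_start) {
  stopifnot(p_start >= 0, p_start <= 1,
            p_root_given_start >= 0, p_root_given_start <= 1)
  structure(list(p_start = p_start, p_root_given_start = p_root_given_start),
            class = "germination_spec")
}

#' Simulate germination counts for one treatment group
#'
#' `started ~ Binomial(collected, p_start)`;
#' `rooted ~ Binomial(started, p_root_given_start)`, so
#' `rooted <= started <= collected` holds by construction.
#'
#' @param spec A [germination_spec()].
#' @param n_collected Number of mature embryos collected for germination.
#' @param seed Integer seed.
#' @param treatment Label attached to the record.
#' @return A `germination_record`: list with `collected`, `started`,
#'   `rooted`, `treatment`.
#' @export
simulate_germination <- function(spec, n_collected, seed,
                                 treatment = "group") {
  stopifnot(inherits(spec, "germination_spec"), n_collected >= 0)
  with_seed(seed, {
    started <- rbinom(1, n_collected, spec$p_start)
    rooted <- rbinom(1, started, spec$p_root_given_start)
    germination_record(n_collected, started, rooted, treatment)
  })
}

#' Construct a germination record from counts
#'
#' @param collected,started,rooted Non-negative counts with
#'   `rooted <= started <= collected`.
#' @param treatment Label.
#' @return An object of class `germination_record`.
#' @export
germination_record <- function(collected, started, rooted,
                               treatment = "group") {
  stopifnot(collected >= 0, started >= 0, rooted >= 0,
            rooted <= started, started <= collected)
  structure(list(collected = as.integer(collected),
                 started = as.integer(started),
                 rooted = as.integer(rooted),
                 treatment = as.character(treatment)),
            class = "germination_record")
}

#' Read / write length-sample CSVs
#'
#' The on-disk format has a header `replicate,treatment,length_mm`,
#' UTF-8, '.' decimal separator.
#'
#' @param x A `length_sample`.
#' @param path File path.
#' @return `read_length_sample` returns a `length_sample`;
#'   `write_length_sample` returns `path` invisibly.
#' @export
write_length_sample <- function(x, path) {
  stopifnot(all(c("replicate", "treatment", "length_mm") %in% names(x)))
  write.csv(x[, c("replicate", "treatment", "length_mm")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_length_sample
#' @export
read_length_sample <- function(path) {
  if (!file.exists(path)) stop("length CSV not found: ", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("replicate", "treatment", "length_mm") %in% names(out)))
  stopifnot(is.numeric(out$length_mm), all(out$length_mm > 0))
  class(out) <- c("length_sample", "data.frame")
  out
}

#' Write a rendered plate's ground-truth table
#'
#' Columns: `id,cx_px,cy_px,theta_rad,major_mm,area_mm2`.
#'
#' @param truth Ground-truth data frame from [render_plate_image()].
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
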