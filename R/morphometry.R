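#' Pixel calibration
#'
#' @param mm_per_px Millimetres per pixel; strictly positive and finite.
#' @return An object of class `calibration_info`.
#' @export
calibration_info <- function(mm_per_px) {
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1L,
            is.finite(mm_per_px), mm_per_px > 0)
  structure(list(mm_per_px = mm_per_px), class = "calibration_info")
}

as_calib <- function(calib) {
  if (inherits(calib, "calibration_info")) calib else calibration_info(calib)
}

#' Threshold a grayscale image to a binary mask
#'
#' Foreground is the set of pixels strictly above the threshold. With
#' `method = "otsu"` the threshold is computed from the image histogram
#' (Otsu's between-class-variance criterion, via EBImage); a constant image
#' has no separable classes and is an error. With `method = "fixed"` the
#' supplied `threshold` is used on the image's own intensity scale.
#'
#' @param img Single-channel numeric matrix (any intensity scale), or a
#'   logical matrix (returned unchanged).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required when `method = "fixed"`.
#' @return Logical matrix, `TRUE` = foreground.
#' @examples
#' m <- matrix(c(40, 40, 200, 200), 2)
#' binarize(m, "fixed", threshold = 128)
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  if (is.logical(img)) return(img)
  stopifnot(is.matrix(img), is.numeric(img))
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    return(img > threshold)
  }
  rng <- range(img)
  if (rng[1] == rng[2])
    stop("Otsu thresholding failed: constant image has no separable classes")
  thr <- EBImage::otsu(EBImage::Image(img), range = rng)
  img > thr
}

#' Label connected particles in a binary image
#'
#' 8-connectivity connected components (two foreground pixels touching even
#' only at a corner belong to the same particle, as in ImageJ's particle
#' analyzer). Components smaller than `min_pixels` are discarded as
#' rasterization/noise debris. Particles are returned in deterministic
#' order: by their first pixel in row-major scan order (top-most, then
#' left-most).
#'
#' @param img Logical (or 0/1) matrix.
#' @param min_pixels Minimum pixel count to keep a component; default 16.
#' @return List of coordinate matrices, one per particle, each with columns
#'   `x` (column) and `y` (row) of member pixels.
#' @export
label_particles <- function(img, min_pixels = 16L) {
  if (!is.logical(img)) {
    stopifnot(all(img %in% c(0, 1)))
    img <- img > 0
  }
  H <- nrow(img); W <- ncol(img)
  lab <- EBImage::bwlabel(matrix(as.numeric(img), H, W))
  lab <- as.matrix(lab)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  # bwlabel is 4-connectivity; merge labels that touch diagonally to get 8
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merge_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    if (!any(keep)) return(invisible())
    pr <- unique(cbind(a[keep], b[keep]))
    for (r in seq_len(nrow(pr))) {
      ra <- find(pr[r, 1]); rb <- find(pr[r, 2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  if (H > 1 && W > 1) {
    merge_pairs(lab[-H, -W], lab[-1, -1])   # down-right diagonal
    merge_pairs(lab[-H, -1], lab[-1, -W])   # down-left diagonal
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  idx <- which(lab > 0)
  comp <- root[lab[idx]]
  xs <- ((idx - 1L) %/% H) + 1L   # column
  ys <- ((idx - 1L) %% H) + 1L    # row
  groups <- split(seq_along(idx), comp)
  parts <- lapply(groups, function(g) cbind(x = xs[g], y = ys[g]))
  parts <- Filter(function(p) nrow(p) >= min_pixels, parts)
  if (length(parts) == 0) return(list())
  # row-major scan order of each particle's first pixel
  first <- vapply(parts, function(p) min((p[, 2] - 1) * W + p[, 1]),
                  numeric(1))
  unname(parts[order(first)])
}

#' Measure one particle: area and moment-equivalent ellipse
#'
#' The particle is summarized by the ellipse having the same second central
#' moments as its pixel set: axis lengths are `4 * sqrt(eigenvalue)` of the
#' pixel-coordinate covariance matrix (population covariance, pixel centers
#' at integer coordinates), the larger eigenvalue giving the major axis —
#' the standard "fit ellipse" definition. Axes are converted to mm via the
#' calibration; area is the pixel count times `mm_per_px^2`. A single-pixel
#' particle yields degenerate zero-length axes (not an error). The
#' orientation is the principal-eigenvector angle in the image frame
#' (x = column, y = row increasing downward), reported modulo pi.
#'
#' @param pixels Coordinate matrix with columns `x`, `y` (as returned by
#'   [label_particles()]); non-empty.
#' @param calib A [calibration_info()] or a bare `mm_per_px` number.
#' @param id Particle id carried into the result.
#' @return One-row data frame: `id, pixel_count, area_mm2, major_mm,
#'   minor_mm, cx_px, cy_px, theta_rad`.
#' @export
measure_particle <- function(pixels, calib, id = 1L) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1)
  calib <- as_calib(calib)
  n <- nrow(pixels)
  cx <- mean(pixels[, 1]); cy <- mean(pixels[, 2])
  dx <- pixels[, 1] - cx; dy <- pixels[, 2] - cy
  sxx <- sum(dx * dx) / n; syy <- sum(dy * dy) / n; sxy <- sum(dx * dy) / n
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 / 4 + sxy^2))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  theta <- if (disc == 0) 0 else atan2(l1 - sxx, sxy)
  theta <- theta %% pi
  data.frame(id = id, pixel_count = n,
             area_mm2 = n * calib$mm_per_px^2,
             major_mm = 4 * sqrt(l1) * calib$mm_per_px,
             minor_mm = 4 * sqrt(l2) * calib$mm_per_px,
             cx_px = cx, cy_px = cy, theta_rad = theta)
}

#' Measure all particles in an image
#'
#' Composition of [binarize()] (when the input is grayscale),
#' [label_particles()] and [measure_particle()], with stable particle
#' ordering.
#'
#' @param img Grayscale numeric matrix or logical/0-1 binary matrix.
#' @param calib A [calibration_info()] or `mm_per_px` number.
#' @param min_pixels Passed to [label_particles()].
#' @param method,threshold Passed to [binarize()] for grayscale input.
#' @return Data frame with one row per particle (columns as in
#'   [measure_particle()]); zero rows for an empty image.
#' @export
measure_all <- function(img, calib, min_pixels = 16L,
                        method = "otsu", threshold = NULL) {
  if (!is.logical(img) && !all(img %in% c(0, 1)))
    img <- binarize(img, method, threshold)
  parts <- label_particles(img, min_pixels)
  if (length(parts) == 0)
    return(data.frame(id = integer(0), pixel_count = integer(0),
                      area_mm2 = numeric(0), major_mm = numeric(0),
                      minor_mm = numeric(0), cx_px = numeric(0),
                      cy_px = numeric(0), theta_rad = numeric(0)))
  do.call(rbind, lapply(seq_along(parts), function(i)
    measure_particle(parts[[i]], calib, id = i)))
}

#' Estimate the harvested fraction from tissue areas
#'
#' The fraction of embryos harvested from a vessel is estimated as the area
#' of tissue sampled over the total area covered by tissue, both measured
#' by image analysis (pixel counts under one calibration).
#'
#' @param sampled_area_px Foreground pixel count of the sampled tissue.
#' @param total_area_px Foreground pixel count of all tissue; positive.
#' @param calib A [calibration_info()] or `mm_per_px` number (converts the
#'   stored areas to mm^2; the fraction itself is calibration-free).
#' @return A `coverage_estimate`: list with `sampled_area` and `total_area`
#'   in mm^2 and `fraction` in `[0, 1]`.
#' @examples
#' estimate_coverage(15, 100, calibration_info(1))$fraction  # 0.15
#' @export
estimate_coverage <- function(sampled_area_px, total_area_px, calib) {
  calib <- as_calib(calib)
  if (total_area_px <= 0) stop("total area must be positive")
  stopifnot(sampled_area_px >= 0, sampled_area_px <= total_area_px)
  structure(list(sampled_area = sampled_area_px * calib$mm_per_px^2,
                 total_area = total_area_px * calib$mm_per_px^2,
                 fraction = sampled_area_px / total_area_px),
            class = "coverage_estimate")
}

#' Aggregate-size histogram across replicates
#'
#' Per-replicate fractions of particle areas falling in each bin (fractions
#' sum to 1 within a replicate), then the mean and sample SD of each bin's
#' fraction across replicates. Empty replicates are excluded with a
#' warning.
#'
#' @param areas_by_replicate List of numeric vectors of areas (mm^2), one
#'   per replicate; or a single numeric vector (one replicate).
#' @param bin_edges Increasing numeric vector of bin edges; bins are
#'   half-open `[lo, hi)` except the last, which is closed.
#' @return List with `bin_lo`, `bin_hi`, `fractions` (replicate x bin
#'   matrix), `mean_fraction`, `sd_fraction` (`NA` with one replicate).
#' @export
area_histogram <- function(areas_by_replicate, bin_edges) {
  if (is.numeric(areas_by_replicate))
    areas_by_replicate <- list(areas_by_replicate)
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1L
  keep <- vapply(areas_by_replicate, length, integer(1)) > 0
  if (!all(keep)) {
    warning(sum(!keep), " empty replicate(s) excluded from area histogram")
    areas_by_replicate <- areas_by_replicate[keep]
  }
  if (length(areas_by_replicate) == 0) stop("no non-empty replicates")
  fr <- t(vapply(areas_by_replicate, function(a) {
    if (any(a < bin_edges[1] | a > bin_edges[nb + 1L]))
      warning("areas outside the binning range are dropped")
    a <- a[a >= bin_edges[1] & a <= bin_edges[nb + 1L]]
    cnt <- tabulate(pmin(findInterval(a, bin_edges), nb), nbins = nb)
    cnt / sum(cnt)
  }, numeric(nb)))
  list(bin_lo = bin_edges[-(nb + 1L)], bin_hi = bin_edges[-1],
       fractions = fr,
       mean_fraction = colMeans(fr),
       sd_fraction = if (nrow(fr) >= 2) apply(fr, 2, sd) else rep(NA_real_, nb))
}
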