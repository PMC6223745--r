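---
title: "Quantifying yield and synchronization of somatic embryo maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying yield and synchronization of somatic embryo maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryosync)
```

## The problem

Conifer somatic embryogenesis multiplies pro-embryogenic masses (PEMs) —
callus-like aggregates of early-stage embryos — and then matures them into
cotyledonary embryos that can be germinated into plants. Maturation is the
rate-limiting step: cultures develop asynchronously, and asynchronous
cultures waste much of their tissue on embryos that never reach a
harvestable stage. Mechanically dispersing PEM aggregates before maturation
is one route to more synchronized development. Evaluating such
interventions needs quantitative, reproducible measures of two things:
**yield** (mature embryos per gram of starting fresh weight, gFW⁻¹) and
**synchronization** (how uniform the mature embryos are in size).

`embryosync` implements that measurement battery for Norway spruce-style
experiments: image-based embryo morphometry, the normalized
length-distribution curve with its fractional-maximum widths, coefficients
of variation with McKay confidence intervals, area-based yield
extrapolation, germination summaries, and a seeded synthetic-data generator
so every stage can be tested end to end without laboratory images.

## Morphometry

Plate or bioreactor photographs are reduced to per-embryo measurements in
three steps.

**Binarization.** Grayscale images are thresholded with Otsu's criterion
(or a fixed threshold); foreground pixels lie above the threshold. A
constant image has no separable classes and is rejected rather than
silently thresholded.

**Labeling.** Connected components under 8-connectivity — two foreground
pixels touching even only at a corner belong to the same particle, the
convention of ImageJ's particle analyzer. Components below `min_pixels`
(default 16) are discarded as rasterization debris. Particles are ordered
deterministically by their first pixel in row-major scan order, so repeated
runs and CSV outputs are stable.

**Moment-equivalent ellipse.** Each particle is summarized by the ellipse
with the same second central moments as its pixel set. If λ₁ ≥ λ₂ are the
eigenvalues of the 2×2 covariance matrix of pixel coordinates (population
covariance, pixel centers at integer coordinates), the axis lengths are
4·√λ₁ and 4·√λ₂ — for a filled disc of diameter d both axes equal d, and
for a filled ellipse with semi-axes a ≥ b the major axis is 2a. The major
axis length, converted to mm through the `mm_per_px` calibration, **is**
the embryo length; particle area is the pixel count times `mm_per_px`².
This measurement is rotation- and translation-invariant to within
rasterization error (about 1–2% for embryos ≥ 50 px long) and scales
exactly linearly with the calibration.

A deliberate limitation: touching embryos are *not* split (no watershed).
The synthetic generator places embryos without contact by default, and real
use assumes images trimmed so that embryos are separable. Areas are pixel
counts, not sub-pixel contours; the harvested-tissue coverage fraction uses
summed particle areas rather than a convex hull, which is the conservative
choice when tissue is patchy.

## The synchronization statistics

**Binned length distribution.** Lengths are counted into half-open bins
`[origin + kδ, origin + (k+1)δ)`. The classical resolution for mature
spruce embryos is δ = 1 mm over 0–5 mm; δ = 0.5 mm resolves the curve
better when samples are large enough. The curve φ is the counts normalized
to unit maximum, evaluated at bin centers. Any positive rescaling of the
counts cancels out of every fractional-maximum width (the level f is a
fraction *of the maximum*), so the choice of normalization constant is
consequence-free for the statistics reported here; unit maximum is simply
the convention that makes curves comparable across groups.

**Fractional-maximum widths.** The curve is linearly interpolated between
successive bin centers and taken as zero one bin width beyond each end. The
width at fraction f is the distance between the *outermost* crossings of
level f; f = 0.5 gives the FWHM. For unimodal curves outermost and
innermost crossings coincide; for noisy multimodal curves the outermost
pair is the conservative reading of a "full" width. Widths are
monotonically non-increasing in f. Smaller widths mean a tighter, more
synchronized length distribution. For replicated experiments widths are
computed per replicate on each replicate's own normalized curve, then
averaged (mean ± n−1 SD across replicates), matching how replicated
bioreactor experiments are conventionally tabulated.

Two numerical caveats, both visible in the test suite:

* **Origin sensitivity.** On coarse bins (δ comparable to the SD) the
  width depends on where bins start; the origin therefore defaults to
  0 mm but is configurable, and comparisons should always share δ and
  origin.
* **Finite-sample bias from unit-max normalization.** The curve maximum is
  estimated by the largest bin count. When counts per bin are small, that
  maximum overshoots the true peak (the largest of several noisy near-peak
  bins), which scales φ down and pulls both crossings inward — widths are
  biased slightly low, increasingly so at higher f where the curve is
  flatter relative to its slope. The bias vanishes as counts per bin grow;
  the suite checks closed-form Gaussian widths (FWHM = 2σ√(2 ln 2), and
  2σ√(2 ln(1/f)) generally) in a converged regime (≈10⁴ counts per bin)
  and exercises the fine-bin regime separately. For the sample sizes of a
  typical maturation experiment (10²–10³ embryos per replicate) the bias
  is well below the between-replicate spread.

**Coefficient of variation and the McKay interval.** CV = sample SD (n−1)
over sample mean; scale-free, so it compares groups with different mean
lengths. Its confidence interval uses the McKay chi-square approximation:
with K the sample CV, v = n−1 and u a χ²(v) quantile, each limit is
K / √((u/v)(1+K²) − K²), the upper-tail quantile giving the lower limit.
The interval always contains K, narrows as n grows, and is accurate for the
CV magnitudes seen here (K ≲ 0.4). For very large K at very small n the
radicand can turn non-positive; that is reported as an explicit error, not
clamped.

**Tests and yield.** Group comparisons use Student's pooled-variance
two-sample t test (the classical default; Welch's variant is a flag).
Yield per gram fresh weight extrapolates the harvested count by the
sampled fraction — estimated from the sampled tissue area over the total
tissue area in the vessel — and divides by starting fresh weight:
harvested / fraction / gFW. Germination is summarized as integer
percentages of collected embryos that started germinating and that formed
a root ≥ 1 cm.

## The synthetic-data generator

The generator's job is to emulate the statistical structure of a real
maturation experiment closely enough that every downstream stage is
testable, with known ground truth.

* **Length populations** are normal, truncated at 0 mm by rejection
  sampling (lengths are physically positive; the truncation is negligible
  for realistic parameters, e.g. mean 3 mm, SD 0.8 mm). Replicate-level
  variation enters as a normal shift of each replicate's mean
  (`between_replicate_sd`, default 0 so single-population tests are
  exact). Parameters of a realistic two-line, two-treatment bioreactor
  study — means near 2.7–3.1 mm, SDs 0.7–0.9 mm, ~100–200 embryos per
  vessel — ship as `inst/extdata/example_study.yaml`; there
  `between_replicate_sd` is 0.10 mm, a modest vessel effect consistent
  with the replicate scatter such experiments report.
* **Plate images** render each length as a filled ellipse at random
  orientation and position, with aspect ratio drawn around 0.35 ± 0.05
  (mature spruce somatic embryos are roughly 3 mm long and 1 mm wide) and
  0.02 mm/px calibration (a DSLR frame over a 9-cm plate). Non-touching
  placement is enforced by rejection: a candidate is accepted only if its
  pixel set, grown by one pixel in all 8 directions, misses everything
  already placed — guaranteeing the component count equals the embryo
  count. Failure to place within `max_placement_attempts` is an explicit
  error naming how many embryos fit. The ground-truth table records center,
  orientation, true major axis, and the continuous ellipse area πab.
* **Aggregate areas** are log-normal — a modeling choice, not an observed
  form: the data motivating it are right-skewed, positive, and summarized
  only by binned fractions, and the log-normal is the simplest family
  matching those facts. `log_mean` is calibrated by quantile matching so a
  stated fraction of aggregates falls at or below a threshold area (the
  field-typical figure is ~80% at or below 0.2 mm²), with `log_sd` held at
  its given value (default 1.0) since one quantile pins down one parameter.
* **Germination** is a binomial chain: started ~ Bin(collected, p_start),
  rooted ~ Bin(started, p_root|start), so rooted ≤ started ≤ collected by
  construction.

What the generator does **not** emulate: lighting, suspensor filaments and
color (silhouettes only); segmentation errors from overlapping tissue;
non-normal length populations; any biology linking dispersion to yield.
Passing tests therefore demonstrate that the *measurement pipeline* is
correct and well-calibrated, not that real cultures satisfy its
distributional assumptions — the optional Shapiro–Wilk diagnostic
(`check_normality`, a warning, never a gate) is the hook for checking the
latter on real data.

Every stochastic stage takes an explicit integer seed; pipeline runs derive
per-stage seeds from one global seed and the stage label, so re-running any
stage in isolation reproduces it bit for bit and adding a group never
perturbs the others.

## A worked run

```{r example, eval = FALSE}
cfg <- read_study_config(system.file("extdata", "example_study.yaml",
                                     package = "embryosync"))
report <- run_study(cfg)
print(report)

# dispersed vs non-dispersed within a cell line
compare_treatments(report, "11:12:02", "bioreactor")
```

The run writes `table1_lengths_cv.csv` (n, mean ± SD, CV with its 90%
McKay interval), `table2_widths.csv` (mean ± SD widths at 50/66/75% of
maximum across replicates), `table3_germination.csv`, a machine-readable
`summary.json`, and a timestamped `run.log` under the configured output
directory. CV and lengths are rounded to 2 decimals and germination to
integer percent in the CSV tables — the JSON keeps full precision.

## Problem sizes used by the test suite

Unit tests run at small n (tens to hundreds of embryos, plates ≤ 1200 px).
The deeper checks use: 10⁵ lengths for truncated-normal and Gaussian-width
convergence; a 4000-px plate with 220 embryos spanning 1–5 mm for
ground-truth recovery (every major axis within 2%, component count exact);
and 200 seeded replications of a two-group study (3 replicates of 129 vs
78 embryos, δ = 0.5 mm) for the power of the synchronization comparison.
These sizes were chosen to match the scale of the experiments the package
targets while keeping a full test run in well under a minute of compute
for the statistical modules.
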