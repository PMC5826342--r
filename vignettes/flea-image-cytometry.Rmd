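---
title: "Quantifying single-cell phosphatase activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell phosphatase activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleacyto)
```

## The assay and what the package computes

The FLEA (fluorescence-labeled enzyme activity) assay measures the
extracellular phosphatase activity of individual cells. Samples are
incubated with ELF97 phosphate, whose enzymatic hydrolysis precipitates a
fluorescent product (ELFA) at the site of activity; cells are then imaged
in two epifluorescence channels — chlorophyll autofluorescence for
locating and sizing cells, and the ELFA channel for the activity signal.
`fleacyto` turns those paired rasters into per-cell activities and
downstream population statistics.

The core quantity is the cell-associated ELFA fluorescence

$$F_{ELFA} = \frac{Area \times (MGrey - BgMGrey)}{T_{exp} \times F_{cal}}$$

with `Area` the projected cell area (µm²), `MGrey` the mean ELFA gray over
the cell, `BgMGrey` the field background gray, `T_exp` the exposure time
(ms) and `F_cal` a dimensionless calibration factor carried as opaque
acquisition metadata. The result is reported in relative fluorescence
units (FU) cell⁻¹ h⁻¹ and converted to fmol cell⁻¹ h⁻¹ with a fixed
0.1 fmol FU⁻¹ factor.

Two unit conventions deserve comment, both deliberate:

* **Incubation time.** The formula contains no incubation term, yet its
  output is conventionally reported per hour; this is coherent under the
  fixed 3-h incubation of the standard protocol. We therefore leave
  division by incubation time off by default and expose it as
  `quant_config(normalize_by_incubation = TRUE)` for cross-protocol use.
* **Negative net gray.** A cell cannot hydrolyze substrate negatively;
  `MGrey < BgMGrey` (possible under noise) is clamped to zero and the
  count of clamped cells is surfaced as a QC message rather than silently
  absorbed.

## Segmentation and measurement

The original workflow demarcated cells manually; `segment_cells()`
replaces this with Otsu thresholding of the chlorophyll channel plus
connected-component labeling (a fixed absolute threshold is available via
`threshold = "fixed"`). This substitution is deliberate and is validated
against ground truth: on noise-free synthetic fields the recovered label
masks equal the painted ellipses pixel for pixel, giving segmentation
precision = recall = 1 in the test suite. Two filters mirror the physical
protocol: objects with area-equivalent diameter below 2 µm are discarded
(samples are collected on 2-µm-pore filters, so smaller objects are out of
scope), and border-touching objects are excluded because their projected
area is truncated.

`measure_cells()` reports area as pixel count × pixel size², length as the
major axis of the moment-based best-fit ellipse, and the ELFA gray
statistics. Background is estimated **per field** (the alternative —
per-cell neighborhoods — is not offered; per field is simpler, and the
synthetic validation shows it suffices) over all pixels outside the union
of cell masks dilated by 2 px. The background statistic is the **median**
by default, robust to stray ELFA precipitates; `bg_stat = "mean"` restores
a plain mean-gray background for fidelity with mean-based workflows.
Because `F_ELFA` depends on gray levels only through `MGrey − BgMGrey`, it
is invariant to any uniform offset of the ELFA channel, and homogeneous of
degree one in the net gray — both asserted as tests.

## Cell volume

Only length and projected area are measurable from a 2-D mask, which
determines a unique ellipsoid model: a prolate spheroid with circular
cross-section. The projected ellipse has `Area = (π/4)·L·W`, so

$$W = \frac{4 \cdot Area}{\pi L}, \qquad V = \frac{\pi}{6} L W^2.$$

The sphere limit (`Area = π(L/2)²` ⇒ `V = (π/6)L³`) is exact to 1e-9 in
the tests. If a noisy mask yields `W > L` the axes are swapped with a
warning so the symmetry axis is always the longer one.

## Growth rates

Semi-continuous cultures are kept near a chlorophyll target by periodic
dilution; the specific growth rate between events is

$$\mu = \frac{\ln N_f - \ln N_i}{t_f - t_i} \quad (\text{day}^{-1}),$$

with the default window spanning the period between the second and third
dilutions — from the first sample strictly after the opening event to the
last sample strictly before the closing one. A window containing a
dilution is an error, not a silent estimate. Density `N` comes from
chlorophyll through a conversion curve; its form is a free choice, so the
default is linear-through-origin, for which µ is provably independent of
the slope (the tests assert this numerically), with a piecewise-linear
option for calibrated curves. Whether endpoints should be single samples
or window regressions is genuinely open; single-sample endpoints are the
default (they invert the generator exactly) and
`method = "regression"` fits `lm(log N ~ t)` over the window.

## The synthetic-data generator

No images or culture series are deposited with the original study, so the
generator *defines* the reference conditions the package is tested under:

* **Geometry.** Cells are prolate spheroids rendered as filled ellipses,
  non-overlapping and clear of the border — fields of unicellular algae
  are sparse, and unambiguous ground truth is the point of the simulator.
  Pixel size defaults to 0.11 µm/px (plausible for a 60× objective);
  rasters are 16-bit, and saturation or (with read noise) negative pixels
  are generation *errors*, never clips.
* **Signal.** The ELFA signal of a cell is painted by inverting the
  F_ELFA equation: the integer gray total over the mask equals
  `true_FU · T_exp · F_cal / pixel_size²` to within one gray level, so
  pipeline recovery is exact up to quantization (<2% for every cell in
  the acceptance suite) and linear in exposure by construction.
* **Noise.** Poisson shot noise and Gaussian read noise are available but
  off by default; the reference conditions are noise-free because the
  study's own noise characteristics are unknown.
* **Treatments.** `default_treatments()` encodes six variants — inorganic
  (I) or organic (O) phosphorus at 858, 16 and 10 µmol L⁻¹ — with
  zero-inflated log-normal single-cell activities. Calibration anchors:
  depleted-variant medians of 0.4 FU (I3) and 1.6 FU (O3), i.e. 0.04 and
  0.16 fmol cell⁻¹ h⁻¹ at 0.1 fmol FU⁻¹; a 10-fold O2:I2 median ratio
  (2.5 vs 0.25 FU); P-replete variants dominated by inactive cells (zero
  fractions 0.6 and 0.8); cell length ranges chosen so the mean spheroid
  volume is ≈27 µm³ when P-replete and ≈45 µm³ when P-depleted. The
  log-scale spread (σ = 0.8) is a declared choice giving activities
  spanning a few geometric classes, as observed distributions do.
* **Median convention.** `activity_median_FU` is the population median
  when the zero fraction is below one half (the log-normal location is
  shifted so the mixture median hits the target exactly); when half or
  more of the cells are inactive the population median is necessarily 0,
  so the parameter then refers to the active subpopulation.
* **Growth series.** Exponential growth punctuated by `n_dilutions`
  evenly spaced events (three over 21 days by default, matching
  semi-continuous practice), each returning the culture to its
  chlorophyll target; declining cultures are not diluted (factors are
  ≥ 1 by invariant). A sample taken exactly at an event time is
  post-dilution. Observation noise is multiplicative log-normal with
  unit mean.

What the generator does **not** emulate: point-spread blur and
out-of-focus light, touching or overlapping cells, mixed-species fields,
bacterial ELFA precipitates, and within-cell signal heterogeneity. Passing
tests therefore certify the quantification chain and its invariances, not
robustness to the full optical complexity of real micrographs — on real
data, segmentation quality is the step that needs case-by-case validation.

## Distributions and treatment statistics

`build_distribution()` keeps a **zero class** (activity exactly 0 after
clamping — "no activity" is a category of its own, distinct from merely
low) separate from half-open geometric bins `(b·r^k, b·r^{k+1}]` with base
0.02 FU and ratio 2. Base and ratio reproduce the class boundaries cited
in descriptions of such distributions (0.02, 0.32, 0.64, ≈1.28, ≈5.12 —
treating printed 1.26 and 5.1 as rounding); both are configurable. Active
cells below the base fall into an explicit underflow class, and values
beyond the last edge are an error rather than silent loss, so percentages
always sum to 100. Replicate distributions average class-wise
(`average_distributions()`), and `summarize_activity()` reports the
median, quartiles and 10/90 percentiles (R's type-7 linear interpolation)
used in box-and-whisker comparisons.

`compare_treatments()` fits the three-way factorial — species (2) ×
P source (2) × P level (3) — on log(x+1)-transformed responses via
`stats::aov`, giving the effect degrees of freedom (1, 1, 2, 1, 2, 2, 2),
with `stats::TukeyHSD` contrasts and a compact letter display of the six
P-source × P-level treatment means (species pooled) computed with
`multcomp`. No additional multiplicity correction is layered on top of the
studentized-range convention. `simulate_factorial()` generates replicate
responses as `expm1` of a Gaussian linear model, so the log(x+1) ANOVA is
exact and the null type-I error is nominal by construction — the test
suite verifies ≈5% per factor over 1000 simulated triplicate designs.

## Problem sizes and numerical choices

The reference checks use 30 fields × 12 cells (360 cells per treatment,
matching per-variant cell counts of ~300–420 in comparable experiments)
for calibrated-recovery medians, 30 × 5 fields for per-cell oracle
equivalence, and 1000 replicate designs for the type-I calibration; the
acceptance script uses 60 fields (720 cells per treatment) for the
median-ratio estimate. Quantization is the only error source in noise-free
recovery (<1 gray per cell by the painting scheme); ties and degenerate
inputs are resolved explicitly (empty fields segment to zero labels;
labels under 4 px are skipped with a warning; flat images are
unsegmentable rather than erroneous).

## Known limitations

* `F_cal` is carried as metadata; how it is determined, and the tension
  between the formula's physical units (µm²·gray·ms⁻¹) and the reported
  FU cell⁻¹ h⁻¹, are documented but not resolved here.
* The 0.1 fmol FU⁻¹ conversion is adopted, not re-derived; it rests on
  calibration against natural plankton for which no data are available.
* No watershed splitting of touching cells and no tracking across fields;
  crowded real-world fields will need manual curation or a different
  segmenter behind the same measurement interface.
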