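# fleacyto

Single-cell extracellular phosphatase activity by fluorescence image
cytometry.

Phosphorus-limited algae express extracellular phosphatases, and the
fluorogenic substrate ELF97 phosphate makes that activity visible cell by
cell: enzymatic hydrolysis deposits an insoluble fluorescent product (ELFA)
on the cell surface, so the activity of each individual cell can be read
from an epifluorescence micrograph. `fleacyto` implements the quantitative
side of this FLEA (fluorescence-labeled enzyme activity) assay for
microbial ecologists and phycologists working with algal cultures or
plankton samples: from dual-channel field images to per-cell activities,
cell volumes, culture growth rates, and per-treatment frequency
distributions and factorial statistics.

## The model

Cells are located and sized on the chlorophyll-autofluorescence channel;
the ELFA channel carries the signal. For each segmented cell,

```
F_ELFA = Area × (MGrey − BgMGrey) / (T_exp × F_cal)
```

where `Area` (µm²) is the projected cell area, `MGrey` the mean ELFA gray
level over the cell, `BgMGrey` the background gray level of the field,
`T_exp` (ms) the exposure time and `F_cal` a dimensionless calibration
factor. `F_ELFA` is expressed in relative fluorescence units (FU) cell⁻¹ h⁻¹
under the standard 3-h incubation and converts to hydrolyzed substrate at
0.1 fmol FU⁻¹. Cell volume uses a prolate-spheroid model determined by
length and projected area (`W = 4·Area/(π·L)`, `V = (π/6)·L·W²`); specific
growth rates in semi-continuous culture use
`µ = (ln N_f − ln N_i)/(t_f − t_i)` between dilution events; frequency
distributions use a zero class plus geometric-progression bins
(base 0.02 FU, ratio 2); treatments are compared by three-way ANOVA
(species × P source × P level) on log(x+1)-transformed responses with
post-hoc Tukey HSD.

Because the original microscope slides are not deposited, the package
includes a first-class synthetic-data module: it renders two-channel fields
of prolate-spheroid cells whose painted ELFA signal inverts the F_ELFA
equation exactly, so every pipeline stage can be validated against known
per-cell ground truth, and six calibrated treatment presets (I1–I3, O1–O3)
emulate the study conditions of inorganic vs organic phosphorus at three
concentrations.

## Worked example

Simulate one P-depleted treatment (I3: inorganic P, 10 µmol L⁻¹), run the
full segment → measure → quantify pipeline, and summarize:

```r
library(fleacyto)

spec  <- default_treatments()[3, ]            # I3
cells <- simulate_treatment_cells(spec, n_fields = 30,
                                  cells_per_field = 12, seed = 1)

dplyr::select(cells, cell_id, area_um2, felfa_FU, activity_fmol,
              volume_um3, true_FU)[1:4, ]
#>   cell_id area_um2 felfa_FU activity_fmol volume_um3 true_FU
#> 1       1     16.1   0.234        0.0234        33.8  0.234
#> 2       2     18.7   0.0785       0.00785       44.0  0.0785
#> 3       3     23.2   0.433        0.0433        59.4  0.433
#> 4       4     17.1   0.724        0.0724        37.0  0.724

summarize_activity(cells, variant)[, 1:8]
#>   variant n_cells median_FU q25_FU q75_FU p10_FU p90_FU median_fmol
#> 1 I3          360     0.405  0.221  0.670 0.0932   1.07      0.0405
```

Per-cell recovered `felfa_FU` matches the generator's `true_FU` to within
gray-level quantization (<2%), and the treatment median lands on the
calibrated 0.04 fmol cell⁻¹ h⁻¹. The frequency distribution with the
standard geometric classes:

```r
build_distribution(cells, n_bins = 10, variant = "I3")
#>   label           n   pct
#> 1 0              24  6.67     # zero class: no activity
#> 2 <0.02           0  0
#> 3 (0.02,0.04]     0  0
#> 4 (0.04,0.08]     9  2.5
#> 5 (0.08,0.16]    30  8.33
#> 6 (0.16,0.32]    87 24.2
#> ...                          # percentages sum to 100
```

Growth rates invert the generator exactly:

```r
s <- generate_growth_series(mu_per_day = 0.17, seed = 1)
growth_rate(s)      # window between the 2nd and 3rd dilutions
#> [1] 0.17
```

`autoplot()` methods are available for distributions and growth series, and
`compare_treatments()` returns a broom-friendly object (`tidy()`,
`glance()`) with Tukey contrasts and compact-letter groupings.

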