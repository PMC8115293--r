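# ecmquant

Quantification pipelines for studies of melanoma invasion into collagenous
dermal matrices. The package implements, as tested reusable R code, the
image- and score-level measurements used to show that collagen degradation
limits melanoma invasion:

- **Spheroid invasion**: maximal projection of a Hoechst nuclear z-stack,
  flatfield correction, layered core/invasive-area segmentation, the
  invasive area as a percentage of spheroid size
  (`100·|invasion| / (|core| + |invasion|)`), and detection of individually
  invading nuclei outside the spheroid perimeter.
- **Fibre alignment**: per-pixel orientation from the structure tensor
  (`θ = 90° + ½·atan2(2Jxy, Jxx − Jyy)`, axial on (−90°, 90°]), orientation
  histograms, mode orientation, and the fraction of fibres within 10° of
  the mode.
- **DQ-collagen degradation**: degraded area per cell, low/medium/high
  scoring of the peri-cytoplasmic degradation ring (width <1/4, ~1/3, ~1/2
  of the cytoplasmic diameter), the H-score
  `H = (1·n_low + 2·n_medium + 3·n_high) / n_total`, and condition ratios.
- **Surface roughness**: AFM `Rq = sqrt(mean((z − mean(z))²))` and SHG
  sum-projection ROI intensities.
- **Expression scores**: qPCR `2^−ΔCt` against the geometric mean of
  housekeepers, geometric-mean gene-signature scores on log2(x+1)
  expression, median splits, collagen-gene stripping, histology-score
  binarisation (solar elastosis noCSD/CSD; invasive-front low/high), and
  Kaplan–Meier/log-rank comparison.

Because the raw images and clinical cohorts behind such studies are not
generally deposited, every stage ships with a synthetic-data generator that
plants machine-readable ground truth (spheroids with known invasive halos
and single cells, von Mises fibre fields, degradation rings with known
classes, closed-form height maps, survival-linked expression signatures),
so the whole pipeline is testable end to end without downloads.

The package is aimed at quantitative biologists building or auditing
invasion/degradation assays, and at developers who need a benchmarked
reference implementation of these measurements.

## Worked example

```r
library(ecmquant)

# a synthetic spheroid: 150 invading halo nuclei + 25 single cells, SNR 10
g <- make_spheroid_image(spheroid_spec(seed = 7))
q <- quantify_spheroid(g$stack)
q$metrics
#>   core_area_px2 invasion_area_px2 invasive_area_pct single_cell_count
#> 1         11447              8481          42.55821                27

g$truth$invasive_area_pct   # planted ground truth
#> [1] 45.85688

match_centroids(q$single_cells$centroids,
                g$truth$single_cell_centroids, match_radius_px = 5)$f1
#> [1] 0.9615385
```

The estimated invasive area (42.6% of the spheroid) sits about three
percentage points from the planted truth, and 25 of the 27 detections match
a planted single cell within one nucleus radius.

```r
# fibre alignment rises with the planted orientation concentration
for (k in c(0, 4)) {
  f <- make_fibre_image(fibre_field_spec(concentration_kappa = k,
                                         mean_angle_deg = 30, seed = 5))
  print(fibre_alignment_summary(f$image))
}
#>   mode_deg aligned_fraction n_pixels_weighted
#> 1    -47.5        0.1448139           3803.06
#>   mode_deg aligned_fraction n_pixels_weighted
#> 1     30.5        0.6208249          3769.519

# degradation H-score from a rendered field with uniform class mixture
d <- make_degradation_image(degradation_field_spec(cell_count = 300, seed = 4))
score_degradation(d$dq, d$cytoplasm)$h_score
#> [1] 2.02      # expectation for p = (1/3, 1/3, 1/3) is 2.0

h_score(5, 3, 2)
#> [1] 1.7
```

For an uninformative uniform fibre field (kappa 0) the aligned fraction
stays near the uniform baseline (21/180 ≈ 0.117) and the mode is arbitrary;
at kappa 4 the planted 30° orientation is recovered and the aligned
fraction rises to 0.62.

A complete synthetic run over all five stages, written as a plain-text
report plus CSVs (byte-identical for a fixed seed):

```r
run_demo(seed = 7, out_dir = "demo_out")
```

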