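# Shared fixtures: signature gene ids, randomised spheroid study specs and
# an end-to-end recovery harness used by unit and acceptance tests.

sig_genes <- sprintf("SIG%02d", 1:20)

# a randomised but seed-determined spheroid spec within the study conditions
random_spheroid_spec <- function(seed) {
  ecmquant:::with_seed(seed + 5000L, {
    spheroid_spec(
      halo_cell_count = sample(80:200, 1),
      single_cell_count = sample(15:35, 1),
      snr = stats::runif(1, 5, 15),
      illumination_gradient_amplitude = stats::runif(1, 0, 0.3),
      seed = seed
    )
  })
}

# run the full quantification on generated spheroids and score against truth
spheroid_recovery <- function(seeds) {
  rows <- lapply(seeds, function(s) {
    spec <- random_spheroid_spec(s)
    g <- make_spheroid_image(spec)
    q <- quantify_spheroid(g$stack)
    m <- match_centroids(q$single_cells$centroids,
                         g$truth$single_cell_centroids,
                         match_radius_px = spec$nucleus_radius_px)
    data.frame(seed = s,
               err_pct = q$metrics$invasive_area_pct - g$truth$invasive_area_pct,
               f1 = m$f1,
               count = q$metrics$single_cell_count,
               true_count = spec$single_cell_count)
  })
  do.call(rbind, rows)
}

# circular (axial, period 180) absolute angle difference in degrees
axial_diff <- function(a, b) {
  d <- abs((a - b + 90) %% 180 - 90)
  d
}
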