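# Generators: determinism, ground-truth consistency, and the planted
# distributions they claim to draw from.

test_that("all generators are deterministic for identical spec and seed", {
  s1 <- make_spheroid_image(spheroid_spec(seed = 11))
  s2 <- make_spheroid_image(spheroid_spec(seed = 11))
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)

  f1 <- make_fibre_image(fibre_field_spec(seed = 4))
  f2 <- make_fibre_image(fibre_field_spec(seed = 4))
  expect_identical(f1, f2)

  d1 <- make_degradation_image(degradation_field_spec(cell_count = 40, seed = 9))
  d2 <- make_degradation_image(degradation_field_spec(cell_count = 40, seed = 9))
  expect_identical(d1, d2)

  e1 <- make_expression_dataset(survival_sim_spec(seed = 3))
  e2 <- make_expression_dataset(survival_sim_spec(seed = 3))
  expect_identical(e1, e2)

  # different seeds give different realisations
  expect_false(identical(s1$stack,
                         make_spheroid_image(spheroid_spec(seed = 12))$stack))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(42)
  expected <- runif(3)
  set.seed(42)
  invisible(make_fibre_image(fibre_field_spec(fibre_count = 5, seed = 1)))
  expect_identical(runif(3), expected)
})

test_that("spheroid ground truth is geometrically consistent", {
  spec <- spheroid_spec(seed = 21)
  g <- make_spheroid_image(spec)
  cents <- g$truth$single_cell_centroids
  expect_equal(nrow(cents), spec$single_cell_count)
  # inside image bounds (0-based coordinates)
  expect_true(all(cents[, "x"] >= 0 & cents[, "x"] < spec$image_size_px[2]))
  expect_true(all(cents[, "y"] >= 0 & cents[, "y"] < spec$image_size_px[1]))
  # all planted singles at least min_dist from the spheroid centre
  ctr <- g$truth$centre_px
  d <- sqrt((cents[, "x"] - ctr["x"])^2 + (cents[, "y"] - ctr["y"])^2)
  expect_true(all(d >= spec$single_cell_min_dist_px))

  expect_equal(nrow(make_spheroid_image(
    spheroid_spec(single_cell_count = 0, seed = 2))$truth$single_cell_centroids),
    0)
})

test_that("impossible single-cell placement fails explicitly", {
  spec <- spheroid_spec(single_cell_count = 2000L, seed = 1)
  expect_error(make_spheroid_image(spec), "infeasible")
})

test_that("noise-free render contains the planted number of isolated blobs", {
  spec <- spheroid_spec(snr = Inf, illumination_gradient_amplitude = 0,
                        single_cell_count = 25L, seed = 8)
  g <- make_spheroid_image(spec)
  proj <- max_project(g$stack)
  # oracle: connected components of the noise-free render beyond the halo
  outside <- !ecmquant:::disc_mask(dim(proj), (nrow(proj) + 1) / 2,
                                   (ncol(proj) + 1) / 2,
                                   spec$halo_outer_radius_px + 3 * spec$nucleus_radius_px)
  lab <- EBImage::bwlabel(proj > 1e-6 & outside)
  expect_equal(max(lab), 25)
})

test_that("axial von Mises sampler has the right distribution", {
  expect_error(fibre_field_spec(concentration_kappa = -1), "kappa")
  expect_error(rvonmises_axial(10, 0, -0.5), "kappa")
  # degenerate concentration: all angles at the mean
  expect_equal(rvonmises_axial(50, 37, Inf), rep(37, 50))
  # kappa = 0 is uniform on (-90, 90]: window fraction and chi-square test
  a <- ecmquant:::with_seed(123, rvonmises_axial(1e5, 0, 0))
  expect_true(all(a > -90 & a <= 90))
  frac <- mean(axial_diff(a, 17) <= 10)
  expect_lt(abs(frac - 20 / 180), 0.01)
  counts <- table(cut(a, breaks = seq(-90, 90, by = 10)))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
  # concentrated draws centre on the mean orientation
  b <- ecmquant:::with_seed(5, rvonmises_axial(1e4, 25, 5))
  expect_lt(axial_diff(median(b), 25), 2)
})

test_that("degradation generator plants the requested classes", {
  d <- make_degradation_image(
    degradation_field_spec(cell_count = 30,
                           class_probabilities = c(1, 0, 0), seed = 2))
  expect_true(all(d$truth$class == 1L))
  expect_true(all(d$truth$ratio < 0.25))

  d0 <- make_degradation_image(degradation_field_spec(cell_count = 0, seed = 1))
  expect_length(d0$truth$class, 0)
  expect_true(all(d0$cytoplasm == 0) && all(d0$nuclei == 0))
  expect_true(all(d0$dq == d0$dq[1]))

  # label counts reproduce the seed-fixed multinomial draw
  dm <- make_degradation_image(
    degradation_field_spec(cell_count = 300, seed = 7))
  redraw <- ecmquant:::with_seed(7, {
    # centre jitter is drawn before classes, mirroring the generator
    stats::runif(2 * 300)
    sample.int(3L, 300, replace = TRUE, prob = c(1, 1, 1) / 3)
  })
  expect_identical(dm$truth$class, redraw)
})

test_that("height-map patterns carry their closed-form roughness", {
  cm <- make_height_map("constant", 3.2)
  expect_equal(cm$rq_analytic, 0)
  expect_true(all(cm$height == 3.2))
  tl <- make_height_map("two_level", 2.5, size = c(64L, 64L))
  expect_equal(tl$rq_analytic, 2.5)
  expect_setequal(unique(as.vector(tl$height)), c(2.5, -2.5))
  sn <- make_height_map("sinusoid", 1.8, size = c(32L, 96L), periods = 3L)
  expect_equal(sn$rq_analytic, 1.8 / sqrt(2))
})

test_that("expression generator balances groups and respects the null", {
  es <- make_expression_dataset(survival_sim_spec(n_samples = 200L, seed = 5))
  expect_true(all(es$values >= 0))
  expect_equal(unname(table(es$truth$group)["high"]), 100L)
  expect_equal(dim(es$values), c(500L, 200L))
  expect_true(all(es$survival$time > 0))
  expect_true(all(es$survival$event %in% 0:1))

  # hazard_ratio = 1: groups exchangeable, log-rank should not reject often
  ps <- vapply(1:10, function(s) {
    e0 <- make_expression_dataset(
      survival_sim_spec(hazard_ratio_high_vs_low = 1, seed = s))
    km_logrank(e0$survival$time, e0$survival$event,
               e0$truth$group[e0$survival$sample_id])$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
})
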