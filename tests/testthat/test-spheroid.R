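# Spheroid invasion pipeline: projection, preprocessing, segmentation,
# invasive-area percentage and single-cell detection against planted truth.

test_that("max_project matches a per-pixel brute-force oracle", {
  m <- matrix(1:6, 2, 3)
  expect_identical(max_project(list(m)), m)
  expect_equal(max_project(list(matrix(3, 2, 2), matrix(7, 2, 2))),
               matrix(7, 2, 2))
  set.seed(1)
  stack <- replicate(4, matrix(rnorm(63), 7, 9), simplify = FALSE)
  ref <- matrix(0, 7, 9)
  for (r in 1:7) for (c in 1:9)
    ref[r, c] <- max(vapply(stack, function(s) s[r, c], numeric(1)))
  expect_equal(max_project(stack), ref)
  expect_error(max_project(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "identical dimensions")
  expect_error(max_project(list()))
})

test_that("gaussian_blur is mass-preserving and matches dense convolution", {
  expect_equal(gaussian_blur(matrix(5, 9, 9), 2), matrix(5, 9, 9))
  delta <- matrix(0, 31, 31); delta[16, 16] <- 1
  expect_equal(sum(gaussian_blur(delta, 2)), 1, tolerance = 1e-12)

  # dense-convolution oracle with the same symmetric boundary rule
  set.seed(2)
  m <- matrix(runif(256), 16, 16)
  k <- exp(-(-8:8)^2 / (2 * 4)); k <- k / sum(k)
  refl <- function(i, n) { i <- (i - 1) %% (2 * n); ifelse(i < n, i + 1, 2 * n - i) }
  ref <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    s <- 0
    for (dr in -8:8) for (dc in -8:8)
      s <- s + k[dr + 9] * k[dc + 9] * m[refl(r + dr, 16), refl(c + dc, 16)]
    ref[r, c] <- s
  }
  expect_lt(max(abs(gaussian_blur(m, 2) - ref)), 1e-6)
})

test_that("flatfield correction removes a planar ramp and is idempotent", {
  cv <- function(x) stats::sd(x) / mean(x)
  expect_equal(flatfield_correct(matrix(4, 32, 32)), matrix(4, 32, 32))
  expect_error(flatfield_correct(matrix(0, 16, 16)), "all-zero")

  ramp <- 1 + 0.3 * outer(rep(1, 64), seq(-1, 1, length.out = 64))
  img <- 5 * ramp
  out <- flatfield_correct(img)
  expect_gt(cv(img) / cv(out), 5)
  expect_equal(mean(out), mean(img), tolerance = 0.01)
  out2 <- flatfield_correct(out)
  expect_lt(max(abs(out2 - out)) / mean(out), 0.01)
})

test_that("invasive_area_pct follows its definition and error contract", {
  seg <- function(core_px, inv_px) {
    m <- matrix(FALSE, 40, 40)
    core <- m; core[which(!m)[seq_len(core_px)]] <- TRUE
    inv <- m; if (inv_px > 0) inv[which(!core)[seq_len(inv_px)]] <- TRUE
    structure(list(core_mask = core, invasion_mask = inv,
                   perimeter_mask = m, centroid_px = c(x = 0, y = 0)),
              class = "spheroid_segmentation")
  }
  expect_equal(invasive_area_pct(seg(120, 0)), 0)
  expect_equal(invasive_area_pct(seg(100, 100)), 50)
  expect_equal(invasive_area_pct(seg(300, 100)), 25)
  expect_error(invasive_area_pct(seg(0, 0)), "empty")
})

test_that("segmentation recovers planted core and halo geometry", {
  expect_error(segment_spheroid(matrix(0, 64, 64)), "no spheroid")

  clean <- make_spheroid_image(
    spheroid_spec(halo_cell_count = 0, single_cell_count = 0, snr = Inf,
                  illumination_gradient_amplitude = 0, seed = 2))
  q <- quantify_spheroid(clean$stack)
  expect_equal(q$metrics$invasion_area_px2, 0)
  expect_lt(abs(q$metrics$core_area_px2 / clean$truth$core_area_px2 - 1), 0.05)

  halo <- make_spheroid_image(spheroid_spec(seed = 3))
  qh <- quantify_spheroid(halo$stack)
  expect_lt(abs(qh$metrics$invasion_area_px2 / halo$truth$halo_area_px2 - 1),
            0.15)
})

test_that("masks are disjoint, perimeter bounds the union, detections lie outside", {
  g <- make_spheroid_image(spheroid_spec(seed = 5))
  q <- quantify_spheroid(g$stack)
  seg <- q$segmentation
  expect_false(any(seg$core_mask & seg$invasion_mask))
  expect_identical(dim(seg$perimeter_mask), dim(seg$core_mask))
  expect_true(all(seg$perimeter_mask[seg$perimeter_mask] &
                  (seg$core_mask | seg$invasion_mask)[seg$perimeter_mask]))
  p <- invasive_area_pct(seg)
  expect_true(p >= 0 && p <= 100)
  cents <- q$single_cells$centroids
  un <- seg$core_mask | seg$invasion_mask
  inside <- un[cbind(round(cents[, "y"]) + 1, round(cents[, "x"]) + 1)]
  expect_false(any(inside))
})

test_that("segmentation is invariant under positive intensity rescaling", {
  g <- make_spheroid_image(spheroid_spec(seed = 5))
  proj <- gaussian_blur(flatfield_correct(max_project(g$stack)), 2)
  s1 <- segment_spheroid(proj)
  s2 <- segment_spheroid(proj * 3.7)
  expect_identical(s1$core_mask, s2$core_mask)
  expect_identical(s1$invasion_mask, s2$invasion_mask)
})

test_that("single-cell detection recovers planted singles", {
  none <- make_spheroid_image(spheroid_spec(single_cell_count = 0,
                                            halo_cell_count = 0, seed = 6))
  expect_equal(quantify_spheroid(none$stack)$metrics$single_cell_count, 0)

  g <- make_spheroid_image(spheroid_spec(seed = 3))  # 25 planted, snr 10
  q <- quantify_spheroid(g$stack)
  expect_lt(abs(q$metrics$single_cell_count - 25) / 25, 0.1 + 1e-9)
  m <- match_centroids(q$single_cells$centroids,
                       g$truth$single_cell_centroids, match_radius_px = 5)
  expect_gte(m$f1, 0.9)

  # doubling the planted singles strictly increases the detected count
  g2 <- make_spheroid_image(spheroid_spec(single_cell_count = 50L, seed = 3))
  q2 <- quantify_spheroid(g2$stack)
  expect_gt(q2$metrics$single_cell_count, q$metrics$single_cell_count)
})

test_that("invasion metrics are non-increasing as planted cells are scaled down", {
  series <- vapply(c(1, 0.5, 0.1), function(sc) {
    g <- make_spheroid_image(
      spheroid_spec(halo_cell_count = round(150 * sc),
                    single_cell_count = round(25 * sc), seed = 11))
    q <- quantify_spheroid(g$stack)
    c(q$metrics$invasive_area_pct, q$metrics$single_cell_count)
  }, numeric(2))
  expect_false(is.unsorted(rev(series[1, ])))
  expect_false(is.unsorted(rev(series[2, ])))
})
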