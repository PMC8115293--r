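# Fibre-orientation analysis: structure-tensor orientation estimation,
# axial orientation histograms, mode orientation, and the aligned-fraction
# statistic (probability mass within 10 degrees of the mode).

#' Per-pixel fibre orientation by the structure tensor
#'
#' After Gaussian pre-smoothing, image gradients are taken by central
#' differences and the structure tensor components `Jxx = <Ix^2>`,
#' `Jyy = <Iy^2>`, `Jxy = <Ix Iy>` are averaged in a Gaussian window. The
#' local fibre orientation is perpendicular to the dominant gradient
#' direction: `theta = 90 + 0.5 atan2(2 Jxy, Jxx - Jyy)` mapped to the
#' axial range `(-90, 90]`. Angles use the mathematical convention (x to the
#' right, y up, counter-clockwise positive), so a vertical stripe pattern
#' has orientation 90 degrees.
#'
#' @param img Image matrix.
#' @param window_sigma_px Gaussian window sigma for tensor averaging.
#' @param grad_sigma_px Pre-smoothing sigma before differentiation.
#' @param weight One of `"energy"` (`Jxx + Jyy`, default) or `"coherence"`.
#' @return An object of class `orientation_field`: list with `angle_deg`
#'   (matrix, values in `(-90, 90]`), `weight` (non-negative matrix), and
#'   `zero_weight` flag (`TRUE` for a constant image, where orientation is
#'   undefined and angles are set to 0 with zero weight).
#' @export
structure_tensor_orientation <- function(img, window_sigma_px = 2,
                                         grad_sigma_px = 1,
                                         weight = c("energy", "coherence")) {
  stopifnot(is.matrix(img), all(is.finite(img)), window_sigma_px > 0)
  weight <- match.arg(weight)
  s <- gaussian_blur(img, grad_sigma_px)
  nr <- nrow(s); nc <- ncol(s)
  # central differences with replicated edges; y axis points up: negate the
  # row-direction derivative
  ix <- (s[, c(2:nc, nc)] - s[, c(1, 1:(nc - 1))]) / 2
  iy <- -(s[c(2:nr, nr), ] - s[c(1, 1:(nr - 1)), ]) / 2
  jxx <- gaussian_blur(ix * ix, window_sigma_px)
  jyy <- gaussian_blur(iy * iy, window_sigma_px)
  jxy <- gaussian_blur(ix * iy, window_sigma_px)
  energy <- jxx + jyy
  zero <- all(energy < .Machine$double.eps * max(1, max(abs(s))))
  theta <- wrap_axial(90 + 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi)
  w <- if (weight == "energy") energy else {
    coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
    ifelse(energy > 0, coh / energy, 0)
  }
  if (zero) {
    theta[] <- 0
    w[] <- 0
  }
  structure(list(angle_deg = theta, weight = w, zero_weight = zero),
            class = "orientation_field")
}

# build an orientation_field directly from sampled angles (unit weights);
# used to analyse drawn fibre angles without rendering
orientation_field_from_angles <- function(angles_deg, weights = NULL) {
  n <- length(angles_deg)
  if (is.null(weights)) weights <- rep(1, n)
  structure(list(angle_deg = matrix(wrap_axial(angles_deg), nrow = 1),
                 weight = matrix(weights, nrow = 1),
                 zero_weight = all(weights == 0)),
            class = "orientation_field")
}

#' Weighted axial orientation histogram
#'
#' Bins the per-pixel orientations over `(-90, 90]` with the per-pixel
#' weights and normalises the masses to sum to 1.
#'
#' @param field An `orientation_field`.
#' @param binwidth_deg Bin width in degrees; must divide 180.
#' @return An object of class `orientation_distribution`: list with
#'   `bin_centers_deg`, `mass` (sums to 1), and `binwidth_deg`.
#' @export
orientation_histogram <- function(field, binwidth_deg = 1) {
  stopifnot(inherits(field, "orientation_field"), binwidth_deg > 0,
            abs(180 / binwidth_deg - round(180 / binwidth_deg)) < 1e-9)
  w_total <- sum(field$weight)
  if (w_total <= 0) stop("total orientation weight is zero")
  nb <- as.integer(round(180 / binwidth_deg))
  idx <- ceiling((as.vector(field$angle_deg) + 90) / binwidth_deg)
  idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
  mass <- numeric(nb)
  agg <- rowsum(as.vector(field$weight), idx)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  structure(list(bin_centers_deg = seq(-90 + binwidth_deg / 2,
                                       90 - binwidth_deg / 2,
                                       by = binwidth_deg),
                 mass = mass / w_total,
                 binwidth_deg = binwidth_deg),
            class = "orientation_distribution")
}

#' Mode orientation of a distribution
#'
#' Bin centre of maximal mass; ties are broken towards the smallest angle.
#'
#' @param dist An `orientation_distribution`.
#' @return Angle in degrees.
#' @export
mode_orientation <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  dist$bin_centers_deg[which.max(dist$mass)]
}

#' Fraction of fibres within a half-width of the mode orientation
#'
#' Sums the probability mass in the circular window `mode +/- halfwidth`
#' with wrap-around at +/-90 degrees (axial period 180). Bins whose centres
#' lie within the half-width inclusive are counted, so with 1-degree bins
#' the window spans 21 bins and the continuous-uniform baseline is 21/180.
#'
#' @param dist An `orientation_distribution` (normalised).
#' @param halfwidth_deg Window half-width in degrees.
#' @return Fraction in `(0, 1]`.
#' @export
aligned_fraction <- function(dist, halfwidth_deg = 10) {
  stopifnot(inherits(dist, "orientation_distribution"), halfwidth_deg >= 0)
  m <- mode_orientation(dist)
  d <- abs(wrap_axial_delta(dist$bin_centers_deg - m))
  sum(dist$mass[d <= halfwidth_deg + 1e-9])
}

# signed axial angle difference mapped to (-90, 90]
wrap_axial_delta <- function(a) {
  w <- (a + 90) %% 180 - 90
  w[w == -90] <- 90
  w
}

#' Orientation analysis of maximal z-stack projections
#'
#' Projects each z-stack by per-pixel maximum and runs the structure-tensor
#' orientation analysis per field of view.
#'
#' @param stacks A list of z-stacks (each a list of image matrices).
#' @param ... Arguments passed to [structure_tensor_orientation()].
#' @return List of `orientation_field` objects, one per stack.
#' @export
project_stacks <- function(stacks, ...) {
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  lapply(stacks, function(s) structure_tensor_orientation(max_project(s), ...))
}

#' One-line fibre alignment summary of an image
#'
#' @param img Image matrix (a projection).
#' @param binwidth_deg,halfwidth_deg Histogram bin width and alignment
#'   window half-width in degrees.
#' @param ... Arguments passed to [structure_tensor_orientation()].
#' @return One-row data frame: `mode_deg`, `aligned_fraction`,
#'   `n_pixels_weighted` (total weight).
#' @export
fibre_alignment_summary <- function(img, binwidth_deg = 1,
                                    halfwidth_deg = 10, ...) {
  field <- structure_tensor_orientation(img, ...)
  dist <- orientation_histogram(field, binwidth_deg)
  data.frame(mode_deg = mode_orientation(dist),
             aligned_fraction = aligned_fraction(dist, halfwidth_deg),
             n_pixels_weighted = sum(field$weight))
}
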