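# Synthetic-data generators. Every generator takes an explicit seed, uses a
# private RNG scope, and returns machine-readable ground truth alongside the
# rendered data, so each downstream quantification stage can be tested
# against known planted geometry.

#' Specification of a synthetic spheroid invasion image
#'
#' Describes a nuclear-channel (Hoechst-like) z-stack of a tumour spheroid:
#' a dense nuclear core disc, an invasive halo of nuclei in the surrounding
#' annulus, and isolated individually invading nuclei far from the spheroid,
#' rendered under a planar illumination gradient and additive Gaussian noise.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param core_radius_px Radius of the dense nuclear core disc.
#' @param halo_cell_count Number of invasive-halo nuclei placed uniformly in
#'   the annulus between the core radius and `halo_outer_radius_px`.
#' @param halo_outer_radius_px Outer radius of the invasive halo.
#' @param single_cell_count Number of isolated single-cell nuclei planted
#'   beyond `single_cell_min_dist_px` from the spheroid centre.
#' @param single_cell_min_dist_px Minimum distance of single cells from the
#'   spheroid centre; must exceed the halo outer radius.
#' @param nucleus_radius_px Nucleus radius; nuclei are rendered as 2-D
#'   Gaussian spots with sigma = radius/2, truncated at 3 sigma.
#' @param snr Peak-signal-to-noise ratio (nucleus amplitude over the noise
#'   standard deviation); `Inf` disables noise.
#' @param illumination_gradient_amplitude Relative amplitude of the planar
#'   multiplicative illumination ramp, in `[0, 1)`; the ramp has mean 1.
#' @param n_slices Number of z-slices; nuclei are distributed across slices
#'   and recovered by maximal projection.
#' @param seed Integer seed for the private RNG stream.
#' @return An object of class `spheroid_spec`.
#' @export
spheroid_spec <- function(image_size_px = c(384L, 384L),
                          core_radius_px = 60,
                          halo_cell_count = 150L,
                          halo_outer_radius_px = 110,
                          single_cell_count = 25L,
                          single_cell_min_dist_px = 150,
                          nucleus_radius_px = 5,
                          snr = 10,
                          illumination_gradient_amplitude = 0.2,
                          n_slices = 3L,
                          seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 32),
            core_radius_px > 0, halo_cell_count >= 0,
            halo_outer_radius_px > core_radius_px,
            single_cell_count >= 0,
            single_cell_min_dist_px > halo_outer_radius_px,
            single_cell_min_dist_px < min(image_size_px) / 2,
            nucleus_radius_px > 0, snr > 0,
            illumination_gradient_amplitude >= 0,
            illumination_gradient_amplitude < 1,
            n_slices >= 1)
  structure(list(image_size_px = as.integer(image_size_px),
                 core_radius_px = core_radius_px,
                 halo_cell_count = as.integer(halo_cell_count),
                 halo_outer_radius_px = halo_outer_radius_px,
                 single_cell_count = as.integer(single_cell_count),
                 single_cell_min_dist_px = single_cell_min_dist_px,
                 nucleus_radius_px = nucleus_radius_px,
                 snr = snr,
                 illumination_gradient_amplitude = illumination_gradient_amplitude,
                 n_slices = as.integer(n_slices),
                 seed = as.integer(seed)),
            class = "spheroid_spec")
}

# Additive rendering of Gaussian nuclear spots (sigma = radius/2, truncated
# at 3 sigma) at the given (row, col) centres into `img`.
render_spots <- function(img, rows, cols, sigma, amplitude = 1) {
  if (length(rows) == 0L) return(img)
  rad <- ceiling(3 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  amplitude <- rep_len(amplitude, length(rows))
  for (i in seq_along(rows)) {
    r0 <- rows[i]; c0 <- cols[i]
    rs <- max(1L, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
    cs <- max(1L, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    spot <- amplitude[i] * exp(-d2 / (2 * sigma^2))
    spot[d2 > (3 * sigma)^2] <- 0
    img[rs, cs] <- img[rs, cs] + spot
  }
  img
}

#' Render a synthetic spheroid z-stack with ground truth
#'
#' @param spec A [spheroid_spec()].
#' @return A list with `stack` (list of image matrices), `truth` (a list
#'   with `core_area_px2`, `halo_area_px2`, `invasive_area_pct`,
#'   `single_cell_centroids` as an n x 2 matrix of 0-based (x, y) pixel
#'   coordinates, and `centre_px`), and the `spec`. Halo area is the pixel
#'   area covered by halo nucleus discs outside the core disc.
#' @export
make_spheroid_image <- function(spec) {
  stopifnot(inherits(spec, "spheroid_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
    sigma <- spec$nucleus_radius_px / 2
    margin <- ceiling(3 * sigma) + 1

    # dense core: enough nuclei that spots saturate the disc into a plateau
    n_core <- ceiling(5 * (spec$core_radius_px / spec$nucleus_radius_px)^2)
    rad <- spec$core_radius_px * sqrt(stats::runif(n_core))
    phi <- stats::runif(n_core, 0, 2 * pi)
    core_r <- ctr_r + rad * sin(phi); core_c <- ctr_c + rad * cos(phi)

    # halo nuclei uniform in the annulus
    nh <- spec$halo_cell_count
    rad <- sqrt(stats::runif(nh, spec$core_radius_px^2,
                             spec$halo_outer_radius_px^2))
    phi <- stats::runif(nh, 0, 2 * pi)
    halo_r <- ctr_r + rad * sin(phi); halo_c <- ctr_c + rad * cos(phi)

    # isolated single cells: rejection sampling with mutual separation
    ns <- spec$single_cell_count
    sep <- 4 * spec$nucleus_radius_px
    sr <- numeric(0); sc <- numeric(0)
    tries <- 0L
    while (length(sr) < ns) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("single-cell placement infeasible: too many cells for the available area")
      r0 <- stats::runif(1, margin, nr - margin)
      c0 <- stats::runif(1, margin, nc - margin)
      if (sqrt((r0 - ctr_r)^2 + (c0 - ctr_c)^2) < spec$single_cell_min_dist_px)
        next
      if (length(sr) && min((sr - r0)^2 + (sc - c0)^2) < sep^2) next
      sr <- c(sr, r0); sc <- c(sc, c0)
    }

    all_r <- c(core_r, halo_r, sr); all_c <- c(core_c, halo_c, sc)
    slice_of <- sample.int(spec$n_slices, length(all_r), replace = TRUE)

    ramp <- matrix(1, nr, nc)
    a <- spec$illumination_gradient_amplitude
    if (a > 0) {
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      ramp <- 1 + a * (cc - (nc + 1) / 2) / ((nc - 1) / 2)
    }
    noise_sd <- if (is.finite(spec$snr)) 1 / spec$snr else 0

    stack <- lapply(seq_len(spec$n_slices), function(s) {
      img <- matrix(0, nr, nc)
      pick <- slice_of == s
      img <- render_spots(img, all_r[pick], all_c[pick], sigma)
      img <- img * ramp
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      img
    })

    core_disc <- disc_mask(c(nr, nc), ctr_r, ctr_c, spec$core_radius_px)
    halo_cov <- matrix(FALSE, nr, nc)
    for (i in seq_len(nh)) {
      halo_cov <- halo_cov |
        disc_mask(c(nr, nc), halo_r[i], halo_c[i], spec$nucleus_radius_px)
    }
    halo_cov <- halo_cov & !core_disc
    core_area <- sum(core_disc); halo_area <- sum(halo_cov)

    cents <- cbind(x = sc - 1, y = sr - 1)
    list(stack = stack,
         truth = list(core_area_px2 = core_area,
                      halo_area_px2 = halo_area,
                      invasive_area_pct = 100 * halo_area / (core_area + halo_area),
                      single_cell_centroids = cents,
                      centre_px = c(x = ctr_c - 1, y = ctr_r - 1)),
         spec = spec)
  })
}

#' Specification of a synthetic fibre field
#'
#' Fibres are anti-aliased line segments whose orientations follow a von
#' Mises distribution on the doubled angle (axial data, period 180 degrees).
#' `concentration_kappa = 0` gives uniform orientations; `Inf` gives all
#' fibres at `mean_angle_deg`.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param fibre_count Number of line segments.
#' @param mean_angle_deg Mean orientation, in `(-90, 90]` degrees.
#' @param concentration_kappa Von Mises concentration on the doubled angle,
#'   `>= 0`.
#' @param fibre_length_px,fibre_width_px Segment length and full width.
#' @param snr Peak-signal-to-noise ratio; `Inf` disables noise.
#' @param seed Integer seed.
#' @return An object of class `fibre_field_spec`.
#' @export
fibre_field_spec <- function(image_size_px = c(256L, 256L),
                             fibre_count = 300L,
                             mean_angle_deg = 0,
                             concentration_kappa = 2,
                             fibre_length_px = 40,
                             fibre_width_px = 3,
                             snr = 20,
                             seed = 1L) {
  if (concentration_kappa < 0) stop("concentration_kappa must be >= 0")
  stopifnot(length(image_size_px) == 2L, fibre_count > 0,
            mean_angle_deg > -90, mean_angle_deg <= 90,
            fibre_length_px > 0, fibre_width_px > 0, snr > 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 fibre_count = as.integer(fibre_count),
                 mean_angle_deg = mean_angle_deg,
                 concentration_kappa = concentration_kappa,
                 fibre_length_px = fibre_length_px,
                 fibre_width_px = fibre_width_px,
                 snr = snr, seed = as.integer(seed)),
            class = "fibre_field_spec")
}

#' Sample axial orientations from a von Mises distribution
#'
#' Angles are axial (equivalence classes modulo 180 degrees): the von Mises
#' distribution is placed on the doubled angle and samples are halved back,
#' giving values in `(-90, 90]`. `kappa = 0` is the uniform distribution,
#' `kappa = Inf` the point mass at `mean_deg`. Sampling uses the
#' Best-Fisher wrapped-rejection algorithm.
#'
#' @param n Number of draws.
#' @param mean_deg Mean orientation in degrees.
#' @param kappa Concentration parameter, `>= 0`.
#' @return Numeric vector of angles in `(-90, 90]` degrees.
#' @export
rvonmises_axial <- function(n, mean_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_axial(mean_deg), n))
  if (kappa == 0) return(wrap_axial(stats::runif(n, -90, 90)))
  mu <- 2 * mean_deg * pi / 180
  # Best & Fisher (1979) rejection sampler for von Mises(mu, kappa)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ce <- kappa * (r - f)
    ok <- (ce * (2 - ce) - u2 > 0) | (log(ce / u2) + 1 - ce >= 0)
    th <- mu + sign(u3 - 0.5) * acos(f)
    th <- th[ok]
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_axial(out * 180 / (2 * pi))
}

#' Render a synthetic fibre image with known orientations
#'
#' @param spec A [fibre_field_spec()].
#' @return A list with `image` (matrix) and `angles_deg` (the drawn
#'   orientations, in `(-90, 90]`).
#' @export
make_fibre_image <- function(spec) {
  stopifnot(inherits(spec, "fibre_field_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    angles <- rvonmises_axial(spec$fibre_count, spec$mean_angle_deg,
                              spec$concentration_kappa)
    img <- matrix(0, nr, nc)
    hl <- spec$fibre_length_px / 2
    sw <- spec$fibre_width_px / 2
    cr <- stats::runif(spec$fibre_count, 1, nr)
    cc <- stats::runif(spec$fibre_count, 1, nc)
    for (i in seq_len(spec$fibre_count)) {
      th <- angles[i] * pi / 180
      # (x = col, y = -row) convention: positive angles run counter-clockwise
      dx <- cos(th); dy <- -sin(th)
      r0 <- cr[i] - hl * dy; c0 <- cc[i] - hl * dx
      r1 <- cr[i] + hl * dy; c1 <- cc[i] + hl * dx
      pad <- ceiling(3 * sw)
      rs <- max(1L, floor(min(r0, r1) - pad)):min(nr, ceiling(max(r0, r1) + pad))
      cs <- max(1L, floor(min(c0, c1) - pad)):min(nc, ceiling(max(c0, c1) + pad))
      if (length(rs) == 0L || length(cs) == 0L) next
      rr <- matrix(rs, length(rs), length(cs))
      ccm <- matrix(cs, length(rs), length(cs), byrow = TRUE)
      # distance from pixel to segment
      vr <- r1 - r0; vc <- c1 - c0
      len2 <- vr^2 + vc^2
      t <- ((rr - r0) * vr + (ccm - c0) * vc) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (rr - (r0 + t * vr))^2 + (ccm - (c0 + t * vc))^2
      img[rs, cs] <- img[rs, cs] + exp(-d2 / (2 * sw^2))
    }
    if (is.finite(spec$snr))
      img <- img + matrix(stats::rnorm(nr * nc, 0, 1 / spec$snr), nr, nc)
    list(image = img, angles_deg = angles)
  })
}

#' Specification of a synthetic DQ-collagen degradation field
#'
#' Each cell is a cytoplasm disc with a nuclear spot and a dark
#' peri-cytoplasmic ring in the DQ-collagen channel; the ring width relative
#' to the cytoplasmic diameter is drawn from one of three classes (low
#' < 1/4, medium about 1/3, high about 1/2 of the diameter).
#'
#' @param cell_count Number of cells (may be 0).
#' @param class_probabilities Length-3 probability vector over the
#'   low/medium/high ring classes; must sum to 1.
#' @param cytoplasm_diameter_px Cytoplasm disc diameter.
#' @param background_intensity Intensity of the intact DQ-collagen layer.
#' @param seed Integer seed.
#' @return An object of class `degradation_field_spec`.
#' @export
degradation_field_spec <- function(cell_count = 100L,
                                   class_probabilities = c(1, 1, 1) / 3,
                                   cytoplasm_diameter_px = 24,
                                   background_intensity = 1,
                                   seed = 1L) {
  stopifnot(cell_count >= 0, length(class_probabilities) == 3L,
            all(class_probabilities >= 0), all(class_probabilities <= 1),
            abs(sum(class_probabilities) - 1) < 1e-8,
            cytoplasm_diameter_px > 0, background_intensity > 0)
  structure(list(cell_count = as.integer(cell_count),
                 class_probabilities = class_probabilities,
                 cytoplasm_diameter_px = cytoplasm_diameter_px,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "degradation_field_spec")
}

# per-class ring-width/diameter ratio draws (kept inside the class anchors)
draw_ring_ratio <- function(class) {
  lo <- c(0.12, 1 / 3 - 0.02, 0.50 - 0.02)[class]
  hi <- c(0.22, 1 / 3 + 0.02, 0.50 + 0.02)[class]
  stats::runif(length(class), lo, hi)
}

#' Render a synthetic DQ-collagen degradation image triple
#'
#' Cells are placed on a jittered grid with a cell-free border so the image
#' border is a clean background reference.
#'
#' @param spec A [degradation_field_spec()].
#' @return A list with `dq`, `cytoplasm`, `nuclei` image matrices and
#'   `truth` (per-cell `class`, `ratio`, `ring_width_px`, centre
#'   coordinates, analytic `ring_area_px2`, and the grid geometry).
#' @export
make_degradation_image <- function(spec) {
  stopifnot(inherits(spec, "degradation_field_spec"))
  with_seed(spec$seed, {
    D <- spec$cytoplasm_diameter_px
    spacing <- ceiling(2.2 * D)
    border <- ceiling(1.3 * D)
    n <- spec$cell_count
    if (n == 0L) {
      dq <- matrix(spec$background_intensity, 2L * border, 2L * border)
      blank <- matrix(0, 2L * border, 2L * border)
      return(list(dq = dq, cytoplasm = blank, nuclei = blank,
                  truth = list(class = integer(0), ratio = numeric(0),
                               ring_width_px = numeric(0),
                               centres = cbind(x = numeric(0), y = numeric(0)),
                               ring_area_px2 = numeric(0))))
    }
    ngc <- ceiling(sqrt(n)); ngr <- ceiling(n / ngc)
    nr <- ngr * spacing + 2L * border
    nc <- ngc * spacing + 2L * border
    cells <- seq_len(n)
    gr <- (cells - 1L) %/% ngc; gc <- (cells - 1L) %% ngc
    jit <- spacing * 0.08
    rows <- border + (gr + 0.5) * spacing + stats::runif(n, -jit, jit)
    cols <- border + (gc + 0.5) * spacing + stats::runif(n, -jit, jit)
    classes <- sample.int(3L, n, replace = TRUE, prob = spec$class_probabilities)
    ratios <- draw_ring_ratio(classes)
    widths <- ratios * D

    dq <- matrix(spec$background_intensity, nr, nc)
    cyto <- matrix(0, nr, nc)
    nuc <- matrix(0, nr, nc)
    for (i in cells) {
      cdisc <- disc_mask(c(nr, nc), rows[i], cols[i], D / 2)
      ring <- disc_mask(c(nr, nc), rows[i], cols[i], D / 2 + widths[i]) & !cdisc
      dq[ring] <- dq[ring] * 0.05
      cyto[cdisc] <- 1
    }
    nuc <- render_spots(nuc, rows, cols, sigma = D / 8)
    ring_area <- pi * ((D / 2 + widths)^2 - (D / 2)^2)
    list(dq = dq, cytoplasm = cyto, nuclei = nuc,
         truth = list(class = classes, ratio = ratios,
                      ring_width_px = widths,
                      centres = cbind(x = cols - 1, y = rows - 1),
                      ring_area_px2 = ring_area))
  })
}

#' Synthetic AFM height map with closed-form roughness
#'
#' @param pattern One of `"constant"`, `"two_level"` (left half `+A`, right
#'   half `-A`), or `"sinusoid"` (amplitude `A`, an integer number of
#'   periods along the columns).
#' @param amplitude Pattern amplitude `A` (height units).
#' @param size Integer pair (rows, cols).
#' @param periods Integer number of sinusoid periods.
#' @return A list with `height` (matrix) and `rq_analytic`, the closed-form
#'   root-mean-square roughness of the pattern.
#' @export
make_height_map <- function(pattern = c("constant", "two_level", "sinusoid"),
                            amplitude = 1, size = c(128L, 128L), periods = 4L) {
  pattern <- match.arg(pattern)
  nr <- size[1]; nc <- size[2]
  if (pattern == "constant") {
    z <- matrix(amplitude, nr, nc)
    rq <- 0
  } else if (pattern == "two_level") {
    half <- nc %/% 2
    z <- matrix(rep(c(rep(amplitude, half), rep(-amplitude, nc - half)),
                    each = nr), nr, nc)
    n1 <- nr * half; n2 <- nr * (nc - half)
    rq <- 2 * amplitude * sqrt(n1 * n2) / (n1 + n2)
  } else {
    stopifnot(periods >= 1)
    x <- seq_len(nc) - 1
    row <- amplitude * sin(2 * pi * periods * x / nc)
    z <- matrix(rep(row, each = nr), nr, nc)
    rq <- amplitude / sqrt(2)
  }
  list(height = z, rq_analytic = rq)
}

#' Specification of a synthetic expression dataset with survival
#'
#' Emulates a log2(x+1)-normalised genes x samples expression matrix in
#' which a signature gene set carries a survival-associated effect: samples
#' are split into true high/low groups, signature-gene values are shifted so
#' the per-sample geometric-mean score separates the groups, and event times
#' are exponential with the hazard multiplied for the true-high group.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_genes Number of genes, including the signature.
#' @param signature_genes Character vector of signature gene ids; defaults
#'   to 20 `SIG...` genes included in the gene universe.
#' @param hazard_ratio_high_vs_low Hazard ratio of the true-high group.
#' @param baseline_hazard Baseline exponential hazard (events per time unit).
#' @param censoring_rate Target fraction of censored observations, `[0, 1)`.
#' @param score_separation_sd Half-distance between the two group score
#'   means, in units of the within-group score standard deviation.
#' @param seed Integer seed.
#' @return An object of class `survival_sim_spec`.
#' @export
survival_sim_spec <- function(n_samples = 200L, n_genes = 500L,
                              signature_genes = sprintf("SIG%02d", 1:20),
                              hazard_ratio_high_vs_low = 2,
                              baseline_hazard = 0.1,
                              censoring_rate = 0.2,
                              score_separation_sd = 2,
                              seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= length(signature_genes),
            length(signature_genes) >= 1,
            hazard_ratio_high_vs_low > 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1,
            score_separation_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 signature_genes = signature_genes,
                 hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 score_separation_sd = score_separation_sd,
                 seed = as.integer(seed)),
            class = "survival_sim_spec")
}

#' Generate a synthetic expression dataset with survival outcomes
#'
#' @param spec A [survival_sim_spec()].
#' @return A list of class `expression_dataset` with `values` (genes x
#'   samples matrix of log2(x+1)-scale values, all `>= 0`), `gene_ids`,
#'   `sample_ids`, `survival` (data frame: `sample_id`, `time`, `event`),
#'   and `truth` (true group labels and latent scores).
#' @export
make_expression_dataset <- function(spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    sig <- spec$signature_genes
    n_bg <- spec$n_genes - length(sig)
    genes <- c(sig, if (n_bg > 0) sprintf("G%04d", seq_len(n_bg)))
    samples <- sprintf("S%03d", seq_len(n))

    grp <- sample(rep(c("high", "low"), length.out = n))
    gene_sd <- 0.5
    score_sd <- gene_sd / sqrt(length(sig))
    delta <- spec$score_separation_sd * score_sd
    base <- 3

    vals <- matrix(pmax(stats::rnorm(spec$n_genes * n, base, 1), 0),
                   spec$n_genes, n, dimnames = list(genes, samples))
    mu_sig <- base + ifelse(grp == "high", delta, -delta)
    sigvals <- matrix(stats::rnorm(length(sig) * n,
                                   rep(mu_sig, each = length(sig)), gene_sd),
                      length(sig), n)
    vals[sig, ] <- pmax(sigvals, 0.01)

    hr <- ifelse(grp == "high", spec$hazard_ratio_high_vs_low, 1)
    t_event <- stats::rexp(n, rate = spec$baseline_hazard * hr)
    if (spec$censoring_rate > 0) {
      lam_c <- spec$baseline_hazard *
        spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- stats::rexp(n, rate = lam_c)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    structure(list(values = vals, gene_ids = genes, sample_ids = samples,
                   survival = data.frame(sample_id = samples,
                                         time = time, event = event),
                   truth = list(group = stats::setNames(grp, samples),
                                score_mean = stats::setNames(mu_sig, samples))),
              class = "expression_dataset")
  })
}
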