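# DQ-collagen degradation quantification (degraded area per cell, ring
# classification, H-score and condition ratios), SHG sum-projection
# intensity, and AFM root-mean-square roughness.

#' Degraded DQ-collagen area per cell
#'
#' Degradation abolishes the DQ-collagen fluorescence, so degraded pixels
#' are those below a background-derived threshold: a fraction of the robust
#' background intensity estimated as the median of a cell-free border
#' frame. The degraded area is normalised to the nucleus count obtained by
#' blob detection on the nuclear channel.
#'
#' @param dq_img DQ-collagen channel matrix.
#' @param nuclei_img Nuclear channel matrix of the same shape.
#' @param threshold_fraction Fraction of the background median below which a
#'   pixel counts as degraded.
#' @param border_px Width of the border frame used for the background
#'   estimate.
#' @param nucleus_sigma_px Smoothing sigma for nuclear blob detection.
#' @return List with `area_px2_per_cell`, `degraded_area_px2`, `n_cells`,
#'   and `threshold`.
#' @export
degraded_area_per_cell <- function(dq_img, nuclei_img,
                                   threshold_fraction = 0.5,
                                   border_px = 8, nucleus_sigma_px = 2) {
  stopifnot(is.matrix(dq_img), is.matrix(nuclei_img),
            identical(dim(dq_img), dim(nuclei_img)))
  nr <- nrow(dq_img); nc <- ncol(dq_img)
  b <- min(border_px, floor(min(nr, nc) / 4))
  frame <- c(dq_img[1:b, ], dq_img[(nr - b + 1):nr, ],
             dq_img[, 1:b], dq_img[, (nc - b + 1):nc])
  bg <- stats::median(frame)
  thr <- threshold_fraction * bg
  degraded <- sum(dq_img < thr)
  n_cells <- count_nuclei(nuclei_img, sigma_px = nucleus_sigma_px)
  if (n_cells == 0L) stop("no nuclei detected: cannot normalise degraded area")
  list(area_px2_per_cell = degraded / n_cells,
       degraded_area_px2 = degraded, n_cells = n_cells, threshold = thr)
}

# nucleus count by smoothing + Otsu + connected components
count_nuclei <- function(nuclei_img, sigma_px = 2, min_area_px = 4) {
  sm <- gaussian_blur(nuclei_img, sigma_px)
  rng <- range(sm)
  if (rng[2] <= rng[1]) return(0L)
  norm <- (sm - rng[1]) / (rng[2] - rng[1])
  mask <- norm > EBImage::otsu(norm)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(0L)
  sum(tabulate(lab[lab > 0]) >= min_area_px)
}

#' Classify a peri-cytoplasmic degradation ring
#'
#' The intensity of collagen degradation around a cell is scored from the
#' width of the dark peri-cytoplasmic ring relative to the cytoplasmic
#' diameter: low (1) for rings under a quarter of the diameter, medium (2)
#' around one third, high (3) around one half. The class boundaries default
#' to the midpoints between those anchors (0.29 between 1/4 and 1/3, 0.42
#' between 1/3 and 1/2) and are configurable.
#'
#' @param ratio Ring width divided by cytoplasmic diameter (vectorised), in
#'   `[0, 1)`; alternatively supply `ring_width_px` and
#'   `cytoplasm_diameter_px`.
#' @param ring_width_px,cytoplasm_diameter_px Optional raw measurements from
#'   which the ratio is computed.
#' @param c12,c23 Class boundaries (low/medium and medium/high).
#' @return Integer vector of classes in `{1, 2, 3}`.
#' @export
classify_ring <- function(ratio = NULL, ring_width_px = NULL,
                          cytoplasm_diameter_px = NULL,
                          c12 = 0.29, c23 = 0.42) {
  if (is.null(ratio)) {
    stopifnot(!is.null(ring_width_px), !is.null(cytoplasm_diameter_px),
              all(cytoplasm_diameter_px > 0))
    ratio <- ring_width_px / cytoplasm_diameter_px
  }
  stopifnot(all(is.finite(ratio)), all(ratio >= 0), all(ratio < 1),
            c12 < c23)
  ifelse(ratio < c12, 1L, ifelse(ratio < c23, 2L, 3L))
}

#' Collagen-degradation H-score
#'
#' Weighted mean of low/medium/high degradation-intensity counts:
#' `H = (1 n_low + 2 n_medium + 3 n_high) / n_total`, bounded in `[1, 3]`.
#'
#' @param n_low,n_medium,n_high Non-negative counts of images (or cells)
#'   scored in each class.
#' @return The H-score.
#' @export
h_score <- function(n_low, n_medium, n_high) {
  stopifnot(length(n_low) == 1, length(n_medium) == 1, length(n_high) == 1,
            n_low >= 0, n_medium >= 0, n_high >= 0)
  total <- n_low + n_medium + n_high
  if (total == 0) stop("H-score undefined for zero scored images")
  (1 * n_low + 2 * n_medium + 3 * n_high) / total
}

#' Ratio of H-scores between two conditions
#'
#' @param h_treated,h_control H-scores of the treated and control condition.
#' @return `h_treated / h_control`.
#' @export
degradation_ratio <- function(h_treated, h_control) {
  stopifnot(is.finite(h_treated), is.finite(h_control))
  if (h_control <= 0) stop("control H-score must be positive")
  h_treated / h_control
}

#' Measure peri-cytoplasmic degradation rings in an image
#'
#' Segments cells from the cytoplasm channel, and for each cell estimates
#' the dark-ring width in the DQ channel from the degraded-pixel area in an
#' annulus around the cytoplasm disc: with cytoplasm radius `R` (from the
#' disc area) and measured ring area `A`, the width is
#' `sqrt(R^2 + A/pi) - R`.
#'
#' @param dq_img,cytoplasm_img Same-shape DQ-collagen and cytoplasm channel
#'   matrices.
#' @param threshold_fraction Degraded-pixel threshold as a fraction of the
#'   border-median background.
#' @param border_px Border frame width for the background estimate.
#' @param max_ring_factor Annulus search extent beyond the cytoplasm radius,
#'   as a multiple of the cytoplasm diameter.
#' @return Data frame with one row per cell: `x`, `y` (0-based centroid),
#'   `cytoplasm_diameter_px`, `ring_width_px`, `ratio`, `class`.
#' @export
measure_rings <- function(dq_img, cytoplasm_img, threshold_fraction = 0.5,
                          border_px = 8, max_ring_factor = 0.8) {
  stopifnot(identical(dim(dq_img), dim(cytoplasm_img)))
  nr <- nrow(dq_img); nc <- ncol(dq_img)
  b <- min(border_px, floor(min(nr, nc) / 4))
  frame <- c(dq_img[1:b, ], dq_img[(nr - b + 1):nr, ],
             dq_img[, 1:b], dq_img[, (nc - b + 1):nc])
  thr <- threshold_fraction * stats::median(frame)
  dark <- dq_img < thr
  lab <- EBImage::bwlabel(cytoplasm_img > 0.5)
  bl <- blob_summaries(lab)
  if (nrow(bl) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      cytoplasm_diameter_px = numeric(0),
                      ring_width_px = numeric(0), ratio = numeric(0),
                      class = integer(0)))
  }
  out <- lapply(seq_len(nrow(bl)), function(i) {
    r0 <- bl$row[i]; c0 <- bl$col[i]
    R <- sqrt(bl$area_px[i] / pi)
    D <- 2 * R
    rmax <- R + max_ring_factor * D
    rs <- max(1L, floor(r0 - rmax)):min(nr, ceiling(r0 + rmax))
    cs <- max(1L, floor(c0 - rmax)):min(nc, ceiling(c0 + rmax))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    ann <- d2 > R^2 & d2 <= rmax^2
    a_ring <- sum(dark[rs, cs] & ann)
    w <- sqrt(R^2 + a_ring / pi) - R
    data.frame(x = c0 - 1, y = r0 - 1, cytoplasm_diameter_px = D,
               ring_width_px = w, ratio = w / D)
  })
  out <- do.call(rbind, out)
  out$class <- classify_ring(out$ratio)
  out
}

#' Score a degradation image into a DegradationRecord
#'
#' Runs [measure_rings()] and aggregates the per-cell classes into class
#' counts and the H-score.
#'
#' @inheritParams measure_rings
#' @return List of class `degradation_record`: `n_low`, `n_medium`,
#'   `n_high`, `n_total`, `h_score`, and the per-cell `cells` data frame.
#' @export
score_degradation <- function(dq_img, cytoplasm_img, ...) {
  cells <- measure_rings(dq_img, cytoplasm_img, ...)
  n <- tabulate(cells$class, nbins = 3L)
  structure(list(n_low = n[1], n_medium = n[2], n_high = n[3],
                 n_total = sum(n),
                 h_score = if (sum(n) > 0) h_score(n[1], n[2], n[3]) else NA_real_,
                 cells = cells),
            class = "degradation_record")
}

#' Mean SHG intensity of sum projections in equal-sized ROIs
#'
#' Sum-projects a z-stack and reports the mean intensity in equal-sized,
#' non-overlapping regions of interest placed on a grid (vertical strips of
#' equal width by default).
#'
#' @param zstack List of image matrices, or a single matrix.
#' @param n_rois Number of regions of interest.
#' @return Numeric vector of per-ROI mean intensities.
#' @export
shg_mean_intensity <- function(zstack, n_rois = 3) {
  if (is.matrix(zstack)) zstack <- list(zstack)
  stopifnot(length(zstack) >= 1L, n_rois >= 1)
  d <- dim(zstack[[1]])
  stopifnot(all(vapply(zstack, function(s) identical(dim(s), d), logical(1))))
  proj <- Reduce(`+`, zstack)
  w <- floor(ncol(proj) / n_rois)
  if (w < 1) stop("image too narrow for the requested number of ROIs")
  vapply(seq_len(n_rois), function(i) {
    mean(proj[, ((i - 1) * w + 1):(i * w)])
  }, numeric(1))
}

#' Root-mean-square surface roughness (Rq)
#'
#' `Rq = sqrt(mean((z - mean(z))^2))`: the RMS deviation of the height
#' image about its mean. Optional plane levelling subtracts the
#' least-squares best-fit plane first.
#'
#' @param height Numeric matrix (or vector) of heights; at least 2 finite
#'   values.
#' @param level If `TRUE`, remove the best-fit plane before computing Rq.
#' @return Rq in the units of `height`.
#' @export
rq_roughness <- function(height, level = FALSE) {
  z <- as.numeric(height)
  if (length(z) < 2L || !all(is.finite(z)))
    stop("height map must contain at least 2 finite values")
  if (level && is.matrix(height)) {
    nr <- nrow(height); nc <- ncol(height)
    rr <- as.vector(matrix(seq_len(nr), nr, nc))
    cc <- as.vector(matrix(seq_len(nc), nr, nc, byrow = TRUE))
    z <- stats::lm.fit(cbind(1, rr, cc), z)$residuals
  }
  sqrt(mean((z - mean(z))^2))
}
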