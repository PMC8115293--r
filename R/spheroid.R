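# Spheroid invasion quantification: maximal projection of the nuclear
# channel, illumination correction, smoothing, layered core/invasion
# segmentation, invasive-area percentage, and detection of individually
# invading nuclei outside the spheroid.

#' Maximal intensity projection of a z-stack
#'
#' @param stack List of image matrices of equal dimensions (at least one).
#' @return Matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(is.list(stack), length(stack) >= 1L,
            all(vapply(stack, is.matrix, logical(1))))
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(s) identical(dim(s), d), logical(1))))
    stop("all slices must have identical dimensions")
  Reduce(pmax, stack)
}

#' Flatfield (shading) correction
#'
#' Estimates a smooth multiplicative shading field as a quadratic polynomial
#' surface fitted to low-intensity (background-dominated) pixels, normalises
#' it to mean 1, divides it out, and rescales so the output mean equals the
#' input mean. A constant image is returned unchanged; the correction is
#' idempotent up to a small tolerance.
#'
#' @param img Image matrix with finite intensities, not all zero.
#' @param bg_quantile Quantile below which pixels are treated as background
#'   for the shading fit.
#' @param max_points Maximum number of background pixels used in the fit.
#' @return Corrected image matrix.
#' @export
flatfield_correct <- function(img, bg_quantile = 0.6, max_points = 20000L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (all(img == 0)) stop("all-zero image: shading undefined")
  nr <- nrow(img); nc <- ncol(img)
  if (max(img) == min(img)) return(img)
  # scaled coordinates in [-1, 1]
  rr <- (matrix(seq_len(nr), nr, nc) - (nr + 1) / 2) / ((nr - 1) / 2)
  cc <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - (nc + 1) / 2) / ((nc - 1) / 2)
  thr <- stats::quantile(img, bg_quantile)
  bg <- which(img <= thr)
  if (length(bg) < 12L) bg <- seq_along(img)
  if (length(bg) > max_points)  # deterministic thinning
    bg <- bg[unique(round(seq(1, length(bg), length.out = max_points)))]
  X <- cbind(1, cc[bg], rr[bg], cc[bg]^2, cc[bg] * rr[bg], rr[bg]^2)
  beta <- stats::lm.fit(X, img[bg])$coefficients
  beta[is.na(beta)] <- 0
  shading <- beta[1] + beta[2] * cc + beta[3] * rr +
    beta[4] * cc^2 + beta[5] * cc * rr + beta[6] * rr^2
  if (!all(is.finite(shading)) || mean(shading) <= 1e-12 * max(abs(img)))
    shading <- matrix(1, nr, nc)  # degenerate background: no correction
  else shading <- shading / mean(shading)
  shading[shading < 0.2] <- 0.2  # guard against division blow-up
  out <- img / shading
  out * mean(img) / mean(out)
}

#' Segmentation of a spheroid into core, invasive area, and perimeter
#'
#' Foreground is obtained by Otsu thresholding of the (preprocessed) image.
#' The core is the largest connected component, hole-filled and opened with
#' a disc of radius `core_open_radius` to shed thin protrusions; the
#' invasive area is the remaining foreground linked to the core within
#' `link_radius` (morphological closing), minus the core. The perimeter is
#' the one-pixel boundary of core plus invasion.
#'
#' @param img Preprocessed (projected, flatfielded, blurred) nuclear image.
#' @param core_open_radius Radius (px) of the opening disc separating the
#'   dense core from protrusions.
#' @param link_radius Radius (px) within which foreground blobs are
#'   considered connected to the spheroid.
#' @param spot_level_fraction Second-pass foreground level for invading
#'   nuclei, as a fraction of the typical single-nucleus peak above
#'   background (see Details).
#' @details The Otsu threshold on a spheroid image separates the bright
#'   dense core from background, which truncates faint invading nuclei to
#'   a fraction of their true footprint. The foreground is therefore
#'   refined in a second pass: the typical single-nucleus peak is estimated
#'   as the median peak intensity of foreground blobs outside the core, and
#'   any pixel above `background + spot_level_fraction * (peak -
#'   background)` is added to the foreground. The refinement is skipped
#'   when no blob lies outside the core. Both passes scale with image
#'   intensity, so segmentation is invariant under multiplication by a
#'   positive constant.
#' @return An object of class `spheroid_segmentation`: list with boolean
#'   `core_mask`, `invasion_mask`, `perimeter_mask` (same shape as `img`)
#'   and `centroid_px` (0-based x, y of the core centroid).
#' @export
segment_spheroid <- function(img, core_open_radius = 10, link_radius = 8,
                             spot_level_fraction = 0.25,
                             nucleus_radius_px = 5) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  rng <- range(img)
  if (rng[2] <= rng[1]) stop("no spheroid detected")
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(norm)
  fg <- norm > th
  if (!any(fg)) stop("no spheroid detected")

  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  c0 <- EBImage::fillHull(EBImage::closing(lab == main, disc_brush(2)))
  core <- EBImage::opening(c0, disc_brush(core_open_radius))
  if (!any(core)) core <- c0
  labc <- EBImage::bwlabel(core)
  cs <- tabulate(labc[labc > 0])
  core <- EBImage::fillHull(labc == which.max(cs))
  core <- core > 0
  # re-absorb boundary shards the opening shaved off the core's own
  # component, so a smooth spheroid yields no spurious invasive area
  for (k in 1:3) {
    add <- (c0 > 0) & (EBImage::dilate(core, disc_brush(2)) > 0) & !core
    if (!any(add)) break
    core <- core | add
  }

  # second pass: recover the full footprint of faint nuclei outside the core.
  # The single-nucleus peak is estimated from nucleus-scale blobs well clear
  # of the core, so bright core-rim fragments cannot bias it.
  out_lab <- lab
  out_lab[EBImage::dilate(core, disc_brush(3 * nucleus_radius_px)) > 0] <- 0L
  out_ids <- setdiff(unique(as.vector(out_lab)), 0L)
  if (length(out_ids) > 0L) {
    nuc_area <- pi * nucleus_radius_px^2
    szs <- tabulate(out_lab[out_lab > 0L])
    out_ids <- out_ids[szs[out_ids] >= 3 & szs[out_ids] <= 8 * nuc_area]
  }
  if (length(out_ids) > 0L) {
    peaks <- vapply(out_ids, function(i) max(norm[out_lab == i]), numeric(1))
    bg <- stats::median(norm[!fg])
    th2 <- bg + spot_level_fraction * (stats::median(peaks) - bg)
    if (is.finite(th2) && th2 < th && th2 > bg) fg <- fg | (norm > th2)
  }

  bridge <- EBImage::closing(fg, disc_brush(link_radius))
  labb <- EBImage::bwlabel(bridge)
  in_core <- labb[core]
  in_core <- in_core[in_core > 0]
  region <- if (length(in_core)) {
    labb == as.integer(names(which.max(table(in_core))))
  } else core
  invasion <- fg & region & !core

  un <- core | invasion
  perim <- un & !(EBImage::erode(un, EBImage::makeBrush(3, "box")) > 0)

  idx <- which(core)
  crow <- mean(((idx - 1L) %% nrow(img)) + 1L)
  ccol <- mean(((idx - 1L) %/% nrow(img)) + 1L)
  structure(list(core_mask = core, invasion_mask = invasion,
                 perimeter_mask = perim,
                 centroid_px = c(x = ccol - 1, y = crow - 1),
                 threshold = th),
            class = "spheroid_segmentation")
}

#' Invasive area as a percentage of spheroid size
#'
#' Computes `100 * invasion / (core + invasion)` by default; with
#' `denominator = "core"` the invasive area is expressed relative to the
#' core alone (the two readings of "total size of the spheroid").
#'
#' @param seg A [segment_spheroid()] result.
#' @param denominator `"union"` (default, core + invasion) or `"core"`.
#' @return Percentage in `[0, 100]` (for `"union"`).
#' @export
invasive_area_pct <- function(seg, denominator = c("union", "core")) {
  stopifnot(inherits(seg, "spheroid_segmentation"))
  denominator <- match.arg(denominator)
  a_core <- sum(seg$core_mask); a_inv <- sum(seg$invasion_mask)
  if (a_core + a_inv == 0) stop("empty segmentation: no spheroid area")
  den <- if (denominator == "union") a_core + a_inv else a_core
  if (den == 0) stop("empty denominator mask")
  100 * a_inv / den
}

#' Detect individually invading nuclei outside the spheroid
#'
#' Blob detection restricted to the image region outside the spheroid (core
#' plus invasive area, dilated by an exclusion margin): the image is
#' smoothed at the nuclear scale, thresholded at `mad_factor` robust
#' standard deviations (MAD) above the exterior background median, and
#' connected components above a minimum area are reported as nuclei, sorted
#' by decreasing peak intensity. The threshold is computed from the
#' exterior region only, so the bright spheroid does not bias it.
#'
#' @param img Nuclear-channel image (projection).
#' @param seg A [segment_spheroid()] result of the same shape.
#' @param nucleus_radius_px Expected nucleus radius (px); sets the smoothing
#'   scale, minimum blob area, and the default exclusion margin.
#' @param exclusion_margin_px Margin (px) by which the spheroid mask is
#'   dilated before exclusion; defaults to one nucleus radius.
#' @param mad_factor Detection threshold in exterior MADs above the
#'   exterior median.
#' @return List with `count`, `centroids` (n x 2 matrix of 0-based x, y,
#'   sorted by intensity), and `areas_px`.
#' @export
detect_single_cells <- function(img, seg, nucleus_radius_px = 5,
                                exclusion_margin_px = nucleus_radius_px,
                                mad_factor = 6) {
  stopifnot(is.matrix(img), inherits(seg, "spheroid_segmentation"),
            identical(dim(img), dim(seg$core_mask)))
  excl <- EBImage::dilate(seg$core_mask | seg$invasion_mask,
                          disc_brush(exclusion_margin_px)) > 0
  sm <- gaussian_blur(img, nucleus_radius_px / 2)
  ext <- sm[!excl]
  if (length(ext) == 0L || max(ext) <= min(ext)) {
    return(list(count = 0L,
                centroids = cbind(x = numeric(0), y = numeric(0)),
                areas_px = integer(0)))
  }
  spread <- stats::mad(ext)
  if (spread == 0) spread <- stats::sd(ext)
  th <- stats::median(ext) + mad_factor * spread
  mask <- sm > th & !excl
  lab <- EBImage::bwlabel(mask)
  bl <- blob_summaries(lab, img = sm)
  min_area <- max(4, round(0.3 * pi * nucleus_radius_px^2))
  bl <- bl[bl$area_px >= min_area, , drop = FALSE]
  bl <- bl[order(-bl$peak, bl$row, bl$col), , drop = FALSE]
  list(count = nrow(bl),
       centroids = cbind(x = bl$x, y = bl$y),
       areas_px = bl$area_px)
}

#' Full spheroid invasion quantification from a z-stack
#'
#' Convenience wrapper chaining maximal projection, flatfield correction,
#' 2 px Gaussian blur, segmentation, invasive-area percentage, and
#' single-cell detection.
#'
#' @param stack List of image matrices (a z-stack) or a single matrix.
#' @param nucleus_radius_px Nucleus radius passed to the detector.
#' @param ... Further arguments to [segment_spheroid()].
#' @return List with `segmentation`, `metrics` (one-row data frame:
#'   `core_area_px2`, `invasion_area_px2`, `invasive_area_pct`,
#'   `single_cell_count`) and `single_cells`.
#' @export
quantify_spheroid <- function(stack, nucleus_radius_px = 5, ...) {
  proj <- max_project(stack)
  proj <- flatfield_correct(proj)
  sm <- gaussian_blur(proj, 2)
  seg <- segment_spheroid(sm, nucleus_radius_px = nucleus_radius_px, ...)
  singles <- detect_single_cells(proj, seg,
                                 nucleus_radius_px = nucleus_radius_px)
  metrics <- data.frame(core_area_px2 = sum(seg$core_mask),
                        invasion_area_px2 = sum(seg$invasion_mask),
                        invasive_area_pct = invasive_area_pct(seg),
                        single_cell_count = singles$count)
  list(segmentation = seg, metrics = metrics, single_cells = singles)
}

#' Match detected centroids to planted ground truth
#'
#' Greedy nearest matching within a radius; used to score detection
#' precision/recall/F1 against generator ground truth.
#'
#' @param detected,truth n x 2 matrices of (x, y) coordinates.
#' @param match_radius_px Maximum centre-to-centre distance for a match.
#' @return List with `n_matched`, `precision`, `recall`, `f1`.
#' @export
match_centroids <- function(detected, truth, match_radius_px) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    f1 <- if (nd == 0L && nt == 0L) 1 else 0
    return(list(n_matched = 0L,
                precision = if (nd) 0 else 1,
                recall = if (nt) 0 else 1, f1 = f1))
  }
  d <- sqrt(outer(detected[, 1], truth[, 1], "-")^2 +
            outer(detected[, 2], truth[, 2], "-")^2)
  matched <- 0L
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > match_radius_px) break
    matched <- matched + 1L
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  prec <- matched / nd; rec <- matched / nt
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(n_matched = matched, precision = prec, recall = rec, f1 = f1)
}
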