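# Shared low-level image helpers: seeded RNG scope, separable Gaussian
# filtering with symmetric boundary handling, disc rasterisation, and
# connected-component blob summaries.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's RNG state afterwards. All generators route
# their randomness through this so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Symmetric (edge-including) reflection of out-of-range indices.
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

#' Gaussian blur of an image
#'
#' Separable Gaussian smoothing with a kernel truncated at four standard
#' deviations and normalised to unit sum, so the filter is linear and
#' mass-preserving. Boundaries are handled by symmetric reflection.
#'
#' @param img Numeric matrix (rows = y, columns = x).
#' @param sigma_px Standard deviation of the Gaussian kernel in pixels;
#'   the default 2 px matches the preprocessing used for spheroid images.
#' @return A numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma_px = 2) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(img)
  k <- gaussian_kernel1d(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(m) {
    # convolve along rows (dimension 1)
    n <- nrow(m)
    idx <- reflect_index(seq(1L - r, n + r), n)
    p <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[seq(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

# Boolean disc mask of the pixels within `radius` of (row0, col0) in a
# matrix of size dim_rc. Pixel centres at integer coordinates.
disc_mask <- function(dim_rc, row0, col0, radius) {
  rr <- matrix(seq_len(dim_rc[1]), dim_rc[1], dim_rc[2])
  cc <- matrix(seq_len(dim_rc[2]), dim_rc[1], dim_rc[2], byrow = TRUE)
  (rr - row0)^2 + (cc - col0)^2 <= radius^2
}

# Odd-sized disc structuring element of the given radius.
disc_brush <- function(radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Per-component summaries of a labelled mask: area, centroid (row/col and
# 0-based x/y), and peak intensity in `img` if supplied.
blob_summaries <- function(labels, img = NULL) {
  idx <- which(labels > 0)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      row = numeric(), col = numeric(),
                      x = numeric(), y = numeric(), peak = numeric()))
  }
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  if (is.null(img)) {
    w <- rep(1, length(idx))
    pk <- tapply(w, lab, length)
  } else {
    w <- img[idx]
    w <- w - min(w) + 1e-9  # intensity weights for centroids
    pk <- tapply(img[idx], lab, max)
  }
  area <- as.integer(tapply(rep(1L, length(idx)), lab, sum))
  sw <- tapply(w, lab, sum)
  crow <- tapply(w * rr, lab, sum) / sw
  ccol <- tapply(w * cc, lab, sum) / sw
  data.frame(label = as.integer(names(sw)), area_px = area,
             row = as.numeric(crow), col = as.numeric(ccol),
             x = as.numeric(ccol) - 1, y = as.numeric(crow) - 1,
             peak = as.numeric(pk))
}

# Map any angle in degrees to the axial range (-90, 90].
wrap_axial <- function(a) {
  w <- a %% 180
  w[w > 90] <- w[w > 90] - 180
  w[w == -90] <- 90
  w
}
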