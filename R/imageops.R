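# R-side wrappers around the compiled raster primitives.

#' Gaussian blur of an intensity raster
#'
#' Separable Gaussian convolution with reflective boundary handling. The
#' kernel is truncated at three standard deviations and renormalized, so total
#' intensity is conserved away from the image border.
#'
#' @param img Numeric matrix (row, col intensity raster).
#' @param sigma Standard deviation of the Gaussian in pixels; `0` returns the
#'   input unchanged.
#' @return Numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (sigma == 0) return(img)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  cpp_conv_sep(img, k)
}

# Grayscale opening (erosion then dilation) with a square structuring element
# of half-width `half`. Used as a smooth lower envelope of the image.
gray_opening <- function(img, half) {
  cpp_dilate_rect(cpp_erode_rect(img, as.integer(half)), as.integer(half))
}

# Otsu threshold on a numeric raster, computed on a 256-bin histogram over the
# observed range. Returns a value on the intensity scale of `img`.
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  n_bins <- 256L
  h <- tabulate(pmin(
    n_bins, 1L + as.integer((v - rng[1]) / diff(rng) * n_bins)
  ), nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Variance of the 4-neighbour Laplacian over the interior of a raster: a
# standard high-frequency sharpness measure.
laplacian_variance <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(0)
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  lap <- 4 * img[ci, cj] -
    img[ci - 1, cj] - img[ci + 1, cj] -
    img[ci, cj - 1] - img[ci, cj + 1]
  stats::var(as.numeric(lap))
}

# Rasterized disk mask of integer radius r (pixels at squared distance <= r^2
# from the center pixel). Shared by the ROI oracle and the simulator.
disk_mask <- function(radius) {
  r <- as.integer(radius)
  x <- seq(-r, r)
  outer(x, x, function(a, b) a^2 + b^2 <= radius^2)
}
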