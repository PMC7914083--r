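# Image enhancement and normalization applied before feature extraction:
# global gray-histogram equalization (the enhancement used on the chest
# radiographs) and a deterministic resize to the network input size.

#' Global histogram equalization
#'
#' Remaps the 256 gray levels through the image's cumulative distribution
#' function, stretching contrast so occupied levels spread over the full
#' range. The map is the classic normalized-CDF form
#' \code{round(255 * (cdf(v) - cdf_min) / (n - cdf_min))}: monotone
#' non-decreasing, an (exact) fixed point on a perfectly uniform histogram,
#' and idempotent up to one gray level.
#'
#' @param image Numeric matrix with intensities in \code{[0, 255]}.
#' @return Matrix of the same dimensions with integer intensities in
#'   \code{[0, 255]}.
#' @export
equalize_histogram <- function(image) {
  if (!is.matrix(image) || length(image) == 0L) {
    stopf("`image` must be a nonempty numeric matrix")
  }
  if (min(image) < 0 || max(image) > 255) stopf("intensities must lie in [0, 255]")
  lev <- as.integer(round(image))       # 256-bin histogram over 0..255
  counts <- tabulate(lev + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0L)[1]]
  n <- length(lev)
  if (n == cdf_min) return(matrix(as.numeric(lev), nrow(image)))  # constant image
  map <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(as.numeric(map[lev + 1L]), nrow(image))
}

#' Resize to a square target and rescale to [0, 1]
#'
#' Deterministic separable resampling: area averaging when shrinking an axis
#' (antialiased block averaging for integer factors) and bilinear
#' interpolation when enlarging. Output intensities are divided by 255, the
#' scale the embedding network expects.
#'
#' @param image Numeric matrix with intensities in \code{[0, 255]}.
#' @param target Output side length in pixels (>= 32).
#' @return \code{target x target} numeric matrix with values in \code{[0, 1]}.
#' @export
resize_normalize <- function(image, target) {
  if (!is.matrix(image) || length(image) == 0L) {
    stopf("`image` must be a nonempty numeric matrix")
  }
  assert_scalar_count(target, "target", min = 32L)
  wr <- resample_weights(nrow(image), target)
  wc <- resample_weights(ncol(image), target)
  (wr %*% image %*% t(wc)) / 255
}

# Row-weight matrix (n_out x n_in) for 1-D resampling along one axis.
#' @keywords internal
#' @noRd
resample_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  w <- matrix(0, n_out, n_in)
  if (n_out < n_in) {                   # area averaging over [i, i+1) cells
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo); j1 <- ceiling(hi) - 1
      for (j in j0:j1) {
        ov <- min(hi, j + 1) - max(lo, j)
        if (ov > 0) w[i, j + 1] <- ov / scale
      }
    }
  } else {                              # bilinear on pixel centers
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      pos <- (i - 0.5) * scale - 0.5
      pos <- min(max(pos, 0), n_in - 1)
      j <- floor(pos); frac <- pos - j
      w[i, j + 1] <- 1 - frac
      if (frac > 0) w[i, j + 2] <- frac
    }
  }
  w
}
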