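## Filtered image variants feeding the radiomics extractor: a single-level
## undecimated (a trous) Haar wavelet decomposition and Laplacian-of-Gaussian
## response images.

#' Single-level 3D stationary wavelet decomposition
#'
#' Separable undecimated Haar transform: along each axis the image is passed
#' through the low-pass `(1, 1)/sqrt(2)` or high-pass `(1, -1)/sqrt(2)` pair
#' (no downsampling, edge replication), giving the 8 sub-bands LLL ... HHH.
#' Letter order follows the (x, y, z) axes.
#'
#' @param arr 3D numeric array
#' @return named list of 8 sub-band arrays (`LLL`, `HLL`, ..., `HHH`)
#' @export
wavelet_decompose <- function(arr) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  pass <- function(a, axis, high) {
    k <- if (high) hi else lo
    ## 2-tap kernel: y_i = k1*x_i + k2*x_{i+1}, replicated edge
    d <- dim(a)
    idx <- vector("list", 3)
    for (ax in 1:3) idx[[ax]] <- seq_len(d[ax])
    nxt <- idx
    nxt[[axis]] <- pmin(idx[[axis]] + 1L, d[axis])
    k[1] * a + k[2] * a[nxt[[1]], nxt[[2]], nxt[[3]]]
  }
  out <- list()
  for (cx in c("L", "H")) for (cy in c("L", "H")) for (cz in c("L", "H")) {
    b <- pass(arr, 1, cx == "H")
    b <- pass(b, 2, cy == "H")
    b <- pass(b, 3, cz == "H")
    out[[paste0(cx, cy, cz)]] <- b
  }
  out[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

#' Laplacian-of-Gaussian response image
#'
#' Separable implementation: the LoG is the sum over axes of the second
#' derivative of a Gaussian along that axis combined with plain Gaussian
#' smoothing along the others. `sigma_mm` is the physical scale in mm and is
#' converted per axis by the voxel spacing.
#'
#' @param arr 3D numeric array
#' @param sigma_mm Gaussian scale in mm
#' @param spacing voxel spacing in mm per axis
#' @return LoG-filtered array (same dimensions)
#' @export
log_filter <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  if (sigma_mm <= 0) stopf("sigma_mm must be > 0")
  sig <- sigma_mm / spacing
  g <- lapply(sig, function(s) {
    r <- max(2L, ceiling(4 * s))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  })
  d2g <- lapply(seq_len(3), function(a) {
    s <- sig[a]
    r <- max(2L, ceiling(4 * s))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    k <- k / sum(k)
    ## second derivative of the Gaussian, converted to physical units (1/mm^2)
    k * (x^2 - s^2) / s^4 / spacing[a]^2
  })
  out <- array(0, dim(arr))
  for (axis in 1:3) {
    tmp <- arr
    for (ax in 1:3) {
      k <- if (ax == axis) d2g[[ax]] else g[[ax]]
      tmp <- convolve_axis(tmp, k, ax, renorm = (ax != axis))
    }
    out <- out + tmp
  }
  out
}
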