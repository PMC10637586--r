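#' Construct a spatial volume
#'
#' Minimal container for a 3D scalar image: a numeric array plus the physical
#' voxel spacing in mm per axis. Axis order is (x, y, z) with z the slice
#' axis; voxel centres sit at `(index - 1) * spacing` mm from the origin.
#'
#' @param data 3D numeric array
#' @param spacing numeric length-3, mm per axis, strictly positive
#' @param origin numeric length-3 physical origin in mm (metadata only)
#' @return an object of class `hab_volume`
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stopf("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive numbers")
  if (any(!is.finite(data))) stopf("volume data must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "hab_volume")
}

#' @export
print.hab_volume <- function(x, ...) {
  cat(sprintf("<hab_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.hab_volume <- function(x) dim(x$data)

## ---- axis-wise filtering ---------------------------------------------------

## Convolve `arr` along `axis` with kernel `k` (odd length, centred).
## Edges are handled by kernel renormalisation over the in-bounds taps for
## smoothing kernels (`renorm = TRUE`) and by zero padding otherwise.
convolve_axis <- function(arr, k, axis, renorm = TRUE) {
  d <- dim(arr)
  array(cpp_convolve_axis(arr, d, k, axis - 1L, isTRUE(renorm)), d)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian filter with the scale given in physical mm; axes whose
#' effective sigma is below 0.2 voxels are left untouched. Edges use
#' renormalised (clipped) kernels.
#'
#' @param arr 3D numeric array
#' @param sigma_mm smoothing scale in mm (scalar or per-axis length 3)
#' @param spacing voxel spacing in mm per axis
#' @return smoothed array of identical dimension
#' @export
smooth_gaussian <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  sigma_mm <- rep_len(sigma_mm, 3)
  for (axis in 1:3) {
    s <- sigma_mm[axis] / spacing[axis]
    if (s < 0.2) next
    arr <- convolve_axis(arr, gaussian_kernel(s), axis, renorm = TRUE)
  }
  arr
}
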