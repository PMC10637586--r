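## Per-voxel features driving habitat clustering: grayscale intensity and
## slice-wise local entropy.

#' Configuration for the local-entropy map
#'
#' Entropy is computed per slice (2D), from the `n_bins`-bin histogram of the
#' grayscale values in the square window of half-width `window_radius`
#' centred on each voxel; windows are clipped at image borders and include
#' window voxels regardless of mask membership. The entropy of a window is
#' `H = -sum_i p_i * log2(p_i + epsilon)` with the `p_i` summing to 1 over
#' occupied bins; `epsilon` keeps the logarithm finite on empty bins so H
#' tends to the Shannon entropy as `epsilon -> 0`.
#'
#' @param window_radius in-plane half-width in voxels (5x5 window by default)
#' @param n_bins number of equal-width histogram bins (>= 2)
#' @param epsilon small positive stabiliser inside the logarithm
#' @param range bin-edge range; `NULL` (default) uses the volume's data range,
#'   which makes the map invariant to adding a constant to the image
#' @return an `entropy_config` list
#' @export
entropy_config <- function(window_radius = 2L, n_bins = 32L,
                           epsilon = 1e-12, range = NULL) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  if (window_radius < 1) stopf("window_radius must be >= 1")
  if (epsilon <= 0) stopf("epsilon must be > 0")
  structure(list(window_radius = as.integer(window_radius),
                 n_bins = as.integer(n_bins), epsilon = epsilon,
                 range = range), class = "entropy_config")
}

#' Slice-wise local-entropy map
#'
#' @param vol `hab_volume` (typically grayscale-normalised)
#' @param mask mask `hab_volume`/logical array (used only for validation; the
#'   window histograms use all window voxels)
#' @param config an [entropy_config()]
#' @return `hab_volume` of entropy values in bits, defined everywhere
#' @export
entropy_map <- function(vol, mask = NULL, config = entropy_config()) {
  x <- vol$data
  if (!is.null(mask)) {
    m <- if (inherits(mask, "hab_volume")) mask$data > 0 else mask > 0
    if (!identical(dim(m), dim(x))) stopf("grid mismatch")
    if (!any(m)) stopf("empty VOI: mask contains no foreground voxels")
  }
  rng <- config$range %||% range(x)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  nb <- config$n_bins
  ## equal-width bins over rng; values at the top edge fall in the last bin
  bin <- pmin(pmax(floor((x - rng[1]) / (rng[2] - rng[1]) * nb) + 1L, 1L), nb)
  d <- dim(x)
  out <- array(cpp_entropy_map(bin, d, nb, config$window_radius,
                               config$epsilon), d)
  volume(out, vol$spacing, vol$origin)
}

#' Build the per-voxel feature table of a patient
#'
#' One row per mask voxel with its grid index, intensity and local entropy.
#' The summed VOI intensity (total voxel signal) is attached as the
#' `total_intensity` attribute for QC.
#'
#' @param vol intensity `hab_volume`
#' @param ent entropy `hab_volume` from [entropy_map()]
#' @param mask mask `hab_volume` or logical array
#' @param patient_id identifier copied into every row
#' @return data.frame with columns `patient_id,i,j,k,intensity,entropy`
#' @export
build_voxel_table <- function(vol, ent, mask, patient_id = "P001") {
  m <- if (inherits(mask, "hab_volume")) mask$data > 0 else mask > 0
  if (!identical(dim(m), dim(vol$data)) ||
      !identical(dim(m), dim(ent$data))) stopf("grid mismatch")
  if (!any(m)) stopf("empty VOI: mask contains no foreground voxels")
  idx <- which_voxels(m)
  tab <- data.frame(patient_id = patient_id,
                    i = idx[, 1], j = idx[, 2], k = idx[, 3],
                    intensity = vol$data[m], entropy = ent$data[m],
                    stringsAsFactors = FALSE)
  attr(tab, "total_intensity") <- sum(tab$intensity)
  tab
}

#' Fit a pooled z-score transform for voxel features
#'
#' Pools `intensity` and `entropy` over a list of voxel tables (typically all
#' training patients) and returns the per-feature mean/SD, so Euclidean
#' distances in the clustering are scale-free and new patients can be
#' transformed with the stored parameters.
#'
#' @param tables list of voxel tables from [build_voxel_table()]
#' @return a `voxel_zscore` transform (means, sds)
#' @export
fit_voxel_zscore <- function(tables) {
  pooled <- do.call(rbind, lapply(tables, function(t)
    t[, c("intensity", "entropy")]))
  if (nrow(pooled) < 2) stopf("need >= 2 pooled voxels")
  mu <- colMeans(pooled)
  sdev <- apply(pooled, 2, sd)
  zero <- names(sdev)[sdev == 0]
  if (length(zero))
    stopf("zero-variance voxel feature: %s", paste(zero, collapse = ", "))
  structure(list(mean = mu, sd = sdev), class = "voxel_zscore")
}

#' Apply a stored voxel z-score transform
#'
#' @param table a voxel table
#' @param transform a `voxel_zscore` from [fit_voxel_zscore()]
#' @return the table with added `z_intensity`, `z_entropy` columns
#' @export
apply_voxel_zscore <- function(table, transform) {
  table$z_intensity <- (table$intensity - transform$mean[["intensity"]]) /
    transform$sd[["intensity"]]
  table$z_entropy <- (table$entropy - transform$mean[["entropy"]]) /
    transform$sd[["entropy"]]
  table
}
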