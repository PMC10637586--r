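## Synthetic phantom cohorts with known habitat ground truth.
##
## The generator emulates the study design the pipeline targets: tumours
## composed of a few spatially contiguous sub-regions ("habitats") with
## distinct intensity means and texture (local smoothness) levels, two
## cohorts, a binary label whose signal is carried by one designated habitat,
## and a perturbed duplicate mask standing in for a second reader.

#' Specification of a single phantom tumour
#'
#' Defaults describe a 30 mm three-habitat tumour made of concentric
#' ellipsoidal shells (core / intermediate / rim) with intensity means
#' 50/125/200 on an arbitrary grayscale, nominal voxel noise SD 25 (adjacent
#' means three nominal SDs apart) and habitat-specific Gaussian smoothing of
#' the noise field (2.5 / 1.2 / 0.4 mm) so the habitats also differ in local
#' entropy, decreasing from rim to core.
#'
#' @param grid_shape voxels per axis (3 integers)
#' @param voxel_spacing mm per axis
#' @param tumour_axes ellipsoid semi-axes in mm
#' @param n_habitats number of sub-regions (>= 1)
#' @param habitat_fractions volume proportions, summing to 1
#' @param habitat_intensity_means per-habitat mean grayscale
#' @param habitat_intensity_sds per-habitat nominal noise SD (before
#'   smoothing; smoothing reduces the realised voxel SD)
#' @param habitat_smoothness per-habitat Gaussian smoothing scale in mm — the
#'   texture knob: larger values lower local entropy
#' @param geometry `"shells"` (concentric, default) or `"sectors"` (angular)
#' @param preserve_noise_sd if `TRUE`, the smoothed noise field is rescaled
#'   back to the nominal SD, so smoothness sets the spatial correlation
#'   length only and texture is decoupled from amplitude; if `FALSE`
#'   (default) smoothing also damps the voxel SD, as for a filtered
#'   acquisition
#' @param seed integer RNG seed
#' @return a `phantom_spec` list, validated
#' @export
phantom_spec <- function(grid_shape = c(36, 36, 12),
                         voxel_spacing = c(1, 1, 3),
                         tumour_axes = c(15, 15, 15),
                         n_habitats = 3,
                         habitat_fractions = rep(1 / n_habitats, n_habitats),
                         habitat_intensity_means = c(50, 125, 200)[seq_len(n_habitats)],
                         habitat_intensity_sds = rep(25, n_habitats),
                         habitat_smoothness = c(2.5, 1.2, 0.4)[seq_len(n_habitats)],
                         geometry = c("shells", "sectors"),
                         preserve_noise_sd = FALSE,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               tumour_axes = as.numeric(tumour_axes),
               n_habitats = as.integer(n_habitats),
               habitat_fractions = as.numeric(habitat_fractions),
               habitat_intensity_means = as.numeric(habitat_intensity_means),
               habitat_intensity_sds = as.numeric(habitat_intensity_sds),
               habitat_smoothness = as.numeric(habitat_smoothness),
               geometry = match.arg(geometry),
               preserve_noise_sd = isTRUE(preserve_noise_sd),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(spec) {
  k <- spec$n_habitats
  if (k < 1) stopf("n_habitats must be >= 1")
  if (abs(sum(spec$habitat_fractions) - 1) > 1e-9)
    stopf("habitat_fractions must sum to 1 (got %.12f)",
          sum(spec$habitat_fractions))
  if (any(spec$habitat_fractions <= 0)) stopf("habitat_fractions must be > 0")
  if (any(spec$habitat_intensity_sds < 0)) stopf("intensity sds must be >= 0")
  for (f in c("habitat_fractions", "habitat_intensity_means",
              "habitat_intensity_sds", "habitat_smoothness"))
    if (length(spec[[f]]) != k)
      stopf("%s must have one entry per habitat (%d)", f, k)
  extent <- (spec$grid_shape - 1) * spec$voxel_spacing / 2
  if (any(spec$tumour_axes > extent))
    stopf("tumour (semi-axes %s mm) larger than grid (half-extent %s mm)",
          paste(spec$tumour_axes, collapse = "/"),
          paste(format(extent), collapse = "/"))
  invisible(spec)
}

#' Specification of a synthetic two-cohort study
#'
#' Label-positive patients receive a standardised shift of the signal
#' habitat's texture: its log-smoothness moves by
#' `-effect_size * smoothness_lsd` (sharper, higher-variance local
#' structure), i.e. the effect is `effect_size` between-patient SDs of that
#' parameter. The default nuisance structure concentrates the
#' between-patient intensity variability on the intermediate habitat while
#' the extreme (darkest/brightest) habitats stay stable, so the whole-VOI
#' min-max grayscale anchors are reproducible across patients — as in
#' contrast-enhanced imaging, where the necrotic floor and peak-enhancement
#' ceiling are comparatively consistent and the transitional zone varies.
#'
#' @param n_train,n_test patients per cohort
#' @param label_prevalence probability a patient is label-positive, in (0,1)
#' @param signal_habitat habitat index whose parameters carry the label
#'   signal; default 2, the intermediate (transitional) stratum
#' @param effect_size standardised log-smoothness shift (in units of
#'   `smoothness_lsd`) applied to the signal habitat of label-positive
#'   patients
#' @param between_sd between-patient SD of each habitat's mean intensity
#'   (scalar or per-habitat vector)
#' @param smoothness_lsd between-patient SD of each habitat's log-smoothness
#'   (also the unit of the textural component of the effect)
#' @param fraction_sd between-patient SD of each habitat's volume fraction
#'   (fractions are re-normalised after jittering): tumours differ in how
#'   much of each compartment they carry, the main nuisance on whole-tumour
#'   features
#' @param mask_jitter_mm magnitude of the second-reader boundary perturbation
#' @param seed integer RNG seed
#' @return a `cohort_spec` list, validated
#' @export
cohort_spec <- function(n_train = 20, n_test = 10, label_prevalence = 0.5,
                        signal_habitat = 2, effect_size = 2,
                        between_sd = c(1.5, 5, 1.5), smoothness_lsd = 0.1,
                        fraction_sd = 0.05,
                        mask_jitter_mm = 1, seed = 1L) {
  if (label_prevalence <= 0 || label_prevalence >= 1)
    stopf("label_prevalence must lie in (0,1)")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 label_prevalence = label_prevalence,
                 signal_habitat = as.integer(signal_habitat),
                 effect_size = effect_size, between_sd = between_sd,
                 smoothness_lsd = smoothness_lsd, fraction_sd = fraction_sd,
                 mask_jitter_mm = mask_jitter_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

## Ellipsoid-normalised radius (and azimuth) of every voxel centre.
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  centre <- (d - 1) * sp / 2
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) * sp[a] - centre[a]))
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  r2 <- (X / spec$tumour_axes[1])^2 + (Y / spec$tumour_axes[2])^2 +
    (Z / spec$tumour_axes[3])^2
  list(r = sqrt(r2), theta = atan2(Y, X))
}

#' Generate one phantom tumour volume
#'
#' Builds an ellipsoidal binary mask on the spec's grid and partitions it into
#' `n_habitats` contiguous compartments: concentric shells (default) whose
#' boundaries are radius quantiles chosen so the voxel fractions match the
#' spec, or angular sectors. Each habitat's intensity is its mean plus
#' Gaussian noise smoothed at the habitat's smoothness scale.
#'
#' @param spec a [phantom_spec()]
#' @return list with `volume` (`hab_volume`), `mask` (logical array) and
#'   `truth` (integer habitat map, 0 = background)
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' table(ph$truth[ph$mask])
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  mask <- geo$r <= 1
  if (!any(mask)) stopf("tumour mask is empty")
  k <- spec$n_habitats
  coord <- if (spec$geometry == "shells") geo$r else geo$theta
  truth <- array(0L, spec$grid_shape)
  cuts <- quantile(coord[mask], probs = cumsum(spec$habitat_fractions),
                   names = FALSE, type = 1)
  lab <- findInterval(coord[mask], c(-Inf, cuts[-k], Inf), left.open = FALSE)
  truth[mask] <- pmin(lab, k)
  vol <- array(0, spec$grid_shape)
  with_seed(spec$seed, {
    for (h in seq_len(k)) {
      sel <- truth == h
      if (!any(sel)) next
      if (spec$habitat_intensity_sds[h] > 0) {
        noise <- array(rnorm(prod(spec$grid_shape),
                             0, spec$habitat_intensity_sds[h]),
                       spec$grid_shape)
        noise <- smooth_gaussian(noise, spec$habitat_smoothness[h],
                                 spec$voxel_spacing)
        if (isTRUE(spec$preserve_noise_sd) && sd(noise) > 0)
          ## rescale so smoothness sets the correlation length only and
          ## the voxel SD keeps its nominal value — texture and amplitude
          ## become independent knobs
          noise <- noise * (spec$habitat_intensity_sds[h] / sd(noise))
      } else noise <- array(0, spec$grid_shape)
      vol[sel] <- spec$habitat_intensity_means[h] + noise[sel]
    }
  })
  list(volume = volume(vol, spec$voxel_spacing), mask = mask, truth = truth)
}

#' Dice similarity of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @param a,b logical/0-1 arrays of identical dimension
#' @return Dice coefficient in \[0, 1\]
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask dimensions differ")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Simulate a second reader by perturbing a mask boundary
#'
#' Applies a seeded random sequence of one-voxel dilations/erosions to small
#' boundary patches, emulating inter-reader outlining variability. The number
#' of patch operations scales with `jitter_mm`; `jitter_mm = 0` returns the
#' mask unchanged.
#'
#' @param mask logical 3D array, non-empty
#' @param jitter_mm perturbation magnitude in mm
#' @param seed integer seed
#' @param spacing voxel spacing in mm
#' @return perturbed logical mask
#' @export
perturb_mask <- function(mask, jitter_mm, seed = 1L, spacing = c(1, 1, 1)) {
  if (!any(mask)) stopf("mask is empty")
  if (jitter_mm < 0) stopf("jitter_mm must be >= 0")
  if (jitter_mm == 0) return(mask)
  d <- dim(mask)
  n_ops <- max(1L, round(4 * jitter_mm / min(spacing[1:2])))
  patch_r <- max(1, round(jitter_mm / min(spacing[1:2]))) + 1L
  with_seed(seed, {
    for (op in seq_len(n_ops)) {
      inner <- boundary_voxels(mask)           # mask voxels touching outside
      outer <- eligible_dilation(mask)         # outside voxels touching mask
      grow <- runif(1) < 0.5
      pool <- if (grow) which(outer) else which(inner)
      if (length(pool) == 0) next
      centre <- arrayInd(sample(pool, 1), d)
      target <- if (grow) outer else inner
      tv <- which_voxels(target)
      dist <- sqrt(colSums((t(tv) - as.vector(centre))^2 *
                             (spacing / min(spacing))^2))
      sel <- tv[dist <= patch_r, , drop = FALSE]
      flat <- sel[, 1] + d[1] * (sel[, 2] - 1) + d[1] * d[2] * (sel[, 3] - 1)
      mask[flat] <- grow
      if (!any(mask)) stopf("perturbation emptied the mask")
    }
  })
  mask
}

## Voxels of `mask` with at least one 6-neighbour outside `mask`.
## Out-of-grid neighbours are treated as inside (phantom masks never touch
## the grid edge; the spec validator guarantees a margin).
boundary_voxels <- function(mask) {
  d <- dim(mask)
  shifted_any_not <- array(FALSE, d)
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx; src[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
    nb <- mask[src[[1]], src[[2]], src[[3]]]
    shifted_any_not <- shifted_any_not | !nb
  }
  mask & shifted_any_not
}

## Outside voxels adjacent (6-connectivity) to the mask.
eligible_dilation <- function(mask) {
  d <- dim(mask)
  near <- array(FALSE, d)
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx; src[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
    near <- near | mask[src[[1]], src[[2]], src[[3]]]
  }
  near & !mask
}

#' Generate a synthetic two-cohort study
#'
#' Draws labels, perturbs the phantom parameters per patient (between-patient
#' jitter on habitat means, smoothness and composition; label-positive
#' patients additionally get a tightened smoothness — sharper texture — in
#' the signal habitat), generates each phantom and a second-reader
#' mask, and returns the cases in memory. If `dir` is given, the standard
#' file tree is also written: one directory per patient with `img.nii.gz`,
#' `mask_r1.nii.gz`, `mask_r2.nii.gz`, `truth.nii.gz`, plus a cohort-level
#' `clinical.csv` and a JSON sidecar with the generating specs.
#'
#' @param cspec a [cohort_spec()]
#' @param pspec a [phantom_spec()] template
#' @param dir optional output directory
#' @return list with `cases` (per-patient list: id, cohort, label, volume,
#'   mask, mask_r2, truth, spacing) and `clinical` (data.frame)
#' @export
generate_cohort <- function(cspec, pspec, dir = NULL) {
  n <- cspec$n_train + cspec$n_test
  ids <- sprintf("P%03d", seq_len(n))
  cohort <- rep(c("train", "test"), c(cspec$n_train, cspec$n_test))
  labels <- with_seed(derive_seed(cspec$seed, "labels"),
                      rbinom(n, 1, cspec$label_prevalence))
  cases <- vector("list", n)
  for (p in seq_len(n)) {
    ps <- pspec
    pseed <- derive_seed(cspec$seed, "patient", p)
    bsd <- rep_len(cspec$between_sd, ps$n_habitats)
    jit <- with_seed(derive_seed(pseed, "means"),
                     rnorm(ps$n_habitats, 0, bsd))
    ps$habitat_intensity_means <- ps$habitat_intensity_means + jit
    sj <- with_seed(derive_seed(pseed, "smoothness"),
                    rnorm(ps$n_habitats, 0, cspec$smoothness_lsd %||% 0))
    ps$habitat_smoothness <- ps$habitat_smoothness * exp(sj)
    if ((cspec$fraction_sd %||% 0) > 0) {
      fj <- with_seed(derive_seed(pseed, "fractions"),
                      rnorm(ps$n_habitats, 0, cspec$fraction_sd))
      f <- pmax(ps$habitat_fractions + fj, 0.05)
      ps$habitat_fractions <- f / sum(f)
    }
    if (labels[p] == 1) {
      h <- cspec$signal_habitat
      ps$habitat_smoothness[h] <- ps$habitat_smoothness[h] *
        exp(-cspec$effect_size * (cspec$smoothness_lsd %||% 0.1))
    }
    ps$seed <- derive_seed(pseed, "phantom")
    ph <- generate_phantom(ps)
    mask_r2 <- if (cspec$mask_jitter_mm > 0)
      perturb_mask(ph$mask, cspec$mask_jitter_mm,
                   derive_seed(pseed, "reader2"), ps$voxel_spacing)
    else ph$mask
    cases[[p]] <- list(id = ids[p], cohort = cohort[p], label = labels[p],
                       volume = ph$volume, mask = ph$mask, mask_r2 = mask_r2,
                       truth = ph$truth, spacing = ps$voxel_spacing)
  }
  clinical <- data.frame(patient_id = ids, cohort = cohort, label = labels,
                         stringsAsFactors = FALSE)
  out <- list(cases = cases, clinical = clinical,
              cohort_spec = cspec, phantom_spec = pspec)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", dir)
  for (case in cohort$cases) {
    pdir <- file.path(dir, case$id)
    dir.create(pdir, showWarnings = FALSE)
    write_nifti_array(case$volume$data, case$spacing,
                      file.path(pdir, "img.nii.gz"))
    write_nifti_array(case$mask * 1L, case$spacing,
                      file.path(pdir, "mask_r1.nii.gz"))
    write_nifti_array(case$mask_r2 * 1L, case$spacing,
                      file.path(pdir, "mask_r2.nii.gz"))
    write_nifti_array(case$truth, case$spacing,
                      file.path(pdir, "truth.nii.gz"))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE, quote = FALSE)
  side <- list(cohort_spec = unclass(cohort$cohort_spec),
               phantom_spec = unclass(cohort$phantom_spec))
  jsonlite::write_json(side, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_nifti_array <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("failed to write NIfTI file '%s'", path)
  invisible(path)
}
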