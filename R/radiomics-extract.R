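## Region-level radiomics extraction: original plus filtered images, seven
## feature families, provenance-tagged column names.

#' Radiomics extraction configuration
#'
#' @param bin_width fixed bin width for gray-level discretisation, anchored
#'   at the region minimum (25 on a 0-255 scale gives ~10 levels)
#' @param families feature families to compute
#' @param filters image filters: subset of `"original"`, `"wavelet"`,
#'   `"log"` (`"original"` is always included)
#' @param log_sigmas Laplacian-of-Gaussian scales in mm
#' @param min_region minimum region size in voxels; smaller regions are
#'   skipped (recorded by the cohort extractor)
#' @param habitat_shape compute shape features for habitat sub-regions too
#' @param gldm_alpha gray-level tolerance for the dependence matrix
#' @return an `extraction_config` list
#' @export
extraction_config <- function(bin_width = 25,
                              families = c("firstorder", "shape", "glcm",
                                           "glrlm", "glszm", "ngtdm", "gldm"),
                              filters = c("original", "wavelet", "log"),
                              log_sigmas = c(1, 2, 3),
                              min_region = 10L,
                              habitat_shape = TRUE,
                              gldm_alpha = 0L) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  if (any(log_sigmas <= 0)) stopf("log_sigmas must be > 0")
  families <- match.arg(families, several.ok = TRUE)
  filters <- unique(c("original", match.arg(filters, several.ok = TRUE)))
  structure(list(bin_width = bin_width, families = families,
                 filters = filters, log_sigmas = log_sigmas,
                 min_region = as.integer(min_region),
                 habitat_shape = habitat_shape,
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "extraction_config")
}

## All filter images for one volume, named by provenance prefix.
filter_images <- function(vol, config) {
  imgs <- list(original = vol$data)
  if ("wavelet" %in% config$filters) {
    wl <- wavelet_decompose(vol$data)
    names(wl) <- paste0("wavelet.", names(wl))
    imgs <- c(imgs, wl)
  }
  if ("log" %in% config$filters) {
    for (s in config$log_sigmas)
      imgs[[sprintf("log.sigma.%.1f.mm", s)]] <-
        log_filter(vol$data, s, vol$spacing)
  }
  imgs
}

## Fixed-bin-width discretisation anchored at the region minimum.
discretise <- function(x, bin_width) {
  g <- floor((x - min(x)) / bin_width) + 1L
  list(g = as.integer(g), ng = max(g))
}

#' Extract radiomics features from one region
#'
#' Computes the configured feature families on the original image and every
#' enabled filter image, restricted to the region mask. Shape features are
#' computed once, on the original-geometry mask. Column names carry
#' provenance as `<filter>_<family>_<feature>`.
#'
#' @param vol preprocessed `hab_volume`
#' @param mask logical array (or `hab_volume`) defining the region
#' @param config an [extraction_config()]
#' @param images optional precomputed [filter_images()] result, so multiple
#'   regions of one patient can share the filtered volumes
#' @return named numeric vector of features
#' @export
extract_region <- function(vol, mask, config = extraction_config(),
                           images = NULL) {
  m <- if (inherits(mask, "hab_volume")) mask$data > 0 else mask > 0
  if (!identical(dim(m), dim(vol$data))) stopf("grid mismatch")
  nvox <- sum(m)
  if (nvox == 0) stopf("empty region")
  if (nvox < config$min_region)
    stopf("region has %d voxels, below the minimum of %d",
          nvox, config$min_region)
  if (is.null(images)) images <- filter_images(vol, config)
  dims <- dim(m)
  vv <- prod(vol$spacing)
  out <- numeric(0)
  if ("shape" %in% config$families) {
    sh <- shape_features(m, vol$spacing)
    names(sh) <- paste0("original_shape_", names(sh))
    out <- c(out, sh)
  }
  tex_fams <- setdiff(config$families, "shape")
  garr <- array(0L, dims)
  for (img_name in names(images)) {
    img <- images[[img_name]]
    x <- img[m]
    disc <- discretise(x, config$bin_width)
    garr[] <- 0L
    garr[m] <- disc$g
    ng <- disc$ng
    for (fam in tex_fams) {
      f <- switch(fam,
        firstorder = firstorder_features(x, disc$g, ng, vv),
        glcm = glcm_features(cpp_glcm(garr, dims, ng)),
        glrlm = glrlm_features(cpp_glrlm(garr, dims, ng), nvox),
        glszm = glszm_features(cpp_glszm_zones(garr, dims), ng, nvox),
        ngtdm = {
          nt <- cpp_ngtdm(garr, dims, ng)
          ngtdm_features(nt$s, nt$n)
        },
        gldm = gldm_features(cpp_gldm(garr, dims, ng, config$gldm_alpha)))
      if (is.null(f)) next
      f[!is.finite(f)] <- 0
      names(f) <- paste(img_name, fam, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  out
}

#' Extract feature matrices for a cohort, per region
#'
#' Runs [extract_region()] for the whole tumour and each habitat of every
#' case, returning one patients-by-features matrix per region with identical
#' row order. Habitats smaller than the configured minimum produce an
#' excluded row for that region, recorded in the `excluded` attribute.
#'
#' @param cases list of cases (each with `id`, `volume`, `mask`)
#' @param habitat_maps list of habitat maps aligned with `cases`
#' @param k number of habitats
#' @param config an [extraction_config()]
#' @param masks optional name of an alternative per-case mask field (e.g.
#'   `"mask_r2"` for second-reader extraction)
#' @return named list of matrices: `whole`, `habitat1` ... `habitatk`, each
#'   with a `provenance` attribute (filter/family per column)
#' @export
extract_cohort <- function(cases, habitat_maps, k,
                           config = extraction_config(), masks = "mask") {
  regions <- c("whole", paste0("habitat", seq_len(k)))
  rows <- lapply(regions, function(r) list())
  names(rows) <- regions
  excluded <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    vol <- case$volume
    m <- case[[masks]]
    m <- if (inherits(m, "hab_volume")) m$data > 0 else m > 0
    hmap <- habitat_maps[[ci]]
    imgs <- filter_images(vol, config)
    hconf <- config
    if (!config$habitat_shape)
      hconf$families <- setdiff(config$families, "shape")
    for (r in regions) {
      rmask <- if (r == "whole") m else
        (unclass(hmap) == as.integer(sub("habitat", "", r))) & m
      f <- tryCatch(
        extract_region(vol, rmask,
                       if (r == "whole") config else hconf, images = imgs),
        error = function(e) e)
      if (inherits(f, "error")) {
        excluded[[length(excluded) + 1]] <-
          data.frame(patient_id = case$id, region = r,
                     reason = conditionMessage(f))
      } else {
        rows[[r]][[case$id]] <- f
      }
    }
  }
  out <- lapply(regions, function(r) {
    lst <- rows[[r]]
    if (!length(lst)) return(NULL)
    mat <- do.call(rbind, lst)
    rownames(mat) <- names(lst)
    prov <- do.call(rbind, strsplit(colnames(mat), "_", fixed = TRUE))
    attr(mat, "provenance") <- data.frame(
      column = colnames(mat), filter = prov[, 1], family = prov[, 2],
      feature = prov[, 3], region = r, stringsAsFactors = FALSE)
    mat
  })
  names(out) <- regions
  attr(out, "excluded") <- if (length(excluded))
    do.call(rbind, excluded) else NULL
  out
}
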