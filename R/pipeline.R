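## End-to-end orchestration: synthetic generation (or loading), geometry and
## grayscale standardisation, voxel maps, consensus k-selection, habitat
## segmentation, per-region extraction, selection, SVM training and
## evaluation, with a machine-readable run report.

#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages. Every value is echoed into the
#' run report so a run is fully auditable from its artifacts.
#'
#' @param seed master seed; every stage derives its own stream from it
#' @return a `run_config` list
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    input = list(dir = NULL, synthetic = list(cohort = cohort_spec(),
                                              phantom = phantom_spec())),
    preprocess = list(target_spacing = c(1, 1, 3),
                      normalize_range = c(0, 255)),
    entropy = list(window_radius = 2L, n_bins = 32L, epsilon = 1e-12),
    habitat = list(k_range = 2:10, reps = 1000L, item_fraction = 0.8,
                   delta_area_threshold = 0.05, max_items = 5000L,
                   max_voxels_per_patient = 2000L, k_star = NULL),
    radiomics = list(bin_width = 25,
                     families = c("firstorder", "shape", "glcm", "glrlm",
                                  "glszm", "ngtdm", "gldm"),
                     filters = c("original", "wavelet", "log"),
                     log_sigmas = c(1, 2, 3), min_region = 10L),
    selection = list(use_icc = TRUE, icc_n = 15L, icc_threshold = 0.75,
                     pearson_threshold = 0.9, n_folds = 5L),
    model = list(cost_grid = c(0.1, 1, 10, 100),
                 gamma_scale = c(0.1, 1, 10), n_folds = 5L),
    outdir = NULL), class = "run_config")
}

#' Configuration of the planted-signal simulation study
#'
#' The package's standard experiment for the habitat-versus-whole-tumour
#' contrast: a two-cohort phantom study with the label signal planted in
#' the intermediate habitat (a standardised shift of its mean intensity and
#' texture for label-positive patients), segmented at the established three
#' habitats,
#' extracted with the unfiltered feature set so a replicate stays fast.
#'
#' @param n_train,n_test cohort sizes
#' @param effect_size standardised shift applied to the signal habitat
#' @param signal_habitat habitat carrying the signal (3 = rim, default)
#' @param seed master seed
#' @return a pipeline config (see [default_config()])
#' @export
signal_study_config <- function(n_train = 120, n_test = 60, effect_size = 2,
                                signal_habitat = 2, seed = 1L) {
  cfg <- default_config(seed)
  cfg$input$synthetic$cohort <- cohort_spec(
    n_train = n_train, n_test = n_test, effect_size = effect_size,
    signal_habitat = signal_habitat, seed = seed)
  cfg$input$synthetic$phantom <- phantom_spec(
    habitat_fractions = c(0.2, 0.2, 0.6))
  cfg$habitat$k_star <- 3L          # established number of habitats
  cfg$radiomics$families <- c("firstorder", "glcm", "glrlm", "gldm")
  cfg$radiomics$filters <- "original"
  cfg$selection$icc_n <- 10L
  cfg
}

required_config_keys <- list(
  c("seed"), c("input"), c("preprocess", "target_spacing"),
  c("entropy", "n_bins"), c("habitat", "k_range"), c("habitat", "reps"),
  c("habitat", "item_fraction"), c("radiomics", "bin_width"),
  c("selection", "pearson_threshold"), c("model", "n_folds"))

#' Validate a pipeline configuration
#'
#' Checks that every required key is present before any computation; the
#' error names the missing key in `section.key` form.
#'
#' @param config a config list (see [default_config()])
#' @return the config, invisibly
#' @export
validate_config <- function(config) {
  for (path in required_config_keys) {
    node <- config
    for (key in path) {
      if (!is.list(node) || is.null(node[[key]]))
        stopf("config is missing required key '%s'",
              paste(path, collapse = "."))
      node <- node[[key]]
    }
  }
  if (is.null(config$input$dir) && is.null(config$input$synthetic))
    stopf("config is missing required key 'input.dir' or 'input.synthetic'")
  invisible(config)
}

## Load a generated cohort from its on-disk layout.
load_cohort_dir <- function(dir) {
  csv <- file.path(dir, "clinical.csv")
  if (!file.exists(csv)) stopf("missing clinical table '%s'", csv)
  clinical <- read.csv(csv, stringsAsFactors = FALSE)
  for (col in c("patient_id", "cohort", "label"))
    if (is.null(clinical[[col]]))
      stopf("clinical table lacks column '%s'", col)
  cases <- lapply(seq_len(nrow(clinical)), function(i) {
    pdir <- file.path(dir, clinical$patient_id[i])
    pair <- load_case(file.path(pdir, "img.nii.gz"),
                      file.path(pdir, "mask_r1.nii.gz"))
    r2p <- file.path(pdir, "mask_r2.nii.gz")
    mask_r2 <- if (file.exists(r2p))
      load_case(file.path(pdir, "img.nii.gz"), r2p)$mask$data > 0
    else pair$mask$data > 0
    list(id = clinical$patient_id[i], cohort = clinical$cohort[i],
         label = clinical$label[i], volume = pair$volume,
         mask = pair$mask$data > 0, mask_r2 = mask_r2,
         spacing = pair$volume$spacing)
  })
  list(cases = cases, clinical = clinical)
}

#' Run the full habitat-radiomics pipeline
#'
#' Executes generation (optional), preprocessing, voxel maps, consensus
#' k-selection on the pooled training voxels, per-patient segmentation,
#' per-region extraction, feature selection and SVM training/evaluation, and
#' returns a run report. Any stage failure aborts with a stage-named error.
#'
#' @param config a config list; see [default_config()]
#' @return a `run_report` list: `k_star`, per-region feature funnel and
#'   evaluation (train/test AUC + CI, threshold metrics, DeLong p versus the
#'   whole-tumour reference), seeds and the echoed config
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- stage("input", {
    if (!is.null(config$input$dir)) load_cohort_dir(config$input$dir)
    else {
      cs <- config$input$synthetic$cohort
      ps <- config$input$synthetic$phantom
      cs$seed <- derive_seed(seed, "cohort")
      generate_cohort(cs, ps)
    }
  })
  cases <- cohort$cases
  is_train <- vapply(cases, function(c) c$cohort == "train", logical(1))
  labels <- vapply(cases, function(c) as.integer(c$label), integer(1))
  ids <- vapply(cases, function(c) c$id, character(1))

  econf <- entropy_config(config$entropy$window_radius,
                          config$entropy$n_bins, config$entropy$epsilon)
  tables <- stage("preprocess+voxel_maps", lapply(cases, function(case) {
    mask_vol <- volume((case$mask > 0) * 1, case$spacing)
    rs <- resample_case(case$volume, mask_vol,
                        config$preprocess$target_spacing)
    nv <- normalize_grayscale(rs$volume, rs$mask,
                              config$preprocess$normalize_range)
    ent <- entropy_map(nv, rs$mask, econf)
    m2 <- if (identical(dim(case$mask_r2), dim(rs$mask$data)))
      case$mask_r2 > 0
    else resample_array((case$mask_r2 > 0) * 1, case$spacing,
                        config$preprocess$target_spacing, "nearest",
                        target_dim = dim(rs$mask$data)) > 0
    list(volume = nv, mask = rs$mask$data > 0, mask_r2 = m2,
         table = build_voxel_table(nv, ent, rs$mask, case$id))
  }))

  transform <- stage("zscore", fit_voxel_zscore(
    lapply(tables[is_train], function(t) t$table)))

  consensus <- NULL
  k_star <- config$habitat$k_star
  if (is.null(k_star)) {
    consensus <- stage("consensus_k", {
      cap <- config$habitat$max_voxels_per_patient
      pooled <- do.call(rbind, lapply(which(is_train), function(i) {
        tz <- apply_voxel_zscore(tables[[i]]$table, transform)
        z <- as.matrix(tz[, c("z_intensity", "z_entropy")])
        if (nrow(z) > cap)
          z <- z[with_seed(derive_seed(seed, "pool", i),
                           sample.int(nrow(z), cap)), , drop = FALSE]
        z
      }))
      consensus_select_k(pooled, k_range = config$habitat$k_range,
                         reps = config$habitat$reps,
                         item_fraction = config$habitat$item_fraction,
                         seed = derive_seed(seed, "consensus"),
                         max_items = config$habitat$max_items,
                         delta_area_threshold =
                           config$habitat$delta_area_threshold)
    })
    k_star <- consensus$k_star
  }

  maps <- stage("segmentation", lapply(seq_along(cases), function(i) {
    segment_patient(tables[[i]]$table, k_star, transform,
                    seed = derive_seed(seed, "segment", i),
                    dims = dim(tables[[i]]$volume$data))
  }))

  exconf <- extraction_config(
    bin_width = config$radiomics$bin_width,
    families = config$radiomics$families,
    filters = config$radiomics$filters,
    log_sigmas = config$radiomics$log_sigmas,
    min_region = config$radiomics$min_region)
  pcases <- lapply(seq_along(cases), function(i) {
    list(id = ids[i], volume = tables[[i]]$volume, mask = tables[[i]]$mask,
         mask_r2 = tables[[i]]$mask_r2)
  })
  matrices <- stage("extraction",
                    extract_cohort(pcases, maps, k_star, exconf))

  icc_by_region <- NULL
  if (isTRUE(config$selection$use_icc)) {
    icc_by_region <- stage("icc", {
      idx <- head(which(is_train), config$selection$icc_n)
      ## second-reader masks are only meaningful on the original grid; the
      ## synthetic generator keeps a shared grid, so reuse it directly
      m2 <- extract_cohort(pcases[idx], maps[idx], k_star, exconf,
                           masks = "mask_r2")
      lapply(names(matrices), function(r) {
        m1r <- matrices[[r]]
        if (is.null(m1r) || is.null(m2[[r]])) return(NULL)
        shared <- intersect(rownames(m1r), rownames(m2[[r]]))
        if (length(shared) < 3) return(NULL)
        icc_per_feature(m1r[shared, , drop = FALSE],
                        m2[[r]][shared, colnames(m1r), drop = FALSE])
      }) |> setNames(names(matrices))
    })
  }

  results <- list()
  whole_scores <- list(train = NULL, test = NULL)
  regions <- names(matrices)
  for (r in c("whole", setdiff(regions, "whole"))) {
    mat <- matrices[[r]]
    if (is.null(mat)) next
    tr_ids <- intersect(rownames(mat), ids[is_train])
    te_ids <- intersect(rownames(mat), ids[!is_train])
    y_tr <- labels[match(tr_ids, ids)]
    y_te <- labels[match(te_ids, ids)]
    res <- stage(paste0("select+train:", r), {
      sel <- select_features(mat[tr_ids, , drop = FALSE],
                             mat[te_ids, , drop = FALSE], y_tr,
                             icc = icc_by_region[[r]],
                             icc_threshold = config$selection$icc_threshold,
                             pearson_threshold =
                               config$selection$pearson_threshold,
                             n_folds = config$selection$n_folds,
                             seed = derive_seed(seed, "select", r))
      feats <- sel$stages$lasso
      if (!length(feats)) feats <- sel$stages$pearson
      bundle <- train_svm(sel$train_z[, feats, drop = FALSE], y_tr,
                          seed = derive_seed(seed, "svm"),
                          cost_grid = config$model$cost_grid,
                          gamma_scale = config$model$gamma_scale,
                          n_folds = config$model$n_folds)
      ev_tr <- evaluate_model(bundle, sel$train_z[, feats, drop = FALSE],
                              y_tr, whole_scores$train)
      ev_te <- evaluate_model(bundle, sel$test_z[, feats, drop = FALSE],
                              y_te, whole_scores$test)
      list(selection = sel, bundle = bundle, train = ev_tr, test = ev_te,
           features = feats, y_train = y_tr, y_test = y_te)
    })
    if (r == "whole")
      whole_scores <- list(train = res$train$scores, test = res$test$scores)
    results[[r]] <- res
  }

  report <- list(
    k_star = k_star,
    consensus = if (!is.null(consensus))
      consensus[c("k_range", "areas", "delta_area", "k_star")],
    feature_funnel = lapply(results, function(r)
      vapply(r$selection$stages, length, integer(1))),
    models = lapply(results, function(r) list(
      features = r$features,
      cost = r$bundle$cost, gamma = r$bundle$gamma,
      threshold = r$bundle$threshold,
      train = c(list(auc = r$train$auc, auc_ci = r$train$auc_ci,
                     delong_p_vs_whole = r$train$delong_p),
                r$train$metrics),
      test = c(list(auc = r$test$auc, auc_ci = r$test$auc_ci,
                    delong_p_vs_whole = r$test$delong_p),
               r$test$metrics))),
    excluded = attr(matrices, "excluded"),
    n_train = sum(is_train), n_test = sum(!is_train),
    seed = seed, config = config)
  class(report) <- "run_report"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report_to_json(report),
      file.path(config$outdir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    if (!is.null(consensus))
      jsonlite::write_json(
        consensus[c("k_range", "areas", "delta_area", "pac", "k_star")],
        file.path(config$outdir, "consensus.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (i in seq_along(maps)) {
      pdir <- file.path(config$outdir, ids[i])
      dir.create(pdir, showWarnings = FALSE)
      write_nifti_array(unclass(maps[[i]]),
                        config$preprocess$target_spacing,
                        file.path(pdir, "habitats.nii.gz"))
    }
  }
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$config <- rapply(unclass(r$config), function(x) x, how = "replace")
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> k* = %d, %d train / %d test patients\n",
              x$k_star, x$n_train, x$n_test))
  for (r in names(x$models)) {
    m <- x$models[[r]]
    cat(sprintf("  %-9s train AUC %.3f | test AUC %.3f | features %d\n",
                r, m$train$auc, m$test$auc, length(m$features)))
  }
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' Reads a flat YAML file and merges it over [default_config()]; unknown
#' keys are kept so the report echoes exactly what was supplied.
#'
#' @param path YAML file path
#' @param seed optional master-seed override
#' @return a validated config
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  user <- yaml::read_yaml(path)
  config <- modify_list_deep(default_config(), user)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(user$input$synthetic)) {
    config$input$synthetic$cohort <-
      do.call(cohort_spec, user$input$synthetic$cohort %||% list())
    config$input$synthetic$phantom <-
      do.call(phantom_spec, user$input$synthetic$phantom %||% list())
  }
  validate_config(config)
  config
}

modify_list_deep <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      modify_list_deep(base[[k]], user[[k]]) else user[[k]]
  }
  base
}
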