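## Feature reduction: inter-reader reproducibility (ICC), z-scoring,
## Pearson redundancy pruning, and LASSO sparse selection. The stages only
## ever remove features, so the surviving sets are nested.

#' Per-feature intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the classical mean-squares decomposition, computed for each shared column
#' of two reader matrices. Features with zero between-subject variance have
#' no defined ICC and are returned as `NA` (callers treat `NA` as failing
#' any threshold).
#'
#' @param m1,m2 patients x features matrices from two readers (same patients
#'   and columns, >= 3 patients)
#' @return named numeric vector of ICC values (<= 1, possibly negative)
#' @export
icc_per_feature <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2)) ||
      !identical(colnames(m1), colnames(m2)) ||
      !identical(rownames(m1), rownames(m2)))
    stopf("reader matrices must share patients and columns")
  n <- nrow(m1)
  if (n < 3) stopf("need >= 3 patients for ICC")
  k <- 2
  vapply(seq_len(ncol(m1)), function(ci) {
    y <- cbind(m1[, ci], m2[, ci])
    row_m <- rowMeans(y)
    col_m <- colMeans(y)
    gm <- mean(y)
    SSR <- k * sum((row_m - gm)^2)           # between subjects
    SSC <- n * sum((col_m - gm)^2)           # between raters
    SSE <- sum((y - outer(row_m, rep(1, k)) -
                  outer(rep(1, n), col_m) + gm)^2)
    MSR <- SSR / (n - 1)
    MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    denom <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
    if (abs(MSR) < 1e-300 || denom == 0) return(NA_real_)
    (MSR - MSE) / denom
  }, numeric(1)) |> setNames(colnames(m1))
}

#' Fit-and-apply column z-scoring
#'
#' Standardises the training matrix to per-column mean 0, SD 1 (sample SD,
#' `n - 1` denominator) and transforms the optional test matrix with the
#' training parameters.
#'
#' @param train patients x features matrix (>= 2 rows)
#' @param test optional matrix with the same columns
#' @return list with `train`, `test` (or `NULL`) and `params` (mean, sd)
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  if (nrow(train) < 2) stopf("need >= 2 training rows")
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  zero <- colnames(train)[sdev == 0]
  if (length(zero))
    stopf("zero-variance feature(s): %s",
          paste(head(zero, 5), collapse = ", "))
  tr <- sweep(sweep(train, 2, mu), 2, sdev, "/")
  te <- if (!is.null(test)) {
    if (!identical(colnames(test), colnames(train)))
      stopf("test columns differ from training columns")
    sweep(sweep(test, 2, mu), 2, sdev, "/")
  } else NULL
  list(train = tr, test = te, params = list(mean = mu, sd = sdev))
}

#' Greedy Pearson redundancy pruning
#'
#' Walks the columns in order of descending raw-feature variance (ties
#' broken by column name) and drops any column whose absolute Pearson
#' correlation with an already-kept column exceeds the threshold, so exactly
#' one representative of each correlated group survives.
#'
#' @param zm z-scored matrix
#' @param threshold absolute correlation cutoff (default 0.9)
#' @param raw_variance optional named per-column variances of the raw
#'   features used for ordering; defaults to the variance of `zm`'s columns
#' @return character vector of surviving column names (deterministic order)
#' @export
pearson_prune <- function(zm, threshold = 0.9, raw_variance = NULL) {
  cols <- colnames(zm)
  v <- raw_variance %||% apply(zm, 2, var)
  ord <- cols[order(-v[cols], cols)]
  cm <- suppressWarnings(cor(zm))
  cm[!is.finite(cm)] <- 0
  kept <- character(0)
  for (cn in ord) {
    if (!length(kept) || all(abs(cm[cn, kept]) <= threshold))
      kept <- c(kept, cn)
  }
  kept
}

#' LASSO feature selection
#'
#' L1-penalised logistic regression over `glmnet`'s log-spaced lambda grid;
#' lambda* minimises the mean cross-validated binomial deviance over seeded
#' stratified folds, and the support is the set of features with non-zero
#' coefficients at lambda*.
#'
#' @param x z-scored training matrix
#' @param y binary labels (0/1)
#' @param n_folds cross-validation folds
#' @param seed integer seed (drives fold assignment)
#' @return list with `support`, `coefficients` (non-zero, named),
#'   `lambda`, `foldid` and the fitted `cv.glmnet` object
#' @export
lasso_select <- function(x, y, n_folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("labels are degenerate (one class)")
  if (min(table(y)) < 2) stopf("need >= 2 patients per class")
  foldid <- stratified_folds(y, n_folds, seed)
  ## glmnet warns whenever a CV fold holds < 8 of a class, which is routine
  ## at pilot cohort sizes; the fit itself is unaffected
  cv <- with_seed(derive_seed(seed, "lasso"), withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  co <- coef(cv, s = "lambda.min")
  co <- setNames(as.numeric(co), rownames(co))
  nz <- co[co != 0 & names(co) != "(Intercept)"]
  list(support = names(nz), coefficients = nz,
       lambda = cv$lambda.min, foldid = foldid, fit = cv)
}

#' Seeded stratified fold assignment
#'
#' @param y binary labels
#' @param k number of folds
#' @param seed integer seed
#' @return integer fold id per observation
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  foldid <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Run the full selection funnel for one region
#'
#' ICC screen (features with ICC < `icc_threshold` or undefined ICC are
#' removed), z-scoring fitted on the training cohort, greedy Pearson
#' pruning, then LASSO. Returns the per-stage survivor sets (always nested)
#' plus everything needed to replay the selection.
#'
#' @param train,test raw feature matrices (test may be `NULL`)
#' @param y training labels
#' @param icc named ICC vector from [icc_per_feature()], or `NULL` to skip
#'   the reproducibility screen
#' @param icc_threshold minimum ICC to retain a feature
#' @param pearson_threshold redundancy cutoff
#' @param n_folds,seed LASSO cross-validation controls
#' @return a `selection_report` list with `stages` (named survivor lists),
#'   z-score `params`, LASSO details, and the reduced `train_z`/`test_z`
#' @export
select_features <- function(train, test = NULL, y, icc = NULL,
                            icc_threshold = 0.75, pearson_threshold = 0.9,
                            n_folds = 5L, seed = 1L) {
  all_cols <- colnames(train)
  keep_icc <- if (is.null(icc)) all_cols else
    all_cols[!is.na(icc[all_cols]) & icc[all_cols] >= icc_threshold]
  ## constant columns can neither be z-scored nor carry signal
  keep_icc <- keep_icc[apply(train[, keep_icc, drop = FALSE], 2, sd) > 0]
  if (!length(keep_icc)) stopf("no features survive the ICC screen")
  z <- zscore_fit_apply(train[, keep_icc, drop = FALSE],
                        if (!is.null(test)) test[, keep_icc, drop = FALSE])
  raw_var <- apply(train[, keep_icc, drop = FALSE], 2, var)
  keep_pear <- pearson_prune(z$train, pearson_threshold, raw_var)
  las <- lasso_select(z$train[, keep_pear, drop = FALSE], y,
                      n_folds = n_folds, seed = seed)
  structure(list(
    stages = list(all = all_cols, icc = keep_icc, pearson = keep_pear,
                  lasso = las$support),
    icc = icc, zscore = z$params, lasso = las,
    train_z = z$train[, keep_pear, drop = FALSE],
    test_z = if (!is.null(z$test)) z$test[, keep_pear, drop = FALSE],
    seed = seed), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  s <- x$stages
  cat(sprintf(
    "<selection_report> %d features -> ICC %d -> Pearson %d -> LASSO %d\n",
    length(s$all), length(s$icc), length(s$pearson), length(s$lasso)))
  invisible(x)
}
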