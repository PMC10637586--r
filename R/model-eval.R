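## SVM modelling and evaluation: RBF support-vector classifier with seeded
## stratified cross-validated hyperparameter search, DeLong AUC machinery,
## threshold metrics, calibration and decision-curve analysis.

#' Train an RBF-kernel SVM with cross-validated hyperparameters
#'
#' Grid-searches (C, gamma) by mean AUC over seeded stratified five-fold
#' cross-validation, refits the winner on the full training set with Platt
#' probability scaling, and fixes the operating threshold at the Youden
#' optimum of the training ROC. The gamma grid is the `1/p` scale heuristic
#' times \{0.1, 1, 10\}.
#'
#' @param x training feature matrix (z-scored)
#' @param y binary labels (0/1)
#' @param seed integer seed (folds and the SVM's internal RNG)
#' @param cost_grid candidate C values
#' @param gamma_scale multipliers of the scale heuristic
#' @param n_folds cross-validation folds
#' @return a `model_bundle`: fitted svm, `cost`, `gamma`, `threshold`,
#'   `cv_auc` grid, fold assignments and seed
#' @export
train_svm <- function(x, y, seed = 1L,
                      cost_grid = c(0.1, 1, 10, 100),
                      gamma_scale = c(0.1, 1, 10), n_folds = 5L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("labels are degenerate (one class)")
  if (min(table(y)) < 2) stopf("need >= 2 patients per class")
  yf <- factor(y, levels = c(0, 1))
  foldid <- stratified_folds(y, n_folds, seed)
  gamma_grid <- gamma_scale / ncol(x)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$cv_auc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    score <- rep(NA_real_, length(y))
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) next
      ## decision values rank identically to Platt probabilities, so the
      ## grid search skips the per-fit probability calibration
      fit <- with_seed(derive_seed(seed, "svm-cv", gi, f),
        e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                   cost = grid$cost[gi], gamma = grid$gamma[gi],
                   scale = FALSE))
      score[!tr] <- svm_decision(fit, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(score)
    grid$cv_auc[gi] <- if (length(unique(y[ok])) == 2)
      auc_mw(score[ok], y[ok]) else NA_real_
  }
  best <- which.max(grid$cv_auc)
  fit <- with_seed(derive_seed(seed, "svm-final"),
    e1071::svm(x, yf, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], probability = TRUE, scale = FALSE))
  train_prob <- svm_prob(fit, x)
  threshold <- youden_threshold(train_prob, y)
  structure(list(fit = fit, cost = grid$cost[best], gamma = grid$gamma[best],
                 threshold = threshold, cv_grid = grid,
                 cv_auc = grid$cv_auc[best], foldid = foldid,
                 train_prob = train_prob, seed = seed,
                 n_support = nrow(fit$SV)),
            class = "model_bundle")
}

## Positive-class probability from an e1071 probability-SVM.
svm_prob <- function(fit, x) {
  pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
  unname(pr[, "1"])
}

## Decision value oriented so larger means more likely class "1".
svm_decision <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  v <- dv[, 1]
  ## the column name "a/b" marks class a as the positive decision side
  if (strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1] == "0") v <- -v
  unname(v)
}

#' Predict label-positive probabilities from a model bundle
#' @param bundle a `model_bundle`
#' @param x feature matrix with the training columns
#' @return numeric probabilities in `[0, 1]`
#' @export
predict_bundle <- function(bundle, x) svm_prob(bundle$fit, as.matrix(x))

## Mann-Whitney AUC (midrank ties).
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Youden-optimal threshold on the score scale: the candidate cut (midpoint
## between adjacent distinct scores) maximising sensitivity + specificity.
youden_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(cand, min(s) - 1e-9, max(s) + 1e-9)
  j <- vapply(cand, function(t) {
    m <- threshold_metrics(scores, labels, t)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  t <- cand[which.max(j)]
  min(max(t, 1e-9), 1 - 1e-9)
}

#' AUC with DeLong 95% confidence interval
#'
#' Mann-Whitney AUC estimate with the DeLong structural-components variance;
#' the interval `AUC +/- 1.96 SE` is clipped to `[0, 1]`.
#'
#' @param scores predicted scores/probabilities
#' @param labels binary labels (0/1), both classes present
#' @return list with `auc`, `ci` (length 2), `se`
#' @export
auc_ci_delong <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes required")
  r <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                 quiet = TRUE)
  ## a perfectly separating score has DeLong variance exactly 0; pROC warns
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(max(v, 0))
  a <- as.numeric(pROC::auc(r))
  list(auc = a,
       ci = c(max(a - 1.96 * se, 0), min(a + 1.96 * se, 1)),
       se = se)
}

#' Paired DeLong test of two correlated AUCs
#'
#' Two-sided p-value for the AUC difference of two models scored on the same
#' patients. Identical score vectors (or a zero-variance difference) return
#' p = 1 by convention.
#'
#' @param scores_a,scores_b model scores on the same patients
#' @param labels binary labels
#' @return two-sided p-value
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes required")
  if (isTRUE(all.equal(scores_a, scores_b, tolerance = 0))) return(1)
  ra <- pROC::roc(labels, scores_a, direction = "<", levels = c(0, 1),
                  quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, direction = "<", levels = c(0, 1),
                  quiet = TRUE)
  p <- tryCatch(
    suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                    paired = TRUE)$p.value),
    error = function(e) NA_real_)
  if (!is.finite(p)) 1 else p
}

#' Confusion-matrix metrics at a threshold
#'
#' @param scores predicted probabilities
#' @param labels binary labels
#' @param threshold decision cut: predicted positive when score >= threshold
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   and the 2x2 `confusion` matrix
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(predicted = c("pos", "neg"),
                                 actual = c("pos", "neg")))
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       confusion = conf)
}

#' Reliability (calibration) curve with recalibration slope
#'
#' Equal-width binning of the predicted probability against the observed
#' event frequency, plus the slope/intercept of a logistic recalibration of
#' the outcome on the logit of the prediction.
#'
#' @param scores predicted probabilities in `[0, 1]`
#' @param labels binary labels
#' @param n_bins number of equal-width probability bins
#' @return list with `curve` (data.frame: bin midpoint, mean predicted,
#'   observed frequency, count) and `slope`, `intercept`
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  labels <- as.integer(labels)
  bin <- pmin(pmax(floor(scores * n_bins) + 1L, 1L), n_bins)
  curve <- data.frame(
    bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
    mean_predicted = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(scores[bin == b]) else NA_real_, numeric(1)),
    observed = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(labels[bin == b]) else NA_real_, numeric(1)),
    n = tabulate(bin, n_bins))
  eps <- 1e-8
  lp <- qlogis(pmin(pmax(scores, eps), 1 - eps))
  fit <- tryCatch(glm(labels ~ lp, family = binomial()),
                  error = function(e) NULL)
  list(curve = curve,
       slope = if (!is.null(fit)) unname(coef(fit)[2]) else NA_real_,
       intercept = if (!is.null(fit)) unname(coef(fit)[1]) else NA_real_)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP/n - FP/n * t/(1-t)` of treating patients whose
#' predicted probability exceeds each threshold t, alongside the treat-all
#' and treat-none references.
#'
#' @param scores predicted probabilities
#' @param labels binary labels
#' @param thresholds threshold grid, strictly inside (0, 1)
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie strictly inside (0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Evaluate a fitted model on one cohort
#'
#' @param bundle a `model_bundle`
#' @param x feature matrix
#' @param y binary labels
#' @param reference_scores optional scores of a reference model on the same
#'   patients, for a paired DeLong comparison
#' @return an `eval_report` list: `auc` (+CI), threshold metrics, DeLong p
#'   versus the reference, calibration and decision-curve tables, and scores
#' @export
evaluate_model <- function(bundle, x, y, reference_scores = NULL) {
  scores <- predict_bundle(bundle, x)
  a <- auc_ci_delong(scores, y)
  m <- threshold_metrics(scores, y, bundle$threshold)
  structure(list(
    auc = a$auc, auc_ci = a$ci, auc_se = a$se,
    metrics = m[c("accuracy", "sensitivity", "specificity", "ppv", "npv")],
    confusion = m$confusion,
    delong_p = if (!is.null(reference_scores))
      delong_paired_test(scores, reference_scores, y) else NA_real_,
    calibration = calibration_curve(scores, y),
    decision = decision_curve(scores, y),
    threshold = bundle$threshold,
    scores = scores), class = "eval_report")
}
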