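## Exhaustive concordant-pair oracle for the AUC.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(auc_ci_delong(c(0.2, 0.8, 0.1, 0.4),
                             c(0, 1, 0, 1))$auc,
               auc_oracle(c(0.2, 0.8, 0.1, 0.4), c(0, 1, 0, 1)))
  ## worked example: neg {0.1, 0.4}, pos {0.2, 0.8} -> AUC 0.75
  expect_equal(auc_ci_delong(c(0.1, 0.4, 0.2, 0.8),
                             c(0, 0, 1, 1))$auc, 0.75)
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)          # ties included
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_ci_delong(sc, lb)$auc, auc_oracle(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("DeLong machinery hits its degenerate and symmetric limits", {
  sc <- c(0.1, 0.2, 0.8, 0.9)
  lb <- c(0, 0, 1, 1)
  a <- auc_ci_delong(sc, lb)
  expect_equal(a$auc, 1)
  expect_equal(a$se, 0)
  expect_equal(a$ci, c(1, 1))
  ## label swap mirrors the AUC
  set.seed(8)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(auc_ci_delong(sc, lb)$auc,
               1 - auc_ci_delong(sc, 1 - lb)$auc, tolerance = 1e-12)
  expect_error(auc_ci_delong(sc, rep(1, 40)), "both classes")
  ## CI always contains the point estimate
  a2 <- auc_ci_delong(sc, lb)
  expect_true(a2$ci[1] <= a2$auc && a2$auc <= a2$ci[2])
})

test_that("paired DeLong test separates perfect from random scores", {
  expect_equal(delong_paired_test(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                  c(0, 0, 1, 1)), 1)
  set.seed(15)
  n <- 200
  lb <- rbinom(n, 1, 0.5)
  perfect <- lb + rnorm(n, 0, 0.01)
  random <- runif(n)
  expect_lt(delong_paired_test(perfect, random, lb), 0.001)
  ## cross-check against a seeded bootstrap difference test: same sign and
  ## comparable magnitude of evidence
  near <- lb + rnorm(n, 0, 2)
  p_delong <- delong_paired_test(perfect, near, lb)
  boot <- replicate(200, {
    idx <- sample(n, replace = TRUE)
    if (length(unique(lb[idx])) < 2) return(NA)
    auc_mw <- function(s, l) {
      r <- rank(s); n1 <- sum(l); n0 <- sum(1 - l)
      (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    auc_mw(perfect[idx], lb[idx]) - auc_mw(near[idx], lb[idx])
  })
  p_boot <- 2 * min(mean(boot > 0, na.rm = TRUE),
                    mean(boot < 0, na.rm = TRUE))
  expect_equal(p_delong < 0.05, p_boot < 0.05)
})

test_that("threshold metrics agree with brute-force confusion counts", {
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.6, 0.2, 0.1, 0.4, 0.55, 0.45)
  lb <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0)
  m <- threshold_metrics(sc, lb, 0.5)
  ## TP=4 FN=1 FP=1 TN=4
  expect_equal(unname(m$confusion["pos", "pos"]), 4)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$ppv, 0.8)
  ## everyone predicted positive
  m2 <- threshold_metrics(sc, lb, 0)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  ## spot instance from printed counts: TP=3 FP=1 FN=1 TN=5
  sc3 <- c(rep(0.9, 3), rep(0.1, 1), rep(0.9, 1), rep(0.1, 5))
  lb3 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m3 <- threshold_metrics(sc3, lb3, 0.5)
  expect_equal(m3$accuracy, 0.8)
  expect_equal(m3$ppv, 0.75)
  set.seed(4)
  sc4 <- runif(30); lb4 <- rbinom(30, 1, 0.4); th <- 0.37
  m4 <- threshold_metrics(sc4, lb4, th)
  expect_equal(sum(m4$confusion), 30)
  expect_equal(unname(m4$confusion["pos", "pos"]),
               sum(sc4 >= th & lb4 == 1))
})

test_that("calibration curve recovers a well-calibrated simulator", {
  set.seed(99)
  p <- runif(2000)
  y <- rbinom(2000, 1, p)
  cal <- calibration_curve(p, y)
  expect_lt(abs(cal$slope - 1), 0.15)
  occupied <- !is.na(cal$curve$observed)
  expect_true(all(abs(cal$curve$observed[occupied] -
                        cal$curve$mean_predicted[occupied]) < 0.12))
  ## constant score at the prevalence: one occupied bin near (0.5, 0.5)
  y2 <- rbinom(400, 1, 0.5)
  cal2 <- calibration_curve(rep(0.5, 400), y2)
  expect_equal(sum(cal2$curve$n > 0), 1)
  expect_lt(abs(cal2$curve$observed[cal2$curve$n > 0] - 0.5), 0.15)
  ## perfectly separated 0/1 scores: endpoints (0,0) and (1,1)
  cal3 <- calibration_curve(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(cal3$curve$observed[1], 0)
  expect_equal(cal3$curve$observed[10], 1)
})

test_that("decision curve has its closed-form references and null bound", {
  lb <- rep(c(0, 1), 50)
  dc <- decision_curve(lb, lb, thresholds = c(0.01, 0.25, 0.5, 0.75))
  ## treat-all at t -> 0 equals prevalence; perfect model stays there
  expect_equal(dc$treat_all[1], 0.5 - 0.5 * 0.01 / 0.99)
  expect_equal(dc$net_benefit, rep(0.5, 4))
  expect_true(all(dc$treat_none == 0))
  expect_error(decision_curve(lb, lb, thresholds = c(0, 0.5)), "strictly")
  ## random scores never materially beat the best naive strategy
  set.seed(6)
  sc <- runif(500); lb <- rbinom(500, 1, 0.4)
  dc2 <- decision_curve(sc, lb)
  ref <- pmax(dc2$treat_all, 0)
  expect_true(all(dc2$net_benefit <= ref + 0.02))
})

test_that("SVM training is seeded, separable-exact and null-calibrated", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, -2, 0.3), ncol = 2),
             matrix(rnorm(60, 2, 0.3), ncol = 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = 30)
  b <- train_svm(x, y, seed = 3)
  expect_equal(auc_ci_delong(predict_bundle(b, x), y)$auc, 1)
  expect_true(b$threshold > 0 && b$threshold < 1)
  b2 <- train_svm(x, y, seed = 3)
  expect_identical(predict_bundle(b, x), predict_bundle(b2, x))
  expect_identical(b$cost, b2$cost)
  expect_error(train_svm(x, rep(0, 60)), "degenerate")
})
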