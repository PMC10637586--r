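test_that("Yates-corrected 2x2 chi-square reproduces the published table", {
  counts <- lvsi_clinical_counts()
  expect_equal(round(chisq_2x2(t(counts$train$categorical$ca125))$p, 3),
               0.046)
  expect_equal(round(chisq_2x2(t(counts$test$categorical$ca125))$p, 3),
               0.481)
  expect_equal(round(chisq_2x2(t(counts$train$categorical$hpv))$p, 3),
               0.275)
  expect_equal(round(chisq_2x2(t(counts$train$categorical$ca199))$p, 3),
               0.878)
  expect_equal(round(chisq_2x2(t(counts$train$categorical$scc))$p, 3),
               0.622)
})

test_that("r x c chi-square reproduces the published multi-level rows", {
  counts <- lvsi_clinical_counts()
  expect_equal(round(chisq_rxc(t(counts$train$categorical$histological_type))$p, 3),
               0.161)
  expect_equal(round(chisq_rxc(t(counts$test$categorical$histological_type))$p, 3),
               0.717)
  expect_equal(round(chisq_rxc(t(counts$train$categorical$figo_stage))$p, 3),
               0.001)
  expect_equal(round(chisq_rxc(t(counts$test$categorical$figo_stage))$p, 2),
               0.04)
})

test_that("chi-square invariances and degeneracies hold", {
  tab <- matrix(c(10, 10, 4, 4), 2)
  r <- chisq_2x2(tab)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  ## permutation invariance
  t2 <- matrix(c(12, 5, 9, 20), 2)
  expect_equal(chisq_2x2(t2)$statistic,
               chisq_2x2(t2[2:1, 2:1])$statistic, tolerance = 1e-12)
  ## Yates statistic never exceeds the uncorrected one
  set.seed(2)
  for (i in 1:10) {
    t3 <- matrix(rpois(4, 20) + 1, 2)
    expect_lte(chisq_2x2(t3)$statistic,
               chisq_2x2(t3, continuity_correction = FALSE)$statistic)
  }
  ## hand-computed Pearson statistic on an r x c table
  t4 <- matrix(c(20, 30, 25, 25, 15, 35), 2)
  E <- outer(rowSums(t4), colSums(t4)) / sum(t4)
  expect_equal(chisq_rxc(t4)$statistic, sum((t4 - E)^2 / E),
               tolerance = 1e-10)
  expect_equal(chisq_rxc(t4)$df, 2)
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher's exact p equals full hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(1, 11, 9, 3), 2),
               matrix(c(5, 5, 5, 5), 2),
               matrix(c(2, 7, 8, 2), 2),
               matrix(c(10, 2, 3, 9), 2))
  for (tab in tabs)
    expect_equal(fisher_exact_2x2(tab), enum_fisher(tab), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  ## directional agreement with chi-square on a well-populated table
  big <- matrix(c(40, 20, 20, 40), 2)
  expect_equal(fisher_exact_2x2(big) < 0.05, chisq_2x2(big)$p < 0.05)
})

test_that("pooled t from printed summaries reproduces the age row", {
  r <- two_sample_t(summary1 = c(51.63, 10.84, 94),
                    summary2 = c(51.35, 10.49, 104))
  expect_lt(abs(r$p - 0.853), 1e-3)
  expect_equal(r$df, 196)
  ## equal groups: t = 0, p = 1
  r0 <- two_sample_t(summary1 = c(5, 1, 10), summary2 = c(5, 1, 10))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  ## raw-sample route agrees with stats::t.test pooled
  set.seed(10)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  r2 <- two_sample_t(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  expect_error(two_sample_t(summary1 = c(1, 0, 5), summary2 = c(1, 0, 5)),
               "zero pooled")
})

test_that("Mann-Whitney U equals the brute-force pairwise count", {
  set.seed(3)
  x <- sample(1:40, 12)
  y <- sample(1:40, 9)
  u_brute <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(unname(mann_whitney(x, y)$U), u_brute)
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4)
  expect_equal(unname(mann_whitney(xt, yt)$U),
               sum(outer(xt, yt, function(a, b) (a > b) + 0.5 * (a == b))))
})

test_that("pooled stage-wise positivity matches the published percentages", {
  counts <- lvsi_clinical_counts()
  train <- t(counts$train$categorical$figo_stage)
  test <- t(counts$test$categorical$figo_stage)
  sp <- stagewise_proportions(train, test)
  expect_equal(sp$positive, c(69, 61, 28))
  expect_equal(sp$total, c(161, 105, 34))
  expect_equal(round(sp$percent, 2), c(42.86, 58.10, 82.35))
  ## a stage with no positives reports exactly zero
  z <- stagewise_proportions(matrix(c(5, 0, 3, 2), 2))
  expect_equal(z$percent[1], 0)
})

test_that("counts round-trip through the long-format CSV", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cohort,variable,level,negative,positive",
               "train,ca125,le35,79,74",
               "train,ca125,gt35,15,30",
               "train,figo,I,63,47",
               "train,figo,II,29,43",
               "train,figo,III,2,14"), csv)
  rep <- stats_report(csv)
  expect_equal(round(rep$p[rep$variable == "ca125"], 3), 0.046)
  expect_equal(round(rep$p[rep$variable == "figo"], 3), 0.001)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cohort,variable,level,negative,positive",
               "train,ca125,le35,79,-4"), bad)
  expect_error(stats_report(bad), "line 2")
  single <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cohort,variable,level,negative,positive",
               "train,ca125,le35,79,74"), single)
  expect_error(stats_report(single), "single level")
})

test_that("the characteristics report runs the whole battery", {
  rep <- stats_report()
  expect_true(all(c("cohort", "variable", "test", "p") %in% names(rep)))
  expect_equal(nrow(rep), 18)   # 7 categorical + 2 continuous per cohort
  expect_true(all(rep$p > 0 & rep$p <= 1))
  figo <- rep[rep$variable == "figo_stage" & rep$cohort == "train", ]
  expect_equal(round(figo$p, 3), 0.001)
})
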