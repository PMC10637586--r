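## The clinical-characteristics statistical battery: chi-square (Yates for
## 2x2, plain Pearson for r x c), Fisher's exact test, two-sample t from raw
## samples or printed summary statistics, Mann-Whitney U, and pooled
## stage-wise positivity proportions.

check_table <- function(tab, square2 = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("table must hold non-negative integer counts")
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least a 2x2 table")
  if (square2 && (nrow(tab) != 2 || ncol(tab) != 2))
    stopf("a 2x2 table is required")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("table has a zero margin")
  tab
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with continuity correction (the default for 2x2
#' clinical contingency tables), df = 1, two-sided.
#'
#' @param tab 2x2 count matrix
#' @param continuity_correction apply the Yates correction (default TRUE)
#' @return list with `statistic` and `p`
#' @export
#' @examples
#' chisq_2x2(matrix(c(79, 74, 15, 30), 2))  # p ~ 0.046
chisq_2x2 <- function(tab, continuity_correction = TRUE) {
  tab <- check_table(tab, square2 = TRUE)
  ct <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Pearson chi-square test for an r x c table
#'
#' Uncorrected Pearson statistic with df = (r-1)(c-1). The expected counts
#' are returned so callers can fall back to an exact test when any expected
#' cell is below 5.
#'
#' @param tab r x c count matrix
#' @return list with `statistic`, `df`, `p`, `expected` and
#'   `fisher_recommended` (TRUE when any expected count < 5)
#' @export
chisq_rxc <- function(tab) {
  tab <- check_table(tab)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected,
       fisher_recommended = any(ct$expected < 5))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing the hypergeometric probabilities of all tables no
#' more probable than the observed one (conditional on the margins).
#'
#' @param tab 2x2 count matrix
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_table(tab, square2 = TRUE)
  fisher.test(tab)$p.value
}

#' Two-sample t-test from raw samples or summary statistics
#'
#' Pooled-variance Student t by default (Welch by flag). Accepts either two
#' raw samples or the printed per-group summaries (mean, SD, n), so rows of
#' a published characteristics table can be re-tested exactly.
#'
#' @param x,y raw samples, or `NULL` when summaries are given
#' @param summary1,summary2 numeric `c(mean, sd, n)` per group
#' @param welch use the Welch (unequal-variance) form
#' @return list with `t`, `df`, `p`
#' @export
#' @examples
#' two_sample_t(summary1 = c(51.63, 10.84, 94),
#'              summary2 = c(51.35, 10.49, 104))  # p ~ 0.853
two_sample_t <- function(x = NULL, y = NULL, summary1 = NULL,
                         summary2 = NULL, welch = FALSE) {
  if (!is.null(x)) summary1 <- c(mean(x), sd(x), length(x))
  if (!is.null(y)) summary2 <- c(mean(y), sd(y), length(y))
  if (is.null(summary1) || is.null(summary2))
    stopf("provide raw samples or summary statistics for both groups")
  m1 <- summary1[1]; s1 <- summary1[2]; n1 <- summary1[3]
  m2 <- summary2[1]; s2 <- summary2[2]; n2 <- summary2[3]
  if (n1 < 2 || n2 < 2) stopf("group sizes must be >= 2")
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) stopf("zero variance in both groups")
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) stopf("zero pooled variance")
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the normal approximation and tie correction; also
#' returns the U statistic of the first sample.
#'
#' @param x,y raw samples
#' @return list with `U` and `p`
#' @export
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pooled stage-wise positivity proportions
#'
#' Pools the per-cohort stage x status counts and reports, per stage, the
#' positive count, total and percentage (exact rational arithmetic before
#' rounding).
#'
#' @param ... one 2 x n_stages count matrix per cohort, rows =
#'   (negative, positive), columns = stages
#' @return data.frame with `stage`, `positive`, `total`, `percent`
#' @export
#' @examples
#' train <- matrix(c(63, 47, 29, 43, 2, 14), 2,
#'                 dimnames = list(c("neg", "pos"), c("I", "II", "III")))
#' test <- matrix(c(29, 22, 15, 18, 4, 14), 2,
#'                dimnames = list(c("neg", "pos"), c("I", "II", "III")))
#' stagewise_proportions(train, test)  # 42.86 / 58.10 / 82.35 %
stagewise_proportions <- function(...) {
  mats <- list(...)
  pooled <- Reduce(`+`, lapply(mats, as.matrix))
  total <- colSums(pooled)
  if (any(total == 0)) stopf("a stage has zero patients")
  pos <- pooled[2, ]
  data.frame(stage = colnames(pooled) %||% as.character(seq_along(total)),
             positive = as.integer(pos), total = as.integer(total),
             percent = 100 * pos / total, row.names = NULL)
}

#' Clinical characteristics counts of the two-centre cervical-cancer cohort
#'
#' The printed patient-characteristics table of the multi-centre
#' cervical-cancer LVSI study the pipeline is designed around: per-cohort
#' group counts for each categorical variable (columns = LVSI-negative /
#' LVSI-positive), and per-group summaries (mean, SD, n) for the continuous
#' variables. These counts are the input to [stats_report()].
#'
#' @return nested list with `train` and `test`, each holding `categorical`
#'   (named list of 2-column count matrices, levels x status) and
#'   `continuous` (named list of `list(neg = c(mean, sd, n), pos = ...)`)
#' @export
lvsi_clinical_counts <- function() {
  cat2 <- function(..., levels = NULL) {
    v <- c(...)
    matrix(v, ncol = 2, byrow = TRUE,
           dimnames = list(levels, c("LVSI_neg", "LVSI_pos")))
  }
  hist_lv <- c("squamous", "adeno", "adenosquamous")
  diff_lv <- c("low", "middle", "high")
  figo_lv <- c("I", "II", "III")
  list(
    train = list(
      categorical = list(
        histological_type = cat2(64, 83, 24, 16, 6, 5, levels = hist_lv),
        differentiation = cat2(10, 21, 68, 82, 16, 1, levels = diff_lv),
        hpv = cat2(48, 44, 46, 60, levels = c("negative", "positive")),
        ca125 = cat2(79, 74, 15, 30),
        ca199 = cat2(75, 81, 19, 23),
        scc = cat2(44, 44, 50, 60),
        figo_stage = cat2(63, 47, 29, 43, 2, 14, levels = figo_lv)),
      continuous = list(
        age = list(neg = c(51.63, 10.84, 94), pos = c(51.35, 10.49, 104)),
        max_diameter = list(neg = c(22.94, 11.66, 94),
                            pos = c(34.31, 12.75, 104)))),
    test = list(
      categorical = list(
        histological_type = cat2(36, 43, 8, 6, 4, 5, levels = hist_lv),
        differentiation = cat2(11, 16, 23, 23, 14, 15, levels = diff_lv),
        hpv = cat2(15, 15, 33, 39, levels = c("negative", "positive")),
        ca125 = cat2(36, 36, 12, 18),
        ca199 = cat2(37, 37, 11, 17),
        scc = cat2(24, 23, 24, 31),
        figo_stage = cat2(29, 22, 15, 18, 4, 14, levels = figo_lv)),
      continuous = list(
        age = list(neg = c(51.81, 8.73, 48), pos = c(49.06, 10.52, 54)),
        max_diameter = list(neg = c(3.14, 1.45, 48),
                            pos = c(3.85, 1.12, 54)))))
}

#' Characteristics-table statistical report
#'
#' Runs the full battery on a nested counts structure (see
#' [lvsi_clinical_counts()] for the layout): Yates-corrected chi-square for
#' two-level variables, plain Pearson chi-square for more levels (with a
#' Fisher recommendation when expected counts drop below 5), pooled t for
#' the continuous summaries. A CSV path may be given instead: long format
#' with header `cohort,variable,level,negative,positive`, one row per
#' category level.
#'
#' @param counts nested counts list with `train`/`test` cohorts, or the path
#'   of a long-format counts CSV; defaults to the bundled cervical-cancer
#'   table
#' @return data.frame with `cohort`, `variable`, `test`, `statistic`, `p`
#' @export
stats_report <- function(counts = lvsi_clinical_counts()) {
  if (is.character(counts)) counts <- read_counts_csv(counts)
  rows <- list()
  for (cohort in names(counts)) {
    cc <- counts[[cohort]]
    for (v in names(cc$categorical)) {
      tab <- t(cc$categorical[[v]])   # status x levels
      if (ncol(tab) == 2) {
        r <- chisq_2x2(t(tab))
        rows[[length(rows) + 1]] <- data.frame(
          cohort = cohort, variable = v, test = "chisq_yates",
          statistic = r$statistic, p = r$p)
      } else {
        r <- chisq_rxc(tab)
        rows[[length(rows) + 1]] <- data.frame(
          cohort = cohort, variable = v,
          test = if (r$fisher_recommended) "chisq (fisher recommended)"
          else "chisq",
          statistic = r$statistic, p = r$p)
      }
    }
    for (v in names(cc$continuous)) {
      s <- cc$continuous[[v]]
      r <- two_sample_t(summary1 = s$neg, summary2 = s$pos)
      rows[[length(rows) + 1]] <- data.frame(
        cohort = cohort, variable = v, test = "t_pooled",
        statistic = r$t, p = r$p)
    }
  }
  do.call(rbind, rows)
}

## Long-format counts CSV -> nested counts structure. Errors carry the
## offending line number.
read_counts_csv <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "variable", "level", "negative", "positive")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("counts CSV lacks column(s): %s", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$negative) | !is.finite(df$positive) |
                 df$negative < 0 | df$positive < 0)
  if (length(bad))
    stopf("malformed count at line %d of '%s'", bad[1] + 1, path)
  out <- list()
  for (co in unique(df$cohort)) {
    sub <- df[df$cohort == co, ]
    cat_list <- list()
    for (v in unique(sub$variable)) {
      sv <- sub[sub$variable == v, ]
      if (nrow(sv) < 2)
        stopf("variable '%s' (cohort %s) has a single level", v, co)
      cat_list[[v]] <- matrix(c(sv$negative, sv$positive), ncol = 2,
                              dimnames = list(sv$level,
                                              c("LVSI_neg", "LVSI_pos")))
    }
    out[[co]] <- list(categorical = cat_list, continuous = list())
  }
  out
}
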