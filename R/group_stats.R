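# Group-level comparison: normality screening, pairwise Wilcoxon rank-sum
# tests, descriptive-only handling of small groups, ROC/AUC analysis, and
# summary tables.
#
# ADC features in cohort tables are expressed in 1e-3 mm^2/s.

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of `x` against a normal law with sample-estimated
#' mean and SD. Because the parameters are estimated from the same sample,
#' the p-value is approximate and anti-conservative (the Lilliefors issue);
#' it is used here only as a screen for choosing nonparametric tests.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @return p-value.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 observations")
  s <- sd(x)
  if (s == 0) stop("degenerate (constant) sample")
  suppressWarnings(ks.test(x, "pnorm", mean(x), s))$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both samples have at most 10 observations
#' and there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise.
#'
#' @param x,y numeric samples, both nonempty.
#' @return list: `statistic` (Mann-Whitney U for `x`), `p_value`, `exact`
#'   (logical).
#' @export
ranksum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' All pairwise group comparisons of ADC features
#'
#' Tests every unordered pair of groups for every feature with
#' [ranksum()]. Pairs involving a group smaller than `min_group_n` are
#' marked `descriptive_only` and not tested (small groups are reported
#' descriptively rather than inferentially). No multiple-testing
#' correction is applied by default; pass e.g. `p_adjust = "holm"` to
#' adjust across all performed tests.
#'
#' @param cohort data.frame with a `group` column and feature columns.
#' @param features character vector of feature column names.
#' @param min_group_n smallest group size eligible for testing (default 5).
#' @param alpha significance level (default 0.05).
#' @param p_adjust method for [stats::p.adjust()] (default `"none"`).
#' @return data.frame: feature, group1, group2, n1, n2, statistic, p_value,
#'   p_adjusted, significant, descriptive_only. Empty when fewer than two
#'   groups are present.
#' @export
pairwise_group_tests <- function(cohort,
                                 features = c("adc_mean_signal", "adc_mean",
                                              "adc_median", "adc_min",
                                              "adc_max"),
                                 min_group_n = 5L, alpha = 0.05,
                                 p_adjust = "none") {
  features <- intersect(features, names(cohort))
  groups <- unique(as.character(cohort$group))
  empty <- data.frame(feature = character(), group1 = character(),
                      group2 = character(), n1 = integer(), n2 = integer(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      descriptive_only = logical(), stringsAsFactors = FALSE)
  if (length(groups) < 2L || length(features) == 0L) return(empty)
  pairs <- utils::combn(sort(groups), 2L)
  rows <- list()
  for (f in features) {
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x <- cohort[[f]][cohort$group == g1]
      y <- cohort[[f]][cohort$group == g2]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      desc <- length(x) < min_group_n || length(y) < min_group_n
      if (desc || length(x) == 0L || length(y) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group1 = g1, group2 = g2,
          n1 = length(x), n2 = length(y), statistic = NA_real_,
          p_value = NA_real_, p_adjusted = NA_real_, significant = FALSE,
          descriptive_only = TRUE, stringsAsFactors = FALSE)
      } else {
        rs <- ranksum(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group1 = g1, group2 = g2,
          n1 = length(x), n2 = length(y), statistic = rs$statistic,
          p_value = rs$p_value, p_adjusted = NA_real_, significant = NA,
          descriptive_only = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  tested <- !out$descriptive_only
  out$p_adjusted[tested] <- p.adjust(out$p_value[tested], method = p_adjust)
  out$significant[tested] <- out$p_adjusted[tested] < alpha
  out
}

# Empirical ROC on raw score vectors. `orientation = "lower"` means a lower
# feature value indicates the positive class (the malignant-ADC convention).
roc_curve <- function(pos, neg, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  sgn <- if (orientation == "lower") -1 else 1
  sp <- sgn * pos; sn <- sgn * neg
  thr <- sort(unique(c(sp, sn)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  k <- which.max(j)
  youden_thr <- if (k == 1L) sgn * thr[1] else sgn * thr[k - 1L]
  list(thresholds = sgn * thr, sensitivities = tpr[-1],
       specificities = 1 - fpr[-1], auc = auc,
       youden_threshold = youden_thr,
       sensitivity = tpr[k], specificity = 1 - fpr[k])
}

#' ROC analysis of one feature between two groups
#'
#' Empirical ROC over all distinct thresholds with trapezoidal AUC (tied
#' scores contribute half, making AUC identical to the Mann-Whitney
#' U / (n1 * n2) identity). The operating point maximizes the Youden index
#' J = sensitivity + specificity - 1. With `orientation = "lower"`
#' (default), lower feature values indicate the positive class — the usual
#' convention when low ADC marks malignancy.
#'
#' @param cohort data.frame with `group` and feature columns.
#' @param feature feature column name.
#' @param positive_group,negative_group group labels.
#' @param orientation `"lower"` or `"higher"`.
#' @return object of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `youden_threshold`, `sensitivity`,
#'   `specificity`, plus the class sizes.
#' @export
roc_analysis <- function(cohort, feature, positive_group, negative_group,
                         orientation = c("lower", "higher")) {
  pos <- cohort[[feature]][cohort$group == positive_group]
  neg <- cohort[[feature]][cohort$group == negative_group]
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both groups must be nonempty (", positive_group, ": ", length(pos),
         ", ", negative_group, ": ", length(neg), ")")
  rc <- roc_curve(pos, neg, orientation)
  structure(c(list(feature = feature, positive_group = positive_group,
                   negative_group = negative_group,
                   n_positive = length(pos), n_negative = length(neg)),
              rc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", x$positive_group, " (n=", x$n_positive, ") vs ",
      x$negative_group, " (n=", x$n_negative, ") on ", x$feature, "\n",
      "  AUC = ", signif(x$auc, 4),
      "; Youden threshold ", signif(x$youden_threshold, 4),
      " (sens ", signif(100 * x$sensitivity, 4), "%, spec ",
      signif(100 * x$specificity, 4), "%)\n", sep = "")
  invisible(x)
}

#' Per-group feature summary table
#'
#' Reports mean, SD, SEM and the min-max range for every group x feature
#' combination — all three dispersion measures are printed so summary
#' tables are unambiguous. SD/SEM are `NA` for single-case groups.
#'
#' @param cohort data.frame with `group` and feature columns.
#' @param features character vector of feature column names.
#' @return data.frame: group, feature, n, mean, sd, sem, min, max.
#' @export
summarize_groups <- function(cohort,
                             features = c("adc_mean_signal", "adc_mean",
                                          "adc_median", "adc_min",
                                          "adc_max")) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  features <- intersect(features, names(cohort))
  groups <- sort(unique(as.character(cohort$group)))
  rows <- list()
  for (g in groups) for (f in features) {
    v <- cohort[[f]][cohort$group == g]
    v <- v[is.finite(v)]
    n <- length(v)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, feature = f, n = n,
      mean = if (n) mean(v) else NA_real_,
      sd = if (n > 1L) sd(v) else NA_real_,
      sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
      min = if (n) min(v) else NA_real_,
      max = if (n) max(v) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
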