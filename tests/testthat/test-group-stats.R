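# Normality screening, rank-sum tests, pairwise comparisons, ROC and
# summaries.

test_that("KS normality screen detects gross non-normality and calibrates", {
  withr::with_seed(81, {
    expect_lt(ks_normality(runif(1e4)), 0.01)
    # fitting mean/SD on the same sample makes the naive KS screen
    # conservative under the null (the Lilliefors issue): p-values are
    # valid but rejection stays at or below the nominal level
    p_null <- replicate(500, ks_normality(rnorm(100)))
    expect_true(all(p_null >= 0 & p_null <= 1))
    expect_lte(mean(p_null < 0.05), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
    # but the screen retains power against gross non-normality at n = 100
    expect_gt(mean(replicate(200, ks_normality(rexp(100)) < 0.05)), 0.5)
  })
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(1, 10)), "degenerate")
})

test_that("rank-sum matches the exact enumeration oracle", {
  rs <- ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)                    # 2/20 as-extreme
  expect_true(rs$exact)
  expect_equal(ranksum(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)  # symmetry
  expect_equal(ranksum(c(1, 2, 9), c(1, 2, 9))$p_value, 1, tolerance = 0.05)
  expect_error(ranksum(numeric(0), 1:3), "nonempty")
  withr::with_seed(82, {
    for (i in 1:30) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- sample(seq_len(100), n1); y <- sample(setdiff(seq_len(100), x), n2)
      expect_equal(ranksum(x, y)$p_value, ranksum_enum_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("pairwise tests honor the descriptive-only rule", {
  withr::with_seed(83, {
    cohort <- data.frame(
      group = rep(c("PD", "SIBC", "BSI"), c(3, 11, 11)),
      adc_mean_signal = c(rnorm(3, 0.95, 0.3), rnorm(11, 1.38, 0.4),
                          rnorm(11, 1.88, 0.35)))
  })
  out <- pairwise_group_tests(cohort, "adc_mean_signal", min_group_n = 5)
  expect_equal(nrow(out), 3L)                      # 3 unordered pairs
  pd <- out[out$group1 == "PD" | out$group2 == "PD", ]
  expect_true(all(pd$descriptive_only))
  expect_true(all(is.na(pd$p_value)))
  tested <- out[!out$descriptive_only, ]
  expect_equal(nrow(tested), 1L)
  expect_true(tested$p_value >= 0 & tested$p_value <= 1)
  # single group: empty result
  expect_equal(nrow(pairwise_group_tests(cohort[cohort$group == "BSI", ],
                                         "adc_mean_signal")), 0L)
  # optional multiplicity correction is monotone
  holm <- pairwise_group_tests(cohort, "adc_mean_signal", min_group_n = 3,
                               p_adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p_value, na.rm = TRUE))
})

test_that("ROC analysis: separation, ties and the AUC/U identity", {
  coh <- data.frame(group = rep(c("SIBC", "BSI"), each = 4),
                    v = c(1.0, 1.1, 1.2, 1.3, 1.8, 1.9, 2.0, 2.1))
  r <- roc_analysis(coh, "v", "SIBC", "BSI", orientation = "lower")
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0); expect_equal(r$specificity, 1.0)
  # threshold separates the classes under the "lower is positive" rule
  expect_true(all(coh$v[coh$group == "SIBC"] <= r$youden_threshold))
  expect_true(all(coh$v[coh$group == "BSI"] > r$youden_threshold))
  same <- data.frame(group = rep(c("A", "B"), each = 3), v = rep(c(1, 2, 3), 2))
  expect_equal(roc_analysis(same, "v", "A", "B")$auc, 0.5)
  expect_error(roc_analysis(coh, "v", "SIBC", "H"), "nonempty")
  withr::with_seed(84, {
    for (i in 1:100) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      pos <- sample(1:8, n1, TRUE); neg <- sample(1:8, n2, TRUE)  # ties likely
      cc <- data.frame(group = rep(c("P", "N"), c(n1, n2)), v = c(pos, neg))
      r <- roc_analysis(cc, "v", "P", "N", orientation = "higher")
      expect_equal(r$auc, u_stat_oracle(pos, neg) / (n1 * n2),
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC curve is monotone nondecreasing in (FPR, TPR)", {
  withr::with_seed(85, {
    cc <- data.frame(group = rep(c("P", "N"), c(15, 20)),
                     v = c(rnorm(15, 1.3, 0.4), rnorm(20, 1.9, 0.4)))
  })
  r <- roc_analysis(cc, "v", "P", "N", orientation = "lower")
  expect_true(all(diff(r$sensitivities) >= 0))
  expect_true(all(diff(1 - r$specificities) >= 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
})

test_that("group summaries report all three dispersion measures", {
  coh <- data.frame(group = c("A", "A", "A", "B"),
                    f1 = c(1, 2, 3, 7), f2 = c(2, 4, 6, 8))
  s <- summarize_groups(coh, c("f1", "f2"))
  expect_equal(nrow(s), 4L)                        # 2 groups x 2 features
  a1 <- s[s$group == "A" & s$feature == "f1", ]
  expect_equal(a1$mean, 2); expect_equal(a1$sd, 1)
  expect_equal(a1$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(c(a1$min, a1$max), c(1, 3))
  b1 <- s[s$group == "B" & s$feature == "f1", ]
  expect_true(is.na(b1$sd) && is.na(b1$sem))       # single case: no dispersion
  expect_error(summarize_groups(coh[0, ]), "empty cohort")
})
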