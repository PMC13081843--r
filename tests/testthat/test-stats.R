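test_that("pairwise tests on identical groups do not reject, and Bonferroni never shrinks p", {
  x <- c(1, 2, 3, 4, 5)
  gt <- group_compare(list(a = x, b = x), method = "mannwhitney_pairwise")
  expect_gt(gt$pairwise$p_raw, 0.9)
  expect_true(all(gt$pairwise$p_adj >= gt$pairwise$p_raw))
  set.seed(1)
  gt3 <- group_compare(list(a = rnorm(8), b = rnorm(8), c = rnorm(8)),
                       method = "mannwhitney_pairwise")
  expect_equal(gt3$m, 3)
  expect_equal(gt3$pairwise$p_adj, pmin(1, gt3$pairwise$p_raw * 3))
})

test_that("group comparison guards its preconditions", {
  expect_error(group_compare(list(a = 1:5)), "two groups")
  expect_error(group_compare(list(a = 1:5, b = 2:6, c = 3:7),
                             method = "ttest"), "two groups")
  expect_error(group_compare(list(a = rep(1, 5), b = 1:5),
                             method = "anova_tukey"), "rank-based")
  expect_error(group_compare(list(a = 1:3, b = c(1)), method = "ttest"),
               "n >= 2")
})

test_that("anova_tukey and kruskal_dunn produce coherent omnibus + post-hoc output", {
  set.seed(2)
  smp <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  at <- group_compare(smp, method = "anova_tukey")
  expect_lt(at$omnibus$p, 0.001)
  expect_equal(nrow(at$pairwise), 3)
  kd <- group_compare(smp, method = "kruskal_dunn")
  expect_lt(kd$omnibus$p, 0.01)
  expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p_raw))
  ks <- group_compare(smp, method = "ks_dunn")
  expect_equal(nrow(ks$pairwise), 3)
})

test_that("Dunn z statistics match the hand-computed rank formula", {
  # groups 1:3, 4:6, 7:9 -> ranks 1..9, mean ranks 2, 5, 8, no ties;
  # se = sqrt((9*10/12) * (2/3)) = sqrt(5); z_ab = (2-5)/sqrt(5)
  kd <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)),
                      method = "kruskal_dunn", correction = "none")
  z_ab <- kd$pairwise$statistic[kd$pairwise$group1 == "a" &
                                  kd$pairwise$group2 == "b"]
  expect_equal(z_ab, -3 / sqrt(5), tolerance = 1e-12)
  expect_equal(kd$pairwise$p_raw[1], 2 * pnorm(-abs(-3 / sqrt(5))),
               tolerance = 1e-12)
})

test_that("Fisher's exact p matches enumeration and the base-R oracle", {
  # [[5,0],[0,5]]: only the two extreme tables reach the observed probability
  f <- fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(f$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2, 2))$p, 1)
  # correction_m = 1 leaves p unchanged; m scales it
  expect_equal(f$p_adj, f$p)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, 2), 3)$p_adj, 3 * f$p,
               tolerance = 1e-12)
  # independent oracle: stats::fisher.test on random tables
  set.seed(4)
  for (i in 1:60) {
    tb <- matrix(rpois(4, 5), 2, 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact(tb)$p, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-12, info = paste(tb, collapse = ","))
  }
  expect_error(fisher_exact(matrix(1:6, 2, 3)), "2x2")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("odds ratios and Wald intervals match hand formulas", {
  o1 <- odds_ratio_ci(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(o1$or, 1)
  expect_true(o1$ci_low < 1 && 1 < o1$ci_high)

  o2 <- odds_ratio_ci(matrix(c(20, 5, 5, 20), 2, 2))
  se <- sqrt(1 / 20 + 1 / 5 + 1 / 5 + 1 / 20)
  expect_equal(o2$or, 16, tolerance = 1e-12)
  expect_equal(o2$ci_low, exp(log(16) - qnorm(0.975) * se), tolerance = 1e-6)
  expect_equal(o2$ci_high, exp(log(16) + qnorm(0.975) * se), tolerance = 1e-6)
  expect_false(o2$continuity_corrected)

  o3 <- odds_ratio_ci(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(o3$or, 9)                       # (1.5*1.5)/(0.5*0.5)
  expect_true(o3$continuity_corrected)

  # row swap inverts the OR exactly; double swap restores it
  tb <- matrix(c(12, 3, 7, 9), 2, 2)
  expect_equal(odds_ratio_ci(tb[2:1, ])$or, 1 / odds_ratio_ci(tb)$or,
               tolerance = 1e-12)
  expect_equal(odds_ratio_ci(tb[2:1, 2:1])$or, odds_ratio_ci(tb)$or,
               tolerance = 1e-12)
})

test_that("delta-delta-Ct reproduces hand-computed folds", {
  # spreadsheet-style oracle on six samples
  cts <- data.frame(sample_id = paste0("s", 1:6),
                    group = c("ref", "ref", "ref", "ko", "ko", "ko"),
                    ct_target = c(25.0, 25.2, 24.8, 26.5, 26.9, 26.1),
                    ct_housekeeping = c(20.0, 20.1, 19.9, 20.2, 20.4, 19.8))
  out <- delta_delta_ct(cts, reference = "ref")
  dct <- cts$ct_target - cts$ct_housekeeping
  expected <- 2^(-(dct - mean(dct[1:3])))
  expect_equal(out$fold, expected, tolerance = 1e-9)
  expect_equal(exp(mean(log(out$fold[out$group == "ref"]))), 1,
               tolerance = 1e-9)

  # one cycle above the reference mean halves expression
  cts2 <- data.frame(group = c("ref", "ko"), ct_target = c(25, 26),
                     ct_housekeeping = c(20, 20))
  expect_equal(delta_delta_ct(cts2, "ref")$fold, c(1, 0.5))

  cts3 <- cts; cts3$ct_housekeeping[4] <- NA
  expect_error(delta_delta_ct(cts3, "ref"), "s4")
  expect_error(delta_delta_ct(cts, reference = "absent"), "not present")
})
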