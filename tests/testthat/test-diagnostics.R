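test_that("sensitivity and specificity follow the count formulas", {
  mk <- function(n_pos, n_neg, group) {
    ids <- sprintf("%s%03d", group, seq_len(n_pos + n_neg))
    list(calls = stats::setNames(rep(c("positive", "negative"),
                                     c(n_pos, n_neg)), ids),
         records = sample_records(ids, group))
  }
  cs <- mk(21, 17, "CRC")
  expect_equal(sensitivity(cs$calls, cs$records, "CRC", 1), 55.3)
  ct <- mk(6, 202, "normal")
  expect_equal(specificity(ct$calls, ct$records, "normal", 1), 97.1)
  expect_equal(sensitivity(mk(0, 5, "CRC")$calls, mk(0, 5, "CRC")$records,
                           "CRC", 1), 0)
  expect_equal(sensitivity(mk(17, 0, "CRC")$calls, mk(17, 0, "CRC")$records,
                           "CRC", 1), 100)
  expect_equal(specificity(mk(5, 0, "normal")$calls,
                           mk(5, 0, "normal")$records, "normal", 1), 0)
  # invalid (NA) calls leave the denominator
  cs2 <- cs; cs2$calls[1:2] <- NA
  expect_equal(sensitivity(cs2$calls, cs2$records, "CRC"),
               100 * 19 / 36)
  expect_error(sensitivity(cs$calls, cs$records, "adenoma"),
               "no valid samples")
})

test_that("AUC equals exhaustive concordant-pair counting", {
  expect_equal(roc_analysis(c(1, 2, 3, 10, 11, 12),
                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                            orientation = "lower")$auc, 1)
  expect_equal(roc_analysis(rep(2, 8), rep(c(TRUE, FALSE), 4),
                            orientation = "lower")$auc, 0.5)
  withr::with_seed(21, {
    for (i in 1:25) {
      n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
      # discretised scores force ties
      sc <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))
      lab <- rep(c(TRUE, FALSE), c(n1, n0))
      orient <- sample(c("lower", "higher"), 1)
      rr <- roc_analysis(sc, lab, orientation = orient)
      expect_equal(rr$auc, auc_by_pairs(sc, lab, orient), tolerance = 1e-12)
    }
  })
})

test_that("Youden cutoff matches the exhaustive grid scan", {
  withr::with_seed(33, {
    for (i in 1:20) {
      sc <- c(round(rnorm(15, 1.2), 1), round(rnorm(15), 1))
      lab <- rep(c(TRUE, FALSE), each = 15)
      orient <- sample(c("lower", "higher"), 1)
      rr <- roc_analysis(sc, lab, orientation = orient)
      oracle <- youden_by_grid(sc, lab, orient)
      j_pkg <- (rr$sensitivity_at_cutoff + rr$specificity_at_cutoff) / 100 - 1
      expect_equal(j_pkg, unname(oracle["j"]), tolerance = 1e-9)
      expect_equal(rr$sensitivity_at_cutoff / 100, unname(oracle["sens"]),
                   tolerance = 1e-9)
    }
  })
})

test_that("orientation flip with negated scores preserves the ROC result", {
  withr::with_seed(8, {
    sc <- c(rnorm(20, 1), rnorm(25))
    lab <- rep(c(TRUE, FALSE), c(20, 25))
    a <- roc_analysis(sc, lab, orientation = "higher")
    b <- roc_analysis(-sc, lab, orientation = "lower")
    expect_equal(a$auc, b$auc)
    expect_equal(a$ci_low, b$ci_low, tolerance = 1e-9)
    expect_equal(a$sensitivity_at_cutoff, b$sensitivity_at_cutoff)
    expect_equal(a$specificity_at_cutoff, b$specificity_at_cutoff)
    expect_equal(a$optimal_cutoff, -b$optimal_cutoff)
  })
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "one case and one control")
})

test_that("DeLong interval brackets the AUC and bootstrap is seeded", {
  withr::with_seed(4, {
    sc <- c(rnorm(40, 1.5), rnorm(40))
    lab <- rep(c(TRUE, FALSE), each = 40)
  })
  rr <- roc_analysis(sc, lab, orientation = "higher")
  expect_true(rr$ci_low <= rr$auc && rr$auc <= rr$ci_high)
  b1 <- roc_analysis(sc, lab, orientation = "higher",
                     ci_method = "bootstrap", seed = 7)
  b2 <- roc_analysis(sc, lab, orientation = "higher",
                     ci_method = "bootstrap", seed = 7)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_true(b1$ci_low <= b1$auc && b1$auc <= b1$ci_high)
})

test_that("Fisher exact agrees with enumeration and the reference test", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  # left- vs right-colon carcinoma detection counts
  tab <- matrix(c(5, 3, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), fisher_by_enumeration(tab))
  expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value)
  # extreme table: p = 2 / C(20, 10)
  ext <- matrix(c(0, 10, 10, 0), 2, byrow = TRUE)
  expect_equal(fisher_exact(ext), 2 / choose(20, 10))
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  withr::with_seed(14, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, sample(1:8, 1)), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), fisher_by_enumeration(tab))
      expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("rank tests match enumeration oracles and reference results", {
  # full separation, n = 3 + 3: exact p from the 20 equally likely orderings
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 2 / choose(6, 3))
  expect_equal(mw$p, stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  # identical multisets: U = n^2/2, p ~ 1
  mw2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(mw2$u, 8)
  expect_gt(mw2$p, 0.95)
  # ties handled by enumeration at small n: cross-check U against ranks
  mw3 <- mann_whitney_u(c(1, 2, 2, 5), c(2, 3, 4, 6))
  u_oracle <- sum(outer(c(1, 2, 2, 5), c(2, 3, 4, 6),
                        function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(mw3$u, u_oracle)
  expect_true(mw3$p >= 0 && mw3$p <= 1)
  # large-sample path agrees with the reference implementation
  withr::with_seed(3, {
    x <- round(rnorm(30), 1); y <- round(rnorm(30, 0.5), 1)
  })
  expect_equal(mann_whitney_u(x, y)$p,
               suppressWarnings(
                 stats::wilcox.test(x, y, correct = TRUE)$p.value),
               tolerance = 1e-9)

  # signed rank: all differences +1 -> extreme W, exact p = 2/2^n
  n <- 8
  wsr <- wilcoxon_signed_rank(2:(n + 1) + 1, 2:(n + 1))
  expect_equal(wsr$w, n * (n + 1) / 2)
  expect_equal(wsr$p, 2 / 2^n)
  # no ties: agrees with the exact reference implementation
  withr::with_seed(6, {
    x <- rnorm(12); y <- rnorm(12, 0.3)
  })
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("marker comparison report obeys the OR-rule inclusions", {
  s <- simulate_ct_cohort(ct_sim_config(120, 80, 100, seed = 17))
  rep <- marker_comparison_report(s$ct, s$samples, decimals = 2)
  sm <- rep$summary
  # dual fixed-cutoff sensitivity >= each single; specificity <= each single
  for (g in unique(sm$group)) {
    ct_rows <- sm[sm$group == g & sm$indicator == "Ct", ]
    dual <- ct_rows[ct_rows$markers == "SDC2/TFPI2", ]
    for (m in c("SDC2", "TFPI2")) {
      one <- ct_rows[ct_rows$markers == m, ]
      expect_gte(dual$sens_fixed, one$sens_fixed)
      expect_lte(dual$spec_fixed, one$spec_fixed)
    }
  }
  # per-location case counts sum to the Total row
  bl <- rep$by_location
  for (g in unique(bl$case_group)) {
    rows <- bl[bl$case_group == g, ]
    expect_equal(sum(rows$n[rows$location != "Total"]),
                 rows$n[rows$location == "Total"])
    expect_true(all(rows$sens_dual >= rows$sens_single))
    expect_true(all(rows$p_fisher >= 0 & rows$p_fisher <= 1))
    expect_true(all(rows$p_mcnemar >= 0 & rows$p_mcnemar <= 1))
  }
})

test_that("exact McNemar reduces to the binomial tail", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(0, 5), 2 / 2^5)
  expect_equal(mcnemar_exact(3, 3), 1)  # balanced discordance: capped at 1
  expect_equal(mcnemar_exact(2, 6), 2 * stats::pbinom(2, 8, 0.5))
})
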