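test_that("AUC equals the brute-force pairwise fraction", {
  expect_equal(rocAUC(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(rocAUC(c(1, 0.9, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(6:20, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 2)  # rounding forces ties
      expect_equal(rocAUC(s, y)$auc, bruteForceAUC(s, y))
    }
  })
  # null scores at large n sit near 0.5
  withr::with_seed(6, {
    y <- rbinom(2000, 1, 0.5); s <- runif(2000)
    expect_lt(abs(rocAUC(s, y)$auc - 0.5), 0.05)
  })
  expect_error(rocAUC(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong CI agrees with pROC on a reference case", {
  withr::with_seed(7, {
    y <- rbinom(80, 1, 0.5)
    s <- y + rnorm(80)
  })
  mine <- rocAUC(s, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s), method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(pROC::roc(y, s,
    quiet = TRUE))))
  expect_equal(mine$ci, as.numeric(ref)[c(1, 3)], tolerance = 1e-6)
})

test_that("paired DeLong test: identity, symmetry, bootstrap concordance", {
  withr::with_seed(8, {
    y <- rbinom(60, 1, 0.5)
    a <- y + rnorm(60)
    b <- y + rnorm(60, sd = 2)
  })
  same <- delongTest(a, a, y)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  ab <- delongTest(a, b, y)
  ba <- delongTest(b, a, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
  # cross-check against pROC's paired DeLong
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ab$p, ref$p.value, tolerance = 1e-9)
  # and against a bootstrap of the AUC difference
  boot <- withr::with_seed(9, vapply(1:10000, function(i) {
    idx <- sample(60, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    rocAUC(a[idx], y[idx])$auc - rocAUC(b[idx], y[idx])$auc
  }, numeric(1)))
  d <- ab$aucA - ab$aucB
  pBoot <- 2 * min(mean(boot <= 0, na.rm = TRUE),
                   mean(boot >= 0, na.rm = TRUE))
  expect_lt(abs(ab$p - pBoot), 0.02)
})

test_that("cutoff selection matches brute force and the boundary rules", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  y <- c(1, 1, 1, 1, 0, 0)
  expect_equal(chooseCutoff(s, y, 0.95), 0.6)
  withr::with_seed(10, {
    for (i in 1:20) {
      n <- sample(8:24, 1)
      y2 <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s2 <- round(runif(n), 2)
      tgt <- sample(c(0.8, 0.9, 0.95), 1)
      expect_equal(chooseCutoff(s2, y2, tgt),
                   bruteForceCutoff(s2, y2, tgt))
    }
  })
  # target 0 returns the maximum observed score
  expect_equal(chooseCutoff(s, y, 0), max(s))
  # adding a non-cancer sample above the cutoff leaves it unchanged
  expect_equal(chooseCutoff(c(s, 0.95), c(y, 0), 0.95), 0.6)
  # the minimum score always attains full sensitivity
  expect_equal(chooseCutoff(c(0.2, 0.9), c(1, 0), 0.95), 0.2)
  expect_error(chooseCutoff(c(0.2, 0.9), c(0, 0), 0.95), "no positive")
})

test_that("confusion metrics reproduce hand arithmetic with exact CIs", {
  rep <- confusionFromCounts(tp = 92, fp = 11, tn = 88, fn = 5)
  expect_equal(rep$sensitivity$est, 92 / 97)
  expect_equal(rep$specificity$est, 88 / 99)
  expect_equal(rep$accuracy$est, 180 / 196)
  expect_equal(rep$sensitivity$ci,
               as.numeric(binom.test(92, 97)$conf.int))
  perfect <- confusionMetrics(c(0.9, 0.8, 0.1), c(1, 1, 0), cutoff = 0.5)
  expect_equal(perfect$sensitivity$est, 1)
  expect_equal(perfect$specificity$est, 1)
  expect_equal(perfect$accuracy$est, 1)
  # CIs contain their point estimates
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    v <- rep[[m]]
    expect_true(v$ci[1] <= v$est && v$est <= v$ci[2])
  }
})

test_that("prevalence adjustment follows Bayes and is monotone", {
  t1 <- prevalenceAdjusted(1, 1, c(0.1, 0.5, 0.9))
  expect_true(all(t1$ppv == 1) && all(t1$npv == 1))
  t2 <- prevalenceAdjusted(0.842, 0.906, 0.001)
  expect_equal(t2$ppv, 0.842 * 0.001 / (0.842 * 0.001 + 0.094 * 0.999),
               tolerance = 1e-12)
  grid <- prevalenceAdjusted(0.842, 0.906,
                             c(0.001, 0.01, 0.1, 0.2, 0.5))
  expect_true(all(diff(grid$ppv) > 0))
  expect_true(all(diff(grid$npv) < 0))
  expect_error(prevalenceAdjusted(0.9, 0.9, 1.2), "\\[0, 1\\]")
})

test_that("wilcoxon effect size: exact p, bounded CI, degenerate rule", {
  we <- wilcoxonEffect(c(4, 5, 6), c(1, 2, 3), n_boot = 200, seed = 1)
  expect_equal(we$p, 0.1)  # 2 of 20 orderings as extreme
  same <- wilcoxonEffect(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$r, 0)
  expect_equal(same$p, 1)
  withr::with_seed(11, {
    a <- rnorm(30, 1); b <- rnorm(30)
  })
  w2 <- wilcoxonEffect(a, b, n_boot = 500, seed = 2)
  expect_true(w2$r >= 0 && w2$r <= 1)
  expect_true(all(w2$ci >= 0 & w2$ci <= 1))
  expect_true(w2$ci[1] <= w2$ci[2])
})

test_that("BH adjustment reproduces the worked example", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("calibration report: Brier identities and recalibration flags", {
  expect_equal(calibrationReport(c(1, 0, 1), c(1, 0, 1))$brier, 0)
  expect_equal(calibrationReport(rep(0.5, 10),
                                 rep(c(0, 1), 5))$brier, 0.25)
  expect_equal(calibrationReport(c(0.8, 0.2), c(1, 0))$brier, 0.04)
  withr::with_seed(12, {
    s <- runif(200)
    y <- rbinom(200, 1, s)
  })
  cal <- calibrationReport(s, y)
  expect_equal(cal$slope, 1, tolerance = 0.35)
  expect_equal(sum(cal$bins$n), 200)
  oneClass <- calibrationReport(c(0.2, 0.6), c(1, 1))
  expect_true(oneClass$degenerate)
  expect_true(is.na(oneClass$slope))
})

test_that("Jonckheere-Terpstra: worked example, reversal, null uniformity", {
  jt <- jonckheereTrend(list(c(1, 2), c(3, 4), c(5, 6)),
                        method = "permutation", n_perm = 2000, seed = 1)
  expect_equal(jt$statistic, 12)  # 3 pairs x 4 concordant comparisons
  rev <- jonckheereTrend(list(c(5, 6), c(3, 4), c(1, 2)),
                         method = "permutation", n_perm = 500, seed = 1)
  expect_equal(rev$statistic, 0)
  expect_error(jonckheereTrend(list(1:3, 4:6)), "3 ordered groups")
  # permutation p is roughly uniform under the null
  ps <- withr::with_seed(13, vapply(1:200, function(i) {
    g <- split(rnorm(18), rep(1:3, each = 6))
    jonckheereTrend(g, method = "permutation", n_perm = 400,
                    seed = i)$p
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # large-sample normal approximation agrees with permutation
  g <- withr::with_seed(14, split(rnorm(60) +
    rep(c(0, 0.5, 1), each = 20), rep(1:3, each = 20)))
  pPerm <- jonckheereTrend(g, method = "permutation", n_perm = 4000,
                           seed = 3)$p
  pNorm <- jonckheereTrend(g, method = "normal")$p
  expect_lt(abs(pPerm - pNorm), 0.02)
})
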