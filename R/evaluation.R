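#' ROC AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney pairwise formulation (ties count 1/2), variance
#' and CI from DeLong's structural components.
#'
#' @param scores numeric predictions (higher = more cancer-like).
#' @param labels binary labels (1/TRUE = cancer).
#' @param conf_level CI level.
#' @return List with `auc`, `var`, `ci` and the component vectors.
#' @export
rocAUC <- function(scores, labels, conf_level = 0.95) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  x <- scores[y == 1]
  z <- scores[y == 0]
  m <- length(x); n <- length(z)
  # structural components: V10_i = mean_j psi(x_i, z_j), psi in {0, .5, 1}
  cmpMat <- outer(x, z, function(a, b)
    (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmpMat)
  v01 <- colMeans(cmpMat)
  auc <- mean(v10)
  v <- if (m > 1 && n > 1) var(v10) / m + var(v01) / n else NA_real_
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(v)) c(NA_real_, NA_real_) else
    pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(v)))
  list(auc = auc, var = v, ci = ci, v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test of `AUC(A) = AUC(B)` for two score vectors over the same
#' samples, using the paired DeLong variance of the AUC difference.
#'
#' @param scoresA,scoresB score vectors over identical samples.
#' @param labels binary labels.
#' @return List with both AUCs, the difference, `z`, `p`, and a
#'   `degenerate` flag (zero variance with a nonzero difference).
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB))
    stopf("paired test needs the same samples for both score vectors")
  a <- rocAUC(scoresA, labels)
  b <- rocAUC(scoresB, labels)
  m <- length(a$v10); n <- length(a$v01)
  vd <- var(a$v10 - b$v10) / m + var(a$v01 - b$v01) / n
  d <- a$auc - b$auc
  if (vd <= .Machine$double.eps) {
    return(list(aucA = a$auc, aucB = b$auc, diff = d,
                z = if (d == 0) 0 else NA_real_,
                p = if (d == 0) 1 else NA_real_,
                degenerate = d != 0))
  }
  z <- d / sqrt(vd)
  list(aucA = a$auc, aucB = b$auc, diff = d, z = z,
       p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Cutoff at a target training sensitivity
#'
#' The largest threshold `t` (among observed scores) such that the
#' sensitivity of the rule `score >= t => cancer` is at least
#' `target_sensitivity`; by construction this maximizes specificity among
#' qualifying thresholds. Must only ever see training out-of-fold scores.
#' A target of 0 returns the maximum observed score (boundary rule).
#'
#' @param scores training OOF risk scores.
#' @param labels binary labels.
#' @param target_sensitivity required sensitivity (default 0.95).
#' @return The threshold.
#' @export
chooseCutoff <- function(scores, labels, target_sensitivity = 0.95) {
  y <- as.integer(as.logical(labels))
  if (!any(y == 1)) stopf("no positive samples")
  cand <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[y == 1]
  for (t in cand) {
    if (mean(pos >= t) >= target_sensitivity) return(t)
  }
  stopf("target sensitivity %.3f unattainable even at the minimum score",
        target_sensitivity)
}

# Exact Clopper-Pearson interval for x successes out of n.
clopperPearson <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Diagnostic confusion-matrix report
#'
#' Applies the rule `score >= cutoff => cancer`, tabulates the confusion
#' counts and reports sensitivity, specificity, PPV, NPV and accuracy with
#' exact Clopper-Pearson 95% CIs.
#'
#' @param scores numeric scores (omit when giving counts directly).
#' @param labels binary labels.
#' @param cutoff decision threshold fixed upstream.
#' @param cohort cohort tag carried into the report.
#' @return A list of class `DiagnosticReport`.
#' @export
confusionMetrics <- function(scores, labels, cutoff, cohort = "cohort") {
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= cutoff)
  confusionFromCounts(tp = sum(pred == 1 & y == 1),
                      fp = sum(pred == 1 & y == 0),
                      tn = sum(pred == 0 & y == 0),
                      fn = sum(pred == 0 & y == 1),
                      cutoff = cutoff, cohort = cohort)
}

#' @rdname confusionMetrics
#' @param tp,fp,tn,fn confusion counts.
#' @export
confusionFromCounts <- function(tp, fp, tn, fn, cutoff = NA_real_,
                                cohort = "cohort") {
  metric <- function(x, n) list(est = if (n > 0) x / n else NA_real_,
                                ci = clopperPearson(x, n))
  rep <- list(cohort = cohort, cutoff = cutoff,
              counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
              sensitivity = metric(tp, tp + fn),
              specificity = metric(tn, tn + fp),
              ppv = metric(tp, tp + fp),
              npv = metric(tn, tn + fn),
              accuracy = metric(tp + tn, tp + fp + tn + fn))
  class(rep) <- "DiagnosticReport"
  rep
}

#' @export
print.DiagnosticReport <- function(x, ...) {
  cat("DiagnosticReport [", x$cohort, "] cutoff ",
      ifelse(is.na(x$cutoff), "-", signif(x$cutoff, 3)), "\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = " "), "\n", sep = "")
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    v <- x[[m]]
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", m, v$est,
                v$ci[1], v$ci[2]))
  }
  invisible(x)
}

#' Prevalence-adjusted predictive values
#'
#' `PPV(pi) = Se pi / (Se pi + (1 - Sp)(1 - pi))` and
#' `NPV(pi) = Sp (1 - pi) / (Sp (1 - pi) + (1 - Se) pi)` over a prevalence
#' grid — the Bayes-theorem translation of a fixed operating point to
#' populations with different disease prevalence.
#'
#' @param sensitivity,specificity operating point, each in `(0, 1]`.
#' @param prevalences vector of prevalences in `[0, 1]`.
#' @return data.frame (prevalence, ppv, npv); PPV is monotone increasing
#'   and NPV monotone decreasing in prevalence.
#' @export
prevalenceAdjusted <- function(sensitivity, specificity,
                               prevalences = c(0.001, 0.01, 0.1,
                                               0.2, 0.5)) {
  if (any(prevalences < 0 | prevalences > 1))
    stopf("prevalences must lie in [0, 1]")
  se <- sensitivity; sp <- specificity
  ppv <- se * prevalences / (se * prevalences +
                             (1 - sp) * (1 - prevalences))
  npv <- sp * (1 - prevalences) / (sp * (1 - prevalences) +
                                   (1 - se) * prevalences)
  data.frame(prevalence = prevalences, ppv = ppv, npv = npv)
}

#' Wilcoxon rank-sum comparison with effect size r
#'
#' Two-sided rank-sum p-value (exact when both groups have at most 12
#' observations and no ties, otherwise normal approximation with
#' continuity correction), effect size `r = |Z| / sqrt(nA + nB)`, and a
#' percentile bootstrap CI for `r` resampling within groups.
#'
#' @param groupA,groupB numeric score vectors.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @param conf_level CI level.
#' @return List with `p`, `r`, `ci`.
#' @export
wilcoxonEffect <- function(groupA, groupB, n_boot = 2000, seed = 1L,
                           conf_level = 0.95) {
  if (!length(groupA) || !length(groupB))
    stopf("both groups must be non-empty")
  if (length(unique(c(groupA, groupB))) == 1L)
    return(list(p = 1, r = 0, ci = c(0, 0)))
  rEff <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    rk <- rank(c(a, b))
    W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sig2 <= 0) return(0)
    zc <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    abs(zc) / sqrt(n1 + n2)
  }
  ex <- length(groupA) <= 12 && length(groupB) <= 12 &&
    !anyDuplicated(c(groupA, groupB))
  p <- suppressWarnings(
    wilcox.test(groupA, groupB, exact = ex, correct = TRUE)$p.value)
  r <- rEff(groupA, groupB)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    rEff(sample(groupA, replace = TRUE),
         sample(groupB, replace = TRUE)), numeric(1)))
  ci <- unname(quantile(boot, c((1 - conf_level) / 2,
                                1 - (1 - conf_level) / 2)))
  list(p = p, r = r, ci = ci)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with enforced monotonicity, returned in input
#' order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Calibration report
#'
#' Brier score (mean squared error of the probabilities), calibration
#' intercept (logistic recalibration with the score logit as offset),
#' calibration slope (coefficient of the score logit), and an equal-width
#' reliability table. Scores are clipped to `[1e-6, 1 - 1e-6]` before the
#' logit.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels binary outcomes.
#' @param n_bins equal-width reliability bins.
#' @return A list of class `CalibrationReport` with `brier`, `intercept`,
#'   `slope`, `bins` and a `degenerate` flag when only one class is
#'   present (slope undefined).
#' @export
calibrationReport <- function(scores, labels, n_bins = 10) {
  y <- as.integer(as.logical(labels))
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  brier <- mean((scores - y)^2)
  edges <- seq(0, 1, length.out = n_bins + 1)
  binIdx <- pmin(n_bins, findInterval(scores, edges,
                                      rightmost.closed = TRUE))
  bins <- data.frame(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)], upper = edges[-1],
    n = as.integer(tabulate(binIdx, n_bins)),
    mean_predicted = as.numeric(tapply(scores, factor(binIdx,
      levels = seq_len(n_bins)), mean)),
    observed_rate = as.numeric(tapply(y, factor(binIdx,
      levels = seq_len(n_bins)), mean)))
  if (length(unique(y)) < 2L) {
    out <- list(brier = brier, intercept = NA_real_, slope = NA_real_,
                bins = bins, degenerate = TRUE)
  } else {
    lp <- qlogis(pmin(1 - 1e-6, pmax(1e-6, scores)))
    slope <- unname(coef(suppressWarnings(
      glm(y ~ lp, family = binomial())))[2])
    intercept <- unname(coef(suppressWarnings(
      glm(y ~ 1 + offset(lp), family = binomial())))[1])
    out <- list(brier = brier, intercept = intercept, slope = slope,
                bins = bins, degenerate = FALSE)
  }
  class(out) <- "CalibrationReport"
  out
}

#' @export
print.CalibrationReport <- function(x, ...) {
  cat(sprintf(
    "CalibrationReport: Brier %.3f | intercept %s | slope %s\n",
    x$brier,
    ifelse(is.na(x$intercept), "NA", sprintf("%.3f", x$intercept)),
    ifelse(is.na(x$slope), "NA", sprintf("%.3f", x$slope))))
  invisible(x)
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' The JT statistic sums, over all ordered group pairs `(i < j)`, the
#' Mann-Whitney count of pairs with the later-group value larger (ties
#' count 1/2). The two-sided p-value comes from a seeded permutation of
#' group membership (default) or the large-sample normal approximation.
#'
#' @param groups list of numeric vectors in increasing group order (at
#'   least 3 groups for a trend; 2 are rejected).
#' @param method `"permutation"`, `"normal"`, or `"auto"` (permutation up
#'   to 200 total observations).
#' @param n_perm permutation count.
#' @param seed permutation seed.
#' @return List with `statistic` and `p`.
#' @export
jonckheereTrend <- function(groups, method = c("auto", "permutation",
                                               "normal"),
                            n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (length(groups) < 3L) stopf("at least 3 ordered groups are required")
  jtStat <- function(gr) {
    s <- 0
    for (i in seq_len(length(gr) - 1)) {
      for (j in (i + 1):length(gr)) {
        s <- s + sum(outer(gr[[i]], gr[[j]], function(a, b)
          (a < b) + 0.5 * (a == b)))
      }
    }
    s
  }
  stat <- jtStat(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  if (method == "auto")
    method <- if (N <= 200) "permutation" else "normal"
  if (method == "permutation") {
    pool <- unlist(groups)
    grp <- rep(seq_along(groups), sizes)
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      pp <- sample(pool)
      jtStat(split(pp, grp))
    }, numeric(1)))
    mu <- (N^2 - sum(sizes^2)) / 4
    p <- (1 + sum(abs(perm - mu) >= abs(stat - mu) - 1e-12)) /
      (n_perm + 1)
  } else {
    mu <- (N^2 - sum(sizes^2)) / 4
    sg <- sqrt((N^2 * (2 * N + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72)
    z <- (stat - mu) / sg
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = stat, p = p)
}
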