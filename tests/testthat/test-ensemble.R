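test_that("candidate search keeps exact OOF bookkeeping and replays from its seed", {
  co <- testCohort()
  X <- co$Xtrain$FSD
  cands <- candidateSearch(X, co$ytrain, n_candidates = 8, folds = 5,
                           seed = 2, family = "FSD")
  expect_length(cands, 8)
  algos <- vapply(cands, function(x) x$algorithm, "")
  expect_true("stacked" %in% algos)
  for (cand in cands) {
    expect_equal(names(cand$oof), rownames(X))
    expect_false(anyNA(cand$oof))        # exactly one prediction each
    expect_true(all(cand$oof >= 0 & cand$oof <= 1))
    expect_equal(cand$oof_auc, rocAUC(cand$oof, co$ytrain)$auc)
  }
  cands2 <- candidateSearch(X, co$ytrain, n_candidates = 8, folds = 5,
                            seed = 2, family = "FSD")
  expect_identical(lapply(cands, function(x) x[c("oof", "oof_auc",
                                                 "hyper", "algorithm")]),
                   lapply(cands2, function(x) x[c("oof", "oof_auc",
                                                  "hyper", "algorithm")]))
  # separable features give a strong best candidate
  expect_gt(max(vapply(cands, function(x) x$oof_auc, numeric(1))), 0.95)
})

test_that("fold assignment is stratified and independent of sample order", {
  ids <- sprintf("s%02d", 1:30)
  y <- rep(c(0, 1), 15)
  f1 <- cfFragSig:::makeFolds(ids, y, k = 5, seed = 3)
  perm <- sample(30)
  f2 <- cfFragSig:::makeFolds(ids[perm], y[perm], k = 5, seed = 3)
  expect_identical(f1[perm], f2)
  for (k in 1:5) expect_setequal(unique(y[f1 == k]), c(0, 1))
  expect_error(cfFragSig:::makeFolds(ids[1:6], c(1, 1, 1, 1, 1, 0),
                                     k = 5, seed = 1), "at least")
})

test_that("ranking is by OOF AUC with id-order tie-break", {
  mk <- function(id, auc) list(id = id, oof_auc = auc)
  sel <- rankAndSelect(list(mk("a", 0.9), mk("b", 0.8), mk("c", 0.7)),
                       K = 2)
  expect_equal(vapply(sel, function(x) x$id, ""), c("a", "b"))
  tied <- rankAndSelect(list(mk("a", 0.8), mk("b", 0.9), mk("c", 0.9)),
                        K = 2)
  expect_equal(vapply(tied, function(x) x$id, ""), c("b", "c"))
  expect_warning(rankAndSelect(list(mk("a", 0.8)), K = 10), "returning all")
})

test_that("score averaging and the equal-weight risk score are arithmetic means", {
  expect_equal(unname(riskScore(0.9, 0.6, 0.3)), 0.6)
  expect_equal(riskScore(0.5, 0.5, 0.5), 0.5)
  expect_equal(riskScore(0.9, 0.6, 0.3), riskScore(0.3, 0.9, 0.6))
  expect_error(riskScore(0.5, NULL, 0.5), "required")
  expect_error(riskScore(c(0.5, 0.2), 0.5, 0.5), "equal length")
})

test_that("fitted ensemble separates a strong synthetic cohort", {
  co <- testCohort()
  ens <- testEnsemble()
  expect_equal(nrow(ensembleManifest(ens)), 15)  # 5 per family here
  expect_equal(sort(unique(ensembleManifest(ens)$family)),
               c("CNV", "FSD", "PFE"))
  pv <- predictRisk(ens, co$Xval)
  expect_gt(rocAUC(pv$risk, co$yval)$auc, 0.9)
  # cutoff meets the training sensitivity target on OOF scores
  rep <- confusionMetrics(unname(trainingScores(ens)), co$ytrain,
                          ensembleCutoff(ens))
  expect_gte(rep$sensitivity$est, 0.95)
  # ensemble at least as good as the weakest family on validation
  famAUC <- vapply(c("CNV", "FSD", "PFE"), function(f)
    rocAUC(perFeatureScore(ens@families[[f]]$candidates, co$Xval[[f]]),
           co$yval)$auc, numeric(1))
  expect_gte(rocAUC(pv$risk, co$yval)$auc, min(famAUC))
})

test_that("prediction refuses leaked training ids and schema drift", {
  co <- testCohort()
  ens <- testEnsemble()
  expect_error(predictRisk(ens, co$Xtrain), "part of training")
  viaGuard <- predictRisk(ens, co$Xtrain, allow_training_samples = TRUE)
  expect_equal(viaGuard$pathway[1], "refit(training-sample)")
  Xbad <- co$Xval
  colnames(Xbad$FSD)[1] <- "renamed"
  expect_error(predictRisk(ens, Xbad), "schema")
})

test_that("the fitted artifact is identical with or without validation data present", {
  co <- testCohort()
  fitOnly <- function(withVal) {
    if (withVal) invisible(co$Xval)  # validation data merely exists
    fitEnsemble(co$Xtrain, co$ytrain, n_candidates = 6, K = 3,
                folds = 5, seed = 17)
  }
  a <- fitOnly(TRUE)
  b <- fitOnly(FALSE)
  art <- function(e) serialize(list(ensembleManifest(e),
                                    trainingScores(e),
                                    ensembleCutoff(e)), NULL)
  expect_identical(art(a), art(b))
})
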