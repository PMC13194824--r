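# Randomized candidate search over {regularized-linear, gradient-boosted
# trees, random forest, stacked logistic combiner}, 5-fold OOF predictions,
# AUC ranking, top-K averaging — a desk-scale surrogate of an AutoML
# search that preserves the search -> rank -> average architecture.

# Deterministic stratified fold assignment keyed by (seed, sample_id):
# ids are sorted within class, permuted under a derived seed, and folds
# assigned cyclically, so membership is independent of input order.
makeFolds <- function(ids, y, k = 5L, seed = 1L) {
  if (anyDuplicated(ids)) stopf("duplicate sample ids")
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (min(table(y)) < k)
    stopf("each class needs at least %d samples for %d folds", k, k)
  fold <- setNames(integer(length(ids)), ids)
  for (cl in c(0L, 1L)) {
    cid <- sort(ids[y == cl])
    perm <- with_seed(deriveSeed(seed, cl + 101L), sample(cid))
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  unname(fold[ids])
}

sampleHyper <- function(algo, hpseed) {
  with_seed(hpseed, switch(algo,
    glmnet = list(alpha = runif(1), lambda = 10^runif(1, -4, 0)),
    xgboost = list(nrounds = sample(20:80, 1),
                   max_depth = sample(2:5, 1),
                   eta = runif(1, 0.05, 0.3),
                   subsample = runif(1, 0.6, 1),
                   colsample = runif(1, 0.5, 1),
                   seed = hpseed),
    ranger = list(num.trees = sample(150:400, 1),
                  mtry_frac = runif(1, 0.1, 0.6),
                  min.node.size = sample(1:5, 1),
                  seed = hpseed)))
}

fitAlgo <- function(algo, hp, X, y) {
  switch(algo,
    glmnet = glmnet::glmnet(X, y, family = "binomial",
                            alpha = hp$alpha, lambda = hp$lambda),
    xgboost = xgboost::xgb.train(
      xgboost::xgb.params(objective = "binary:logistic",
                          max_depth = hp$max_depth,
                          learning_rate = hp$eta,
                          subsample = hp$subsample,
                          colsample_bytree = hp$colsample,
                          nthread = 1, seed = hp$seed),
      xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nrounds, verbose = 0),
    ranger = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            probability = TRUE,
                            num.trees = hp$num.trees,
                            mtry = max(1L, floor(hp$mtry_frac * ncol(X))),
                            min.node.size = hp$min.node.size,
                            seed = hp$seed, num.threads = 1))
}

predictAlgo <- function(algo, model, X) {
  switch(algo,
    glmnet = as.numeric(predict(model, X, type = "response")[, 1]),
    xgboost = as.numeric(predict(model, xgboost::xgb.DMatrix(X))),
    ranger = as.numeric(predict(model, data = X,
                                num.threads = 1)$predictions[, "1"]))
}

# Predict a candidate (base or stacked) on new data; errors on schema drift.
predictCandidate <- function(cand, X) {
  if (!identical(colnames(X), cand$schema))
    stopf("feature names of the input do not match the training schema")
  if (cand$algorithm == "stacked") {
    Z <- vapply(cand$model$base,
                function(b) predictAlgo(b$algorithm, b$model, X),
                numeric(nrow(X)))
    Z <- matrix(Z, nrow = nrow(X))
    as.numeric(plogis(cbind(1, Z) %*% cand$model$coef))
  } else {
    predictAlgo(cand$algorithm, cand$model, X)
  }
}

#' Randomized candidate model search with out-of-fold predictions
#'
#' Generates `n_candidates` candidate classifiers for one feature family:
#' randomized hyperparameters over regularized logistic regression
#' (glmnet), gradient-boosted trees (xgboost) and random forests (ranger),
#' plus stacked logistic combiners over random subsets of the base
#' candidates. Every candidate is trained on the complement of each of
#' `folds` stratified folds; the held-out predictions form one OOF vector
#' per candidate, from which its ranking AUC is computed. Candidates are
#' finally refit on the full training data. Fully deterministic given
#' `seed`.
#'
#' @param X samples x features numeric matrix with rownames (sample ids).
#' @param y binary labels (1/TRUE = cancer).
#' @param n_candidates number of candidates (roughly one sixth of them are
#'   stacked combiners once `n_candidates >= 6`).
#' @param folds number of stratified CV folds.
#' @param seed integer seed replaying the whole search.
#' @param family feature-family tag carried into candidate ids.
#' @return List of candidate objects (id, family, algorithm,
#'   hyperparameters, `oof`, `oof_auc`, refit `model`, feature `schema`).
#' @export
candidateSearch <- function(X, y, n_candidates = 30, folds = 5, seed = 1L,
                            family = "feature") {
  if (n_candidates < 1) stopf("n_candidates must be at least 1")
  if (is.null(rownames(X))) stopf("X must have sample ids as rownames")
  y <- as.integer(as.logical(y))
  ids <- rownames(X)
  foldid <- makeFolds(ids, y, folds, seed)
  nStack <- if (n_candidates >= 6) max(1L, n_candidates %/% 6L) else 0L
  nBase <- n_candidates - nStack

  base <- vector("list", nBase)
  for (i in seq_len(nBase)) {
    hpseed <- deriveSeed(seed, i)
    algo <- with_seed(deriveSeed(hpseed, 1L),
                      sample(c("glmnet", "xgboost", "ranger"), 1))
    hp <- sampleHyper(algo, hpseed)
    oof <- rep(NA_real_, length(y))
    foldModels <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      m <- with_seed(deriveSeed(hpseed, 10L + f),
                     fitAlgo(algo, hp, X[tr, , drop = FALSE], y[tr]))
      foldModels[[f]] <- m
      oof[!tr] <- predictAlgo(algo, m, X[!tr, , drop = FALSE])
    }
    refit <- with_seed(deriveSeed(hpseed, 99L), fitAlgo(algo, hp, X, y))
    base[[i]] <- list(id = sprintf("%s_c%03d", family, i),
                      family = family, algorithm = algo, hyper = hp,
                      oof = setNames(oof, ids),
                      oof_auc = rocAUC(oof, y)$auc,
                      model = refit, schema = colnames(X))
  }

  stacked <- vector("list", nStack)
  if (nStack > 0) {
    Z <- vapply(base, function(b) b$oof, numeric(length(y)))
    Z <- matrix(Z, nrow = length(y))
    for (j in seq_len(nStack)) {
      hpseed <- deriveSeed(seed, 1000L + j)
      sub <- with_seed(hpseed,
        sort(sample.int(nBase, min(nBase, sample(3:6, 1)))))
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(folds)) {
        tr <- foldid != f
        fit <- suppressWarnings(
          glm.fit(cbind(1, Z[tr, sub, drop = FALSE]), y[tr],
                  family = binomial()))
        eta <- cbind(1, Z[!tr, sub, drop = FALSE]) %*% coef(fit)
        oof[!tr] <- plogis(as.numeric(eta))
      }
      full <- suppressWarnings(
        glm.fit(cbind(1, Z[, sub, drop = FALSE]), y,
                family = binomial()))
      stacked[[j]] <- list(
        id = sprintf("%s_s%03d", family, j), family = family,
        algorithm = "stacked", hyper = list(base_ids = sub),
        oof = setNames(oof, ids), oof_auc = rocAUC(oof, y)$auc,
        model = list(coef = coef(full),
                     base = lapply(base[sub], function(b)
                       list(algorithm = b$algorithm, model = b$model))),
        schema = colnames(X))
    }
  }
  c(base, stacked)
}

#' Rank candidates by OOF AUC and keep the top K
#'
#' Descending OOF AUC, exact ties broken by candidate id order. Fewer than
#' `K` candidates returns them all with a warning (scaled runs).
#'
#' @param candidates list from [candidateSearch()].
#' @param K number to keep (default 10).
#' @return The selected candidates, best first.
#' @export
rankAndSelect <- function(candidates, K = 10) {
  if (length(candidates) < K) {
    warning(sprintf("only %d candidates available; returning all",
                    length(candidates)), call. = FALSE)
    K <- length(candidates)
  }
  auc <- vapply(candidates, function(x) x$oof_auc, numeric(1))
  ord <- order(-auc, seq_along(candidates))
  candidates[ord[seq_len(K)]]
}

#' Per-feature ensemble score
#'
#' Unweighted mean of the K selected candidates' predicted probabilities.
#'
#' @param selected top-K candidates (refit on the full training set).
#' @param X samples x features matrix matching the training schema.
#' @return Numeric vector of scores in `[0, 1]`, named by rownames of `X`.
#' @export
perFeatureScore <- function(selected, X) {
  P <- vapply(selected, function(cand) predictCandidate(cand, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  setNames(rowMeans(P), rownames(X))
}

#' Equal-weight risk score
#'
#' Arithmetic mean of the three per-family ensemble scores. A missing
#' family is an error — the score is never silently reweighted.
#'
#' @param cnv_score,fsd_score,pfe_score numeric vectors of equal length.
#' @return Numeric vector in `[0, 1]`.
#' @export
riskScore <- function(cnv_score, fsd_score, pfe_score) {
  if (is.null(cnv_score) || is.null(fsd_score) || is.null(pfe_score) ||
      anyNA(cnv_score) || anyNA(fsd_score) || anyNA(pfe_score))
    stopf("all three family scores are required")
  if (length(unique(c(length(cnv_score), length(fsd_score),
                      length(pfe_score)))) != 1L)
    stopf("family score vectors must have equal length")
  (cnv_score + fsd_score + pfe_score) / 3
}

#' Fit the three-family ensemble
#'
#' Runs the candidate search, OOF-AUC ranking and top-K selection per
#' feature family (CNV, FSD, PFE), averages the selected candidates' OOF
#' predictions into per-family OOF scores, combines them into equal-weight
#' OOF risk scores, and derives the decision cutoff at the target training
#' sensitivity — all strictly within the training cohort.
#'
#' @param Xlist named list of three matrices (`CNV`, `FSD`, `PFE`), equal
#'   rownames in equal order.
#' @param labels binary labels (1/TRUE = cancer).
#' @param n_candidates candidates per family.
#' @param K models kept per family.
#' @param folds stratified CV folds.
#' @param seed master seed.
#' @param target_sensitivity training sensitivity defining the cutoff.
#' @return A [TrainedEnsemble-class].
#' @export
fitEnsemble <- function(Xlist, labels, n_candidates = 30, K = 10,
                        folds = 5, seed = 1L,
                        target_sensitivity = 0.95) {
  fams <- c("CNV", "FSD", "PFE")
  if (!all(fams %in% names(Xlist)))
    stopf("Xlist must contain CNV, FSD and PFE matrices")
  ids <- rownames(Xlist[[fams[1]]])
  for (f in fams[-1])
    if (!identical(rownames(Xlist[[f]]), ids))
      stopf("all family matrices must share sample order")
  y <- as.integer(as.logical(labels))

  families <- list()
  manifest <- list()
  famOOF <- matrix(NA_real_, length(ids), length(fams),
                   dimnames = list(ids, fams))
  for (k in seq_along(fams)) {
    f <- fams[k]
    cands <- candidateSearch(Xlist[[f]], y, n_candidates, folds,
                             seed = deriveSeed(seed, 7000L + k),
                             family = f)
    top <- rankAndSelect(cands, K)
    oofs <- vapply(top, function(x) x$oof, numeric(length(ids)))
    famOOF[, f] <- rowMeans(matrix(oofs, nrow = length(ids)))
    families[[f]] <- list(candidates = top)
    manifest[[f]] <- data.frame(
      id = vapply(top, function(x) x$id, ""),
      family = f,
      algorithm = vapply(top, function(x) x$algorithm, ""),
      hyperparameters = vapply(top, function(x)
        paste(names(x$hyper), vapply(x$hyper, function(v)
          paste(signif(unlist(v), 4), collapse = "/"), ""),
          sep = "=", collapse = ";"), ""),
      oof_auc = vapply(top, function(x) x$oof_auc, numeric(1)),
      stringsAsFactors = FALSE)
  }
  riskOOF <- riskScore(famOOF[, "CNV"], famOOF[, "FSD"], famOOF[, "PFE"])
  cutoff <- chooseCutoff(riskOOF, y, target_sensitivity)
  methods::new("TrainedEnsemble",
    families = families, cutoff = cutoff,
    trainingScores = unname(riskOOF), sampleIDs = ids,
    manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
    config = list(n_candidates = n_candidates, K = K, folds = folds,
                  seed = seed, target_sensitivity = target_sensitivity))
}

#' Predict risk scores with a trained ensemble
#'
#' Applies the refit top-K models per family, averages into per-family
#' scores and combines them into the equal-weight risk score. Touches no
#' label. By default refuses samples whose ids appeared in training (the
#' leakage guard); training-cohort scores should instead come from
#' [trainingScores()], which returns the out-of-fold pathway.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param Xlist named list of CNV/FSD/PFE matrices sharing the training
#'   feature schema.
#' @param allow_training_samples set `TRUE` to bypass the id-overlap guard
#'   (predictions for training samples via the refit pathway are
#'   optimistically biased; they are labelled as such).
#' @return data.frame with per-family scores, the `risk` score and the
#'   dichotomized `predicted` class at the training cutoff.
#' @export
predictRisk <- function(ensemble, Xlist, allow_training_samples = FALSE) {
  fams <- c("CNV", "FSD", "PFE")
  if (!all(fams %in% names(Xlist)))
    stopf("Xlist must contain CNV, FSD and PFE matrices")
  ids <- rownames(Xlist[[fams[1]]])
  overlap <- intersect(ids, ensemble@sampleIDs)
  if (length(overlap) && !allow_training_samples)
    stopf(paste("sample id(s) %s were part of training;",
                "use trainingScores() for out-of-fold scores"),
          paste(head(overlap, 3), collapse = ", "))
  sc <- lapply(fams, function(f)
    perFeatureScore(ensemble@families[[f]]$candidates, Xlist[[f]]))
  risk <- riskScore(sc[[1]], sc[[2]], sc[[3]])
  data.frame(sample_id = ids, cnv = unname(sc[[1]]),
             fsd = unname(sc[[2]]), pfe = unname(sc[[3]]),
             risk = unname(risk),
             predicted = ifelse(risk >= ensemble@cutoff,
                                "cancer", "non-cancer"),
             pathway = if (length(overlap)) "refit(training-sample)" else
               "refit",
             stringsAsFactors = FALSE)
}
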