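test_that("entropy closed forms hold", {
  point <- c(rep(0, 60), 1, rep(0, 60))
  expect_equal(shannonEntropy(point), 0)
  expect_equal(shannonEntropy(rep(1 / 121, 121)), log(121))
  expect_equal(shannonEntropy(rep(0.25, 4)), log(4))
  expect_equal(shannonEntropy(c(3, 3, 3, 3)), log(4))  # counts normalize
  expect_error(shannonEntropy(c(-0.1, 1.1)), "negative")
})

test_that("prior distribution reflects the NDR-flank fragments", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 50000, seed = 6))
  cfg <- testPFEConfig()
  pr <- priorDistribution(fs, gm, cfg)
  expect_length(pr, 121)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # flanks sample bulk chromatin: mononucleosomal mode near 167
  expect_equal(as.integer(names(which.max(pr))), 167, tolerance = 3)
  # an empty fragment pool is an instructive error
  empty <- methods::new("FragmentSet", sampleID = "e",
    fragments = GenomicRanges::GRanges(), metadata = list())
  expect_error(priorDistribution(empty, gm, cfg), "NDR flank")
})

test_that("control entropies: five values, seeded, near-equal for iid genes", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 50000, seed = 6))
  cfg <- testPFEConfig()
  ce1 <- controlEntropies(fs, gm, cfg)
  ce2 <- controlEntropies(fs, gm, cfg)
  expect_length(ce1, 5)
  expect_identical(ce1, ce2)
  # background genes share one length distribution: entropies near-equal
  expect_lt(diff(range(ce1)), 0.15)
  # different seed, different gene sets
  ce3 <- controlEntropies(fs, gm, pfeConfig(seed = 99))
  expect_false(identical(ce1, ce3))
})

test_that("margin probability closed form matches the Monte-Carlo oracle", {
  cfg <- pfeConfig()
  controls <- c(3.0, 3.1, 3.05, 2.95, 3.2)
  E <- c(2.9, 3.21, 3.6, 4.2, 6.4)
  closed <- vapply(E, function(e)
    cfFragSig:::marginProbability(e, controls, cfg), numeric(1))
  mc <- mcMarginProbability(E, controls, n_mc = 1e6)
  # draws with min ratio <= 1 contribute exactly zero
  expect_equal(closed[1], 0)
  se <- sqrt(pmax(mc * (1 - mc), 1e-12) / 1e6)
  expect_true(all(abs(closed - mc) <= 3 * se + 1e-9))
  # all five ratios equal to 2 contribute F_Gamma(1) = erf(1)
  expect_equal(cfFragSig:::marginProbability(2, rep(1, 5), cfg),
               pgamma(1, 0.5, 1))
  expect_equal(pgamma(1, 0.5, 1), 0.8427008, tolerance = 1e-6)
})

test_that("gene PFE scores live in [0,1], vanish for low-entropy genes and rise with entropy", {
  cfg <- testPFEConfig()
  prior <- rep(1 / 121, 121)
  controls <- rep(3.5, 5)
  lowCounts <- c(rep(0, 60), 200, rep(0, 60))       # near point mass
  withr::with_seed(1, {
    low <- genePFE(lowCounts, prior, controls, cfg)
    hi <- genePFE(rep(2, 121), prior, controls, cfg) # near uniform
  })
  expect_equal(low, 0)
  expect_gt(hi, low)
  expect_lte(hi, 1)
  # a gene with zero fragments is a missing value, not an error
  expect_true(is.na(genePFE(rep(0, 121), prior, controls, cfg)))
  expect_error(genePFE(rep(1, 121), prior, c(0, 1, 1, 1, 1), cfg),
               "positive")
  # monotone in gene entropy: wider Beta-binomial shapes never score lower
  shapes <- c(2, 6, 20)
  sc <- vapply(shapes, function(s) {
    p <- dbeta(seq(0.01, 0.99, length.out = 121), s, s)
    counts <- round(200 * p / sum(p))
    withr::with_seed(2, genePFE(counts, prior, controls, cfg))
  }, numeric(1))
  expect_true(all(diff(sc) <= 1e-6))  # larger shape = narrower = lower
})

test_that("prior dominance: scores converge as the prior weight grows", {
  cfg10 <- testPFEConfig()
  prior <- rep(1 / 121, 121)
  controls <- rep(4.2, 5)
  genesCounts <- list(c(rep(0, 50), rep(10, 21), rep(0, 50)),
                      rep(2, 121),
                      c(rep(4, 30), rep(0, 91)))
  spread <- vapply(c(20, 2000, 2e5), function(W) {
    cfg <- pfeConfig(prior_weight = W, seed = 1)
    sc <- vapply(genesCounts, function(ct)
      withr::with_seed(3, genePFE(ct, prior, controls, cfg)), numeric(1))
    max(sc) - min(sc)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[3], 0.02)
})

test_that("shared-k and independent-k variants order consistently", {
  cfg_shared <- testPFEConfig()
  cfg_indep <- pfeConfig(shared_k = FALSE, seed = 5)
  controls <- c(3.0, 3.1, 3.2, 3.0, 3.1)
  E <- c(3.5, 4.0)
  ps <- vapply(E, function(e)
    cfFragSig:::marginProbability(e, controls, cfg_shared), numeric(1))
  pi <- vapply(E, function(e)
    cfFragSig:::marginProbability(e, controls, cfg_indep), numeric(1))
  # independent margins are stricter than one shared margin
  expect_true(all(pi <= ps + 1e-12))
  expect_true(all(diff(ps) > 0) && all(diff(pi) > 0))
})

test_that("PFE matrix is normalized per sample and order-independent", {
  co <- testCohort()
  sub <- co$train$samples[c(1, 2, 17, 18)]
  M <- pfeMatrix(sub, co$model, co$pfe)
  expect_equal(dim(M), c(4, 16))
  expect_equal(unname(rowMeans(M)), rep(0, 4), tolerance = 1e-9)
  Mperm <- pfeMatrix(sub[c(3, 1, 4, 2)], co$model, co$pfe)
  expect_equal(M[rownames(Mperm), ], Mperm)
})

test_that("boosted genes outrank background-like quiet genes in cancer samples", {
  co <- testCohort()
  gm <- co$model
  M <- co$Xtrain$PFE
  cancer <- co$ytrain == 1
  markers <- genes(gm)$gene_id[genes(gm)$active & !genes(gm)$background]
  quiet <- setdiff(colnames(M), markers)
  quiet <- quiet[order(setNames(genes(gm)$activity,
                                genes(gm)$gene_id)[quiet])][1:5]
  expect_gt(median(M[cancer, markers]) - median(M[!cancer, markers]),
            median(M[cancer, quiet]) - median(M[!cancer, quiet]))
})

test_that("feature selection keeps cancer-high genes below the p threshold only", {
  withr::with_seed(4, {
    n <- 20
    M <- cbind(good = c(rnorm(n, 2), rnorm(n, 0)),       # cancer-high
               inverted = c(rnorm(n, -2), rnorm(n, 0)),  # cancer-low
               null = rnorm(2 * n))
    rownames(M) <- sprintf("s%02d", 1:(2 * n))
  })
  labels <- rep(c(1, 0), each = 20)
  sel <- selectPFEFeatures(M, labels)
  expect_true(sel$selected[sel$gene == "good"])
  expect_false(sel$selected[sel$gene == "inverted"])
  expect_lt(sel$p[sel$gene == "inverted"], 0.01)  # excluded by direction
  expect_error(selectPFEFeatures(M, rep(1, 40)), "both classes")
})

test_that("null genes are selected at about the one-sided 0.005 rate", {
  hits <- withr::with_seed(8, vapply(1:1000, function(i) {
    a <- rnorm(20); b <- rnorm(20)
    p <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    p < 0.01 && mean(a) - mean(b) > 0
  }, logical(1)))
  ci <- binom.test(sum(hits), 1000)$conf.int
  # nominal rate 0.005 (p < 0.01, one-sided direction)
  expect_lte(ci[1], 0.005)
  expect_gte(ci[2], 0.002)
})

test_that("pfe summary averages the selected features", {
  M <- matrix(1:12, nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("g", 1:4)))
  s <- pfeSummary(M, c("g1", "g3"))
  expect_equal(unname(s), rowMeans(M[, c("g1", "g3")]),
               ignore_attr = TRUE)
  expect_error(pfeSummary(M, "nope"), "no selected genes")
})
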