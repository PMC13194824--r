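test_that("bin counts conserve fragments and spread uniformly", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 20000, seed = 2))
  ct <- binCounts(fs, gm)
  expect_length(ct, length(cnvBins(gm)))
  expect_equal(sum(ct), 20000)
  gof <- chisq.test(ct)
  expect_gt(gof$p.value, 0.001)
})

test_that("baseline is a median profile robust to one outlier", {
  gm <- testModel()
  healthy <- lapply(1:5, function(i) simulateSample(gm,
    sampleProfile("healthy", target_fragment_count = 20000, seed = i)))
  outlier <- simulateSample(gm, sampleProfile("cancer",
    tumor_fraction = 0.5, arm_copy_factors = c("1q" = 3),
    target_fragment_count = 20000, seed = 99))
  clean <- buildBaseline(healthy, gm)
  spiked <- buildBaseline(c(healthy, list(outlier)), gm)
  # with 5 clean samples the median ignores a single aberrant member
  expect_lt(max(abs(clean$h - spiked$h)), 0.1 * max(clean$h))
  expect_equal(sum(clean$h[clean$usable]), 1)
  expect_error(buildBaseline(healthy[1], gm), "at least 2")
  # identical panel members reproduce the member profile
  dup <- buildBaseline(list(healthy[[1]], healthy[[1]]), gm)
  expect_equal(dup$h, cfFragSig:::binProportions(healthy[[1]], gm),
               ignore_attr = TRUE)
})

test_that("log2 ratio identities hold and masked bins stay missing", {
  h <- c(0.25, 0.25, 0.25, 0.25, 0)
  r <- c(0.25, 0.50, 0.125, 0.25, 0)
  l <- log2Ratio(r, h, usable = h > 0)
  expect_equal(l[1], 0)
  expect_equal(l[2], 1)
  expect_equal(l[3], -1)
  expect_true(is.na(l[5]))
  expect_false(any(is.infinite(l), na.rm = TRUE))
  expect_error(log2Ratio(c(-1, 1), c(1, 1)), "negative")
})

test_that("Viterbi path equals exhaustive enumeration on small instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    mu <- runif(1, 0.2, 0.7)
    sigma <- runif(1, 0.05, 0.3)
    stay <- runif(1, 0.6, 0.995)
    l <- rnorm(n, sample(c(-mu, 0, mu), n, replace = TRUE), sigma)
    expect_identical(segmentStates(l, mu, sigma, stay),
                     bruteForceViterbi(l, mu, sigma, stay))
  }
})

test_that("segmentation labels blocks and absorbs single-bin spikes", {
  expect_true(all(segmentStates(rep(0, 20)) == "neutral"))
  l <- c(rep(0, 5), rep(0.58, 4), rep(0, 5))
  st <- segmentStates(l, mu = 0.58, sigma = 0.1, stay = 0.99)
  expect_equal(st[6:9], rep("gain", 4))
  expect_equal(st[c(1:5, 10:14)], rep("neutral", 10))
  # single-bin spike below transition strength is absorbed
  spike <- c(rep(0, 6), 0.4, rep(0, 7))
  expect_true(all(segmentStates(spike, mu = 0.3, sigma = 0.15,
                                stay = 0.99) == "neutral"))
  # missing bins are skipped, not fatal
  withNA <- c(0, NA, 0.6, 0.6, NA, 0)
  st2 <- segmentStates(withNA, mu = 0.58, sigma = 0.1, stay = 0.9)
  expect_true(is.na(st2[2]) && is.na(st2[5]))
  expect_error(segmentStates(c(0, 1), sigma = 0), "positive")
})

test_that("CNV features are depth-invariant and carry arm means", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 40000, seed = 12))
  healthy <- lapply(20:23, function(i) simulateSample(gm,
    sampleProfile("healthy", target_fragment_count = 20000, seed = i)))
  bl <- buildBaseline(healthy, gm)
  full <- cnvFeatures(fs, gm, bl)
  half <- cnvFeatures(downsampleFragments(fs, fraction = 0.5, seed = 1),
                      gm, bl)
  expect_length(full, length(cnvBins(gm)) + 39)
  # proportions normalize depth out: same expectation, binomial noise only
  expect_lt(mean(abs(full - half)), 0.2)
  expect_true(all(paste0("armmean_", armVocabulary()) %in% names(full)))
})

test_that("simulated gains raise mean log2 ratio on altered arms", {
  gm <- testModel()
  healthy <- lapply(1:4, function(i) simulateSample(gm,
    sampleProfile("healthy", target_fragment_count = 20000, seed = i)))
  bl <- buildBaseline(healthy, gm)
  hits <- vapply(1:20, function(i) {
    fs <- simulateSample(gm, sampleProfile("cancer", tumor_fraction = 0.3,
      arm_copy_factors = c("1q" = 1.5, "2p" = 1.5),
      target_fragment_count = 20000, seed = 400 + i))
    fv <- cnvFeatures(fs, gm, bl)
    altered <- mean(fv[c("armmean_1q", "armmean_2p")])
    neutral <- mean(fv[paste0("armmean_",
      setdiff(names(arms(gm)), c("1q", "2p")))])
    altered > neutral
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
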