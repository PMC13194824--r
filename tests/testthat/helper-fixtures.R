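# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), .fixtures)
  get(key, envir = .fixtures)
}

# Small scaled model: 8 arms, 16 target genes, 60 background genes.
testModel <- function() memo("model", function()
  buildGenomeModel(n_arms = 8, n_target_genes = 16, background_size = 60,
                   seed = 1))

testPFEConfig <- function() pfeConfig(seed = 5)

# Small labelled train/validation cohorts with features extracted once.
# Fragment counts are reduced (15k) relative to the study default; the
# properties exercised on this fixture are depth-independent.
testCohort <- function() memo("cohort", function() {
  gm <- testModel()
  tr <- simulateCohort(gm, n_cancer = 16, n_benign = 4, n_healthy = 12,
                       cohort = "tr", tumor_fraction = 0.2,
                       target_fragment_count = 15000, master_seed = 11)
  va <- simulateCohort(gm, n_cancer = 8, n_benign = 2, n_healthy = 6,
                       cohort = "va", tumor_fraction = 0.2,
                       target_fragment_count = 15000, master_seed = 22)
  bl <- buildBaseline(tr$samples[tr$sheet$label == "healthy"], gm)
  cfg <- testPFEConfig()
  list(model = gm, train = tr, val = va, baseline = bl, pfe = cfg,
       Xtrain = extractFeatureMatrices(tr$samples, gm, bl, cfg),
       Xval = extractFeatureMatrices(va$samples, gm, bl, cfg),
       ytrain = as.integer(tr$sheet$label == "cancer"),
       yval = as.integer(va$sheet$label == "cancer"))
})

testEnsemble <- function() memo("ensemble", function() {
  co <- testCohort()
  fitEnsemble(co$Xtrain, co$ytrain, n_candidates = 12, K = 5, folds = 5,
              seed = 3)
})

# Full-scale model at the study conditions (39 arms, 370 genes).
studyModel <- function() memo("studyModel", function()
  buildGenomeModel(seed = 1))

# Full-scale cohorts at the study conditions: 40 cancer vs 40 non-cancer
# training samples, 20 vs 20 validation, tumour fraction 0.2, nominal
# per-sample depth (117k fragments).
studyCohort <- function() memo("studyCohort", function() {
  gm <- studyModel()
  tr <- simulateCohort(gm, n_cancer = 40, n_benign = 10, n_healthy = 30,
                       cohort = "train", tumor_fraction = 0.2,
                       master_seed = 101)
  va <- simulateCohort(gm, n_cancer = 20, n_benign = 5, n_healthy = 15,
                       cohort = "validation", tumor_fraction = 0.2,
                       master_seed = 202)
  bl <- buildBaseline(tr$samples[tr$sheet$label == "healthy"], gm)
  cfg <- pfeConfig(seed = 7)
  list(model = gm, baseline = bl, pfe = cfg,
       Xtrain = extractFeatureMatrices(tr$samples, gm, bl, cfg),
       Xval = extractFeatureMatrices(va$samples, gm, bl, cfg),
       ytrain = as.integer(tr$sheet$label == "cancer"),
       yval = as.integer(va$sheet$label == "cancer"))
})

# Write a BED3 file from a data.frame of (chrom, start, end).
writeBed <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}
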