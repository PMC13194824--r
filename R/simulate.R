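#' Describe one synthetic sample
#'
#' A `SampleProfile` captures the tumour-dependent distortions applied to a
#' simulated cfDNA fragment collection: the tumour fraction, a genome-wide
#' short-fragment (100-150 bp) enrichment, arm-level copy-number factors,
#' and a set of genes whose promoters release fragments from a widened
#' length distribution. With `tumor_fraction = 0` every distortion is
#' neutral regardless of the other settings.
#'
#' @param label one of `"cancer"`, `"benign"`, `"healthy"`.
#' @param tumor_fraction tumour-derived proportion of cfDNA, in `[0, 1]`.
#' @param short_fragment_boost multiplier controlling how strongly the
#'   short-fragment mixture weight grows with tumour fraction: the weight is
#'   `base * (1 + tumor_fraction * short_fragment_boost)`.
#' @param arm_copy_factors named numeric vector of relative copy multipliers
#'   per arm (e.g. `c("8q" = 1.5)`); must be positive.
#' @param entropy_boost_genes gene ids whose promoter fragments are drawn
#'   from the widened tumour length distribution; `NULL` means the model's
#'   active set when the sample is simulated.
#' @param target_fragment_count exact number of fragments to emit (the
#'   depth surrogate; the default equals 5x coverage of the default scaled
#'   genome).
#' @param seed integer seed for this sample.
#' @return A list of class `SampleProfile`.
#' @export
#' @examples
#' sampleProfile("cancer", tumor_fraction = 0.1, seed = 3)
sampleProfile <- function(label = c("healthy", "benign", "cancer"),
                          tumor_fraction = 0,
                          short_fragment_boost = 3,
                          arm_copy_factors = NULL,
                          entropy_boost_genes = NULL,
                          target_fragment_count = 117000L,
                          seed = 1L) {
  label <- match.arg(label)
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stopf("tumor_fraction must lie in [0, 1]")
  if (!is.null(arm_copy_factors)) {
    if (is.null(names(arm_copy_factors)) || any(arm_copy_factors <= 0))
      stopf("arm_copy_factors must be a named vector of positive multipliers")
  }
  if (target_fragment_count <= 0)
    stopf("target_fragment_count must be positive")
  structure(list(label = label,
                 tumor_fraction = tumor_fraction,
                 short_fragment_boost = short_fragment_boost,
                 arm_copy_factors = arm_copy_factors,
                 entropy_boost_genes = entropy_boost_genes,
                 target_fragment_count = as.integer(target_fragment_count),
                 seed = as.integer(seed)),
            class = "SampleProfile")
}

# Fragment length mixture constants (study conditions; see methods vignette):
# bulk mononucleosomal mode N(167, 10) truncated to [100, 220]; short
# component uniform on {100..150} with baseline weight 0.12 (0.04 inside
# promoter windows, where protected cores deplete short fragments).
# Promoter fragments reflect nucleosome organisation: silent promoters
# carry a strongly positioned nucleosome, hence a narrow N(167, 3) length
# distribution, while open promoters release fragments from a widened
# N(167, 25) component with probability wide_gain * openness, where
# openness is the gene's baseline activity raised towards 1 by the tumour
# fraction for entropy-boosted genes.
.SIM <- list(len_mode = 167, len_sd = 10, len_lo = 100L, len_hi = 220L,
             short_lo = 100L, short_hi = 150L, short_base = 0.12,
             short_promoter = 0.04, promoter_sd = 3, boost_sd = 25,
             wide_gain = 0.6)

#' Simulate one cfDNA sample
#'
#' Draws exactly `target_fragment_count` fragments. Genomic placement is
#' uniform within arms, with arm weights proportional to
#' `arm_length * (1 + tumor_fraction * (copy_factor - 1))` — the expected
#' coverage of a mixture of a diploid background and a tumour clone with the
#' given arm copy factors. Fragment lengths come from a two-component
#' mixture: a short component on 100-150 bp whose weight scales with
#' `tumor_fraction * short_fragment_boost`, and a mononucleosomal component
#' whose spread at promoters grows with the gene's baseline activity and,
#' for entropy-boosted genes, jumps to the widened tumour distribution with
#' probability `tumor_fraction`.
#'
#' @param model a [GenomeModel-class].
#' @param profile a [sampleProfile()].
#' @param sample_id sample identifier (defaults to the profile label plus
#'   seed).
#' @return A [FragmentSet-class]; deterministic given the profile seed.
#' @export
#' @examples
#' gm <- buildGenomeModel(n_arms = 4, n_target_genes = 8,
#'                        background_size = 30, seed = 1)
#' fs <- simulateSample(gm, sampleProfile("healthy",
#'         target_fragment_count = 2000, seed = 7))
#' fs
simulateSample <- function(model, profile,
                           sample_id = paste0(profile$label, "_",
                                              profile$seed)) {
  if (!methods::is(model, "GenomeModel") || length(model@arms) == 0)
    stopf("a non-empty GenomeModel is required")
  if (!inherits(profile, "SampleProfile"))
    stopf("profile must be a SampleProfile")
  n <- profile$target_fragment_count
  tf <- profile$tumor_fraction

  armGR <- model@arms
  armNames <- names(armGR)
  fac <- setNames(rep(1, length(armNames)), armNames)
  if (!is.null(profile$arm_copy_factors)) {
    unknown <- setdiff(names(profile$arm_copy_factors), armNames)
    if (length(unknown))
      stopf("unknown arm(s) in arm_copy_factors: %s",
            paste(unknown, collapse = ", "))
    fac[names(profile$arm_copy_factors)] <- profile$arm_copy_factors
  }
  boostGenes <- profile$entropy_boost_genes
  if (is.null(boostGenes))
    boostGenes <- model@genes$gene_id[model@genes$active]

  prom <- promoterWindows(model)
  promAct <- setNames(model@genes$activity, model@genes$gene_id)

  fr <- with_seed(profile$seed, {
    armW <- GenomicRanges::width(armGR) * (1 + tf * (fac - 1))
    armIdx <- sample.int(length(armGR), n, replace = TRUE,
                         prob = armW / sum(armW))
    mid <- GenomicRanges::start(armGR)[armIdx] - 1L +
      as.integer(floor(runif(n) * GenomicRanges::width(armGR)[armIdx]))

    # promoter membership by midpoint
    midGR <- GRanges(seqnames(armGR)[armIdx], IRanges(mid, width = 1L))
    ov <- findOverlaps(midGR, prom)
    promGene <- rep(NA_character_, n)
    promGene[queryHits(ov)] <- prom$gene_id[subjectHits(ov)]

    # promoter openness: baseline activity, raised towards 1 by the
    # tumour fraction for entropy-boosted genes; open promoters release
    # fragments from the widened N(167, 25) component
    openness <- rep(0, n)
    inProm <- !is.na(promGene)
    openness[inProm] <- promAct[promGene[inProm]]
    if (tf > 0 && length(boostGenes)) {
      atBoost <- inProm & promGene %in% boostGenes
      openness[atBoost] <- openness[atBoost] +
        (1 - openness[atBoost]) * tf
    }
    sdVec <- rep(.SIM$len_sd, n)
    sdVec[inProm] <- .SIM$promoter_sd
    wide <- runif(n) < .SIM$wide_gain * openness
    sdVec[wide] <- .SIM$boost_sd

    # short fragments are depleted at nucleosome-protected promoter cores
    wShort <- ifelse(inProm, .SIM$short_promoter, .SIM$short_base) *
      (1 + tf * profile$short_fragment_boost)
    isShort <- runif(n) < wShort
    len <- integer(n)
    len[isShort] <- .SIM$short_lo +
      as.integer(floor(runif(sum(isShort)) *
                       (.SIM$short_hi - .SIM$short_lo + 1L)))
    ns <- !isShort
    len[ns] <- rtrunc_norm_int(sum(ns), .SIM$len_mode, sdVec[ns],
                               .SIM$len_lo, .SIM$len_hi)

    s <- mid - len %/% 2L
    # keep fragments inside the chromosome
    s <- pmax.int(s, 0L)
    GRanges(seqnames(armGR)[armIdx], IRanges(s + 1L, s + len))
  })
  fr <- GenomicRanges::sort(fr)
  methods::new("FragmentSet", sampleID = sample_id, fragments = fr,
               metadata = list(source = "simulateSample",
                               profile = unclass(profile),
                               n_fragments = length(fr)))
}

#' Simulate a labelled cohort
#'
#' Generates per-sample [sampleProfile()]s from group sizes, draws each
#' sample with a seed derived from `master_seed` via [deriveSeed()], and
#' (optionally) writes one BED file per sample plus a TSV sample sheet with
#' columns `sample_id cohort label stage timepoint path`.
#'
#' Cancer samples receive a clinical stage sampled from `stage_probs` and a
#' tumour fraction from `stage_tf` (a documented configuration default, not
#' a literature-calibrated map), unless `tumor_fraction` pins a single
#' value for all cancer samples. Cancer copy-number profiles use recurrent
#' arm-level gains (1q, 5p, 6q) and losses (4p, 6p, 8p).
#'
#' @param model a [GenomeModel-class].
#' @param n_cancer,n_benign,n_healthy group sizes.
#' @param cohort cohort tag written to the sample sheet.
#' @param tumor_fraction if non-`NULL`, fixed tumour fraction for all cancer
#'   samples; otherwise drawn from `stage_tf` by stage.
#' @param stage_probs sampling probabilities of stages I/II/III for cancer.
#' @param stage_tf named tumour-fraction map per stage.
#' @param arm_gains,arm_losses arms gaining (factor 1.5) / losing (factor
#'   0.5) copies in cancer samples.
#' @param target_fragment_count fragments per sample.
#' @param short_fragment_boost passed to [sampleProfile()].
#' @param master_seed master seed; per-sample seeds are derived from it.
#' @param out_dir if non-`NULL`, directory receiving one BED per sample and
#'   `samples.tsv`; fragments are also returned in memory.
#' @return A list with `samples` (named list of [FragmentSet-class]),
#'   `sheet` (data.frame) and `profiles`.
#' @export
simulateCohort <- function(model,
                           n_cancer = 20, n_benign = 5, n_healthy = 15,
                           cohort = "train",
                           tumor_fraction = NULL,
                           stage_probs = c(I = 0.15, II = 0.65, III = 0.20),
                           stage_tf = c(I = 0.02, II = 0.05, III = 0.12),
                           arm_gains = c("1q", "5p", "6q"),
                           arm_losses = c("4p", "6p", "8p"),
                           target_fragment_count = 117000L,
                           short_fragment_boost = 3,
                           master_seed = 1L,
                           out_dir = NULL) {
  armNames <- names(model@arms)
  arm_gains <- intersect(arm_gains, armNames)
  arm_losses <- intersect(arm_losses, armNames)
  cancerFac <- c(setNames(rep(1.5, length(arm_gains)), arm_gains),
                 setNames(rep(0.5, length(arm_losses)), arm_losses))

  labels <- c(rep("cancer", n_cancer), rep("benign", n_benign),
              rep("healthy", n_healthy))
  nTot <- length(labels)
  if (nTot == 0) stopf("empty cohort configuration")
  ids <- sprintf("%s_%s_%03d", cohort, labels, seq_len(nTot))
  if (anyDuplicated(ids)) stopf("duplicate sample ids")

  stages <- rep(NA_character_, nTot)
  tfs <- rep(0, nTot)
  if (n_cancer > 0) {
    stages[labels == "cancer"] <- with_seed(deriveSeed(master_seed, 0L),
      sample(names(stage_probs), n_cancer, replace = TRUE,
             prob = stage_probs))
    tfs[labels == "cancer"] <- if (!is.null(tumor_fraction))
      tumor_fraction else unname(stage_tf[stages[labels == "cancer"]])
  }

  profiles <- vector("list", nTot)
  samples <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    isCancer <- labels[i] == "cancer"
    profiles[[i]] <- sampleProfile(
      label = labels[i],
      tumor_fraction = if (isCancer) tfs[i] else 0,
      short_fragment_boost = short_fragment_boost,
      arm_copy_factors = if (isCancer && length(cancerFac)) cancerFac
                         else NULL,
      entropy_boost_genes = NULL,
      target_fragment_count = target_fragment_count,
      seed = deriveSeed(master_seed, i))
    samples[[i]] <- simulateSample(model, profiles[[i]], sample_id = ids[i])
  }
  names(samples) <- names(profiles) <- ids

  sheet <- data.frame(sample_id = ids, cohort = cohort, label = labels,
                      stage = stages, timepoint = "baseline",
                      path = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sheet$path <- file.path(out_dir, paste0(ids, ".bed"))
    for (i in seq_len(nTot)) writeFragments(samples[[i]], sheet$path[i])
    fwrite(sheet, file.path(out_dir, "samples.tsv"), sep = "\t")
  }
  list(samples = samples, sheet = sheet, profiles = profiles)
}
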