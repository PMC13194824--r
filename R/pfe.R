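#' PFE configuration
#'
#' All tunable constants of the promoter-fragmentation-entropy statistic,
#' with the method's canonical defaults: Dirichlet prior pseudo-count mass
#' `prior_weight = 20`, `n_dirichlet = 2000` posterior draws, five control
#' entropies of 20 background genes each, margin distribution
#' `k ~ Gamma(shape = 0.5, rate = 1)`, TSS window half-width 1 kb, NDR
#' flanks 750-1000 bp, and a length support of 100-220 bp at 1-bp
#' resolution (121 cells).
#'
#' @param prior_weight Dirichlet pseudo-count mass given to the genome-wide
#'   prior length distribution.
#' @param n_dirichlet number of posterior Dirichlet draws per gene.
#' @param n_controls number of control entropy values.
#' @param genes_per_control background genes pooled per control repeat.
#' @param gamma_shape,gamma_rate parameters of the Gamma margin.
#' @param tss_halfwidth promoter window half-width (bp).
#' @param ndr_flank offsets (bp) of the prior-estimation flank on each side
#'   of an NDR.
#' @param support inclusive fragment-length support in bp.
#' @param shared_k if `TRUE` (default) one margin `k` is shared across the
#'   five controls, giving the closed form `F_Gamma(min ratio - 1)`; if
#'   `FALSE`, independent margins per control (product form).
#' @param seed seed for control gene draws and Dirichlet sampling.
#' @return A list of class `PFEConfig`.
#' @export
pfeConfig <- function(prior_weight = 20, n_dirichlet = 2000,
                      n_controls = 5, genes_per_control = 20,
                      gamma_shape = 0.5, gamma_rate = 1,
                      tss_halfwidth = 1000, ndr_flank = c(750, 1000),
                      support = c(100L, 220L), shared_k = TRUE,
                      seed = 1L) {
  vals <- c(prior_weight, n_dirichlet, n_controls, genes_per_control,
            gamma_shape, gamma_rate, tss_halfwidth, ndr_flank)
  if (any(vals <= 0)) stopf("all PFE configuration values must be positive")
  structure(list(prior_weight = prior_weight, n_dirichlet = n_dirichlet,
                 n_controls = n_controls,
                 genes_per_control = genes_per_control,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 tss_halfwidth = tss_halfwidth, ndr_flank = ndr_flank,
                 support = as.integer(support), shared_k = shared_k,
                 seed = as.integer(seed)),
            class = "PFEConfig")
}

# Count histogram of fragment lengths over the configured support.
lengthHistogram <- function(lengths, support = c(100L, 220L)) {
  cells <- support[1]:support[2]
  h <- tabulate(lengths - support[1] + 1L, nbins = length(cells))
  setNames(h, cells)
}

#' Genome-wide fragment-length prior from NDR flanks
#'
#' Pools the lengths of all fragments whose midpoints fall in the NDR
#' flank regions (750 bp - 1 kb beyond each NDR edge) and normalizes the
#' histogram over the 1-bp support. These flanks sample nucleosome-bound
#' background chromatin, so the prior captures the sample's global
#' mononucleosomal length profile.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @return Named numeric probability vector over the length support.
#' @export
priorDistribution <- function(fragset, model, config = pfeConfig()) {
  flanks <- ndrFlanks(model, config$ndr_flank)
  flanks <- IRanges::reduce(flanks)
  counts <- assignIntervals(fragset, flanks)
  asg <- attr(counts, "assignment")
  len <- fragmentLengths(fragset)
  inFlank <- !is.na(asg) & len >= config$support[1] &
    len <= config$support[2]
  if (!any(inFlank))
    stopf(paste("no fragments in NDR flanks: widen the simulation or",
                "check the NDR annotation"))
  h <- lengthHistogram(len[inFlank], config$support)
  h / sum(h)
}

#' Shannon entropy of a length distribution
#'
#' `-sum(p * log(p))` in nats, with `0 * log(0) := 0`. Count vectors are
#' normalized first.
#'
#' @param p numeric vector of probabilities or counts (non-negative).
#' @return Entropy in nats.
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stopf("negative mass in distribution")
  s <- sum(p)
  if (s == 0) stopf("empty distribution")
  p <- p / s
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

# Per-gene fragment-length count histograms (midpoint in TSS window).
geneLengthCounts <- function(fragset, model, config = pfeConfig(),
                             gene_ids = NULL) {
  prom <- promoterWindows(model, config$tss_halfwidth)
  if (!is.null(gene_ids)) prom <- prom[prom$gene_id %in% gene_ids]
  counts <- assignIntervals(fragset, prom)
  asg <- attr(counts, "assignment")
  len <- fragmentLengths(fragset)
  ok <- !is.na(asg) & len >= config$support[1] & len <= config$support[2]
  cells <- config$support[1]:config$support[2]
  out <- matrix(0L, nrow = length(prom), ncol = length(cells),
                dimnames = list(prom$gene_id, cells))
  if (any(ok)) {
    tab <- table(factor(asg[ok], levels = seq_along(prom)),
                 factor(len[ok], levels = cells))
    out <- unclass(tab)
    dimnames(out) <- list(prom$gene_id, cells)
  }
  out
}

#' Control entropies from the background gene set
#'
#' Draws `n_controls` sets of `genes_per_control` background genes without
#' replacement (independently across repeats), pools each set's TSS-window
#' fragments and returns one Shannon entropy per repeat. The same seed
#' always yields the same gene sets, so control entropies are comparable
#' across samples.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @param gene_sets optional pre-drawn list of control gene sets (as
#'   returned by [drawControlSets()]); if `NULL`, drawn from
#'   `config$seed`.
#' @return Numeric vector of `n_controls` entropies (nats).
#' @export
controlEntropies <- function(fragset, model, config = pfeConfig(),
                             gene_sets = NULL) {
  if (is.null(gene_sets)) gene_sets <- drawControlSets(model, config)
  counts <- geneLengthCounts(fragset, model, config,
                             gene_ids = unique(unlist(gene_sets)))
  vapply(gene_sets, function(gs) {
    pooled <- colSums(counts[gs, , drop = FALSE])
    if (sum(pooled) == 0)
      stopf("a control repeat pooled zero fragments")
    shannonEntropy(pooled)
  }, numeric(1))
}

#' @rdname controlEntropies
#' @export
drawControlSets <- function(model, config = pfeConfig()) {
  bg <- model@backgroundGenes
  if (length(bg) < config$genes_per_control)
    stopf("background set smaller than genes_per_control")
  with_seed(config$seed, lapply(seq_len(config$n_controls), function(i)
    sample(bg, config$genes_per_control)))
}

#' PFE score of one gene
#'
#' The central statistic. The gene's TSS-window length counts are combined
#' with the genome-wide prior as Dirichlet pseudo-counts,
#' `alpha = prior_weight * p_prior + counts`; `n_dirichlet` distributions
#' are drawn from `Dirichlet(alpha)` and the Shannon entropy `E_j` of each
#' draw is compared with the five control entropies `c_i`. With a single
#' margin `k ~ Gamma(shape, rate)` shared across controls, the probability
#' that all five ratios `E_j / c_i` exceed `1 + k` is
#' `F_Gamma(min_i E_j / c_i - 1)` when the minimum ratio exceeds 1 and 0
#' otherwise. The PFE score is the mean of these probabilities over the
#' draws, a value in `[0, 1]` that grows with promoter fragment-length
#' diversity.
#'
#' @param gene_counts integer count histogram over the length support.
#' @param prior probability vector from [priorDistribution()].
#' @param controls numeric vector of control entropies (all positive).
#' @param config a [pfeConfig()].
#' @return Score in `[0, 1]`, or `NA` if the gene has no fragments.
#' @export
genePFE <- function(gene_counts, prior, controls, config = pfeConfig()) {
  if (length(controls) != config$n_controls || any(controls <= 0))
    stopf("controls must be %d positive entropies", config$n_controls)
  if (sum(gene_counts) == 0) return(NA_real_)
  alpha <- config$prior_weight * prior + gene_counts
  if (sum(alpha) <= 0) stopf("Dirichlet parameter has zero total mass")
  nc <- length(alpha)
  nd <- config$n_dirichlet
  G <- matrix(rgamma(nc * nd, shape = alpha), nrow = nc, ncol = nd)
  P <- sweep(G, 2L, colSums(G), "/")
  PL <- P * log(P)
  PL[P == 0] <- 0
  E <- -colSums(PL)
  marginProbability(E, controls, config)
}

# Mean over draws of P(all control ratios exceed 1 + k).
marginProbability <- function(E, controls, config) {
  if (config$shared_k) {
    m <- E / max(controls)
    mean(ifelse(m > 1,
                pgamma(m - 1, shape = config$gamma_shape,
                       rate = config$gamma_rate), 0))
  } else {
    R <- outer(E, controls, "/")
    Pq <- matrix(0, nrow(R), ncol(R))
    gt <- R > 1
    Pq[gt] <- pgamma(R[gt] - 1, shape = config$gamma_shape,
                     rate = config$gamma_rate)
    mean(apply(Pq, 1L, prod))
  }
}

#' PFE result for one sample
#'
#' Computes the prior, the five control entropies and all target-gene PFE
#' scores for one sample, plus the within-sample z-normalized scores.
#' Genes with zero TSS-window fragments score `NA` and are excluded from
#' the normalization (they impute to the sample mean, 0, in model
#' matrices).
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @param gene_sets optional pre-drawn control gene sets.
#' @param draw_seed seed for the Dirichlet draws of this sample.
#' @return List with `gene_scores`, `normalized_scores`,
#'   `control_entropies` and `prior`.
#' @export
pfeSample <- function(fragset, model, config = pfeConfig(),
                      gene_sets = NULL, draw_seed = config$seed) {
  prior <- priorDistribution(fragset, model, config)
  controls <- controlEntropies(fragset, model, config, gene_sets)
  tg <- targetGenes(model)
  counts <- geneLengthCounts(fragset, model, config, gene_ids = tg)
  counts <- counts[tg, , drop = FALSE]
  scores <- with_seed(draw_seed,
    vapply(tg, function(g)
      genePFE(counts[g, ], prior, controls, config), numeric(1)))
  if (all(is.na(scores)))
    stopf("all target genes are missing for sample %s", sampleID(fragset))
  list(gene_scores = scores,
       normalized_scores = pop_zscore(scores),
       control_entropies = controls,
       prior = prior)
}

#' PFE feature matrix for a cohort
#'
#' Per sample: compute all target-gene PFE scores, then z-score across
#' genes within the sample. Control gene sets are drawn once from the
#' configuration seed and shared by all samples; Dirichlet draw seeds are
#' derived per sample, so any sample's vector is independent of cohort
#' order.
#'
#' @param fragsets named list of [FragmentSet-class] objects.
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @param impute_missing replace `NA` (zero-fragment genes) by 0 — the
#'   sample mean after normalization — as required for model matrices.
#' @return Numeric matrix, samples in rows, target genes in columns.
#' @export
pfeMatrix <- function(fragsets, model, config = pfeConfig(),
                      impute_missing = TRUE) {
  gene_sets <- drawControlSets(model, config)
  ids <- unname(vapply(fragsets, sampleID, ""))
  rows <- lapply(seq_along(fragsets), function(i) {
    res <- pfeSample(fragsets[[i]], model, config, gene_sets,
                     draw_seed = deriveSeed(config$seed,
                                            idHash(ids[i])))
    res$normalized_scores
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  if (impute_missing) out[is.na(out)] <- 0
  out
}

# Stable numeric hash of a sample id (draw seeds independent of order).
idHash <- function(id) {
  v <- utf8ToInt(id)
  as.integer(sum(v * (seq_along(v) %% 31 + 1)) %% 1000003L)
}

#' Training-only PFE feature selection
#'
#' Per gene: two-sided Wilcoxon rank-sum test of cancer vs non-cancer
#' normalized scores (exact when both groups have at most 12 samples and no
#' ties, otherwise the normal approximation with continuity correction);
#' genes with `p < 0.01` and a positive cancer-minus-noncancer mean
#' difference are selected. Must only ever see training samples.
#'
#' @param training_matrix samples x genes matrix from [pfeMatrix()].
#' @param labels binary vector (1/TRUE = cancer), one per row.
#' @param p_threshold selection threshold on the unadjusted p-value.
#' @return data.frame (gene, p, mean_diff, selected) with the selected gene
#'   ids in attribute `"selected"`.
#' @export
selectPFEFeatures <- function(training_matrix, labels, p_threshold = 0.01) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L)
    stopf("training set must contain both classes")
  res <- lapply(colnames(training_matrix), function(g) {
    a <- training_matrix[y == 1, g]
    b <- training_matrix[y == 0, g]
    ex <- length(a) <= 12 && length(b) <= 12 &&
      !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      wilcox.test(a, b, exact = ex, correct = TRUE)$p.value)
    data.frame(gene = g, p = p, mean_diff = mean(a) - mean(b))
  })
  res <- do.call(rbind, res)
  res$selected <- res$p < p_threshold & res$mean_diff > 0
  attr(res, "selected") <- res$gene[res$selected]
  res
}

#' Integrated PFE summary score
#'
#' Mean of the selected normalized PFE features per sample — a one-number
#' promoter-entropy summary for group comparisons.
#'
#' @param matrix samples x genes matrix from [pfeMatrix()].
#' @param selected_genes character vector of selected gene ids.
#' @return Named numeric vector, one value per sample.
#' @export
pfeSummary <- function(matrix, selected_genes) {
  sel <- intersect(selected_genes, colnames(matrix))
  if (!length(sel)) stopf("no selected genes present in the matrix")
  rowMeans(matrix[, sel, drop = FALSE])
}
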