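#' Build a scaled genome annotation model
#'
#' Constructs the annotation substrate used by every feature extractor: up
#' to 39 chromosome arms in a 1/1000-scale coordinate space, uniform CNV
#' bins tiling the arms, gene TSS positions with one nucleosome-depleted
#' region (NDR) per promoter, and a background control gene set that is
#' disjoint from the designated cancer-active gene set.
#'
#' Genes are placed on a regular grid of promoter slots (2.5 kb spacing,
#' 1.5 kb arm margins) so TSS windows and NDR flanks of neighbouring genes
#' never overlap. Each gene carries a baseline promoter `activity` level in
#' `[0, 1]` governing how open (hence entropy-rich) its promoter is in every
#' sample; the `active` genes model promoters that additionally open in
#' tumours and are drawn with low baseline activity.
#'
#' @param n_arms number of arms to instantiate, at most 39; arm names are
#'   taken in order from [armVocabulary()].
#' @param arm_length arm length in bp of the scaled space (default 100 kb,
#'   i.e. 1/1000 of a typical arm).
#' @param bin_width CNV bin width in bp; must divide `arm_length`.
#' @param n_target_genes number of scored (non-background) genes.
#' @param n_active number of target genes in the cancer-active set.
#' @param background_size size of the background control gene set
#'   (default 330).
#' @param ndr_halfwidth NDR half-width around the TSS in bp.
#' @param tss_halfwidth promoter window half-width around the TSS in bp.
#' @param ndr_flank two offsets (bp) delimiting the prior-estimation flank
#'   on each side of an NDR.
#' @param seed integer seed; the model is deterministic given the seed.
#' @return A [GenomeModel-class] object.
#' @export
#' @examples
#' gm <- buildGenomeModel(n_arms = 4, n_target_genes = 8,
#'                        background_size = 30, seed = 1)
#' gm
buildGenomeModel <- function(n_arms = 39,
                             arm_length = 1e5,
                             bin_width = 1e4,
                             n_target_genes = 40,
                             n_active = ceiling(n_target_genes / 2),
                             background_size = 330,
                             ndr_halfwidth = 150,
                             tss_halfwidth = 1000,
                             ndr_flank = c(750, 1000),
                             seed = 1) {
  if (n_arms < 1 || n_arms > 39)
    stopf("n_arms must be between 1 and 39 (got %s)", n_arms)
  if (arm_length %% bin_width != 0)
    stopf("bin_width (%s) must divide arm_length (%s)",
          bin_width, arm_length)
  if (n_active > n_target_genes)
    stopf("n_active cannot exceed n_target_genes")

  armNames <- armVocabulary()[seq_len(n_arms)]
  chrom <- paste0("chr", sub("[pq]$", "", armNames))
  isQ <- grepl("q$", armNames)
  hasP <- paste0("chr", sub("[pq]$", "", armNames))[!isQ]
  armStart <- ifelse(isQ & chrom %in% hasP, arm_length, 0)
  armGR <- GRanges(chrom, IRanges(armStart + 1L, armStart + arm_length))
  names(armGR) <- armNames
  armGR$arm <- armNames

  # CNV bins tiling each arm
  nb <- arm_length %/% bin_width
  binStart <- rep(armStart, each = nb) +
    rep(seq(0, arm_length - bin_width, by = bin_width), times = n_arms)
  binArm <- rep(armNames, each = nb)
  binGR <- GRanges(rep(chrom, each = nb),
                   IRanges(binStart + 1L, binStart + bin_width))
  binGR$arm <- binArm
  binGR$bin_id <- sprintf("%s_%07d", binArm, binStart)

  # promoter slots: regular grid, 2.5 kb apart, 1.5 kb margin
  spacing <- 2500
  margin <- 1500
  slotPos <- seq(margin + 500, arm_length - margin - 500, by = spacing)
  nSlots <- length(slotPos) * n_arms
  nGenes <- n_target_genes + background_size
  if (nGenes > nSlots)
    stopf("model too small: %d genes requested but only %d promoter slots",
          nGenes, nSlots)

  gm <- with_seed(seed, {
    slots <- sort(sample.int(nSlots, nGenes))
    slotArm <- (slots - 1L) %/% length(slotPos) + 1L
    tss <- armStart[slotArm] + slotPos[(slots - 1L) %% length(slotPos) + 1L]
    isBg <- c(rep(FALSE, n_target_genes), rep(TRUE, background_size))
    isBg <- isBg[sample.int(nGenes)]
    gene_id <- character(nGenes)
    gene_id[!isBg] <- sprintf("TG%03d", seq_len(n_target_genes))
    gene_id[isBg] <- sprintf("BG%03d", seq_len(background_size))
    active <- rep(FALSE, nGenes)
    active[which(!isBg)[sample.int(n_target_genes, n_active)]] <- TRUE
    # cancer-active genes are quiet at baseline; other targets follow a
    # bimodal (off/on) activity distribution as gene expression does;
    # background genes are low-expressed by definition
    activity <- stats::rbeta(nGenes, 0.25, 0.25)
    activity[active | isBg] <- runif(sum(active | isBg), 0, 0.25)
    geneGR <- GRanges(chrom[slotArm], IRanges(tss, width = 1L))
    geneGR$gene_id <- gene_id
    geneGR$gene_strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    geneGR$active <- active
    geneGR$activity <- activity
    geneGR$background <- isBg
    geneGR$arm <- armNames[slotArm]
    list(geneGR = geneGR, background = gene_id[isBg])
  })

  ndrGR <- GRanges(seqnames(gm$geneGR),
                   IRanges(start(gm$geneGR) - ndr_halfwidth,
                           start(gm$geneGR) + ndr_halfwidth))
  ndrGR$gene_id <- gm$geneGR$gene_id

  methods::new("GenomeModel",
    arms = armGR, cnvBins = binGR, genes = gm$geneGR, ndr = ndrGR,
    backgroundGenes = gm$background,
    params = list(n_arms = n_arms, arm_length = arm_length,
                  bin_width = bin_width, n_target_genes = n_target_genes,
                  n_active = n_active, background_size = background_size,
                  ndr_halfwidth = ndr_halfwidth,
                  tss_halfwidth = tss_halfwidth,
                  ndr_flank = ndr_flank, seed = seed))
}

# Promoter windows (TSS +/- tss_halfwidth), one per gene.
promoterWindows <- function(model, halfwidth = NULL) {
  hw <- if (is.null(halfwidth)) model@params$tss_halfwidth else halfwidth
  g <- model@genes
  out <- GRanges(seqnames(g), IRanges(pmax(1L, start(g) - hw),
                                      start(g) + hw))
  out$gene_id <- g$gene_id
  out
}

# NDR flank intervals (two per gene) used for the fragment-length prior.
ndrFlanks <- function(model, flank = NULL) {
  fl <- if (is.null(flank)) model@params$ndr_flank else flank
  n <- model@ndr
  left <- GRanges(seqnames(n),
                  IRanges(pmax(1L, start(n) - fl[2]), pmax(1L, start(n) - fl[1])))
  right <- GRanges(seqnames(n), IRanges(end(n) + fl[1], end(n) + fl[2]))
  out <- c(left, right)
  out$gene_id <- c(n$gene_id, n$gene_id)
  out
}
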