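#' @title Core S4 classes
#' @name cfFragSig-classes
#' @description
#' `FragmentSet` holds one sample's cfDNA fragments as a sorted `GRanges`
#' (1-based, closed; converted from BED half-open coordinates on IO) plus
#' provenance metadata. `GenomeModel` holds the annotation substrate: arms,
#' CNV bins, gene TSS, NDR intervals and the background control gene set.
#' `TrainedEnsemble` holds the fitted classifier: per-family top-K base
#' models, their out-of-fold predictions and the decision cutoff.
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FragmentSet: one sample's cfDNA fragments
#'
#' @slot sampleID single sample identifier.
#' @slot fragments sorted `GRanges`; fragment length equals `width()`.
#' @slot metadata list recording source path, filters applied and
#'   read/kept/dropped counts.
#' @export
setClass("FragmentSet",
  representation(sampleID = "character",
                 fragments = "GRanges",
                 metadata = "list"))

setValidity("FragmentSet", function(object) {
  msg <- character(0)
  if (length(object@sampleID) != 1L || is.na(object@sampleID))
    msg <- c(msg, "sampleID must be a single non-NA string")
  fr <- object@fragments
  if (length(fr)) {
    if (any(GenomicRanges::width(fr) < 1L))
      msg <- c(msg, "all fragment lengths must be positive")
    if (is.unsorted(order(as.integer(GenomicRanges::seqnames(fr)),
                          GenomicRanges::start(fr))))
      msg <- c(msg, "fragments must be sorted by (chrom, start)")
  }
  if (length(msg)) msg else TRUE
})

#' GenomeModel: annotation substrate for feature extraction
#'
#' @slot arms `GRanges` of chromosome arms, names from [armVocabulary()].
#' @slot cnvBins `GRanges` of uniform-width bins tiling the arms; mcols
#'   carry `bin_id` and `arm`.
#' @slot genes `GRanges` of width 1 at each TSS; mcols carry `gene_id`,
#'   `gene_strand`, `active` (designated cancer-activated set), `activity`
#'   (baseline promoter openness in `[0,1]`) and `background`.
#' @slot ndr `GRanges` of one nucleosome-depleted region per gene.
#' @slot backgroundGenes character vector of control gene ids.
#' @slot params list of construction parameters (bin width, window sizes,
#'   seed), consumed by feature extractors instead of hard-coded constants.
#' @export
setClass("GenomeModel",
  representation(arms = "GRanges",
                 cnvBins = "GRanges",
                 genes = "GRanges",
                 ndr = "GRanges",
                 backgroundGenes = "character",
                 params = "list"))

setValidity("GenomeModel", function(object) {
  msg <- character(0)
  if (!all(names(object@arms) %in% armVocabulary()))
    msg <- c(msg, "arm names must come from the 39-arm vocabulary")
  ids <- object@genes$gene_id
  if (anyDuplicated(ids))
    msg <- c(msg, "gene ids must be unique")
  if (length(object@ndr) != length(object@genes))
    msg <- c(msg, "every gene must have exactly one NDR")
  act <- ids[object@genes$active]
  if (length(intersect(object@backgroundGenes, act)))
    msg <- c(msg, "background gene set must be disjoint from the active set")
  if (!all(object@backgroundGenes %in% ids))
    msg <- c(msg, "backgroundGenes must be gene ids of the model")
  # bins tile arms without overlap
  if (length(object@cnvBins)) {
    byArm <- split(object@cnvBins, object@cnvBins$arm)
    for (a in names(byArm)) {
      b <- byArm[[a]]
      o <- order(GenomicRanges::start(b))
      s <- GenomicRanges::start(b)[o]; e <- GenomicRanges::end(b)[o]
      if (any(s[-1] != e[-length(e)] + 1L)) {
        msg <- c(msg, "cnv bins must tile arms without gaps or overlap")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' TrainedEnsemble: OOF-ranked, top-K-averaged classifier
#'
#' @slot families named list (CNV/FSD/PFE), each holding the top-K refit
#'   candidates, their OOF predictions and the family OOF ensemble score.
#' @slot cutoff decision threshold derived from training OOF risk scores.
#' @slot trainingScores per-training-sample OOF risk scores.
#' @slot sampleIDs training sample ids (leakage guard for `predictRisk`).
#' @slot manifest data.frame of selected base models (id, family, algorithm,
#'   hyperparameters, OOF AUC).
#' @slot config echo of the fitting configuration.
#' @export
setClass("TrainedEnsemble",
  representation(families = "list",
                 cutoff = "numeric",
                 trainingScores = "numeric",
                 sampleIDs = "character",
                 manifest = "data.frame",
                 config = "list"))

setValidity("TrainedEnsemble", function(object) {
  msg <- character(0)
  if (length(object@cutoff) != 1L)
    msg <- c(msg, "cutoff must be a single number")
  if (length(object@trainingScores) != length(object@sampleIDs))
    msg <- c(msg, "one training OOF score per training sample is required")
  if (length(msg)) msg else TRUE
})
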