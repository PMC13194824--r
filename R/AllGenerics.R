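# Accessors and show methods for the core classes.

#' @rdname FragmentSet-class
#' @param object,x a `FragmentSet`.
#' @export
setGeneric("sampleID", function(object) standardGeneric("sampleID"))

#' @rdname FragmentSet-class
#' @export
setMethod("sampleID", "FragmentSet", function(object) object@sampleID)

#' @rdname FragmentSet-class
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(object) object@fragments)

#' @rdname FragmentSet-class
#' @export
setGeneric("nFragments", function(object) standardGeneric("nFragments"))

#' @rdname FragmentSet-class
#' @export
setMethod("nFragments", "FragmentSet",
          function(object) length(object@fragments))

#' Fragment lengths in bp (`end - start` in BED half-open coordinates)
#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentLengths", function(object)
  standardGeneric("fragmentLengths"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentLengths", "FragmentSet",
          function(object) GenomicRanges::width(object@fragments))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentMetadata", function(object)
  standardGeneric("fragmentMetadata"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentMetadata", "FragmentSet", function(object) object@metadata)

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet <", object@sampleID, ">: ",
      length(object@fragments), " fragments", sep = "")
  if (length(object@fragments)) {
    w <- GenomicRanges::width(object@fragments)
    cat(sprintf(" | length median %d bp [%d-%d]",
                as.integer(median(w)), min(w), max(w)))
  }
  cat("\n")
  if (length(object@metadata$filters))
    cat("  filters:", paste(unlist(object@metadata$filters),
                            collapse = ", "), "\n")
})

#' @rdname GenomeModel-class
#' @param object a `GenomeModel`.
#' @export
setGeneric("arms", function(object) standardGeneric("arms"))

#' @rdname GenomeModel-class
#' @export
setMethod("arms", "GenomeModel", function(object) object@arms)

#' @rdname GenomeModel-class
#' @export
setGeneric("cnvBins", function(object) standardGeneric("cnvBins"))

#' @rdname GenomeModel-class
#' @export
setMethod("cnvBins", "GenomeModel", function(object) object@cnvBins)

#' @rdname GenomeModel-class
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname GenomeModel-class
#' @export
setMethod("genes", "GenomeModel", function(object) object@genes)

#' @rdname GenomeModel-class
#' @export
setGeneric("ndrRegions", function(object) standardGeneric("ndrRegions"))

#' @rdname GenomeModel-class
#' @export
setMethod("ndrRegions", "GenomeModel", function(object) object@ndr)

#' @rdname GenomeModel-class
#' @export
setGeneric("backgroundGenes", function(object)
  standardGeneric("backgroundGenes"))

#' @rdname GenomeModel-class
#' @export
setMethod("backgroundGenes", "GenomeModel",
          function(object) object@backgroundGenes)

#' Ids of genes scored by the PFE stage (all non-background genes)
#' @rdname GenomeModel-class
#' @export
setGeneric("targetGenes", function(object) standardGeneric("targetGenes"))

#' @rdname GenomeModel-class
#' @export
setMethod("targetGenes", "GenomeModel", function(object)
  object@genes$gene_id[!object@genes$background])

#' @rdname GenomeModel-class
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname GenomeModel-class
#' @export
setMethod("modelParams", "GenomeModel", function(object) object@params)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel: ", length(object@arms), " arms, ",
      length(object@cnvBins), " CNV bins (width ",
      object@params$bin_width, "), ", length(object@genes), " genes (",
      sum(!object@genes$background), " target / ",
      length(object@backgroundGenes), " background)\n", sep = "")
})

#' @rdname TrainedEnsemble-class
#' @param object a `TrainedEnsemble`.
#' @export
setGeneric("ensembleCutoff", function(object)
  standardGeneric("ensembleCutoff"))

#' @rdname TrainedEnsemble-class
#' @export
setMethod("ensembleCutoff", "TrainedEnsemble", function(object) object@cutoff)

#' Selected-model manifest (id, family, algorithm, hyperparameters, OOF AUC)
#' @rdname TrainedEnsemble-class
#' @export
setGeneric("ensembleManifest", function(object)
  standardGeneric("ensembleManifest"))

#' @rdname TrainedEnsemble-class
#' @export
setMethod("ensembleManifest", "TrainedEnsemble",
          function(object) object@manifest)

#' Out-of-fold risk scores of the training samples
#' @rdname TrainedEnsemble-class
#' @export
setGeneric("trainingScores", function(object)
  standardGeneric("trainingScores"))

#' @rdname TrainedEnsemble-class
#' @export
setMethod("trainingScores", "TrainedEnsemble", function(object)
  setNames(object@trainingScores, object@sampleIDs))

setMethod("show", "TrainedEnsemble", function(object) {
  cat("TrainedEnsemble: ", nrow(object@manifest), " base models (",
      paste(vapply(object@families, function(f) length(f$candidates), 1L),
            collapse = "/"), " per family ",
      paste(names(object@families), collapse = "/"),
      "), cutoff ", signif(object@cutoff, 3), "\n", sep = "")
})
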