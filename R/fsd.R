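#' Fragment-size-distribution proportions per arm
#'
#' Fragment lengths are binned in 5-bp intervals (100-104, 105-109, ...,
#' 215-219 bp; 24 bins) separately for each of the 39 chromosome arms, and
#' converted to proportions using the arm's in-range fragment total.
#' Lengths of 220 bp and above are excluded (the last bin ends at 219).
#' Arms absent from a scaled model, or with zero in-range fragments, emit
#' zeros (with a warning for the latter) so the feature schema is always
#' 24 x 39.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param denominator `"arm"` (default: per-arm totals) or `"genome"`
#'   (a single genome-wide total).
#' @return 39 x 24 numeric matrix (arms x length bins), rows named by the
#'   arm vocabulary, columns `bin100_104`, ..., `bin215_219`.
#' @export
fsdProportions <- function(fragset, model,
                           denominator = c("arm", "genome")) {
  denominator <- match.arg(denominator)
  edges <- seq(100L, 215L, by = 5L)
  binNames <- sprintf("bin%d_%d", edges, edges + 4L)
  allArms <- armVocabulary()
  counts <- matrix(0, nrow = length(allArms), ncol = 24L,
                   dimnames = list(allArms, binNames))

  fr <- fragset@fragments
  if (length(fr)) {
    asg <- assignIntervals(fragset, model@arms)
    armIdx <- attr(asg, "assignment")
    len <- GenomicRanges::width(fr)
    ok <- !is.na(armIdx) & len >= 100L & len <= 219L
    if (any(ok)) {
      armName <- names(model@arms)[armIdx[ok]]
      lenBin <- (len[ok] - 100L) %/% 5L + 1L
      tab <- table(factor(armName, levels = allArms),
                   factor(lenBin, levels = 1:24))
      counts <- counts + unclass(tab)
    }
  }
  tot <- if (denominator == "arm") rowSums(counts) else
    rep(sum(counts), nrow(counts))
  present <- rownames(counts) %in% names(model@arms)
  if (any(present & rowSums(counts) == 0))
    warning("arm(s) with zero in-range fragments: ",
            paste(rownames(counts)[present & rowSums(counts) == 0],
                  collapse = ", "), call. = FALSE)
  prop <- counts
  nz <- tot > 0
  prop[nz, ] <- counts[nz, , drop = FALSE] / tot[nz]
  prop
}

#' Within-sample z-scoring of an FSD vector
#'
#' Standardizes the full 936-entry proportion vector of one sample using
#' that sample's own mean and population (divisor `n`) standard deviation;
#' a degenerate (constant) vector maps to all zeros. This purely
#' within-sample normalization is what makes the features portable across
#' cohorts.
#'
#' @param x numeric vector (or matrix flattened row-wise).
#' @return z-scored vector of the same shape.
#' @export
zscoreWithinSample <- function(x) {
  dims <- dim(x)
  z <- pop_zscore(as.numeric(x))
  dim(z) <- dims
  dimnames(z) <- dimnames(x)
  z
}

#' FSD feature vector for one sample
#'
#' The 936 within-sample z-scored proportions, named `<arm>_bin<lo>_<hi>`.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param denominator see [fsdProportions()].
#' @return Named numeric vector of length 936.
#' @export
fsdFeatures <- function(fragset, model, denominator = c("arm", "genome")) {
  prop <- fsdProportions(fragset, model, denominator)
  z <- zscoreWithinSample(prop)
  nm <- as.vector(outer(rownames(prop), colnames(prop), paste, sep = "_"))
  setNames(as.vector(z), nm)
}

#' FSD feature matrix for a cohort
#'
#' @param fragsets named list of [FragmentSet-class] objects.
#' @param model,denominator see [fsdFeatures()].
#' @return Numeric matrix, samples in rows, 936 columns.
#' @export
fsdFeatureMatrix <- function(fragsets, model,
                             denominator = c("arm", "genome")) {
  rows <- lapply(fragsets, fsdFeatures, model = model,
                 denominator = denominator)
  out <- do.call(rbind, rows)
  rownames(out) <- unname(vapply(fragsets, sampleID, ""))
  out
}
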