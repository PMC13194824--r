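#' Per-bin fragment counts
#'
#' Midpoint-assigned fragment counts over the model's CNV bins. The genome
#' is partitioned into uniform bins (1 Mb at full scale; taken from the
#' [GenomeModel-class], never hard-coded) and each fragment contributes to
#' the bin containing its midpoint.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @return Named integer vector of counts, one per bin in model order.
#' @export
binCounts <- function(fragset, model) {
  counts <- assignIntervals(fragset, model@cnvBins)
  out <- counts[seq_len(length(model@cnvBins))]
  attr(out, "assignment") <- NULL
  out
}

# Normalized per-bin proportions (depth cancels out).
binProportions <- function(fragset, model) {
  ct <- binCounts(fragset, model)
  tot <- sum(ct)
  if (tot == 0) stopf("no fragments fall into any CNV bin")
  ct / tot
}

#' Build a healthy copy-number baseline
#'
#' Per-bin median of each healthy sample's normalized bin proportions,
#' renormalized to sum one over usable bins. Bins with zero median are
#' flagged unusable (the analogue of mappability-filtered bins) and masked
#' from log2 ratios downstream. The median makes the reference robust to a
#' minority of aberrant panel members.
#'
#' @param fragsets list of healthy-donor [FragmentSet-class] objects
#'   (at least 2).
#' @param model a [GenomeModel-class].
#' @return data.frame with columns `bin_id`, `chrom`, `start`, `end`,
#'   `arm`, `h` (baseline proportion) and `usable`.
#' @export
buildBaseline <- function(fragsets, model) {
  if (length(fragsets) < 2L)
    stopf("a baseline panel needs at least 2 healthy samples")
  P <- vapply(fragsets, binProportions, numeric(length(model@cnvBins)),
              model = model)
  h <- apply(P, 1L, median)
  usable <- h > 0
  h[usable] <- h[usable] / sum(h[usable])
  b <- model@cnvBins
  data.frame(bin_id = b$bin_id, chrom = as.character(seqnames(b)),
             start = start(b) - 1L, end = end(b), arm = b$arm,
             h = h, usable = usable, stringsAsFactors = FALSE)
}

#' Write / read a baseline reference as TSV
#' @param baseline data.frame from [buildBaseline()].
#' @param path TSV path.
#' @return `path` (write) or the baseline data.frame (read).
#' @export
writeBaseline <- function(baseline, path) {
  fwrite(baseline, path, sep = "\t")
  invisible(path)
}

#' @rdname writeBaseline
#' @export
readBaseline <- function(path) {
  as.data.frame(fread(path, sep = "\t"))
}

#' Bin-level log2 copy ratio
#'
#' `l_t = log2(r_t / h_t)` where `r_t` is the sample's normalized bin
#' proportion and `h_t` the baseline proportion. Unusable bins (baseline
#' zero) yield `NA`, never infinities.
#'
#' @param r numeric vector of sample proportions.
#' @param h numeric vector of baseline proportions, same length.
#' @param usable logical mask of usable bins (default `h > 0`).
#' @return Numeric vector `l` with `NA` at masked bins.
#' @export
log2Ratio <- function(r, h, usable = h > 0) {
  if (length(r) != length(h)) stopf("r and h must be aligned")
  if (any(r < 0, na.rm = TRUE)) stopf("negative proportions in r")
  l <- rep(NA_real_, length(r))
  ok <- usable & !is.na(r) & r > 0
  l[ok] <- log2(r[ok] / h[ok])
  l[usable & !is.na(r) & r == 0] <- NA_real_  # zero-count bins stay missing
  l
}

#' Three-state Viterbi segmentation of log2 ratios
#'
#' A simplified copy-number smoother: hidden states `{loss, neutral, gain}`
#' with Gaussian emissions centred at `-mu`, `0`, `+mu` (shared `sigma`),
#' symmetric transitions with stay-probability `stay`, and a uniform initial
#' distribution. Missing bins are skipped (the chain continues across
#' them). Defaults are chosen so single-bin noise does not segment.
#'
#' @param l numeric vector of bin-level log2 ratios (`NA` = missing).
#' @param mu emission mean magnitude for gain/loss states.
#' @param sigma shared emission standard deviation; must be positive.
#' @param stay self-transition probability.
#' @return Character vector of states per bin (`NA` where `l` is missing).
#' @export
segmentStates <- function(l, mu = 0.3, sigma = 0.15, stay = 0.99) {
  if (sigma <= 0) stopf("sigma must be positive")
  states <- c("loss", "neutral", "gain")
  obs <- which(!is.na(l))
  out <- rep(NA_character_, length(l))
  if (!length(obs)) return(out)
  x <- l[obs]
  means <- c(-mu, 0, mu)
  nT <- length(x)
  logTrans <- matrix(log((1 - stay) / 2), 3, 3)
  diag(logTrans) <- log(stay)
  em <- vapply(means, function(m) dnorm(x, m, sigma, log = TRUE),
               numeric(nT))
  em <- matrix(em, nrow = nT)
  delta <- matrix(-Inf, nT, 3)
  psi <- matrix(0L, nT, 3)
  delta[1, ] <- log(1 / 3) + em[1, ]
  if (nT > 1) {
    for (t in 2:nT) {
      for (j in 1:3) {
        cand <- delta[t - 1, ] + logTrans[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- cand[psi[t, j]] + em[t, j]
      }
    }
  }
  path <- integer(nT)
  path[nT] <- which.max(delta[nT, ])
  if (nT > 1) for (t in (nT - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  out[obs] <- states[path]
  out
}

#' Copy-number feature vector for one sample
#'
#' Bin-level log2 ratios (masked bins imputed to 0, i.e. neutral) plus the
#' 39 per-arm mean log2 ratios; optionally per-bin segment means from the
#' Viterbi smoother instead of raw bin values.
#'
#' @param fragset a [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param baseline data.frame from [buildBaseline()] /[readBaseline()].
#' @param use_segment_means replace bin-level values by the mean of their
#'   Viterbi segment.
#' @param hmm list of smoother parameters (`mu`, `sigma`, `stay`).
#' @return Named numeric vector: `bin_<bin_id>` entries followed by
#'   `armmean_<arm>` entries for the full 39-arm vocabulary (arms absent
#'   from the model occupy zero-valued slots, keeping the schema fixed).
#' @export
cnvFeatures <- function(fragset, model, baseline,
                        use_segment_means = FALSE,
                        hmm = list(mu = 0.3, sigma = 0.15, stay = 0.99)) {
  if (!identical(baseline$bin_id, model@cnvBins$bin_id))
    stopf("baseline does not match the model's bins")
  r <- binProportions(fragset, model)
  l <- log2Ratio(r, baseline$h, baseline$usable)
  if (use_segment_means) {
    st <- segmentStates(l, hmm$mu, hmm$sigma, hmm$stay)
    runs <- rle(paste0(st, ""))
    idx <- rep(seq_along(runs$lengths), runs$lengths)
    segMean <- tapply(l, idx, function(v) mean(v, na.rm = TRUE))
    l <- as.numeric(segMean[as.character(idx)])
  }
  armOfBin <- model@cnvBins$arm
  allArms <- armVocabulary()
  armMean <- setNames(numeric(length(allArms)), allArms)
  mm <- tapply(l, armOfBin, function(v) mean(v, na.rm = TRUE))
  mm[is.na(mm)] <- 0
  armMean[names(mm)] <- mm
  lImp <- ifelse(is.na(l), 0, l)
  c(setNames(lImp, paste0("bin_", baseline$bin_id)),
    setNames(armMean, paste0("armmean_", allArms)))
}

#' CNV feature matrix for a cohort
#'
#' @param fragsets named list of [FragmentSet-class] objects.
#' @param model,baseline,use_segment_means,hmm see [cnvFeatures()].
#' @return Numeric matrix, samples in rows.
#' @export
cnvFeatureMatrix <- function(fragsets, model, baseline,
                             use_segment_means = FALSE,
                             hmm = list(mu = 0.3, sigma = 0.15,
                                        stay = 0.99)) {
  rows <- lapply(fragsets, cnvFeatures, model = model, baseline = baseline,
                 use_segment_means = use_segment_means, hmm = hmm)
  out <- do.call(rbind, rows)
  rownames(out) <- unname(vapply(fragsets, sampleID, ""))
  out
}
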