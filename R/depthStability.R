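#' Build a composite reference sample within a stratum
#'
#' Merges fragments of same-stratum samples (never mixing cancer and
#' non-cancer) until the cumulative count reaches
#' `target_multiple * nominal_count`, emulating the construction of
#' high-depth composite references from individual low-pass samples.
#'
#' @param fragsets list of [FragmentSet-class] objects from one stratum
#'   (at least 2).
#' @param target_multiple composite depth as a multiple of the nominal
#'   per-sample depth (default 10, the analogue of 50x references built
#'   from 5x samples).
#' @param nominal_count nominal per-sample fragment count; defaults to the
#'   median member count.
#' @param stratum label recorded in the metadata.
#' @param composite_id id of the resulting set.
#' @return A merged, sorted [FragmentSet-class].
#' @export
buildComposite <- function(fragsets, target_multiple = 10,
                           nominal_count = NULL,
                           stratum = "stratum",
                           composite_id = paste0("composite_", stratum)) {
  if (length(fragsets) < 2L)
    stopf("a composite needs at least 2 samples")
  counts <- vapply(fragsets, nFragments, 1L)
  if (is.null(nominal_count)) nominal_count <- median(counts)
  target <- target_multiple * nominal_count
  if (sum(counts) < target)
    stopf("insufficient fragments: %d available, %d required (short %d)",
          sum(counts), as.integer(target),
          as.integer(target - sum(counts)))
  cum <- cumsum(counts)
  k <- which(cum >= target)[1]
  merged <- GenomicRanges::sort(do.call(c, lapply(fragsets[seq_len(k)],
                                                  fragments)))
  methods::new("FragmentSet", sampleID = composite_id, fragments = merged,
    metadata = list(source = "buildComposite", stratum = stratum,
                    members = vapply(fragsets[seq_len(k)], sampleID, ""),
                    nominal_count = nominal_count,
                    target_multiple = target_multiple))
}

#' PFE vectors across a depth series
#'
#' For each depth fraction, downsamples the composite without replacement
#' and recomputes the full PFE pipeline from scratch — NDR-flank prior,
#' control entropies, gene scores and within-sample normalization (prior
#' reuse from the reference is available behind `reuse_prior`).
#'
#' @param composite a composite [FragmentSet-class].
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @param depth_fractions fractions of the composite to retain; the
#'   defaults mirror target depths of 40/30/20/10/5x against a 50x
#'   reference.
#' @param seed seed for the downsampling draws.
#' @param reuse_prior reuse the reference prior instead of recomputing it
#'   at each depth.
#' @return Matrix genes x (1 + length(depth_fractions)): the reference
#'   normalized PFE vector (`reference` column) followed by one column per
#'   fraction.
#' @export
depthSeries <- function(composite, model, config = pfeConfig(),
                        depth_fractions = c(40, 30, 20, 10, 5) / 50,
                        seed = 1L, reuse_prior = FALSE) {
  gene_sets <- drawControlSets(model, config)
  refRes <- pfeSample(composite, model, config, gene_sets,
                      draw_seed = deriveSeed(config$seed, 1L))
  out <- matrix(NA_real_, nrow = length(refRes$normalized_scores),
                ncol = 1 + length(depth_fractions),
                dimnames = list(names(refRes$gene_scores),
                                c("reference",
                                  sprintf("frac%g", depth_fractions))))
  out[, 1] <- refRes$normalized_scores
  for (i in seq_along(depth_fractions)) {
    fr <- depth_fractions[i]
    if (fr >= 1) {            # full depth is the reference itself
      out[, i + 1] <- out[, 1]
      next
    }
    ds <- downsampleFragments(composite, fraction = fr,
                              seed = deriveSeed(seed, i))
    res <- if (reuse_prior) {
      controls <- controlEntropies(ds, model, config, gene_sets)
      tg <- targetGenes(model)
      counts <- geneLengthCounts(ds, model, config, gene_ids = tg)
      sc <- with_seed(deriveSeed(config$seed, 100L + i),
        vapply(tg, function(g)
          genePFE(counts[g, ], refRes$prior, controls, config),
          numeric(1)))
      list(normalized_scores = pop_zscore(sc))
    } else {
      pfeSample(ds, model, config, gene_sets,
                draw_seed = deriveSeed(config$seed, 100L + i))
    }
    out[, i + 1] <- res$normalized_scores
  }
  out
}

#' Depth-concordance report
#'
#' Pearson correlation of each depth's PFE vector against the reference
#' vector of the same composite; genes missing at either depth are dropped
#' pairwise.
#'
#' @param series matrix from [depthSeries()].
#' @param composite_id,stratum labels carried into the report.
#' @return data.frame (composite_id, stratum, depth, pearson_r).
#' @export
depthCorrelation <- function(series, composite_id = "composite",
                             stratum = NA_character_) {
  ref <- series[, "reference"]
  depths <- setdiff(colnames(series), "reference")
  r <- vapply(depths, function(d) {
    ok <- !is.na(ref) & !is.na(series[, d])
    if (sum(ok) < 3L) stopf("fewer than 3 shared genes at depth %s", d)
    cor(ref[ok], series[ok, d])
  }, numeric(1))
  data.frame(composite_id = composite_id, stratum = stratum,
             depth = depths, pearson_r = unname(r),
             stringsAsFactors = FALSE)
}

#' End-to-end depth-stability study on synthetic composites
#'
#' Simulates per-stratum cohorts, builds `n_composites` composite
#' references at `target_multiple` times the nominal per-sample depth,
#' downsamples each to the requested fractions and reports the Pearson
#' concordance of the recomputed PFE vectors with the reference.
#'
#' @param model a [GenomeModel-class].
#' @param config a [pfeConfig()].
#' @param n_composites total composites (split between cancer and
#'   non-cancer strata).
#' @param samples_per_composite samples merged per composite.
#' @param target_fragment_count nominal per-sample fragment count.
#' @param tumor_fraction tumour fraction of cancer stratum members.
#' @param depth_fractions see [depthSeries()].
#' @param seed master seed.
#' @return data.frame as in [depthCorrelation()], all composites stacked.
#' @export
depthStabilityStudy <- function(model, config = pfeConfig(),
                                n_composites = 10,
                                samples_per_composite = 10,
                                target_fragment_count = 117000L,
                                tumor_fraction = 0.05,
                                depth_fractions = c(40, 30, 20, 10, 5) / 50,
                                seed = 1L) {
  nCancer <- ceiling(n_composites / 2)
  out <- vector("list", n_composites)
  for (i in seq_len(n_composites)) {
    stratum <- if (i <= nCancer) "cancer" else "non-cancer"
    cseed <- deriveSeed(seed, 500L + i)
    members <- lapply(seq_len(samples_per_composite), function(j) {
      prof <- sampleProfile(
        label = if (stratum == "cancer") "cancer" else "healthy",
        tumor_fraction = if (stratum == "cancer") tumor_fraction else 0,
        arm_copy_factors = if (stratum == "cancer") {
          fac <- c("1q" = 1.5, "5p" = 1.5, "4p" = 0.5)
          fac[names(fac) %in% names(arms(model))]
        } else NULL,
        target_fragment_count = target_fragment_count,
        seed = deriveSeed(cseed, j))
      simulateSample(model, prof,
                     sample_id = sprintf("comp%02d_m%02d", i, j))
    })
    comp <- buildComposite(members,
                           target_multiple = samples_per_composite,
                           nominal_count = target_fragment_count,
                           stratum = stratum,
                           composite_id = sprintf("composite%02d", i))
    series <- depthSeries(comp, model, config, depth_fractions,
                          seed = deriveSeed(cseed, 999L))
    out[[i]] <- depthCorrelation(series, sampleID(comp), stratum)
  }
  do.call(rbind, out)
}
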