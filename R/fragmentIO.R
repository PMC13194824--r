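#' Read fragments from a BED3(+) file
#'
#' Parses a (optionally gzipped) BED file with at least three columns,
#' applies the inclusive fragment-length filter `lo <= end - start <= hi`,
#' rejects records with `end <= start` (counted, not fatal), and returns a
#' sorted [FragmentSet-class]. Coordinates follow the BED convention:
#' 0-based half-open, so the fragment length is `end - start`.
#'
#' @param path BED3+ file; extra columns are ignored.
#' @param length_range inclusive `[lo, hi]` length filter in bp; `NULL`
#'   disables filtering.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return A [FragmentSet-class] with read/kept/dropped counts in its
#'   metadata. An empty file yields an empty set, not an error.
#' @export
readFragments <- function(path, length_range = c(100, 220),
                          sample_id = sub("\\.bed(\\.gz)?$", "",
                                          basename(path))) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rt")
      on.exit(close(con), add = TRUE)
      txt <- readLines(con)
      if (!length(txt)) data.table() else
        suppressWarnings(fread(text = txt, header = FALSE, sep = "\t",
                               fill = TRUE,
                               colClasses = list(character = 1)))
    } else {
      suppressWarnings(fread(path, header = FALSE, sep = "\t",
                             fill = TRUE,
                             colClasses = list(character = 1)))
    }
  }, error = function(e) stopf("failed to parse %s: %s", path,
                               conditionMessage(e)))
  if (nrow(dt) == 0L) {
    return(methods::new("FragmentSet", sampleID = sample_id,
      fragments = GRanges(),
      metadata = list(source = path, filters = list(),
                      n_read = 0L, n_kept = 0L, n_dropped = 0L)))
  }
  if (ncol(dt) < 3L) stopf("%s: BED3 requires at least 3 columns", path)
  s <- suppressWarnings(as.numeric(dt[[2]]))
  e <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stopf("%s: malformed coordinates at line %d", path, bad[1])

  nRead <- nrow(dt)
  invalid <- e <= s
  keep <- !invalid
  if (!is.null(length_range)) {
    len <- e - s
    keep <- keep & len >= length_range[1] & len <= length_range[2]
  }
  fr <- GRanges(dt[[1]][keep], IRanges(as.integer(s[keep]) + 1L,
                                       as.integer(e[keep])))
  fr <- GenomicRanges::sort(fr)
  methods::new("FragmentSet", sampleID = sample_id, fragments = fr,
    metadata = list(source = path,
                    filters = if (is.null(length_range)) list() else
                      list(length_range = length_range),
                    n_read = nRead, n_kept = sum(keep),
                    n_dropped = nRead - sum(keep),
                    n_invalid = sum(invalid)))
}

#' Write a FragmentSet as BED3
#'
#' @param fragset a [FragmentSet-class].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeFragments <- function(fragset, path) {
  fr <- fragset@fragments
  dt <- data.table(chrom = as.character(seqnames(fr)),
                   start = start(fr) - 1L, end = end(fr))
  fwrite(dt, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Randomly downsample a FragmentSet
#'
#' Simple random sampling without replacement, re-sorted, deterministic
#' given `seed` — the depth-reduction primitive of the stability analysis.
#'
#' @param fragset a [FragmentSet-class].
#' @param target_count exact number of fragments to keep (mutually
#'   exclusive with `fraction`).
#' @param fraction fraction in `(0, 1]` of fragments to keep.
#' @param seed integer seed.
#' @return A [FragmentSet-class] with the subset.
#' @export
downsampleFragments <- function(fragset, target_count = NULL,
                                fraction = NULL, seed = 1L) {
  n <- length(fragset@fragments)
  if (is.null(target_count) == is.null(fraction))
    stopf("give exactly one of target_count or fraction")
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1)
      stopf("fraction must lie in (0, 1]")
    target_count <- as.integer(round(fraction * n))
  }
  if (target_count > n)
    stopf("target_count (%d) exceeds available fragments (%d)",
          target_count, n)
  idx <- with_seed(seed, sort(sample.int(n, target_count)))
  methods::new("FragmentSet", sampleID = fragset@sampleID,
    fragments = fragset@fragments[idx],
    metadata = modifyList(fragset@metadata,
      list(downsampled_to = target_count, downsample_seed = seed)))
}

#' Assign fragments to intervals by midpoint containment
#'
#' The fragment midpoint `floor((start0 + end0) / 2)` (BED coordinates) is
#' located within a track of non-overlapping half-open intervals. Fragments
#' outside every interval are grouped under `"unassigned"`.
#'
#' @param fragset a [FragmentSet-class].
#' @param intervals `GRanges` track; must be disjoint. Interval names come
#'   from `names()`, an `id`-like metadata column, or are synthesized.
#' @return Integer vector of fragment counts per interval (named, in track
#'   order) with a trailing `"unassigned"` entry, plus attribute
#'   `"assignment"`: the per-fragment interval index (`NA` = unassigned).
#' @export
assignIntervals <- function(fragset, intervals) {
  if (!IRanges::isDisjoint(intervals))
    stopf("intervals within one track must be non-overlapping")
  nm <- names(intervals)
  if (is.null(nm)) {
    mc <- mcols(intervals)
    idcol <- intersect(c("bin_id", "gene_id", "id", "name"), colnames(mc))
    nm <- if (length(idcol)) as.character(mc[[idcol[1]]]) else
      sprintf("iv%05d", seq_along(intervals))
  }
  fr <- fragset@fragments
  counts <- setNames(integer(length(intervals) + 1L), c(nm, "unassigned"))
  assignment <- rep(NA_integer_, length(fr))
  if (length(fr)) {
    # midpoint in BED space; +1 to 1-based for overlap with GRanges track
    mid0 <- (start(fr) - 1L + end(fr)) %/% 2L
    midGR <- GRanges(seqnames(fr), IRanges(mid0 + 1L, width = 1L))
    ov <- suppressWarnings(
      findOverlaps(midGR, intervals, select = "first"))
    assignment <- ov
    tab <- tabulate(ov, nbins = length(intervals))
    counts[seq_along(intervals)] <- tab
    counts["unassigned"] <- sum(is.na(ov))
  }
  attr(counts, "assignment") <- assignment
  counts
}
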