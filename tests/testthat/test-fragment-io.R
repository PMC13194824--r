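test_that("length filter is inclusive on both ends and lengths are end - start", {
  bed <- writeBed(data.frame(
    chrom = "chr1",
    start = c(1000, 2000, 3000, 4000, 5000),
    end = c(1090, 2100, 3160, 4220, 5240)))  # lengths 90,100,160,220,240
  fs <- readFragments(bed, length_range = c(100, 220), sample_id = "s")
  expect_equal(nFragments(fs), 3)
  expect_setequal(fragmentLengths(fs), c(100, 160, 220))
  expect_equal(fragmentMetadata(fs)$n_read, 5)
  expect_equal(fragmentMetadata(fs)$n_dropped, 2)
  # half-open convention: (1000, 1167) has length 167
  bed2 <- writeBed(data.frame(chrom = "chr1", start = 1000, end = 1167))
  expect_equal(fragmentLengths(readFragments(bed2)), 167)
})

test_that("empty files and invalid records are handled without dying", {
  empty <- tempfile(fileext = ".bed"); file.create(empty)
  fs <- readFragments(empty)
  expect_equal(nFragments(fs), 0)
  # end <= start is rejected and counted, not fatal
  bed <- writeBed(data.frame(chrom = "chr1", start = c(100, 500),
                             end = c(50, 667)))
  fs2 <- readFragments(bed, length_range = c(100, 220))
  expect_equal(nFragments(fs2), 1)
  expect_equal(fragmentMetadata(fs2)$n_invalid, 1)
  # malformed coordinates raise with a line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t267", "chr1\tnope\t350"), bad)
  expect_error(readFragments(bad), "line 2")
})

test_that("read -> write -> read round-trips records and handles gzip", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 2000, seed = 8))
  gz <- tempfile(fileext = ".bed.gz")
  writeFragments(fs, gz)
  back <- readFragments(gz, length_range = NULL, sample_id = sampleID(fs))
  expect_identical(GenomicRanges::granges(fragments(back)),
                   GenomicRanges::granges(fragments(fs)))
})

test_that("downsampling is exact, nested and deterministic", {
  gm <- testModel()
  fs <- simulateSample(gm, sampleProfile("healthy",
    target_fragment_count = 1000, seed = 8))
  d1 <- downsampleFragments(fs, target_count = 100, seed = 3)
  expect_equal(nFragments(d1), 100)
  ov <- GenomicRanges::countOverlaps(fragments(d1), fragments(fs),
                                     type = "equal")
  expect_true(all(ov >= 1))
  expect_identical(fragments(downsampleFragments(fs, fraction = 1,
                                                 seed = 1)),
                   fragments(fs))
  expect_identical(fragments(downsampleFragments(fs, 100, seed = 3)),
                   fragments(d1))
  expect_error(downsampleFragments(fs, target_count = 2000, seed = 1),
               "exceeds")
  expect_error(downsampleFragments(fs), "exactly one")
})

test_that("interval assignment uses half-open midpoint containment", {
  mk <- function(chrom, s, e) {
    methods::new("FragmentSet", sampleID = "x",
      fragments = GenomicRanges::GRanges(chrom,
        IRanges::IRanges(s + 1L, e)),
      metadata = list())
  }
  iv <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 151), c(150, 300)))  # BED [0,150) and [150,300)
  # fragment (100, 200): midpoint 150 -> second interval (half-open)
  counts <- assignIntervals(mk("chr1", 100, 200), iv)
  expect_equal(as.vector(counts), c(0, 1, 0))
  # fragment fully inside first interval
  counts2 <- assignIntervals(mk("chr1", 10, 110), iv)
  expect_equal(unname(counts2[1]), 1)
  # fragment on a chromosome with no intervals -> unassigned
  counts3 <- assignIntervals(mk("chr9", 10, 110), iv)
  expect_equal(unname(counts3[["unassigned"]]), 1)
  # overlapping intervals are rejected
  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), c(150, 250)))
  expect_error(assignIntervals(mk("chr1", 10, 110), bad),
               "non-overlapping")
})
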