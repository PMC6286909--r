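test_that("pure arrays are reported with exact unit, span and score", {
  gr <- detectTandemRepeats(c(chr1 = strrep("AG", 25)))
  expect_equal(length(gr), 1L)
  expect_equal(start(gr), 1L)
  expect_equal(end(gr), 50L)
  expect_equal(mcols(gr)$unit, "AG")
  expect_equal(mcols(gr)$array_length, 50L)
  expect_equal(mcols(gr)$copy_number, 25)
  expect_equal(mcols(gr)$score, 100L) # 2 points per matching base
})

test_that("homopolymer runs are never reported as tandem repeats", {
  expect_equal(length(detectTandemRepeats(c(chr1 = strrep("A", 60)))), 0L)
  # even embedded in background sequence
  set.seed(4)
  s <- paste0(randSeq(50L), strrep("T", 45), randSeq(50L))
  gr <- detectTandemRepeats(c(chr1 = s))
  expect_false(any(mcols(gr)$unit_length < 2L))
})

test_that("the 30 bp array-length filter is a hard boundary", {
  expect_equal(length(detectTandemRepeats(c(chr1 = strrep("CAG", 10)))), 1L)
  expect_equal(
    length(detectTandemRepeats(c(chr1 = paste0(strrep("CAG", 9), "CA")))),
    0L)
})

test_that("sequences without a scoring tandem run give an empty catalog", {
  set.seed(11)
  s <- "TCGGACTTAAGCGATCCTAGTGGACCATTCGAAGGCTTCAGGATCCAATTCGGGACTTAC"
  expect_equal(length(detectTandemRepeats(c(chr1 = s))), 0L)
  expect_equal(length(detectTandemRepeats(c(chr1 = ""))), 0L)
})

test_that("unknown characters are rejected with their position", {
  expect_error(detectTandemRepeats(c(chr1 = "ACGTXACGT")),
               "position 5")
  expect_error(detectTandemRepeats(c(chr1 = "ACGU")), "'U'")
})

test_that("detection is case-insensitive and strand-consistent", {
  s <- paste0("TTTTCTTTCT", strrep("catgg", 12), "AAGAAAGAAG")
  up <- detectTandemRepeats(c(chr1 = toupper(s)))
  lo <- detectTandemRepeats(c(chr1 = s))
  expect_equal(as.data.frame(up), as.data.frame(lo))
  # reverse complement mirrors coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rv <- detectTandemRepeats(c(chr1 = rc))
  n <- nchar(s)
  expect_equal(sort(n - end(up) + 1L), sort(start(rv)))
  expect_equal(sort(n - start(up) + 1L), sort(end(rv)))
  expect_equal(mcols(rv)$score, mcols(up)$score)
})

test_that("all reported loci satisfy the catalog invariants", {
  set.seed(21)
  g <- setNames(vapply(1:6, function(i) plantedSeq(200L), ""),
                paste0("chr", 1:6))
  gr <- detectTandemRepeats(g)
  if (length(gr)) {
    expect_true(all(mcols(gr)$array_length == width(gr)))
    expect_true(all(mcols(gr)$array_length >= 30L))
    expect_true(all(mcols(gr)$unit_length >= 2L))
    expect_true(all(mcols(gr)$score >= 50L))
    expect_true(all(mcols(gr)$copy_number >= 2))
    expect_equal(mcols(gr)$copy_number,
                 mcols(gr)$array_length / mcols(gr)$unit_length)
    expect_equal(mcols(gr)$unit, canonicalUnit(mcols(gr)$unit))
  }
})

test_that("redundancy elimination keeps longer arrays, then shorter units", {
  mk <- function(starts, ends, units) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      unit = units, unit_length = nchar(units),
      array_length = ends - starts + 1L, score = 50L)
    gr
  }
  # 60 bp and 40 bp arrays overlapping by 35 bp: longer retained
  gr <- mk(c(1L, 26L), c(60L, 65L), c("AC", "AG"))
  expect_equal(start(eliminateRedundancy(gr)), 1L)
  # equal-length arrays, units 2 and 4, overlap 30 bp: unit-2 retained
  gr <- mk(c(1L, 11L), c(40L, 50L), c("ACGG", "AT"))
  expect_equal(mcols(eliminateRedundancy(gr))$unit, "AT")
  # 25% overlap (10 of 40 bp): both retained
  gr <- mk(c(1L, 31L), c(40L, 70L), c("AC", "AG"))
  expect_equal(length(eliminateRedundancy(gr)), 2L)
})

test_that("redundancy elimination is idempotent and order-independent", {
  set.seed(33)
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample(1:500, 40L), width = sample(30:90, 40L)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    unit = rep(c("AC", "ACG", "ACGT", "AT"), 10L),
    unit_length = rep(c(2L, 3L, 4L, 2L), 10L),
    array_length = width(gr), score = 60L)
  once <- eliminateRedundancy(gr)
  twice <- eliminateRedundancy(once)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  perm <- sample(length(gr))
  shuffled <- eliminateRedundancy(gr[perm])
  expect_equal(sort(as.data.frame(once)$start),
               sort(as.data.frame(shuffled)$start))
})

test_that("genic context uses gap distances and flags missing chromosomes", {
  loci <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                                 IRanges::IRanges(c(1000L, 300L, 5L),
                                                  c(1060L, 400L, 40L)))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501L, 2000L),
                                  type = "gene")
  expect_warning(ann <- annotateGenicContext(loci, genes), "NA")
  expect_equal(mcols(ann)$genic, c(TRUE, FALSE, FALSE))
  expect_equal(mcols(ann)$distance_to_nearest_gene[1:2], c(0L, 100L))
  expect_true(is.na(mcols(ann)$distance_to_nearest_gene[3]))
})

test_that("catalog summaries canonicalize units and conserve counts", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1, 991, 10), width = 5))
  n <- length(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    unit = rep(c("GA", "AG", "AG", "CAG"), length.out = n),
    unit_length = rep(c(2L, 2L, 2L, 3L), length.out = n),
    array_length = seq_len(n), score = 60L)
  s <- summarizeCatalog(gr)
  expect_equal(unname(s$top_units["AG"]), 75L)
  expect_equal(sum(s$unit_length_hist), n)
  expect_equal(s$p90_array_length, 90) # uniform 1..100
  e <- summarizeCatalog(gr[0])
  expect_equal(sum(e$unit_length_hist), 0L)
  expect_true(is.na(e$p90_array_length))
})
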