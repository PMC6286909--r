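mkVar <- function(chrom = "chr1", start, end, unit = "CAG", delta = 3L) {
  data.frame(locus_id = paste0(chrom, ":", start, "-", end),
             chrom = chrom, start = start, end = end, unit = unit,
             unit_length = nchar(unit), array_length = end - start + 1L,
             array_seq = strrep(unit, (end - start + 1L) %/% nchar(unit)),
             array_length_delta = delta,
             unit_count_delta = delta / nchar(unit),
             delta_is_unit_multiple = delta %% nchar(unit) == 0L,
             stringsAsFactors = FALSE)
}

annotFixture <- GenomicRanges::GRanges(
  "chr1", IRanges::IRanges(c(900L, 900L, 1000L), c(1600L, 1600L, 1500L)),
  strand = "+", type = c("gene", "mRNA", "CDS"),
  ID = c("G1", "G1.m", "G1.cds"), Parent = c(NA, "G1", "G1.m"),
  gene_id = "G1", phase = c(NA, NA, 0L))

test_that("CDS residency means full containment in one CDS feature", {
  inside <- mkVar(start = 1200L, end = 1250L)
  straddle <- mkVar(start = 1480L, end = 1520L)
  utr <- mkVar(start = 910L, end = 960L) # inside gene, outside CDS
  hit <- intersectCDS(inside, annotFixture)
  expect_equal(hit$gene_id, "G1")
  expect_false(hit$ambiguous)
  expect_equal(nrow(intersectCDS(straddle, annotFixture)), 0L)
  expect_equal(nrow(intersectCDS(utr, annotFixture)), 0L)
})

test_that("overlapping genes are all reported and flagged ambiguous", {
  two <- c(annotFixture,
           GenomicRanges::GRanges(
             "chr1", IRanges::IRanges(c(1100L, 1100L, 1100L),
                                      c(1900L, 1900L, 1700L)),
             strand = "+", type = c("gene", "mRNA", "CDS"),
             ID = c("G2", "G2.m", "G2.cds"), Parent = c(NA, "G2", "G2.m"),
             gene_id = "G2", phase = c(NA, NA, 0L)))
  hits <- intersectCDS(mkVar(start = 1200L, end = 1250L), two)
  expect_equal(sort(hits$gene_id), c("G1", "G2"))
  expect_true(all(hits$ambiguous))
})

test_that("protein confirmation recovers the repeat-encoded residues", {
  # unit GAT (Asp), two units lost in the target lineage
  fx <- codingPairFixture(unit = "GAT", copiesA = 12L, extraUnits = 2L,
                          seed = 41L)
  v <- mkVar(start = fx$arrayStartA, end = fx$arrayEndA, unit = "GAT",
             delta = -6L)
  cand <- intersectCDS(v, fx$annotA)
  expect_equal(nrow(cand), 1L)
  conf <- confirmProteinVariation(cand, fx$proteinsA, fx$proteinsB,
                                  fx$annotA)
  expect_equal(nrow(conf), 1L)
  expect_equal(conf$aa_length_delta, -2L)
  expect_equal(conf$repeat_amino_acids, "DD")
  expect_true(conf$in_frame)
  expect_true(conf$consistent)
  # independent translation oracle: whole-protein length difference
  expect_equal(Biostrings::width(fx$proteinsB["G1"]) -
                 Biostrings::width(fx$proteinsA["G1"]), -2L)
})

test_that("five extra glutamine-coding units confirm as +5 Q residues", {
  fx <- codingPairFixture(unit = "CAG", copiesA = 15L, extraUnits = 5L)
  v <- mkVar(start = fx$arrayStartA, end = fx$arrayEndA, unit = "CAG",
             delta = -15L) # target (congener) has five units fewer
  conf <- confirmProteinVariation(intersectCDS(v, fx$annotA),
                                  fx$proteinsA, fx$proteinsB, fx$annotA)
  expect_equal(conf$aa_length_delta, -5L)
  expect_equal(conf$repeat_amino_acids, "QQQQQ")
  expect_true(conf$consistent)
})

test_that("identical proteins are never confirmed", {
  fx <- codingPairFixture(unit = "CAG", copiesA = 12L, extraUnits = 0L,
                          seed = 43L)
  v <- mkVar(start = fx$arrayStartA, end = fx$arrayEndA, unit = "CAG",
             delta = 9L) # claimed delta, but proteins are identical
  conf <- confirmProteinVariation(intersectCDS(v, fx$annotA),
                                  fx$proteinsA, fx$proteinsB, fx$annotA)
  expect_equal(nrow(conf), 0L)
})

test_that("missing proteins raise an error naming the gene", {
  fx <- codingPairFixture()
  v <- mkVar(start = fx$arrayStartA, end = fx$arrayEndA)
  empty <- Biostrings::AAStringSet(setNames("MK", "other"))
  expect_error(
    confirmProteinVariation(intersectCDS(v, fx$annotA), empty,
                            fx$proteinsB, fx$annotA),
    "G1")
})

test_that("frame statistics partition counts and handle empty input", {
  conf <- data.frame(unit_length = c(3L, 3L, 6L, 9L))
  fs <- frameStatistics(conf)
  expect_equal(unname(fs$counts_by_unit_length["3"]), 2L)
  expect_equal(sum(fs$counts_by_unit_length), 4L)
  expect_equal(fs$fraction_multiple_of_3, 1)
  expect_equal(frameStatistics(
    data.frame(unit_length = c(3L, 4L)))$fraction_multiple_of_3, 0.5)
  expect_true(is.na(frameStatistics(
    data.frame(unit_length = integer()))$fraction_multiple_of_3))
})
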