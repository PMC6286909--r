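mkCatalog <- function(chrom, start, end, unit) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    unit = unit, unit_length = nchar(unit),
    array_length = end - start + 1L, score = 100L)
  gr
}

test_that("flank filter applies the >10 bp lowercase-run boundary", {
  set.seed(7)
  arr <- strrep("AG", 20)
  mkGenome <- function(runLen) {
    left <- randSeq(120L)
    # plant a lowercase run ending 20 bp before the array
    substr(left, 80L - runLen + 1L, 80L) <-
      tolower(substr(left, 80L - runLen + 1L, 80L))
    c(chr1 = paste0(left, arr, randSeq(120L)))
  }
  cat11 <- mkCatalog("chr1", 121L, 160L, "AG")
  expect_equal(nrow(suppressMessages(
    filterCleanFlanks(cat11, mkGenome(11L)))), 0L)
  kept <- filterCleanFlanks(cat11, mkGenome(10L))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$max_masked_run_left, 10L)
  expect_equal(nchar(kept$left_flank), 100L)
  expect_equal(nchar(kept$right_flank), 100L)
})

test_that("loci too close to a sequence end are excluded", {
  set.seed(8)
  g <- c(chr1 = paste0(randSeq(49L), strrep("AG", 20), randSeq(150L)))
  cat_ <- mkCatalog("chr1", 50L, 89L, "AG")
  out <- suppressMessages(filterCleanFlanks(cat_, g))
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "rejections")["incomplete_flank"]), 1L)
})

test_that("self-anchoring recovers every locus with zero delta", {
  set.seed(12)
  g <- c(chr1 = paste0(randSeq(200L), strrep("TAG", 15), randSeq(250L),
                       strrep("ATTC", 10), randSeq(200L)))
  cat_ <- detectTandemRepeats(g)
  fl <- filterCleanFlanks(cat_, g)
  m <- anchorLoci(fl, g, mode = "ingroup")
  expect_equal(nrow(m), nrow(fl))
  expect_true(all(m$array_length_delta == 0L))
  expect_true(all(m$left_flank_aligned == 100L))
  expect_true(all(m$right_flank_aligned == 100L))
  expect_equal(m$target_array_start, m$start)
  expect_equal(m$target_array_end, m$end)
})

test_that("unit-count changes project to exact signed deltas", {
  set.seed(13)
  L <- randSeq(300L); R <- randSeq(300L)
  gA <- c(chr1 = paste0(L, strrep("CAG", 20), R))
  gBgain <- c(chr1 = paste0(L, strrep("CAG", 25), R))  # +5 units in target
  gBloss <- c(chr1 = paste0(L, strrep("CAG", 15), R))  # -5 units in target
  fl <- filterCleanFlanks(detectTandemRepeats(gA), gA)
  gain <- anchorLoci(fl, gBgain, mode = "ingroup")
  expect_equal(gain$array_length_delta, 15L)
  expect_equal(gain$unit_count_delta, 5)
  loss <- anchorLoci(fl, gBloss, mode = "ingroup")
  expect_equal(loss$array_length_delta, -15L)
  expect_equal(loss$unit_count_delta, -5)
  # variable calls carry the delta through
  expect_equal(callVariableLength(gain)$unit_count_delta, 5)
  expect_true(callVariableLength(gain)$delta_is_unit_multiple)
})

test_that("a random target genome yields no anchoring", {
  set.seed(14)
  gA <- c(chr1 = paste0(randSeq(200L), strrep("GATTC", 10), randSeq(200L)))
  gRand <- c(chr1 = randSeq(600L))
  fl <- filterCleanFlanks(detectTandemRepeats(gA), gA)
  m <- anchorLoci(fl, gRand, mode = "ingroup")
  expect_equal(nrow(m), 0L)
  expect_gt(sum(attr(m, "rejections")), 0L)
})

test_that("indels confined to a flank never produce a variable call", {
  set.seed(15)
  L <- randSeq(300L); R <- randSeq(300L)
  arr <- strrep("CTGA", 12)
  gA <- c(chr1 = paste0(L, arr, R))
  # 3 bp insertion in the right flank only, 40 bp away from the array
  gB <- c(chr1 = paste0(L, arr, substr(R, 1, 40), "ACT",
                        substr(R, 41, 300)))
  fl <- filterCleanFlanks(detectTandemRepeats(gA), gA)
  m <- anchorLoci(fl, gB, mode = "ingroup")
  expect_equal(nrow(m), 1L)
  expect_equal(m$array_length_delta, 0L)
  expect_equal(nrow(callVariableLength(m)), 0L)
})

test_that("swapping query and target negates the deltas", {
  set.seed(16)
  sim <- simulateGenomeTrio(simConfig(n_tr_loci = 20L,
                                      chrom_length = 50000L,
                                      n_chromosomes = 1L, seed = 31L,
                                      masked_repeat_density = 0))
  gA <- genomeSeqs(sim, "a"); gB <- genomeSeqs(sim, "b")
  flA <- filterCleanFlanks(detectTandemRepeats(gA, maxPeriod = 60L), gA)
  flB <- filterCleanFlanks(detectTandemRepeats(gB, maxPeriod = 60L), gB)
  mAB <- anchorLoci(flA, gB, mode = "ingroup")
  mBA <- anchorLoci(flB, gA, mode = "ingroup")
  # match reciprocal pairs through the projected target span
  key <- function(chrom, s, e) paste0(chrom, ":", s, "-", e)
  idx <- match(key(mAB$target_chrom, mAB$target_array_start,
                   mAB$target_array_end),
               key(mBA$chrom, mBA$start, mBA$end))
  paired <- !is.na(idx)
  expect_gt(sum(paired), 0L)
  expect_equal(mBA$array_length_delta[idx[paired]],
               -mAB$array_length_delta[paired])
})

test_that("variable-to-invariable ratios handle empty denominators", {
  variable <- data.frame(unit_length = c(rep(2L, 10L), rep(30L, 3L)))
  invariable <- data.frame(unit_length = rep(2L, 40L))
  r <- ratioByUnitLength(variable, invariable)
  expect_equal(r$ratio[r$unit_length == 2L], 0.25)
  expect_true(is.na(r$ratio[r$unit_length == 30L]))
})

test_that("planted mutability regimes separate in the estimated ratios", {
  # short units planted mutable at 0.4, long units at 0.1: the ratio
  # table must recover the ordering from the truth alone
  set.seed(77)
  n <- 400L
  short <- rep(c(TRUE, FALSE), each = n / 2L)
  pvar <- ifelse(short, 0.4, 0.1)
  varFlag <- runif(n) < pvar
  ul <- ifelse(short, sample(2:10, n, TRUE), sample(11:30, n, TRUE))
  r <- ratioByUnitLength(data.frame(unit_length = ul[varFlag]),
                         data.frame(unit_length = ul[!varFlag]))
  rShort <- sum(r$n_variable[r$unit_length <= 10]) /
    sum(r$n_invariable[r$unit_length <= 10])
  rLong <- sum(r$n_variable[r$unit_length > 10]) /
    sum(r$n_invariable[r$unit_length > 10])
  expect_gt(rShort, rLong)
})
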