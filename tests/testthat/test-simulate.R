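smallCfg <- function(...) {
  simConfig(n_tr_loci = 25L, chrom_length = 60000L, n_chromosomes = 2L,
            seed = 17L, ...)
}

test_that("identical seed and config give byte-identical outputs", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  f1 <- writeSimOutputs(simulateGenomeTrio(smallCfg()), d1)
  f2 <- writeSimOutputs(simulateGenomeTrio(smallCfg()), d2)
  expect_identical(unname(tools::md5sum(unname(f1))),
                   unname(tools::md5sum(unname(f2))))
  # a different seed changes sequences but not the truth-table schema
  s3 <- simulateGenomeTrio(simConfig(n_tr_loci = 25L,
                                     chrom_length = 60000L, seed = 18L))
  expect_identical(names(truthTable(s3)),
                   names(truthTable(simulateGenomeTrio(smallCfg()))))
})

test_that("zero planted loci give pure background and an empty truth", {
  sim <- simulateGenomeTrio(simConfig(n_tr_loci = 0L,
                                      chrom_length = 10000L,
                                      n_chromosomes = 1L))
  expect_equal(nrow(truthTable(sim)), 0L)
  expect_equal(length(genomeSeqs(sim, "a")[[1]]), 10000L)
  expect_identical(as.character(genomeSeqs(sim, "a")[[1]]),
                   as.character(genomeSeqs(sim, "a")[[1]]))
})

test_that("background composition matches the configured AT fraction", {
  sim <- simulateGenomeTrio(simConfig(n_tr_loci = 0L,
                                      chrom_length = 500000L,
                                      n_chromosomes = 1L, seed = 2L))
  s <- as.character(genomeSeqs(sim, "a")[[1]])
  at <- sum(strsplit(s, "")[[1]] %in% c("A", "T", "a", "t")) / nchar(s)
  expect_lt(abs(at - 0.63), 0.01)
})

test_that("truth table invariants hold and genic fraction is calibrated", {
  sim <- simulateGenomeTrio(simConfig(n_tr_loci = 300L,
                                      chrom_length = 200000L,
                                      n_chromosomes = 2L, seed = 5L))
  tr <- truthTable(sim)
  expect_equal(nrow(tr), 300L)
  expect_true(all(tr$genic[tr$coding]))
  expect_true(all(tr$end - tr$start + 1L == tr$unit_length * tr$copies_a))
  expect_true(all(tr$unit_length >= 2L))
  expect_true(all(tr$unit_length * pmin(tr$copies_a, tr$copies_b,
                                        tr$copies_out) >= 30L))
  expect_true(all(tr$in_frame == (tr$unit_length %% 3L == 0L)))
  # binomial 99% bounds around 0.667 at n = 300
  p <- 0.667
  half <- qnorm(0.995) * sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(mean(tr$genic) - p), half + 1e-9)
  # planted arrays are verbatim in the focal genome
  g <- as.character(genomeSeqs(sim, "a"))
  for (i in sample(nrow(tr), 20L)) {
    arr <- toupper(substr(g[[tr$chrom[i]]], tr$start[i], tr$end[i]))
    expect_equal(arr, strrep(tr$unit_sequence[i], tr$copies_a[i]))
  }
})

test_that("coding loci translate to proteins differing by the unit change", {
  sim <- simulateGenomeTrio(smallCfg())
  tr <- truthTable(sim)
  cod <- tr[tr$coding, ]
  expect_gt(nrow(cod), 0L)
  pa <- proteinSeqs(sim, "a"); pb <- proteinSeqs(sim, "b")
  dAA <- Biostrings::width(pa[cod$gene_id]) -
    Biostrings::width(pb[cod$gene_id])
  expect_equal(dAA,
               (cod$copies_a - cod$copies_b) * cod$unit_length / 3L)
})

test_that("flank masking plants a >10 bp lowercase run next to the array", {
  sim <- simulateGenomeTrio(simConfig(n_tr_loci = 40L,
                                      chrom_length = 80000L,
                                      n_chromosomes = 1L, seed = 9L,
                                      masked_repeat_density = 0.5))
  tr <- truthTable(sim)
  g <- as.character(genomeSeqs(sim, "a"))
  masked <- tr[tr$flank_masked, ]
  expect_gt(nrow(masked), 0L)
  for (i in seq_len(nrow(masked))) {
    fl <- paste0(substr(g[[masked$chrom[i]]], masked$start[i] - 100L,
                        masked$start[i] - 1L),
                 "#",
                 substr(g[[masked$chrom[i]]], masked$end[i] + 1L,
                        masked$end[i] + 100L))
    expect_gte(max(attr(gregexpr("[acgtn]+", fl)[[1]], "match.length")),
               11L)
  }
})

test_that("population alleles follow copy counts exactly when sd is zero", {
  truth <- data.frame(locus_id = c("L1", "L2"), unit_length = c(3L, 4L),
                      copies_a = c(20L, 8L), copies_b = c(15L, 8L))
  pan <- simulatePopulationAlleles(truth, c(a = 3L, b = 5L),
                                   withinSpeciesSd = 0)
  expect_equal(nrow(pan), 2L * (3L + 5L))
  l1 <- pan[pan$locus_id == "L1", ]
  expect_true(all(l1$length_bp[l1$species == "a"] == 60L))
  expect_true(all(l1$length_bp[l1$species == "b"] == 45L))
  expect_equal(sum(pan$species == "a"), 2L * 3L)
  expect_equal(sum(pan$species == "b"), 2L * 5L)
})

test_that("allele perturbations stay positive multiples of the unit", {
  truth <- data.frame(locus_id = sprintf("L%02d", 1:20),
                      unit_length = rep(c(3L, 7L), 10L),
                      copies_a = rep(3L, 20L), copies_b = rep(3L, 20L))
  pan <- simulatePopulationAlleles(truth, c(a = 4L, b = 4L),
                                   withinSpeciesSd = 2, seed = 3L)
  expect_true(all(pan$length_bp > 0L))
  ul <- truth$unit_length[match(pan$locus_id, truth$locus_id)]
  expect_true(all(pan$length_bp %% ul == 0L))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(at_fraction = 1.2), "proportions")
  expect_error(simConfig(copy_number_range = c(1L, 5L)), "copy_number")
  expect_error(simConfig(min_spacing = 50L), "100 bp")
  expect_error(
    simulateGenomeTrio(simConfig(n_tr_loci = 200L, chrom_length = 5000L,
                                 n_chromosomes = 1L)),
    "too short")
})
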