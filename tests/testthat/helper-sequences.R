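# Shared fixture builders: random backgrounds, mutated arrays, and a
# minimal single-gene universe used by the anchoring/coding tests.

randSeq <- function(n, atFraction = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, TRUE,
               c(atFraction / 2, atFraction / 2,
                 (1 - atFraction) / 2, (1 - atFraction) / 2)),
        collapse = "")
}

mutateSeq <- function(s, nSub = 0L, nIndel = 0L) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (nSub > 0L) {
    i <- sample(length(v), nSub)
    v[i] <- sample(c("A", "C", "G", "T"), nSub, TRUE)
  }
  if (nIndel > 0L) {
    for (k in seq_len(nIndel)) {
      i <- sample(length(v), 1L)
      if (runif(1) < 0.5) v <- v[-i]
      else v <- append(v, sample(c("A", "C", "G", "T"), 1L), i)
    }
  }
  paste(v, collapse = "")
}

# sequence with one planted (possibly mutated) tandem array, <= maxLen bp
plantedSeq <- function(maxLen = 200L, pureFraction = 0.2) {
  if (runif(1) < pureFraction) return(randSeq(sample(60:maxLen, 1L)))
  p <- sample(2:6, 1L)
  cop <- sample(ceiling(30 / p):(120 %/% p), 1L)
  u <- randSeq(p)
  arr <- mutateSeq(strrep(u, cop), rbinom(1L, 3L, 0.5), rbinom(1L, 2L, 0.4))
  s <- paste0(randSeq(sample(10:40, 1L)), arr, randSeq(sample(10:40, 1L)))
  substr(s, 1L, maxLen)
}

# Two-genome, single-gene universe around an in-frame repeat inside a
# CDS; the focal genome a carries `extraUnits` more unit copies than b.
# Returns genomes, annotation of a, and the two proteomes.
codingPairFixture <- function(unit = "CAG", copiesA = 12L,
                              extraUnits = 5L, seed = 99L) {
  set.seed(seed)
  copiesB <- copiesA - extraUnits
  utr5 <- randSeq(200L)
  utr3 <- randSeq(200L)
  cds1 <- paste0("ATG", paste(sample(trvar:::.SENSE_CODONS, 40L, TRUE),
                              collapse = ""))
  cds2 <- paste0(paste(sample(trvar:::.SENSE_CODONS, 40L, TRUE),
                       collapse = ""), "TAA")
  mkGenome <- function(copies) {
    c(chr1 = paste0(utr5, cds1, strrep(unit, copies), cds2, utr3))
  }
  gA <- mkGenome(copiesA)
  gB <- mkGenome(copiesB)
  cdsStart <- nchar(utr5) + 1L
  cdsEndA <- nchar(utr5) + nchar(cds1) + copiesA * nchar(unit) +
    nchar(cds2)
  annotA <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(cdsStart, cdsStart, cdsStart),
                             c(cdsEndA, cdsEndA, cdsEndA)),
    strand = "+", type = c("gene", "mRNA", "CDS"),
    ID = c("G1", "G1.m", "G1.cds"),
    Parent = c(NA, "G1", "G1.m"), gene_id = "G1", phase = c(NA, NA, 0L))
  prot <- function(g, copies) {
    cds <- paste0(cds1, strrep(unit, copies), cds2)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    Biostrings::AAStringSet(setNames(sub("\\*$", "", aa), "G1"))
  }
  list(genomeA = gA, genomeB = gB, annotA = annotA,
       proteinsA = prot(gA, copiesA), proteinsB = prot(gB, copiesB),
       arrayStartA = nchar(utr5) + nchar(cds1) + 1L,
       arrayEndA = nchar(utr5) + nchar(cds1) + copiesA * nchar(unit))
}
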