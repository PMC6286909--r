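#' Detect tandem repeats in a genome
#'
#' Scans each chromosome for tandem arrays with a TRF-style wraparound
#' alignment score (+match per matching base, -mismatch, -indel), keeping
#' loci whose score reaches `minScore`, whose primitive repeat unit is at
#' least `minUnit` bp (so homopolymer runs are never reported), and whose
#' array spans at least `minArray` bp with at least two unit copies.
#' Candidate periods are seeded from self-match runs at each lag and
#' boundaries are refined by exhaustive dynamic programming inside each
#' seeded window; among overlapping candidates the highest-scoring array
#' is reported (ties: longer array, then shorter unit, then leftmost).
#' Detection is case-insensitive; soft-masking in the input is preserved
#' for the later flank filter, not used here. Arrays with more than 10%
#' N are discarded and N always scores as a mismatch.
#'
#' @param genome named character vector, [Biostrings::BStringSet] or
#'   [Biostrings::DNAStringSet] of chromosome sequences.
#' @param params a [detectorParams()] object.
#' @param maxPeriod optional cap on the scanned period, defaulting to
#'   `params@maxUnit`; lower it to bound runtime on large genomes.
#' @return [GenomicRanges::GRanges] (1-based inclusive) sorted by
#'   position with metadata columns `unit` (lexicographically minimal
#'   rotation of the primitive consensus), `unit_length`, `array_length`,
#'   `copy_number` (array/unit length, possibly fractional), `score`,
#'   `percent_matches` and `period` (the enumerated period).
#' @examples
#' detectTandemRepeats(c(chr1 = paste0(strrep("T", 40), strrep("CAG", 12),
#'                                     strrep("A", 40))))
#' @seealso [bruteForceTandemRepeats()] for the exhaustive reference,
#'   [eliminateRedundancy()], [summarizeCatalog()].
#' @export
detectTandemRepeats <- function(genome, params = detectorParams(),
                                maxPeriod = params@maxUnit) {
  stopifnot(is(params, "DetectorParams"))
  seqs <- .asSeqChar(genome)
  res <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    if (nchar(s) == 0L) return(NULL)
    .validateAlphabet(s, chrom)
    df <- .detect_tr_core(toupper(s), params@match, params@mismatch,
                          params@indel, params@minScore, params@minUnit,
                          params@minArray, as.integer(maxPeriod))
    if (nrow(df) == 0L) return(NULL)
    df$chrom <- chrom
    df
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    gr <- GRanges(seqnames = factor(levels = names(seqs)), IRanges())
    mcols(gr) <- DataFrame(unit = character(), unit_length = integer(),
                           array_length = integer(), copy_number = numeric(),
                           score = integer(), percent_matches = numeric(),
                           period = integer())
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GRanges(factor(df$chrom, levels = names(seqs)),
                IRanges(df$start, df$end))
  mcols(gr) <- DataFrame(unit = df$unit, unit_length = df$unit_length,
                         array_length = df$array_length,
                         copy_number = df$copy_number, score = df$score,
                         percent_matches = df$percent_matches,
                         period = df$period)
  sort(gr, ignore.strand = TRUE)
}

#' Remove redundant tandem repeat calls
#'
#' When two loci overlap by more than half the length of the shorter
#' array, only one is retained: the longer array wins, ties go to the
#' shorter repeat unit, remaining ties to the leftmost locus. Processing
#' in that fixed order makes the result independent of input order, and
#' the operation is idempotent.
#'
#' @param loci `GRanges` catalog as returned by [detectTandemRepeats()].
#' @param maxOverlap retained loci may overlap at most this fraction of
#'   the shorter array (default 0.5).
#' @return the retained subset of `loci`, position-sorted.
#' @export
eliminateRedundancy <- function(loci, maxOverlap = 0.5) {
  if (length(loci) <= 1L) return(loci)
  hits <- findOverlaps(loci, ignore.strand = TRUE, drop.self = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ovw <- width(pintersect(loci[q], loci[s], ignore.strand = TRUE))
  frac <- ovw / pmin(width(loci[q]), width(loci[s]))
  conflict <- frac > maxOverlap
  adj <- split(s[conflict], factor(q[conflict], levels = seq_along(loci)))
  ord <- order(-width(loci), mcols(loci)$unit_length,
               as.integer(seqnames(loci)), start(loci))
  keep <- logical(length(loci))
  decided <- logical(length(loci))
  for (i in ord) {
    if (decided[i]) next
    keep[i] <- !any(keep[adj[[i]]])
    decided[i] <- TRUE
  }
  loci[keep]
}

#' Annotate tandem repeats with gene context
#'
#' Flags each locus as genic when its interval intersects any gene span,
#' and reports the distance in bp to the nearest gene on the same
#' chromosome (0 when genic, the gap size otherwise, `NA` when the
#' chromosome carries no annotated gene).
#'
#' @param loci `GRanges` catalog.
#' @param annotation `GRanges` of gene features; if a `type` metadata
#'   column is present only rows with `type == "gene"` are used.
#' @return `loci` with added metadata columns `genic` and
#'   `distance_to_nearest_gene`.
#' @export
annotateGenicContext <- function(loci, annotation) {
  genes <- annotation
  if (!is.null(mcols(genes)$type))
    genes <- genes[mcols(genes)$type == "gene"]
  genic <- IRanges::overlapsAny(loci, genes, ignore.strand = TRUE)
  dist <- rep(NA_integer_, length(loci))
  if (length(genes)) {
    nh <- distanceToNearest(loci, genes, ignore.strand = TRUE)
    dist[queryHits(nh)] <- mcols(nh)$distance
  }
  if (anyNA(dist) && length(loci))
    warning(sum(is.na(dist)),
            " locus/loci on chromosomes without annotated genes: ",
            "distance set to NA")
  mcols(loci)$genic <- genic
  mcols(loci)$distance_to_nearest_gene <- dist
  loci
}

#' Summarize a tandem repeat catalog
#'
#' Computes the repeat unit length distribution, the most abundant
#' canonical unit sequences, the array length distribution and the 90th
#' percentile of array lengths (empirical, inverse-ECDF definition).
#'
#' @param loci `GRanges` catalog.
#' @param topK how many top unit sequences to report (default 10).
#' @return list with elements `unit_length_hist` (named counts),
#'   `top_units` (named counts, canonicalized), `array_length_hist`,
#'   and `p90_array_length`. Empty catalog gives empty summaries.
#' @export
summarizeCatalog <- function(loci, topK = 10L) {
  if (length(loci) == 0L)
    return(list(unit_length_hist = table(integer()),
                top_units = table(character()),
                array_length_hist = table(integer()),
                p90_array_length = NA_real_))
  units <- canonicalUnit(mcols(loci)$unit)
  ucount <- sort(table(units), decreasing = TRUE)
  list(unit_length_hist = table(mcols(loci)$unit_length),
       top_units = head(ucount, topK),
       array_length_hist = table(mcols(loci)$array_length),
       p90_array_length = .empiricalPercentile(mcols(loci)$array_length, 0.9))
}
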