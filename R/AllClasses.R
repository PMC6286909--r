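#' Detector scoring parameters
#'
#' Holds the TRF-style scoring weights and catalog filters used by
#' [detectTandemRepeats()]: +match per matching base, -mismatch per
#' mismatching base, -indel per inserted or deleted base, with loci kept
#' only when the tandem alignment score reaches `minScore`, the primitive
#' repeat unit is at least `minUnit` bp (homopolymers are never reported)
#' and the array spans at least `minArray` bp with at least two unit
#' copies at the enumerated period.
#'
#' @slot match positive integer, score per matching base (default 2).
#' @slot mismatch positive integer, penalty per mismatch (default 7).
#' @slot indel positive integer, penalty per indel base (default 7).
#' @slot minScore integer, minimal tandem alignment score (default 50).
#' @slot minUnit integer, minimal primitive unit length in bp (>= 2).
#' @slot minArray integer, minimal array length in bp (default 30).
#' @slot maxUnit integer, largest period scanned (default 2000).
#' @export
setClass("DetectorParams",
  representation(match = "integer", mismatch = "integer", indel = "integer",
                 minScore = "integer", minUnit = "integer",
                 minArray = "integer", maxUnit = "integer"))

setValidity("DetectorParams", function(object) {
  v <- c(match = object@match, mismatch = object@mismatch,
         indel = object@indel, minScore = object@minScore,
         minUnit = object@minUnit, minArray = object@minArray,
         maxUnit = object@maxUnit)
  if (any(is.na(v)) || any(v <= 0L))
    return("all detector parameters must be positive integers")
  if (object@minUnit < 2L)
    return("minUnit must be >= 2 (unit lengths below 2 bp are discarded)")
  if (object@maxUnit < object@minUnit)
    return("maxUnit must be >= minUnit")
  TRUE
})

#' @param match,mismatch,indel,minScore,minUnit,minArray,maxUnit see slots.
#' @return A `DetectorParams` object.
#' @examples
#' detectorParams()
#' @rdname DetectorParams-class
#' @export
detectorParams <- function(match = 2L, mismatch = 7L, indel = 7L,
                           minScore = 50L, minUnit = 2L, minArray = 30L,
                           maxUnit = 2000L) {
  new("DetectorParams", match = as.integer(match),
      mismatch = as.integer(mismatch), indel = as.integer(indel),
      minScore = as.integer(minScore), minUnit = as.integer(minUnit),
      minArray = as.integer(minArray), maxUnit = as.integer(maxUnit))
}

setMethod("show", "DetectorParams", function(object) {
  cat("DetectorParams: match +", object@match,
      ", mismatch -", object@mismatch, ", indel -", object@indel,
      ", min score ", object@minScore, "\n",
      "  unit >= ", object@minUnit, " bp, array >= ", object@minArray,
      " bp, period <= ", object@maxUnit, " bp\n", sep = "")
})

#' Synthetic genome trio with planted tandem repeat loci
#'
#' Container produced by [simulateGenomeTrio()]: three soft-masked genome
#' sequence sets (focal species "a", congener "b", outgroup "out"), gene
#' annotations and translated proteomes for the two ingroup species, the
#' ground-truth table of every planted locus, and the configuration that
#' generated it.
#'
#' @slot genomes named list of case-preserving [Biostrings::BStringSet]
#'   objects with elements "a", "b" and "out".
#' @slot annotations named list of [GenomicRanges::GRanges] ("a", "b")
#'   carrying gene/mRNA/CDS features with `type`, `ID`, `Parent`,
#'   `gene_id` and `phase` metadata columns.
#' @slot proteins named list of [Biostrings::AAStringSet] ("a", "b"),
#'   names are gene identifiers.
#' @slot truth data.frame of ground truth, one row per planted locus
#'   (1-based inclusive coordinates on the focal genome).
#' @slot config the validated simulation configuration list.
#' @export
setClass("GenomeTrioSim",
  representation(genomes = "list", annotations = "list",
                 proteins = "list", truth = "data.frame", config = "list"))

setValidity("GenomeTrioSim", function(object) {
  if (!identical(sort(names(object@genomes)), c("a", "b", "out")))
    return("genomes must be a list with elements 'a', 'b', 'out'")
  if (!all(vapply(object@genomes, is, TRUE, class2 = "BStringSet")))
    return("genomes must be BStringSet objects (case preserved)")
  if (!identical(sort(names(object@annotations)), c("a", "b")))
    return("annotations must be a list with elements 'a', 'b'")
  need <- c("locus_id", "chrom", "start", "end", "unit_sequence",
            "unit_length", "copies_a", "copies_b", "copies_out",
            "genic", "coding", "in_frame", "flank_masked")
  if (nrow(object@truth) > 0L && !all(need %in% names(object@truth)))
    return(paste("truth table lacks columns:",
                 paste(setdiff(need, names(object@truth)), collapse = ", ")))
  tr <- object@truth
  if (nrow(tr) > 0L) {
    if (any(tr$coding & !tr$genic))
      return("coding loci must be genic")
    if (any(tr$end - tr$start + 1L != tr$unit_length * tr$copies_a))
      return("focal array length must equal unit_length * copies_a")
  }
  TRUE
})

#' @param x,object a `GenomeTrioSim`.
#' @param species one of `"a"`, `"b"`, `"out"`.
#' @rdname GenomeTrioSim-class
#' @export
genomeSeqs <- function(x, species = c("a", "b", "out")) {
  stopifnot(is(x, "GenomeTrioSim"))
  x@genomes[[match.arg(species)]]
}

#' @rdname GenomeTrioSim-class
#' @export
annotationOf <- function(x, species = c("a", "b")) {
  stopifnot(is(x, "GenomeTrioSim"))
  x@annotations[[match.arg(species)]]
}

#' @rdname GenomeTrioSim-class
#' @export
proteinSeqs <- function(x, species = c("a", "b")) {
  stopifnot(is(x, "GenomeTrioSim"))
  x@proteins[[match.arg(species)]]
}

#' @rdname GenomeTrioSim-class
#' @export
truthTable <- function(x) {
  stopifnot(is(x, "GenomeTrioSim"))
  x@truth
}

#' @rdname GenomeTrioSim-class
#' @export
trioConfig <- function(x) {
  stopifnot(is(x, "GenomeTrioSim"))
  x@config
}

setMethod("show", "GenomeTrioSim", function(object) {
  tr <- object@truth
  cat("GenomeTrioSim with", length(object@genomes$a), "chromosome(s) of",
      object@config$chrom_length, "bp per lineage\n")
  cat("  planted TR loci:", nrow(tr),
      sprintf("(genic %d, coding %d, flank-masked %d)\n",
              sum(tr$genic), sum(tr$coding), sum(tr$flank_masked)))
  nvar <- sum(tr$copies_a != tr$copies_b)
  cat("  length-variable between ingroup lineages:", nvar, "\n")
  cat("  annotated genes:",
      sum(object@annotations$a$type == "gene"), "\n")
})

#' End-to-end pipeline result
#'
#' Returned by [runTRPipeline()]. Carries the monotone stage-count funnel
#' (detected, nonredundant, clean-flanked, anchored, variable,
#' coding-variable, genes affected, polarized), the per-stage tables, and
#' a manifest of every emitted file with its md5 checksum.
#'
#' @slot counts named integer vector of funnel stage counts.
#' @slot tables named list of per-stage result tables.
#' @slot manifest data.frame with columns `file` and `md5`.
#' @slot outDir output directory used for the run.
#' @export
setClass("TRPipelineResult",
  representation(counts = "integer", tables = "list",
                 manifest = "data.frame", outDir = "character"))

#' @param x,object a `TRPipelineResult`.
#' @rdname TRPipelineResult-class
#' @export
stageCounts <- function(x) {
  stopifnot(is(x, "TRPipelineResult"))
  x@counts
}

#' @rdname TRPipelineResult-class
#' @export
stageTables <- function(x) {
  stopifnot(is(x, "TRPipelineResult"))
  x@tables
}

#' @rdname TRPipelineResult-class
#' @export
fileManifest <- function(x) {
  stopifnot(is(x, "TRPipelineResult"))
  x@manifest
}

setMethod("show", "TRPipelineResult", function(object) {
  cat("TRPipelineResult funnel:\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-16s %d\n", nm, object@counts[[nm]]))
  cat("  files written:", nrow(object@manifest), "in", object@outDir, "\n")
})
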