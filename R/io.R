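# Plain-text import/export: TSV catalogs (1-based inclusive), a
# BED-compatible export (0-based half-open), and the simulator bundle.

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read a tandem repeat catalog as TSV
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `unit`,
#' `unit_length`, `array_length`, `copy_number`, `score`,
#' `percent_matches`, `period`.
#'
#' @param loci `GRanges` catalog from [detectTandemRepeats()].
#' @param path output (input) file path.
#' @return `writeTRCatalog` returns the path invisibly;
#'   `readTRCatalog` returns a `GRanges`.
#' @export
writeTRCatalog <- function(loci, path) {
  df <- data.frame(chrom = as.character(seqnames(loci)),
                   start = start(loci), end = end(loci),
                   as.data.frame(mcols(loci)), stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @rdname writeTRCatalog
#' @export
readTRCatalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr) <- DataFrame(df[setdiff(names(df),
                                    c("chrom", "start", "end"))])
  gr
}

#' Export a catalog in BED format
#'
#' 0-based half-open intervals with the canonical unit as the feature
#' name and the tandem alignment score in the score column.
#'
#' @param loci `GRanges` catalog.
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportTRBed <- function(loci, path) {
  df <- data.frame(chrom = as.character(seqnames(loci)),
                   start = start(loci) - 1L, end = end(loci),
                   name = mcols(loci)$unit,
                   score = mcols(loci)$score,
                   strand = ".", stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# GFF3 export wants Parent as a CharacterList
.gffReady <- function(gr) {
  p <- mcols(gr)$Parent
  if (!is.null(p) && is.character(p))
    mcols(gr)$Parent <- IRanges::CharacterList(
      lapply(p, function(x) if (is.na(x)) character(0L) else x))
  gr
}

#' Write the synthetic trio to disk
#'
#' Emits soft-masked genome FASTA for the three lineages, GFF3
#' annotation and protein FASTA for the two ingroup lineages, and the
#' ground-truth table as TSV (1-based inclusive coordinates on the
#' focal genome).
#'
#' @param sim a [GenomeTrioSim-class] object.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeSimOutputs <- function(sim, dir) {
  stopifnot(is(sim, "GenomeTrioSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (L in c("a", "b", "out")) {
    f <- file.path(dir, paste0("genome_", L, ".fa"))
    writeXStringSet(genomeSeqs(sim, L), f)
    files[paste0("genome_", L)] <- f
  }
  for (L in c("a", "b")) {
    f <- file.path(dir, paste0("annotation_", L, ".gff3"))
    ann <- annotationOf(sim, L)
    if (length(ann) == 0L) {
      writeLines("##gff-version 3", f)
    } else {
      rtracklayer::export(.gffReady(ann), f, format = "gff3")
    }
    files[paste0("annotation_", L)] <- f
    f <- file.path(dir, paste0("proteins_", L, ".fa"))
    writeXStringSet(proteinSeqs(sim, L), f)
    files[paste0("proteins_", L)] <- f
  }
  f <- file.path(dir, "truth.tsv")
  .writeTSV(truthTable(sim), f)
  files["truth"] <- f
  files
}
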