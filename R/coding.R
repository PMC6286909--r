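# From variable tandem repeats to confirmed protein-length changes.

.blosumEnv <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosumEnv$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumEnv$m <- e$BLOSUM62
  }
  .blosumEnv$m
}

# CDS feature rows of the annotation with a resolved gene_id column
.cdsFeatures <- function(annotation) {
  stopifnot(!is.null(mcols(annotation)$type))
  cds <- annotation[mcols(annotation)$type == "CDS"]
  if (is.null(mcols(cds)$gene_id)) {
    # resolve Parent (mRNA) -> gene through ID links
    ids <- as.character(mcols(annotation)$ID)
    par <- as.character(mcols(annotation)$Parent)
    mrnaParent <- setNames(par[mcols(annotation)$type == "mRNA"],
                           ids[mcols(annotation)$type == "mRNA"])
    mcols(cds)$gene_id <- unname(mrnaParent[as.character(mcols(cds)$Parent)])
  }
  cds
}

# coding-strand CDS coordinate of genomic position g within the gene's
# CDS features (which must contain g)
.cdsPos <- function(cdsGene, g) {
  minus <- as.character(strand(cdsGene)[1L]) == "-"
  ord <- order(start(cdsGene), decreasing = minus)
  cdsGene <- cdsGene[ord]
  acc <- 0L
  for (k in seq_along(cdsGene)) {
    lo <- start(cdsGene)[k]; hi <- end(cdsGene)[k]
    if (g >= lo && g <= hi)
      return(acc + if (minus) hi - g + 1L else g - lo + 1L)
    acc <- acc + hi - lo + 1L
  }
  stop("position ", g, " not inside the CDS of the gene")
}

#' Variable tandem repeats residing in coding sequence
#'
#' A variable locus qualifies when its array interval is fully contained
#' within a single CDS feature (partial overlaps would make the reading
#' frame ambiguous and are excluded, as are repeats in untranslated exon
#' regions). When overlapping genes each contain the array, every
#' containing gene is reported and the rows are flagged ambiguous.
#'
#' @param variables data.frame from [callVariableLength()].
#' @param annotation `GRanges` with gene/mRNA/CDS features (`type`,
#'   `ID`, `Parent` and optionally `gene_id` metadata columns).
#' @return data.frame of qualifying rows with added `gene_id`,
#'   `cds_strand` and `ambiguous` columns.
#' @export
intersectCDS <- function(variables, annotation) {
  cds <- .cdsFeatures(annotation)
  if (nrow(variables) == 0L || length(cds) == 0L) {
    out <- cbind(variables[integer(0L), , drop = FALSE],
                 data.frame(gene_id = character(),
                            cds_strand = character(),
                            ambiguous = logical()))
    rownames(out) <- NULL
    return(out)
  }
  arrGR <- GRanges(variables$chrom,
                   IRanges(variables$start, variables$end))
  ov <- findOverlaps(arrGR, cds, type = "within", ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(intersectCDS(variables[integer(0L), , drop = FALSE], annotation))
  q <- queryHits(ov); s <- subjectHits(ov)
  nGenes <- vapply(split(mcols(cds)$gene_id[s], q), function(g)
    length(unique(g)), 0L)
  out <- cbind(variables[q, , drop = FALSE],
               data.frame(gene_id = mcols(cds)$gene_id[s],
                          cds_strand = as.character(strand(cds)[s]),
                          ambiguous = unname(nGenes[as.character(q)] > 1L),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Confirm protein-length variation caused by a variable tandem repeat
#'
#' For each CDS-resident variable locus, takes the encoded protein of
#' the query gene, finds its counterpart in the target proteome by best
#' local-alignment score (optionally requiring the hit to be reciprocal,
#' the default intended for the synthetic universe), aligns the pair
#' globally (BLOSUM62, affine gaps), and confirms the locus when a net
#' nonzero indel falls inside the repeat-encoded residue window. The
#' window is widened by one repeat unit of residues on each side because
#' aligners may slide gaps within a repeat run. For in-frame repeats the
#' gained or lost residues are reported as the translated, codon-aligned
#' unit repeated once per unit copy changed.
#'
#' @param cands data.frame from [intersectCDS()].
#' @param proteinsQuery,proteinsTarget [Biostrings::AAStringSet]
#'   proteomes; `proteinsQuery` must be named by gene identifier.
#' @param annotation query-genome annotation (for the residue window).
#' @param reciprocal require a reciprocal best hit (default TRUE).
#' @return data.frame with one row per confirmed locus: `locus_id`,
#'   `gene_id`, `protein_id_query`, `protein_id_target`, `unit_length`,
#'   `array_length_delta`, `unit_count_delta`, `aa_length_delta`
#'   (target minus query, residues), `repeat_amino_acids`, `in_frame`
#'   and `consistent` (`aa_length_delta * 3 == array_length_delta`).
#' @export
confirmProteinVariation <- function(cands, proteinsQuery, proteinsTarget,
                                    annotation, reciprocal = TRUE) {
  emptyOut <- data.frame(
    locus_id = character(), gene_id = character(),
    protein_id_query = character(), protein_id_target = character(),
    unit_length = integer(), array_length_delta = integer(),
    unit_count_delta = numeric(), aa_length_delta = integer(),
    repeat_amino_acids = character(), in_frame = logical(),
    consistent = logical(), stringsAsFactors = FALSE)
  if (nrow(cands) == 0L) return(emptyOut)
  cds <- .cdsFeatures(annotation)
  bl <- .blosum62()
  out <- list()
  for (r in seq_len(nrow(cands))) {
    gid <- cands$gene_id[r]
    if (!gid %in% names(proteinsQuery))
      stop("no protein found for gene ", gid, " in the query proteome")
    qprot <- proteinsQuery[[gid]]
    if (length(qprot) == 0L)
      stop("zero-length protein for gene ", gid)
    sc <- pairwiseAlignment(proteinsTarget, qprot, type = "local",
                            substitutionMatrix = bl, gapOpening = 10,
                            gapExtension = 0.5, scoreOnly = TRUE)
    ord <- order(-sc, names(proteinsTarget))
    tid <- names(proteinsTarget)[ord[1L]]
    tprot <- proteinsTarget[[tid]]
    if (length(tprot) == 0L)
      stop("zero-length protein ", tid, " in the target proteome")
    if (reciprocal) {
      sc2 <- pairwiseAlignment(proteinsQuery, tprot, type = "local",
                               substitutionMatrix = bl, gapOpening = 10,
                               gapExtension = 0.5, scoreOnly = TRUE)
      ord2 <- order(-sc2, names(proteinsQuery))
      if (names(proteinsQuery)[ord2[1L]] != gid) next
    }
    aln <- pairwiseAlignment(qprot, tprot, type = "global",
                             substitutionMatrix = bl, gapOpening = 10,
                             gapExtension = 0.5)
    ## repeat-encoded residue window on the query protein
    cdsGene <- cds[mcols(cds)$gene_id == gid]
    minus <- cands$cds_strand[r] == "-"
    firstBase <- if (minus) cands$end[r] else cands$start[r]
    cp1 <- .cdsPos(cdsGene, firstBase)
    cp2 <- cp1 + cands$array_length[r] - 1L
    wpad <- ceiling(cands$unit_length[r] / 3)
    win <- c(max(1L, ceiling(cp1 / 3) - wpad), ceiling(cp2 / 3) + wpad)
    ## net indel length within the window
    pc <- strsplit(as.character(pattern(aln)), "", fixed = TRUE)[[1L]]
    sc2c <- strsplit(as.character(subject(aln)), "", fixed = TRUE)[[1L]]
    qres <- cumsum(pc != "-")
    isGap <- pc == "-" | sc2c == "-"
    net <- 0L
    if (any(isGap)) {
      blockId <- cumsum(c(TRUE, diff(isGap) != 0L))[isGap]
      gapIdx <- which(isGap)
      for (b in unique(blockId)) {
        cols <- gapIdx[blockId == b]
        qlo <- if (qres[cols[1L]] == 0L) 0L else qres[cols[1L]]
        qhi <- qres[cols[length(cols)]] + 1L
        if (qhi < win[1L] || qlo > win[2L]) next
        sign <- if (pc[cols[1L]] == "-") 1L else -1L
        net <- net + sign * length(cols)
      }
    }
    if (net == 0L) next
    inFrame <- cands$unit_length[r] %% 3L == 0L
    repAA <- ""
    if (inFrame && isTRUE(cands$delta_is_unit_multiple[r])) {
      arrCod <- toupper(cands$array_seq[r])
      if (minus) arrCod <- .revcomp(arrCod)
      off <- (3L - ((cp1 - 1L) %% 3L)) %% 3L
      if (off + cands$unit_length[r] <= nchar(arrCod)) {
        unitCod <- substr(arrCod, off + 1L, off + cands$unit_length[r])
        aaUnit <- as.character(translate(DNAString(unitCod)))
        repAA <- strrep(aaUnit, abs(cands$unit_count_delta[r]))
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      locus_id = cands$locus_id[r], gene_id = gid,
      protein_id_query = gid, protein_id_target = tid,
      unit_length = cands$unit_length[r],
      array_length_delta = cands$array_length_delta[r],
      unit_count_delta = cands$unit_count_delta[r],
      aa_length_delta = net, repeat_amino_acids = repAA,
      in_frame = inFrame,
      consistent = net * 3L == cands$array_length_delta[r],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(emptyOut)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frame statistics of confirmed coding variable repeats
#'
#' @param confirmed data.frame from [confirmProteinVariation()].
#' @return list with `counts_by_unit_length` (named counts) and
#'   `fraction_multiple_of_3` (`NA` for empty input).
#' @export
frameStatistics <- function(confirmed) {
  if (nrow(confirmed) == 0L)
    return(list(counts_by_unit_length = table(integer()),
                fraction_multiple_of_3 = NA_real_))
  list(counts_by_unit_length = table(confirmed$unit_length),
       fraction_multiple_of_3 = mean(confirmed$unit_length %% 3L == 0L))
}
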