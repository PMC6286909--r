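#' Keep tandem repeats with clean, complete flanks
#'
#' Extracts the two `flankSize` bp flanks of every locus from the
#' soft-masked genome (case preserved) and keeps a locus only when both
#' flanks are complete (loci closer than `flankSize` bp to a sequence
#' end are excluded rather than given truncated flanks) and neither
#' flank contains a run of more than `maxMaskedRun` lowercase letters —
#' the signature of an adjacent interspersed repeat that would make
#' flank anchoring ambiguous. A run of exactly `maxMaskedRun` is kept.
#'
#' @param loci `GRanges` catalog from [detectTandemRepeats()].
#' @param genome case-preserving genome ([Biostrings::BStringSet] or
#'   named character vector) the loci were detected in.
#' @param flankSize flank length in bp (default 100).
#' @param maxMaskedRun longest tolerated lowercase run (default 10).
#' @return data.frame of retained loci with columns `locus_id`, `chrom`,
#'   `start`, `end`, `unit`, `unit_length`, `array_length`, `array_seq`,
#'   `left_flank`, `right_flank` (case preserved),
#'   `max_masked_run_left`, `max_masked_run_right`. Rejection counts are
#'   attached as `attr(, "rejections")`.
#' @export
filterCleanFlanks <- function(loci, genome, flankSize = 100L,
                              maxMaskedRun = 10L) {
  seqs <- .asSeqChar(genome)
  n <- length(loci)
  chrom <- as.character(seqnames(loci))
  st <- start(loci); en <- end(loci)
  lens <- nchar(seqs)[chrom]
  complete <- st - flankSize >= 1L & en + flankSize <= lens
  left <- right <- arr <- rep(NA_character_, n)
  if (any(complete)) {
    idx <- which(complete)
    left[idx] <- substr(seqs[chrom[idx]], st[idx] - flankSize, st[idx] - 1L)
    right[idx] <- substr(seqs[chrom[idx]], en[idx] + 1L, en[idx] + flankSize)
    arr[idx] <- substr(seqs[chrom[idx]], st[idx], en[idx])
  }
  runL <- runR <- rep(NA_integer_, n)
  runL[complete] <- .maxLowercaseRun(left[complete])
  runR[complete] <- .maxLowercaseRun(right[complete])
  clean <- complete & runL <= maxMaskedRun & runR <= maxMaskedRun
  out <- data.frame(
    locus_id = paste0(chrom, ":", st, "-", en, recycle0 = TRUE),
    chrom = chrom, start = st, end = en,
    unit = mcols(loci)$unit, unit_length = mcols(loci)$unit_length,
    array_length = mcols(loci)$array_length,
    array_seq = arr, left_flank = left, right_flank = right,
    max_masked_run_left = runL, max_masked_run_right = runR,
    stringsAsFactors = FALSE)[clean, , drop = FALSE]
  rownames(out) <- NULL
  rej <- c(incomplete_flank = sum(!complete),
           masked_flank = sum(complete & !clean))
  if (sum(rej) > 0L)
    message("filterCleanFlanks: excluded ", rej[["incomplete_flank"]],
            " locus/loci with incomplete flanks and ",
            rej[["masked_flank"]], " with masked flanks")
  attr(out, "rejections") <- rej
  out
}

# Karlin-Altschul lambda for the +match/-mismatch scheme under uniform
# base frequencies; K is fixed (the e-value is an estimate used for
# ranking and generous thresholding, not a BLAST replication).
.kaEnv <- new.env(parent = emptyenv())
.kaLambda <- function(match, mismatch) {
  key <- paste(match, mismatch)
  if (is.null(.kaEnv[[key]]))
    .kaEnv[[key]] <- uniroot(function(l)
      0.25 * exp(match * l) + 0.75 * exp(-mismatch * l) - 1,
      c(1e-6, 5))$root
  .kaEnv[[key]]
}
.KA_K <- 0.1

.nucMatrix <- function(match, mismatch) {
  m <- matrix(-mismatch, 5L, 5L, dimnames = list(.BASES, .BASES))
  diag(m) <- match
  m["N", "N"] <- -mismatch # N never matches
  m
}

# Column walk of a local alignment: flank coverage, identity, and the
# target span of the array, delimited by the innermost aligned flank
# columns so whole-unit indels that an aligner slides against the
# array/flank boundary are still attributed to the array.
.projectAlignment <- function(aln, qlen, alen, flankSize, windowOffset) {
  pc <- strsplit(as.character(pattern(aln)), "", fixed = TRUE)[[1L]]
  sc <- strsplit(as.character(subject(aln)), "", fixed = TRUE)[[1L]]
  qadv <- pc != "-"; tadv <- sc != "-"
  qpos <- start(pattern(aln)) - 1L + cumsum(qadv)
  tpos <- start(subject(aln)) - 1L + cumsum(tadv)
  aligned <- qadv & tadv
  leftCols <- aligned & qpos <= flankSize
  rightCols <- aligned & qpos > flankSize + alen
  identity <- if (any(aligned)) sum(pc == sc & aligned) / sum(aligned) else 0
  res <- list(left_aligned = sum(leftCols), right_aligned = sum(rightCols),
              identity = identity,
              target_start = windowOffset + start(subject(aln)) - 1L,
              target_end = windowOffset + max(tpos) - 1L,
              target_array_start = NA_integer_,
              target_array_end = NA_integer_)
  if (any(leftCols) && any(rightCols)) {
    res$target_array_start <- windowOffset + max(tpos[leftCols])
    res$target_array_end <- windowOffset + min(tpos[rightCols]) - 2L
  }
  res
}

#' Anchor tandem repeat loci in a second genome by their flanks
#'
#' For each clean-flanked query locus (array plus two flanks), performs
#' a seeded local-alignment search against the target genome: exact
#' flank k-mers seed candidate regions, and each candidate window is
#' aligned locally with the detector's match/mismatch weights and
#' BLAST-like affine gaps (`gapOpening` 10, `gapExtension` 1). Affine
#' gaps serve two purposes: they keep a unit-number indel in one
#' contiguous block (a linear gap cost lets the aligner scatter
#' tie-equivalent gap columns through the flanks, corrupting the array
#' projection), and they keep large copy-number changes cheap enough
#' that the alignment still spans both flanks instead of truncating at
#' the indel. Hits
#' are ranked by a Karlin-Altschul e-value estimate, and only the best
#' hit is evaluated. The best hit is retained when it covers more than
#' `minFlank` bp of flank on both sides at an e-value at or below
#' `maxEvalue` (ingroup defaults: 95 bp, 1e-10; outgroup: 90 bp, 1e-5)
#' and at least `minIdentity` identity over the aligned span. The
#' target array span is projected through the alignment columns and the
#' signed length difference (target minus query) is reported.
#'
#' @param flanked data.frame from [filterCleanFlanks()].
#' @param targetGenome target genome sequences (any case).
#' @param mode `"ingroup"` or `"outgroup"`; sets the flank-coverage and
#'   e-value thresholds unless overridden.
#' @param minFlank,maxEvalue,minIdentity threshold overrides.
#' @param gapOpening,gapExtension affine gap costs of the anchoring
#'   aligner.
#' @param seedLength,seedStep exact-seed length and spacing along the
#'   flanks.
#' @param params [detectorParams()] supplying the alignment weights.
#' @return data.frame with one row per anchored locus: query fields plus
#'   `target_chrom`, `target_start`, `target_end`, `target_array_start`,
#'   `target_array_end`, `left_flank_aligned`, `right_flank_aligned`,
#'   `alignment_score`, `evalue`, `identity`, `array_length_delta`
#'   (target minus query) and `unit_count_delta`. Rejection counts
#'   (`no_hit`, `failed_flank_coverage`, `failed_evalue`,
#'   `failed_identity`) are attached as `attr(, "rejections")`.
#' @seealso [findOrtholog()] for a single locus, [callVariableLength()].
#' @export
anchorLoci <- function(flanked, targetGenome,
                       mode = c("ingroup", "outgroup"),
                       minFlank = NULL, maxEvalue = NULL,
                       minIdentity = 0.8, gapOpening = 10, gapExtension = 1,
                       seedLength = 18L, seedStep = 8L,
                       params = detectorParams()) {
  mode <- match.arg(mode)
  if (is.null(minFlank)) minFlank <- if (mode == "ingroup") 95L else 90L
  if (is.null(maxEvalue)) maxEvalue <- if (mode == "ingroup") 1e-10 else 1e-5
  tseqs <- toupper(.asSeqChar(targetGenome))
  tlens <- nchar(tseqs)
  totalT <- sum(as.numeric(tlens))
  lambda <- .kaLambda(params@match, params@mismatch)
  mat <- .nucMatrix(params@match, params@mismatch)
  empty <- data.frame()
  nq <- nrow(flanked)
  rej <- c(no_hit = 0L, failed_flank_coverage = 0L, failed_evalue = 0L,
           failed_identity = 0L)
  if (nq == 0L) {
    attr(empty, "rejections") <- rej
    return(empty)
  }
  flankSize <- nchar(flanked$left_flank[1L])
  qseq <- toupper(paste0(flanked$left_flank, flanked$array_seq,
                         flanked$right_flank))
  qlen <- nchar(qseq)

  ## seed harvest: positions along both flanks of every query
  seedTab <- list()
  for (qi in seq_len(nq)) {
    offL <- seq(1L, flankSize - seedLength + 1L, by = seedStep)
    offR <- seq(qlen[qi] - flankSize + 1L, qlen[qi] - seedLength + 1L,
                by = seedStep)
    off <- c(offL, offR)
    sd <- substring(qseq[qi], off, off + seedLength - 1L)
    ok <- !grepl("[^ACGT]", sd)
    if (any(ok))
      seedTab[[qi]] <- data.frame(qi = qi, off = off[ok], seed = sd[ok],
                                  stringsAsFactors = FALSE)
  }
  seedTab <- do.call(rbind, seedTab)
  hits <- NULL
  if (!is.null(seedTab) && nrow(seedTab) > 0L) {
    pd <- PDict(DNAStringSet(seedTab$seed))
    hitList <- list()
    for (chromName in names(tseqs)) {
      mp <- matchPDict(pd, DNAString(tseqs[[chromName]]))
      cnt <- S4Vectors::elementNROWS(mp)
      if (sum(cnt) == 0L) next
      sidx <- rep.int(seq_along(cnt), cnt)
      starts <- unlist(IRanges::start(mp), use.names = FALSE)
      hitList[[chromName]] <- data.frame(
        qi = seedTab$qi[sidx], chrom = chromName,
        diag = starts - (seedTab$off[sidx] - 1L),
        stringsAsFactors = FALSE)
    }
    if (length(hitList)) hits <- do.call(rbind, hitList)
  }

  out <- vector("list", nq)
  for (qi in seq_len(nq)) {
    h <- if (is.null(hits)) NULL else
      hits[hits$qi == qi, , drop = FALSE]
    if (is.null(h) || nrow(h) == 0L) {
      rej[["no_hit"]] <- rej[["no_hit"]] + 1L
      next
    }
    best <- NULL
    for (chromName in unique(h$chrom)) {
      d <- sort(unique(h$diag[h$chrom == chromName]))
      grp <- cumsum(c(1L, diff(d) > 400L))
      for (g in unique(grp)) {
        dg <- d[grp == g]
        wlo <- max(1L, min(dg) - 150L)
        whi <- min(tlens[[chromName]],
                   max(dg) + qlen[qi] + 450L)
        aln <- pairwiseAlignment(
          DNAString(qseq[qi]),
          DNAString(substr(tseqs[[chromName]], wlo, whi)),
          type = "local", substitutionMatrix = mat,
          gapOpening = gapOpening, gapExtension = gapExtension)
        ev <- .KA_K * qlen[qi] * totalT * exp(-lambda * score(aln))
        tstart <- wlo + start(subject(aln)) - 1L
        cand <- list(chrom = chromName, wlo = wlo, aln = aln,
                     score = score(aln), evalue = ev, tstart = tstart)
        # tie-break: higher raw score, then lowest target coordinate
        if (is.null(best) || ev < best$evalue ||
            (ev == best$evalue && (cand$score > best$score ||
              (cand$score == best$score && tstart < best$tstart))))
          best <- cand
      }
    }
    pr <- .projectAlignment(best$aln, qlen[qi], flanked$array_length[qi],
                            flankSize, best$wlo)
    if (best$evalue > maxEvalue) {
      rej[["failed_evalue"]] <- rej[["failed_evalue"]] + 1L
      next
    }
    if (pr$left_aligned <= minFlank || pr$right_aligned <= minFlank) {
      rej[["failed_flank_coverage"]] <- rej[["failed_flank_coverage"]] + 1L
      next
    }
    if (pr$identity < minIdentity) {
      rej[["failed_identity"]] <- rej[["failed_identity"]] + 1L
      next
    }
    tArrLen <- pr$target_array_end - pr$target_array_start + 1L
    delta <- tArrLen - flanked$array_length[qi]
    out[[qi]] <- cbind(
      flanked[qi, c("locus_id", "chrom", "start", "end", "unit",
                    "unit_length", "array_length", "array_seq")],
      data.frame(target_chrom = best$chrom,
                 target_start = pr$target_start,
                 target_end = pr$target_end,
                 target_array_start = pr$target_array_start,
                 target_array_end = pr$target_array_end,
                 left_flank_aligned = pr$left_aligned,
                 right_flank_aligned = pr$right_aligned,
                 alignment_score = best$score, evalue = best$evalue,
                 identity = pr$identity, array_length_delta = delta,
                 unit_count_delta = delta / flanked$unit_length[qi],
                 stringsAsFactors = FALSE))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "rejections") <- rej
  res
}

#' Find the orthologous locus of a single tandem repeat
#'
#' Convenience wrapper around [anchorLoci()] for one clean-flanked
#' locus; returns the match row, or `NULL` when there is no hit passing
#' the mode's thresholds.
#'
#' @param query single-row data.frame from [filterCleanFlanks()].
#' @param targetGenome,mode,... passed to [anchorLoci()].
#' @return one-row data.frame or `NULL`.
#' @export
findOrtholog <- function(query, targetGenome,
                         mode = c("ingroup", "outgroup"), ...) {
  stopifnot(is.data.frame(query), nrow(query) == 1L)
  res <- anchorLoci(query, targetGenome, mode = match.arg(mode), ...)
  if (nrow(res) == 0L) NULL else res
}

#' Call length-variable tandem repeats from anchoring results
#'
#' A locus is called variable when the net indel length within the
#' array columns of its alignment is nonzero, i.e. when the projected
#' target array span differs in length from the query array. Indels
#' confined to the flanks never produce a call.
#'
#' @param matches data.frame from [anchorLoci()].
#' @return the variable subset with an added logical column
#'   `delta_is_unit_multiple` flagging whether the length difference is
#'   an exact multiple of the unit length.
#' @export
callVariableLength <- function(matches) {
  if (nrow(matches) == 0L) {
    matches$delta_is_unit_multiple <- logical(0L)
    return(matches)
  }
  v <- matches[matches$array_length_delta != 0L, , drop = FALSE]
  v$delta_is_unit_multiple <- v$array_length_delta %% v$unit_length == 0L
  rownames(v) <- NULL
  v
}

#' Variable-to-invariable ratio by repeat unit length
#'
#' For each repeat unit length, the ratio between the number of
#' length-variable loci and the number of invariable loci drawn from
#' the same anchored universe; unit lengths with no invariable locus
#' get a missing ratio rather than infinity.
#'
#' @param variable,invariable data.frames with a `unit_length` column
#'   (e.g. the output of [callVariableLength()] and its complement).
#' @return data.frame with `unit_length`, `n_variable`, `n_invariable`,
#'   `ratio`.
#' @export
ratioByUnitLength <- function(variable, invariable) {
  ul <- sort(unique(c(variable$unit_length, invariable$unit_length)))
  nv <- vapply(ul, function(u) sum(variable$unit_length == u), 0L)
  ni <- vapply(ul, function(u) sum(invariable$unit_length == u), 0L)
  data.frame(unit_length = ul, n_variable = nv, n_invariable = ni,
             ratio = ifelse(ni > 0L, nv / ni, NA_real_))
}
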