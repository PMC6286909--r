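#' Polarize a between-species repeat length difference with an outgroup
#'
#' Single-outgroup parsimony on array lengths in bp: when the two
#' ingroup lengths differ and one of them equals the outgroup length,
#' the matching lineage is taken as ancestral and the other as derived
#' (a gain when longer than the outgroup, a loss when shorter). When
#' both ingroup lengths differ from the outgroup the locus cannot be
#' polarized; when all three agree it is conserved. Lengths are compared
#' in bp rather than copy numbers because the outgroup unit consensus
#' may drift; differences that are not exact unit multiples are reported
#' with `units_integral = FALSE`.
#'
#' @param len_a,len_b,len_out array lengths in bp (vectorized).
#' @param unit_length repeat unit length(s) in bp.
#' @return data.frame with `len_a`, `len_b`, `len_out`, `unit_length`,
#'   `classification` (`conserved`, `derived_in_a`, `derived_in_b`,
#'   `unpolarized`), `direction` (`gain`, `loss`, `none`),
#'   `units_changed` (signed difference of the derived lineage from the
#'   outgroup, in units; `NA` when not applicable) and `units_integral`.
#' @examples
#' polarize(240, 228, 240, 12)  # loss of one unit in species B
#' polarize(283, 235, 235, 24)  # gain of two units in species A
#' @export
polarize <- function(len_a, len_b, len_out, unit_length) {
  n <- max(length(len_a), length(len_b), length(len_out),
           length(unit_length))
  len_a <- rep_len(len_a, n); len_b <- rep_len(len_b, n)
  len_out <- rep_len(len_out, n)
  unit_length <- rep_len(unit_length, n)
  stopifnot(all(len_a > 0), all(len_b > 0), all(len_out > 0),
            all(unit_length >= 2))
  cls <- ifelse(len_a == len_out & len_b == len_out, "conserved",
         ifelse(len_b == len_out & len_a != len_out, "derived_in_a",
         ifelse(len_a == len_out & len_b != len_out, "derived_in_b",
                "unpolarized")))
  derivedLen <- ifelse(cls == "derived_in_a", len_a,
                ifelse(cls == "derived_in_b", len_b, NA_real_))
  diffBp <- derivedLen - len_out
  dir <- ifelse(cls %in% c("conserved", "unpolarized"), "none",
                ifelse(diffBp > 0, "gain", "loss"))
  unitsChanged <- diffBp / unit_length
  integral <- !is.na(unitsChanged) & unitsChanged == round(unitsChanged)
  unitsChanged[integral] <- round(unitsChanged[integral])
  data.frame(len_a = len_a, len_b = len_b, len_out = len_out,
             unit_length = unit_length, classification = cls,
             direction = dir, units_changed = unitsChanged,
             units_integral = ifelse(is.na(unitsChanged), NA, integral),
             stringsAsFactors = FALSE)
}

#' Summary counts of polarity calls
#'
#' @param calls data.frame with a `classification` column, e.g. from
#'   [polarize()] or [buildPolarityCalls()].
#' @return named integer vector: `n_with_outgroup` (total calls),
#'   `n_unpolarized`, `n_derived_in_a`, `n_derived_in_b`,
#'   `n_conserved`; the last four partition the first.
#' @export
polaritySummary <- function(calls) {
  cl <- calls$classification
  c(n_with_outgroup = length(cl),
    n_unpolarized = sum(cl == "unpolarized"),
    n_derived_in_a = sum(cl == "derived_in_a"),
    n_derived_in_b = sum(cl == "derived_in_b"),
    n_conserved = sum(cl == "conserved"))
}

#' Anchor variable loci in an outgroup and polarize their changes
#'
#' Re-anchors each variable locus (typically the coding-variable
#' subset) in the outgroup genome with the relaxed outgroup thresholds
#' (>90 bp of flank on both sides, e-value at most 1e-5), assembles the
#' three array lengths from the two pairwise anchorings, and applies
#' [polarize()]. Loci without an eligible outgroup hit are dropped from
#' the output (they cannot be polarized at all).
#'
#' @param variables data.frame from [callVariableLength()] (optionally
#'   subset to CDS-resident loci), carrying `array_length` and
#'   `array_length_delta` relative to the congener.
#' @param flanked data.frame from [filterCleanFlanks()] providing the
#'   query flanks (rows matched by `locus_id`).
#' @param outgroupGenome outgroup genome sequences.
#' @param ... passed to [anchorLoci()].
#' @return data.frame: `locus_id`, `unit_length`, the three lengths,
#'   and the [polarize()] columns.
#' @export
buildPolarityCalls <- function(variables, flanked, outgroupGenome, ...) {
  emptyOut <- cbind(data.frame(locus_id = character()),
                    polarize(1, 1, 1, 2)[integer(0L), , drop = FALSE])
  if (nrow(variables) == 0L) return(emptyOut)
  fl <- flanked[match(unique(variables$locus_id), flanked$locus_id), ,
                drop = FALSE]
  fl <- fl[!is.na(fl$locus_id), , drop = FALSE]
  om <- anchorLoci(fl, outgroupGenome, mode = "outgroup", ...)
  if (nrow(om) == 0L) return(emptyOut)
  v <- variables[!duplicated(variables$locus_id), , drop = FALSE]
  idx <- match(om$locus_id, v$locus_id)
  keep <- !is.na(idx)
  om <- om[keep, , drop = FALSE]; idx <- idx[keep]
  if (!nrow(om)) return(emptyOut)
  lenA <- v$array_length[idx]
  lenB <- lenA + v$array_length_delta[idx]
  lenOut <- om$target_array_end - om$target_array_start + 1L
  cbind(data.frame(locus_id = om$locus_id, stringsAsFactors = FALSE),
        polarize(lenA, lenB, lenOut, v$unit_length[idx]))
}
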