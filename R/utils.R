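# Shared small utilities: sequence coercion/validation, unit
# canonicalization, lowercase-run measurement.

.BASES <- c("A", "C", "G", "T", "N")

# Coerce a genome to a named character vector, preserving case.
.asSeqChar <- function(genome) {
  if (is(genome, "XStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("genome must be a character vector or an XStringSet")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop("genome sequences must be named (chromosome names)")
  out
}

# Error naming the first offending position, per the detection contract.
.validateAlphabet <- function(seq, chrom = "sequence") {
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (bad > 0L)
    stop(sprintf("unknown character '%s' in %s at position %d",
                 substr(seq, bad, bad), chrom, bad))
  invisible(TRUE)
}

# integer codes 1..5 = A C G T N (lowercase folded)
.encodeSeq <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], .BASES)
  x[is.na(x)] <- 5L
  x
}

#' Canonical form of a repeat unit
#'
#' Reduces a unit to its primitive period (so "AGAG" becomes "AG") and
#' returns the lexicographically minimal rotation, the form under which
#' unit sequences are counted in catalog summaries. No reverse-complement
#' merging is performed: units are counted on the given strand.
#'
#' @param unit character vector of unit sequences (A/C/G/T/N).
#' @return character vector of canonical units.
#' @examples
#' canonicalUnit(c("GA", "AG", "AGAG", "CAG"))
#' @export
canonicalUnit <- function(unit) {
  vapply(toupper(unit), function(u) {
    v <- strsplit(u, "", fixed = TRUE)[[1L]]
    p <- length(v)
    if (p == 0L) return("")
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && all(v == v[((seq_len(p) - 1L) %% d) + 1L])) {
        v <- v[seq_len(d)]
        p <- d
        break
      }
    }
    if (p == 1L) return(v)
    # compare rotations on base codes (A<C<G<T<N), not locale collation
    code <- match(v, .BASES)
    code[is.na(code)] <- 5L
    best <- 0L
    for (r in seq_len(p - 1L)) {
      a <- code[((seq_len(p) + r - 1L) %% p) + 1L]
      b <- code[((seq_len(p) + best - 1L) %% p) + 1L]
      d <- which(a != b)
      if (length(d) && a[d[1L]] < b[d[1L]]) best <- r
    }
    paste(v[((seq_len(p) + best - 1L) %% p) + 1L], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Majority consensus of encoded segment read at period p (ties toward the
# alphabetically first base; all-N classes stay N). Returns integer codes.
.phaseConsensus <- function(enc, p) {
  cls <- ((seq_along(enc) - 1L) %% p) + 1L
  vapply(seq_len(p), function(j) {
    b <- enc[cls == j]
    cnt <- tabulate(b[b < 5L], nbins = 4L)
    if (all(cnt == 0L)) 5L else which.max(cnt)
  }, 0L)
}

.primitivePeriod <- function(cons) {
  p <- length(cons)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L && all(cons == cons[((seq_len(p) - 1L) %% d) + 1L]))
      return(d)
  }
  p
}

# longest run of lowercase (soft-masked) letters in a string
.maxLowercaseRun <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1L]]
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
  }, 0L, USE.NAMES = FALSE)
}

# empirical percentile, inverse-ECDF definition (smallest observed value
# with cumulative frequency >= prob)
.empiricalPercentile <- function(x, prob) {
  if (length(x) == 0L) return(NA_real_)
  unname(quantile(x, probs = prob, type = 1L))
}
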