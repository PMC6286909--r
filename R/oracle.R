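#' Brute-force tandem repeat reference
#'
#' Exhaustive reference implementation of the tandem repeat search used to
#' validate [detectTandemRepeats()]. For every (start, end, period) triple
#' with period between 2 and `maxPeriod` and array length at least
#' max(`minArray`, 2 * period), it computes the tandem alignment score by
#' wraparound dynamic programming (the same scoring definition as the
#' detector, implemented independently in pure R), applies the catalog
#' filters, and performs the same greedy best-score selection. Intended
#' for short sequences (a few hundred bp): runtime grows with
#' length^2 * period.
#'
#' @param sequence a single character string over A/C/G/T/N (case folded).
#' @param params a [detectorParams()] object.
#' @param maxPeriod largest period enumerated (default 6).
#' @return data.frame with columns `start`, `end`, `unit`, `unit_length`,
#'   `array_length`, `copy_number`, `score`, `percent_matches`, `period`,
#'   sorted by start; zero rows if nothing qualifies.
#' @examples
#' bruteForceTandemRepeats(strrep("AG", 25))
#' @export
bruteForceTandemRepeats <- function(sequence, params = detectorParams(),
                                    maxPeriod = 6L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  .validateAlphabet(sequence)
  S <- .encodeSeq(sequence)
  n <- length(S)
  emptyRes <- data.frame(start = integer(), end = integer(),
                         unit = character(), unit_length = integer(),
                         array_length = integer(), copy_number = numeric(),
                         score = integer(), percent_matches = numeric(),
                         period = integer(), stringsAsFactors = FALSE)
  if (n < params@minArray) return(emptyRes)
  mt <- params@match; mm <- params@mismatch; ind <- params@indel
  nCum <- cumsum(c(0L, S == 5L))
  cs <- ce <- csc <- cp <- integer(0L)

  for (p in 2:max(2L, min(maxPeriod, n %/% 2L))) {
    minLen <- max(params@minArray, 2L * p)
    if (minLen > n) break
    nS <- n - minLen + 1L
    if (nS < 1L) next
    # U[s, j] = base j of the unit anchored at start s
    U <- matrix(S[outer(seq_len(nS) - 1L, seq_len(p), "+")], nS, p)
    D <- matrix(0L, nS, p)
    wrap <- c(p, seq_len(p - 1L))
    starts <- seq_len(nS)
    for (i in seq_len(n)) {
      M <- matrix(-mm, nS, p)
      if (S[i] != 5L) M[U == S[i]] <- mt
      Tm <- pmax(D[, wrap, drop = FALSE] + M, D - ind)
      repeat {
        T2 <- pmax(Tm, Tm[, wrap, drop = FALSE] - ind)
        if (identical(T2, Tm)) break
        Tm <- T2
      }
      D <- Tm
      if (i < nS) D[(i + 1L):nS, ] <- 0L
      lens <- i - starts + 1L
      sc <- D[, 1L]
      if (p > 1L) for (j in 2:p) sc <- pmax(sc, D[, j])
      qual <- which(lens >= minLen & sc >= params@minScore &
                      10L * (nCum[i + 1L] - nCum[starts]) <= lens)
      if (length(qual)) {
        cs <- c(cs, qual)
        ce <- c(ce, rep.int(i, length(qual)))
        csc <- c(csc, sc[qual])
        cp <- c(cp, rep.int(p, length(qual)))
      }
    }
  }
  if (!length(cs)) return(emptyRes)

  # consensus-based primitive period for filtering and tie-breaks
  cq <- mapply(function(s, e, p) {
    .primitivePeriod(.phaseConsensus(S[s:e], p))
  }, cs, ce, cp)
  keep <- cq >= params@minUnit
  cs <- cs[keep]; ce <- ce[keep]; csc <- csc[keep]
  cp <- cp[keep]; cq <- cq[keep]
  if (!length(cs)) return(emptyRes)

  # greedy: best score, longest array, shortest unit, leftmost, smallest
  # enumerated period; accepted arrays must not overlap
  ord <- order(-csc, -(ce - cs + 1L), cq, cs, cp)
  accS <- accE <- integer(0L)
  accIdx <- integer(0L)
  for (k in ord) {
    if (any(ce[k] >= accS & cs[k] <= accE)) next
    accIdx <- c(accIdx, k)
    accS <- c(accS, cs[k]); accE <- c(accE, ce[k])
  }
  accIdx <- accIdx[order(cs[accIdx])]

  res <- lapply(accIdx, function(k) {
    seg <- S[cs[k]:ce[k]]
    cons <- .phaseConsensus(seg, cp[k])
    len <- ce[k] - cs[k] + 1L
    pm <- mean(seg == cons[((seq_len(len) - 1L) %% cp[k]) + 1L] & seg != 5L)
    data.frame(start = cs[k], end = ce[k],
               unit = canonicalUnit(paste(.BASES[cons[seq_len(cq[k])]],
                                          collapse = "")),
               unit_length = cq[k], array_length = len,
               copy_number = len / cq[k], score = csc[k],
               percent_matches = pm, period = cp[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
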