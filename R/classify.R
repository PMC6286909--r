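#' Classify a per-individual allele-length panel
#'
#' Classifies the array lengths observed across individuals of two
#' species at one locus into four categories: `invariant` (every
#' individual of both species shows the same length), `not_fixed` (the
#' two species' observed length sets share at least one value —
#' trans-species variation with overlapping distributions),
#' `within_species_variation` (the species' length sets are disjoint
#' but at least one species is polymorphic), and `fixed_between`
#' (disjoint sets, each species internally monomorphic). Overlap is
#' judged on shared observed values, not ranges: with the small panels
#' this scheme is designed for, ranges would overstate overlap.
#'
#' @param lengths_a,lengths_b numeric vectors of observed array lengths
#'   (one entry per individual); both must be non-empty.
#' @return a single classification string.
#' @examples
#' classifyPanel(c(312, 312, 312), c(327, 327, 327, 327, 327))
#' classifyPanel(c(312, 315, 315), c(321, 324, 324, 321, 324))
#' @export
classifyPanel <- function(lengths_a, lengths_b) {
  if (length(lengths_a) == 0L || length(lengths_b) == 0L)
    stop("both species need at least one observed length")
  ua <- unique(lengths_a); ub <- unique(lengths_b)
  if (length(ua) == 1L && length(ub) == 1L && ua == ub)
    return("invariant")
  if (length(intersect(ua, ub)) > 0L)
    return("not_fixed")
  if (length(ua) > 1L || length(ub) > 1L)
    return("within_species_variation")
  "fixed_between"
}

#' Classify every locus of a long-format allele panel
#'
#' @param panel data.frame with columns `locus_id`, `species` (values
#'   "a"/"b"), `length_bp`, e.g. from [simulatePopulationAlleles()].
#' @return data.frame with `locus_id` and `classification`.
#' @export
classifyPanels <- function(panel) {
  stopifnot(all(c("locus_id", "species", "length_bp") %in% names(panel)))
  ids <- unique(panel$locus_id)
  cls <- vapply(ids, function(id) {
    p <- panel[panel$locus_id == id, ]
    classifyPanel(p$length_bp[p$species == "a"],
                  p$length_bp[p$species == "b"])
  }, "")
  data.frame(locus_id = ids, classification = unname(cls),
             stringsAsFactors = FALSE)
}

#' Category enrichment fold from contingency counts
#'
#' Compares the share of a category among `k` of `n` foreground genes
#' with its share among `K` of `N` background genes:
#' fold = (k/n) / (K/N). A hypergeometric upper-tail probability can be
#' reported as well, but is off by default since the fold alone is the
#' headline statistic.
#'
#' @param k,n category hits and total in the foreground.
#' @param K,N category hits and total in the background.
#' @param hypergeometric also compute the upper-tail probability of
#'   observing at least `k` hits.
#' @return one-row data.frame with `k`, `n`, `K`, `N`,
#'   `foreground_pct`, `background_pct`, `fold` (`NA` with
#'   `fold_defined = FALSE` when `K = 0` and `k > 0`), and
#'   `hypergeometric_p` when requested.
#' @examples
#' enrichmentFold(11, 85, 529, 13000)
#' @export
enrichmentFold <- function(k, n, K, N, hypergeometric = FALSE) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (k < 0 || K < 0 || k > n || K > N || n <= 0 || N <= 0)
    stop("need 0 <= k <= n and 0 <= K <= N with n, N positive")
  fg <- 100 * k / n
  bg <- 100 * K / N
  defined <- K > 0 || k == 0
  fold <- if (!defined) NA_real_ else if (k == 0) 0 else (k / n) / (K / N)
  out <- data.frame(k = k, n = n, K = K, N = N, foreground_pct = fg,
                    background_pct = bg, fold = fold,
                    fold_defined = defined)
  if (hypergeometric)
    out$hypergeometric_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out
}
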