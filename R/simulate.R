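#' Simulation configuration for a synthetic genome trio
#'
#' Builds and validates the configuration for [simulateGenomeTrio()]. The
#' defaults emulate the study system the package targets: an AT-rich
#' (~63% AT) insect genome carrying planted tandem repeat arrays (units
#' of at least 2 bp, arrays of at least 30 bp) of which roughly two
#' thirds fall inside genes, with two closely related ingroup lineages
#' and a more distant
#' outgroup diverging from a common ancestor by lineage-specific repeat
#' unit-number changes and background point substitutions.
#'
#' @param seed integer RNG seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param n_chromosomes,chrom_length genome shape of every lineage.
#' @param at_fraction background A+T fraction in `[0,1]`.
#' @param n_tr_loci number of planted tandem repeat loci.
#' @param genic_fraction probability a locus falls inside a gene.
#' @param coding_fraction_of_genic probability a genic locus lies inside
#'   the CDS (in frame, codon aligned).
#' @param unit_length_weights numeric weights over unit lengths 2..50;
#'   default decays as length^-1.2, mirroring the dominance of short
#'   units in real catalogs.
#' @param copy_number_range integer range for ancestral unit copies;
#'   raised per locus so every lineage keeps arrays >= 30 bp and >= 2
#'   copies.
#' @param p_variable per-locus, per-lineage probability of a
#'   unit-number change.
#' @param step_probs named numeric vector of signed unit-count changes
#'   (names are the steps) used when a lineage mutates.
#' @param point_divergence_ingroup,point_divergence_outgroup per-site
#'   substitution rate applied to each ingroup lineage and to the
#'   outgroup, outside planted arrays and CDS.
#' @param masked_repeat_density fraction of loci given a 15 bp
#'   soft-masked (lowercase) run within one flank, mimicking an adjacent
#'   interspersed repeat.
#' @param array_noise per-base substitution rate inside planted arrays
#'   (0 by default so ground truth stays exact; raise it for robustness
#'   tests).
#' @param reverse_strand_fraction fraction of genes placed on the minus
#'   strand (0 by default; raise it to exercise strand handling).
#' @param min_spacing minimal intergenic gap around each planted
#'   cassette in bp (>= 100 so full flanks always exist).
#' @return validated configuration list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(n_tr_loci = 10, chrom_length = 30000)
#' @export
simConfig <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 250000L,
                      at_fraction = 0.63, n_tr_loci = 500L,
                      genic_fraction = 0.667,
                      coding_fraction_of_genic = 0.5,
                      unit_length_weights = NULL,
                      copy_number_range = c(4L, 12L), p_variable = 0.3,
                      step_probs = c("-2" = 0.2, "-1" = 0.3,
                                     "1" = 0.3, "2" = 0.2),
                      point_divergence_ingroup = 0.005,
                      point_divergence_outgroup = 0.03,
                      masked_repeat_density = 0.1, array_noise = 0,
                      reverse_strand_fraction = 0, min_spacing = 250L) {
  if (is.null(unit_length_weights))
    unit_length_weights <- (2:50)^-1.2
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              at_fraction = at_fraction, n_tr_loci = as.integer(n_tr_loci),
              genic_fraction = genic_fraction,
              coding_fraction_of_genic = coding_fraction_of_genic,
              unit_length_weights = unit_length_weights,
              copy_number_range = as.integer(copy_number_range),
              p_variable = p_variable, step_probs = step_probs,
              point_divergence_ingroup = point_divergence_ingroup,
              point_divergence_outgroup = point_divergence_outgroup,
              masked_repeat_density = masked_repeat_density,
              array_noise = array_noise,
              reverse_strand_fraction = reverse_strand_fraction,
              min_spacing = as.integer(min_spacing))
  props <- c(cfg$at_fraction, cfg$genic_fraction,
             cfg$coding_fraction_of_genic, cfg$p_variable,
             cfg$masked_repeat_density, cfg$array_noise,
             cfg$reverse_strand_fraction)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (length(cfg$unit_length_weights) != 49L ||
      any(cfg$unit_length_weights < 0) || sum(cfg$unit_length_weights) <= 0)
    stop("unit_length_weights must be 49 non-negative weights over 2..50")
  if (length(cfg$copy_number_range) != 2L ||
      any(cfg$copy_number_range < 2L) || diff(cfg$copy_number_range) < 0L)
    stop("copy_number_range must be two integers >= 2, low <= high")
  if (is.null(names(cfg$step_probs)) ||
      any(is.na(suppressWarnings(as.integer(names(cfg$step_probs))))) ||
      any(as.integer(names(cfg$step_probs)) == 0L) ||
      any(cfg$step_probs < 0) || sum(cfg$step_probs) <= 0)
    stop("step_probs must be named by non-zero signed integer steps")
  if (cfg$min_spacing < 100L)
    stop("min_spacing must be >= 100 bp so flanks are always complete")
  if (cfg$n_chromosomes < 1L || cfg$chrom_length < 1000L)
    stop("need at least one chromosome of >= 1000 bp")
  class(cfg) <- "SimConfig"
  cfg
}

.STOPS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.randBg <- function(n, atf) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "C", "G"), n, TRUE,
               c(atf / 2, atf / 2, (1 - atf) / 2, (1 - atf) / 2)),
        collapse = "")
}

.randCodons <- function(k) paste(sample(.SENSE_CODONS, k, TRUE), collapse = "")

# primitive unit with the requested AT content; coding units additionally
# avoid stop codons in reading frame 0
.sampleUnit <- function(len, atf, coding) {
  for (try in 1:200) {
    u <- .randBg(len, atf)
    codes <- .encodeSeq(u)
    if (.primitivePeriod(codes) != len) next
    if (coding) {
      cod <- substring(u, seq(1L, len, 3L), seq(3L, len, 3L))
      if (any(cod %in% .STOPS)) next
    }
    return(u)
  }
  stop("could not sample a primitive unit of length ", len)
}

.mutateSubs <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(runif(length(v)) < rate)
  if (length(idx)) {
    b <- c("A", "C", "G", "T")
    off <- sample.int(3L, length(idx), replace = TRUE)
    v[idx] <- b[((match(v[idx], b) - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

.revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

#' Simulate a three-genome test universe with planted tandem repeats
#'
#' Draws an i.i.d. AT-rich ancestor, plants tandem repeat cassettes
#' (intergenic, genic-untranslated, or inside a CDS with in-frame,
#' codon-aligned units), then lets three lineages evolve independently:
#' each lineage gains or loses whole repeat units with probability
#' `p_variable` per locus and accumulates background point substitutions
#' at the configured rates (never inside planted arrays or CDS by
#' default, so ground truth stays exact). A fraction of loci receive a
#' soft-masked 15 bp lowercase run in one flank. Gene annotations
#' (gene/mRNA/CDS) and translated proteomes are produced for the two
#' ingroup lineages.
#'
#' @param config a [simConfig()] object.
#' @return a [GenomeTrioSim-class] object.
#' @examples
#' sim <- simulateGenomeTrio(simConfig(n_tr_loci = 5, chrom_length = 20000,
#'                                     n_chromosomes = 1, seed = 7))
#' truthTable(sim)
#' @export
simulateGenomeTrio <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_tr_loci
  lineages <- c("a", "b", "out")
  drate <- c(a = cfg$point_divergence_ingroup,
             b = cfg$point_divergence_ingroup,
             out = cfg$point_divergence_outgroup)

  ## ---- per-locus properties -------------------------------------------
  loci <- NULL
  if (n > 0L) {
    genic <- runif(n) < cfg$genic_fraction
    coding <- genic & (runif(n) < cfg$coding_fraction_of_genic)
    ulen <- integer(n)
    wAll <- cfg$unit_length_weights
    lenAll <- 2:50
    len3 <- lenAll[lenAll %% 3L == 0L]
    w3 <- wAll[lenAll %% 3L == 0L]
    for (i in seq_len(n)) {
      ulen[i] <- if (coding[i]) sample(len3, 1L, prob = w3)
                 else sample(lenAll, 1L, prob = wAll)
    }
    unit <- vapply(seq_len(n), function(i)
      .sampleUnit(ulen[i], cfg$at_fraction, coding[i]), "")
    cmin <- pmax(2L, ceiling(30L / ulen))
    c0 <- pmax(sample(seq(cfg$copy_number_range[1L],
                          cfg$copy_number_range[2L]), n, TRUE), cmin + 2L)
    steps <- as.integer(names(cfg$step_probs))
    copies <- matrix(rep(c0, 3L), n, 3L,
                     dimnames = list(NULL, lineages))
    for (L in lineages) {
      mut <- runif(n) < cfg$p_variable
      for (i in which(mut)) {
        for (try in 1:50) {
          st <- sample(steps, 1L, prob = cfg$step_probs)
          if (c0[i] + st >= cmin[i]) break
          st <- 0L
        }
        copies[i, L] <- c0[i] + st
      }
    }
    masked <- runif(n) < cfg$masked_repeat_density
    maskLeft <- runif(n) < 0.5
    strand <- rep("+", n)
    strand[genic & runif(n) < cfg$reverse_strand_fraction] <- "-"
    chrom <- rep(seq_len(cfg$n_chromosomes), length.out = n)
    loci <- data.frame(idx = seq_len(n), chrom = chrom, genic = genic,
                       coding = coding, unit = unit, unit_length = ulen,
                       strand = strand, masked = masked,
                       maskLeft = maskLeft, stringsAsFactors = FALSE)
    loci <- cbind(loci, copies_a = copies[, "a"], copies_b = copies[, "b"],
                  copies_out = copies[, "out"])
  }

  ## ---- cassette templates (sense orientation) -------------------------
  # A cassette is a list of pieces: list(kind, seq or unit info).
  # kinds: "utr" (mutable), "cds" (immutable codons), "array".
  cassettes <- vector("list", if (is.null(loci)) 0L else n)
  if (!is.null(loci)) {
    for (i in seq_len(n)) {
      if (!loci$genic[i]) {
        cassettes[[i]] <- list(pieces = list(list(kind = "array")),
                               gene = FALSE)
      } else if (!loci$coding[i]) {
        k <- sample(30:50, 1L)
        cassettes[[i]] <- list(pieces = list(
          list(kind = "utr", seq = .randBg(40L, cfg$at_fraction)),
          list(kind = "array"),
          list(kind = "utr", seq = .randBg(40L, cfg$at_fraction)),
          list(kind = "cds", seq = paste0("ATG", .randCodons(k), "TAA")),
          list(kind = "utr", seq = .randBg(30L, cfg$at_fraction))),
          gene = TRUE)
      } else {
        k1 <- sample(15:35, 1L); k2 <- sample(15:35, 1L)
        cassettes[[i]] <- list(pieces = list(
          list(kind = "utr", seq = .randBg(30L, cfg$at_fraction)),
          list(kind = "cds", seq = paste0("ATG", .randCodons(k1))),
          list(kind = "array"),
          list(kind = "cds", seq = paste0(.randCodons(k2), "TAA")),
          list(kind = "utr", seq = .randBg(30L, cfg$at_fraction))),
          gene = TRUE)
      }
    }
  }
  # layout budgets each cassette at its largest per-lineage length
  casLen0 <- integer(0L)
  if (!is.null(loci)) {
    anc <- pmax(loci$copies_a, loci$copies_b, loci$copies_out)
    casLen0 <- vapply(seq_len(n), function(i)
      sum(vapply(cassettes[[i]]$pieces, function(pc)
        as.integer(if (pc$kind == "array") loci$unit_length[i] * anc[i]
                   else nchar(pc$seq)), 0L)), 0L)
  }

  ## ---- chromosome layout + ancestral gaps -----------------------------
  gapSeqs <- vector("list", cfg$n_chromosomes)
  chromLoci <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    ids <- if (is.null(loci)) integer(0L) else loci$idx[loci$chrom == ch]
    chromLoci[[ch]] <- ids
    ngap <- length(ids) + 1L
    leftover <- cfg$chrom_length - sum(casLen0[ids])
    if (leftover < cfg$min_spacing * ngap)
      stop("chromosome ", ch, " too short to host ", length(ids),
           " loci with ", cfg$min_spacing, " bp clearances")
    extra <- leftover - cfg$min_spacing * ngap
    props <- runif(ngap)
    g <- floor(props / sum(props) * extra)
    g[1L] <- g[1L] + extra - sum(g)
    glen <- cfg$min_spacing + g
    gapSeqs[[ch]] <- vapply(glen, .randBg, "", atf = cfg$at_fraction)
  }

  ## ---- assemble each lineage ------------------------------------------
  genomes <- list()
  geneTabs <- list()
  arrayPos <- list()  # per lineage: data.frame idx, start, end
  cdsSeqs <- list()   # per lineage: named character per gene
  for (L in lineages) {
    chromStrings <- character(cfg$n_chromosomes)
    art <- list(); genes <- list(); cdss <- character(0L)
    for (ch in seq_len(cfg$n_chromosomes)) {
      ids <- chromLoci[[ch]]
      parts <- character(0L)
      cursor <- 0L
      for (k in seq_along(ids)) {
        gseq <- .mutateSubs(gapSeqs[[ch]][k], drate[[L]])
        parts <- c(parts, gseq)
        cursor <- cursor + nchar(gseq)
        i <- ids[k]
        cp <- loci[[paste0("copies_", L)]][i]
        arr <- strrep(loci$unit[i], cp)
        if (cfg$array_noise > 0)
          arr <- .mutateSubs(arr, cfg$array_noise)
        pieces <- cassettes[[i]]$pieces
        built <- character(length(pieces))
        off <- 0L
        aLo <- aHi <- NA_integer_
        cdsLo <- cdsHi <- NA_integer_
        senseCds <- character(0L)
        for (pi in seq_along(pieces)) {
          pc <- pieces[[pi]]
          pseq <- switch(pc$kind,
                         array = arr,
                         utr = .mutateSubs(pc$seq, drate[[L]]),
                         cds = pc$seq)
          built[pi] <- pseq
          if (pc$kind == "array") {
            aLo <- off + 1L; aHi <- off + nchar(pseq)
          }
          if (pc$kind == "cds" ||
              (pc$kind == "array" && loci$coding[i])) {
            if (is.na(cdsLo)) cdsLo <- off + 1L
            cdsHi <- off + nchar(pseq)
            senseCds <- c(senseCds, pseq)
          }
          off <- off + nchar(pseq)
        }
        cas <- paste(built, collapse = "")
        casL <- nchar(cas)
        str <- loci$strand[i]
        if (str == "-") {
          cas <- .revcomp(cas)
          tmp <- aLo; aLo <- casL - aHi + 1L; aHi <- casL - tmp + 1L
          if (!is.na(cdsLo)) {
            tmp <- cdsLo; cdsLo <- casL - cdsHi + 1L; cdsHi <- casL - tmp + 1L
          }
        }
        art[[length(art) + 1L]] <- data.frame(
          idx = i, chrom = ch, start = cursor + aLo, end = cursor + aHi,
          stringsAsFactors = FALSE)
        if (cassettes[[i]]$gene) {
          gid <- sprintf("G%04d", i)
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = gid, chrom = ch, gene_start = cursor + 1L,
            gene_end = cursor + casL, cds_start = cursor + cdsLo,
            cds_end = cursor + cdsHi, strand = str,
            stringsAsFactors = FALSE)
          cdss[gid] <- paste(senseCds, collapse = "")
        }
        parts <- c(parts, cas)
        cursor <- cursor + casL
      }
      finalGap <- .mutateSubs(gapSeqs[[ch]][length(ids) + 1L], drate[[L]])
      parts <- c(parts, finalGap)
      chromStrings[ch] <- paste(parts, collapse = "")
    }
    names(chromStrings) <- paste0("chr", seq_len(cfg$n_chromosomes))
    # soft-mask a 15 bp run in one flank of flagged loci
    aTab <- if (length(art)) do.call(rbind, art) else
      data.frame(idx = integer(), chrom = integer(), start = integer(),
                 end = integer())
    if (nrow(aTab) > 0L) {
      for (r in seq_len(nrow(aTab))) {
        i <- aTab$idx[r]
        if (!loci$masked[i]) next
        ch <- aTab$chrom[r]
        if (loci$maskLeft[i]) {
          lo <- aTab$start[r] - 40L; hi <- aTab$start[r] - 26L
        } else {
          lo <- aTab$end[r] + 26L; hi <- aTab$end[r] + 40L
        }
        s <- chromStrings[ch]
        substr(s, lo, hi) <- tolower(substr(s, lo, hi))
        chromStrings[ch] <- s
      }
    }
    genomes[[L]] <- BStringSet(chromStrings)
    arrayPos[[L]] <- aTab
    geneTabs[[L]] <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = integer(),
                 gene_start = integer(), gene_end = integer(),
                 cds_start = integer(), cds_end = integer(),
                 strand = character())
    cdsSeqs[[L]] <- cdss
  }

  ## ---- annotations and proteomes for the ingroup ----------------------
  annotations <- list()
  proteins <- list()
  for (L in c("a", "b")) {
    gt <- geneTabs[[L]]
    if (nrow(gt) > 0L) {
      mk <- function(type, s, e, id, parent, phase) {
        GRanges(paste0("chr", gt$chrom), IRanges(s, e), strand = gt$strand,
                type = type, ID = id, Parent = parent,
                gene_id = gt$gene_id, phase = phase)
      }
      gr <- c(
        mk("gene", gt$gene_start, gt$gene_end, gt$gene_id,
           NA_character_, NA_integer_),
        mk("mRNA", gt$gene_start, gt$gene_end, paste0(gt$gene_id, ".m"),
           gt$gene_id, NA_integer_),
        mk("CDS", gt$cds_start, gt$cds_end, paste0(gt$gene_id, ".cds"),
           paste0(gt$gene_id, ".m"), 0L))
      gr <- sort(gr, ignore.strand = TRUE)
    } else {
      gr <- GRanges()
      mcols(gr) <- DataFrame(type = character(), ID = character(),
                             Parent = character(), gene_id = character(),
                             phase = integer())
    }
    GenomeInfoDb::seqlevels(gr) <-
      paste0("chr", seq_len(cfg$n_chromosomes))
    annotations[[L]] <- gr
    cds <- cdsSeqs[[L]]
    if (length(cds)) {
      aa <- as.character(translate(DNAStringSet(cds)))
      aa <- sub("\\*$", "", aa)
      proteins[[L]] <- AAStringSet(setNames(aa, names(cds)))
    } else {
      proteins[[L]] <- AAStringSet()
    }
  }

  ## ---- ground truth (focal coordinates) -------------------------------
  if (!is.null(loci) && nrow(arrayPos[["a"]]) > 0L) {
    pa <- arrayPos[["a"]]
    pa <- pa[order(pa$idx), ]
    unitOnGenome <- ifelse(loci$strand == "-",
                           vapply(loci$unit, .revcomp, ""), loci$unit)
    truth <- data.frame(
      locus_id = sprintf("L%04d", loci$idx),
      chrom = paste0("chr", loci$chrom),
      start = pa$start, end = pa$end,
      unit_sequence = unname(unitOnGenome),
      unit_length = loci$unit_length,
      copies_a = loci$copies_a, copies_b = loci$copies_b,
      copies_out = loci$copies_out,
      genic = loci$genic, coding = loci$coding,
      in_frame = loci$unit_length %% 3L == 0L,
      flank_masked = loci$masked,
      strand = loci$strand,
      gene_id = ifelse(loci$genic, sprintf("G%04d", loci$idx),
                       NA_character_),
      stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(
      locus_id = character(), chrom = character(), start = integer(),
      end = integer(), unit_sequence = character(),
      unit_length = integer(), copies_a = integer(),
      copies_b = integer(), copies_out = integer(), genic = logical(),
      coding = logical(), in_frame = logical(), flank_masked = logical(),
      strand = character(), gene_id = character(),
      stringsAsFactors = FALSE)
  }

  new("GenomeTrioSim", genomes = genomes, annotations = annotations,
      proteins = proteins, truth = truth, config = unclass(cfg))
}

#' Simulate per-individual allele lengths for planted loci
#'
#' For each planted locus and each of the two ingroup species, draws
#' `nPerSpecies` individual array lengths: the species' true copy count
#' plus an integer unit-count perturbation with standard deviation
#' `withinSpeciesSd` (rounded normal), floored at one copy. With
#' `withinSpeciesSd = 0` every individual carries the species truth.
#'
#' @param truth truth table from [truthTable()] (or any data.frame with
#'   `locus_id`, `unit_length`, `copies_a`, `copies_b`).
#' @param nPerSpecies named integer vector `c(a = ..., b = ...)`.
#' @param withinSpeciesSd standard deviation of the unit-count
#'   perturbation, in units.
#' @param seed RNG seed.
#' @return data.frame with columns `locus_id`, `species`, `individual`,
#'   `length_bp`; lengths are positive multiples of the unit length.
#' @examples
#' sim <- simulateGenomeTrio(simConfig(n_tr_loci = 4, chrom_length = 20000,
#'                                     n_chromosomes = 1))
#' simulatePopulationAlleles(truthTable(sim), c(a = 3, b = 5))
#' @export
simulatePopulationAlleles <- function(truth, nPerSpecies = c(a = 3L, b = 5L),
                                      withinSpeciesSd = 0, seed = 1L) {
  stopifnot(all(c("a", "b") %in% names(nPerSpecies)),
            all(nPerSpecies >= 1L))
  set.seed(seed)
  out <- list()
  for (sp in c("a", "b")) {
    ni <- as.integer(nPerSpecies[[sp]])
    cp <- truth[[paste0("copies_", sp)]]
    for (ind in seq_len(ni)) {
      pert <- if (withinSpeciesSd > 0)
        as.integer(round(rnorm(nrow(truth), 0, withinSpeciesSd)))
      else rep(0L, nrow(truth))
      cpi <- pmax(1L, cp + pert)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = truth$locus_id, species = sp, individual = ind,
        length_bp = cpi * truth$unit_length, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$locus_id, res$species, res$individual), , drop = FALSE]
}
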