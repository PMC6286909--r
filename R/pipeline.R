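#' Run the full comparative tandem repeat pipeline
#'
#' Orchestrates simulate (or load) - detect - dedupe - annotate -
#' flank-filter - anchor - call variable - coding impact - polarize -
#' classify as one reproducible run. Every stage writes a TSV into the
#' output directory, per-stage counts form a monotone funnel, and a
#' manifest with md5 checksums makes determinism checkable: identical
#' configuration and seed reproduce identical tables.
#'
#' The configuration is a named list (or the path of a YAML file with
#' the same structure) with entries:
#' \describe{
#'   \item{sim}{arguments for [simConfig()] (synthetic mode), or}
#'   \item{paths}{`genome_a`, `genome_b`, `genome_out`, `gff_a`,
#'     `proteins_a`, `proteins_b` for assembled inputs (proteins must
#'     be named by gene identifier),}
#'   \item{detector}{overrides for [detectorParams()] plus an optional
#'     `max_period` scan cap,}
#'   \item{anchor}{`identity` plus `ingroup`/`outgroup` lists with
#'     `min_flank` and `max_evalue` (defaults 95/1e-10 and 90/1e-5),}
#'   \item{population}{`n_a`, `n_b`, `sd` for the allele panel
#'     (synthetic mode only),}
#'   \item{out_dir}{output directory,}
#'   \item{seed}{integer seed for every stochastic step.}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @return a [TRPipelineResult-class] object.
#' @examples
#' \donttest{
#' res <- runTRPipeline(list(
#'   sim = list(n_tr_loci = 30, chrom_length = 40000, n_chromosomes = 1),
#'   out_dir = tempfile("trvar_run"), seed = 11))
#' stageCounts(res)
#' }
#' @export
runTRPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  hasSim <- !is.null(config$sim)
  hasPaths <- !is.null(config$paths)
  if (hasSim == hasPaths)
    stop("config needs exactly one of 'sim' (synthetic) or 'paths'")
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config$out_dir is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  det <- config$detector
  params <- detectorParams(
    match = det$match %||% 2L, mismatch = det$mismatch %||% 7L,
    indel = det$indel %||% 7L, minScore = det$min_score %||% 50L,
    minArray = det$min_array %||% 30L, maxUnit = det$max_unit %||% 2000L)
  maxPeriod <- det$max_period %||% params@maxUnit
  anc <- config$anchor
  inThr <- list(min_flank = anc$ingroup$min_flank %||% 95L,
                max_evalue = anc$ingroup$max_evalue %||% 1e-10)
  outThr <- list(min_flank = anc$outgroup$min_flank %||% 90L,
                 max_evalue = anc$outgroup$max_evalue %||% 1e-5)
  minIdent <- anc$identity %||% 0.8

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- c()
  emit <- function(df, name) {
    f <- file.path(outDir, paste0(name, ".tsv"))
    .writeTSV(df, f)
    files[name] <<- f
  }

  sim <- NULL; truth <- NULL
  if (hasSim) {
    simArgs <- config$sim
    simArgs$seed <- simArgs$seed %||% seed
    sim <- stage("simulate", simulateGenomeTrio(do.call(simConfig, simArgs)))
    files <- c(files, stage("simulate", writeSimOutputs(sim, outDir)))
    truth <- truthTable(sim)
    genomeA <- genomeSeqs(sim, "a"); genomeB <- genomeSeqs(sim, "b")
    genomeOut <- genomeSeqs(sim, "out")
    annotA <- annotationOf(sim, "a")
    protA <- proteinSeqs(sim, "a"); protB <- proteinSeqs(sim, "b")
  } else {
    p <- config$paths
    genomeA <- stage("load", readBStringSet(p$genome_a))
    genomeB <- stage("load", readBStringSet(p$genome_b))
    genomeOut <- stage("load", readBStringSet(p$genome_out))
    annotA <- stage("load", rtracklayer::import(p$gff_a))
    protA <- stage("load", readAAStringSet(p$proteins_a))
    protB <- stage("load", readAAStringSet(p$proteins_b))
    names(genomeA) <- sub("\\s.*", "", names(genomeA))
    names(genomeB) <- sub("\\s.*", "", names(genomeB))
    names(genomeOut) <- sub("\\s.*", "", names(genomeOut))
    names(protA) <- sub("\\s.*", "", names(protA))
    names(protB) <- sub("\\s.*", "", names(protB))
  }

  cat_ <- stage("detect",
                detectTandemRepeats(genomeA, params, maxPeriod = maxPeriod))
  emit(as.data.frame(cat_), "catalog")
  nr <- stage("dedupe", eliminateRedundancy(cat_))
  nr <- stage("annotate", annotateGenicContext(nr, annotA))
  emit(as.data.frame(nr), "catalog_nonredundant")
  fl <- stage("flanks", filterCleanFlanks(nr, genomeA))
  emit(fl, "clean_flanked")
  m <- stage("anchor", anchorLoci(fl, genomeB, mode = "ingroup",
                                  minFlank = inThr$min_flank,
                                  maxEvalue = inThr$max_evalue,
                                  minIdentity = minIdent, params = params))
  emit(m, "matches")
  v <- stage("variable", callVariableLength(m))
  emit(v, "variables")
  cd <- stage("coding", intersectCDS(v, annotA))
  conf <- stage("coding",
                confirmProteinVariation(cd, protA, protB, annotA,
                                        reciprocal = hasSim))
  emit(conf, "coding_variants")
  confLoci <- cd[cd$locus_id %in% conf$locus_id, , drop = FALSE]
  pol <- stage("polarize",
               buildPolarityCalls(confLoci, fl, genomeOut,
                                  minFlank = outThr$min_flank,
                                  maxEvalue = outThr$max_evalue,
                                  minIdentity = minIdent, params = params))
  emit(pol, "polarity")

  cls <- data.frame(locus_id = character(), classification = character())
  if (hasSim && nrow(conf) > 0L && nrow(truth) > 0L) {
    pop <- config$population
    confGR <- GRanges(confLoci$chrom,
                      IRanges(confLoci$start, confLoci$end))
    truthGR <- GRanges(truth$chrom, IRanges(truth$start, truth$end))
    ov <- findOverlaps(confGR, truthGR)
    tsub <- truth[unique(subjectHits(ov)), , drop = FALSE]
    panel <- stage("classify", simulatePopulationAlleles(
      tsub, c(a = pop$n_a %||% 3L, b = pop$n_b %||% 5L),
      withinSpeciesSd = pop$sd %||% 0, seed = seed))
    emit(panel, "allele_panel")
    cls <- stage("classify", classifyPanels(panel))
  }
  emit(cls, "classification")

  counts <- c(detected = length(cat_), nonredundant = length(nr),
              clean_flanked = nrow(fl), anchored = nrow(m),
              variable = nrow(v),
              coding_variable = length(unique(conf$locus_id)),
              genes_affected = length(unique(conf$gene_id)),
              polarized = nrow(pol))
  funnel <- counts[c("detected", "nonredundant", "clean_flanked",
                     "anchored", "variable", "coding_variable",
                     "polarized")]
  if (any(diff(funnel) > 0L))
    stop("pipeline funnel is not monotone: ",
         paste(names(funnel), funnel, sep = "=", collapse = ", "))

  manifest <- data.frame(
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL

  new("TRPipelineResult", counts = counts,
      tables = list(catalog = cat_, nonredundant = nr, clean_flanked = fl,
                    matches = m, variables = v, coding_variants = conf,
                    polarity = pol, classification = cls,
                    truth = truth),
      manifest = manifest, outDir = outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
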