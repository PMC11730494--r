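# End-to-end pipeline: config handling, module orchestration and
# human-readable run reports. Config is a YAML file (or equivalent list)
# with sections input, pattern, cascade, linkage, ranking, output; a schema
# violation raises a "usage_error" condition before any computation.

.usageError <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.dataError <- function(...) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.validatePipelineConfig <- function(cfg) {
  if (!is.list(cfg)) .usageError("config must be a list or a YAML file")
  inp <- cfg$input
  if (is.null(inp)) .usageError("config section 'input' is required")
  simulate <- !is.null(inp$simulate)
  if (!simulate) {
    for (f in c("vcf", "ped"))
      if (is.null(inp[[f]])) .usageError("config input$", f, " is required")
    pat <- cfg$pattern
    if (is.null(pat$affected) || length(pat$affected) == 0L)
      .usageError("config pattern$affected is required")
    if (is.null(pat$unaffected) || length(pat$unaffected) == 0L)
      .usageError("config pattern$unaffected is required")
  } else if (!identical(inp$simulate, "study_emulation")) {
    .usageError("input$simulate must be 'study_emulation'")
  }
  invisible(cfg)
}

.cascadeFromConfig <- function(cc) {
  CascadeConfig(
    gnomadMaxAf = cc$gnomad_max_af %||% 0.001,
    cohortAf = cc$cohort_af %||% 0.02,
    caddMin = cc$cadd_min %||% 15,
    requirePass = cc$require_pass %||% TRUE,
    applyIbd = cc$apply_ibd %||% TRUE,
    ibdMode = cc$ibd_mode %||% "gene")
}

#' Run the full prioritisation pipeline
#'
#' Executes, in order: data loading (or the study-emulation simulation),
#' the segregation filter and five-step cascade, IBD shared-region
#' intersection, single-point parametric linkage at each final surviving
#' site, and gene ranking. Every number in the returned report is a module
#' output. With an \code{output$dir} config entry the ledger, linkage table
#' and a text report are written; regeneration from the same inputs and
#' seed is byte-identical.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Sections: \code{input} (\code{vcf}, \code{ped}, \code{annotations},
#'   \code{ibd}, \code{genes} paths, or \code{simulate: study_emulation}),
#'   \code{pattern} (\code{affected}, \code{unaffected} ids),
#'   \code{cascade} (threshold overrides), \code{linkage}
#'   (\code{prevalence}, \code{penetrances}, \code{marker_af}),
#'   \code{ranking} (\code{seed_genes}), \code{seed}, \code{output}
#'   (\code{dir}).
#' @return a [RunReport-class].
#' @export
runFullPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validatePipelineConfig(config)
  seed <- config$seed %||% 1L

  if (!is.null(config$input$simulate)) {
    preset <- studyEmulationPreset(seed = seed)
    sim <- simulateFamily(preset$config)
    ped <- sim$pedigree
    av <- sim$variants
    pattern <- preset$pattern
    ibdSegments <- sim$truth$ibd_tracts
    geneSpans <- sim$truth$gene_spans
  } else {
    inp <- config$input
    ped <- readPed(inp$ped)
    av <- readAnnotatedVcf(inp$vcf, inp$annotations)
    pattern <- SegregationPattern(config$pattern$affected,
                                  config$pattern$unaffected)
    ibdSegments <- if (!is.null(inp$ibd)) readIbd(inp$ibd)
                   else GenomicRanges::GRanges()
    geneSpans <- if (!is.null(inp$genes)) readGeneSpans(inp$genes) else NULL
  }

  cascadeCfg <- .cascadeFromConfig(config$cascade %||% list())
  regions <- if (length(ibdSegments) &&
                 !is.null(ibdSegments$sample1) &&
                 length(unique(c(ibdSegments$sample1,
                                 ibdSegments$sample2))) >= 2L) {
    req <- intersect(pattern@affectedIds,
                     c(ibdSegments$sample1, ibdSegments$sample2))
    if (length(req) >= 2L)
      sharedRegions(ibdSegments, req,
                    minPairs = config$cascade$min_pairs %||% NULL)
    else GenomicRanges::GRanges()
  } else GenomicRanges::GRanges()

  ledger <- runCascade(av, pattern, cascadeCfg, ibdRegions = regions,
                       geneSpans = geneSpans)

  lk <- config$linkage %||% list()
  model <- DiseaseModel(
    prevalence = lk$prevalence %||% 0.01,
    penetrances = as.numeric(lk$penetrances %||% c(0, 0.9, 0.9)))
  markerAf <- lk$marker_af %||% 0.001
  fin <- survivors(ledger)
  linkRows <- list()
  pedIds <- pedIndividuals(ped)$iid
  if (length(fin)) {
    g <- genotypes(fin)
    keys <- variantKeys(fin)
    for (i in seq_len(length(fin))) {
      mg <- g[i, intersect(colnames(g), pedIds)]
      res <- singlePointLod(ped, mg, model, markerAf = markerAf)
      linkRows[[i]] <- data.frame(site = keys[i], lod = lodScore(res),
                                  p_value = pValue(res))
    }
  }
  linkage <- if (length(linkRows)) do.call(rbind, linkRows)
             else data.frame(site = character(), lod = numeric(),
                             p_value = numeric())

  ranked <- rankSurvivors(ledger,
                          seedGenes = config$ranking$seed_genes %||% NULL)
  report <- new("RunReport", configEcho = config, ledger = ledger,
                linkage = linkage, rankedGenes = ranked,
                version = as.character(utils::packageVersion("famcascade")),
                seed = as.numeric(seed))
  if (!is.null(config$output$dir)) writeRunReport(report, config$output$dir)
  report
}

setMethod("show", "RunReport", function(object) {
  cat("RunReport (famcascade ", object@version, ", seed ", object@seed,
      ")\n\n", sep = "")
  print(ledgerCounts(object@ledger))
  if (nrow(object@linkage)) {
    cat("\nLinkage at final survivors:\n")
    print(object@linkage)
  }
  cat("\nRanked genes: ",
      if (length(object@rankedGenes)) paste(object@rankedGenes, collapse = ", ")
      else "(none)", "\n", sep = "")
})

#' Write a RunReport to a directory
#'
#' Emits \code{ledger.tsv} (one row per cascade step), \code{linkage.tsv}
#' and a plain-text \code{report.txt}. No timestamps are written, so
#' regeneration from identical inputs is byte-identical.
#'
#' @param report a [RunReport-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLedger(report@ledger, file.path(dir, "ledger.tsv"))
  utils::write.table(report@linkage, file.path(dir, "linkage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- c(
    paste0("famcascade run report (version ", report@version, ", seed ",
           report@seed, ")"),
    "",
    "Filter cascade:",
    utils::capture.output(print(ledgerCounts(report@ledger))),
    "",
    "Linkage at final survivors:",
    if (nrow(report@linkage)) utils::capture.output(print(report@linkage))
    else "  (no final survivors)",
    "",
    paste0("Ranked genes: ",
           if (length(report@rankedGenes))
             paste(report@rankedGenes, collapse = ", ")
           else "(none)"))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
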