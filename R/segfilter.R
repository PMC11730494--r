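# The segregation rule and the five-step rare-damaging-variant cascade.

#' Construct a SegregationPattern
#'
#' @param affectedIds,unaffectedIds disjoint, non-empty character vectors of
#'   sample ids present in the genotype data.
#' @return a validated [SegregationPattern-class].
#' @export
SegregationPattern <- function(affectedIds, unaffectedIds) {
  new("SegregationPattern", affectedIds = as.character(affectedIds),
      unaffectedIds = as.character(unaffectedIds))
}

#' Construct a CascadeConfig
#'
#' @param gnomadMaxAf,cohortAf,caddMin,consequencesKept,requirePass,applyIbd,ibdMode
#'   see [CascadeConfig-class]; defaults are the study thresholds
#'   (gnomAD max AF <= 0.001, cohort AF <= 0.02, CADD phred >= 15,
#'   protein-altering consequences, PASS only, gene-span IBD overlap).
#' @return a validated [CascadeConfig-class].
#' @export
CascadeConfig <- function(gnomadMaxAf = 0.001, cohortAf = 0.02, caddMin = 15,
                          consequencesKept = c("missense", "frameshift",
                                               "nonsense", "splice"),
                          requirePass = TRUE, applyIbd = TRUE,
                          ibdMode = c("gene", "position")) {
  new("CascadeConfig", gnomadMaxAf = gnomadMaxAf, cohortAf = cohortAf,
      caddMin = caddMin, consequencesKept = consequencesKept,
      requirePass = requirePass, applyIbd = applyIbd,
      ibdMode = match.arg(ibdMode))
}

#' Co-segregation filter
#'
#' Splits variants into dominant (het) and recessive (hom) candidates under
#' the shared-segregation rule: a het candidate is heterozygous in
#' \emph{every} affected individual of the pattern and homozygous-reference
#' in every unaffected one; a hom candidate is homozygous-alt in every
#' affected while unaffecteds are wild-type or carriers (het). A variant with
#' a missing genotype in any pattern individual is excluded from both sets
#' (conservative reading of "shared").
#'
#' @param av an [AnnotatedVariants-class].
#' @param pattern a [SegregationPattern-class]; all ids must be genotyped
#'   samples of \code{av}.
#' @return list with elements \code{het} and \code{hom}, each an
#'   [AnnotatedVariants-class].
#' @export
segregationFilter <- function(av, pattern) {
  miss <- setdiff(c(pattern@affectedIds, pattern@unaffectedIds), sampleIds(av))
  if (length(miss))
    stop("pattern id(s) not among the VCF samples: ",
         paste(miss, collapse = ", "))
  flags <- segregationFlags(av, pattern)
  list(het = av[flags$het], hom = av[flags$hom])
}

#' @describeIn segregationFilter logical flags instead of subsets: a
#'   data.frame with columns \code{het} and \code{hom}, one row per variant.
#' @export
segregationFlags <- function(av, pattern) {
  gA <- av@geno[, pattern@affectedIds, drop = FALSE]
  gU <- av@geno[, pattern@unaffectedIds, drop = FALSE]
  anyMissing <- rowSums(gA == "missing") > 0 | rowSums(gU == "missing") > 0
  het <- rowSums(gA == "het") == ncol(gA) &
         rowSums(gU == "homref") == ncol(gU) & !anyMissing
  hom <- rowSums(gA == "homalt") == ncol(gA) &
         rowSums(gU == "homref" | gU == "het") == ncol(gU) & !anyMissing
  data.frame(het = het, hom = hom)
}

.emptyLike <- function(av) av[integer(0)]

#' Run the five-step filter cascade
#'
#' Applies, in order: (1) the co-segregation rule ([segregationFilter()]),
#' whose survivors define the ledger input with its het/hom split; (2) FILTER
#' status PASS and protein-altering consequence; (3) rarity — gnomAD max AF
#' and in-cohort AF both at or below their thresholds (one step, as the two
#' frequency rules act together); (4) CADD phred at or above the minimum;
#' (5) overlap with IBD shared regions, by default with gene-span semantics
#' ("variants in genes within IBD segments"). A missing gnomAD frequency is
#' treated as 0 (absent from gnomAD = rare); a missing CADD score fails the
#' score step; an undefined cohort frequency (no called genotypes) fails the
#' rarity step. Survivors at every step are kept in deterministic
#' (chrom, pos, ref, alt) order.
#'
#' @param av an [AnnotatedVariants-class].
#' @param pattern a [SegregationPattern-class].
#' @param cfg a [CascadeConfig-class].
#' @param ibdRegions \code{GRanges} of shared IBD regions (e.g. from
#'   [sharedRegions()]); may be empty, in which case step 5 retains nothing
#'   (unless \code{applyIbd} is FALSE in \code{cfg}).
#' @param geneSpans named \code{GRanges} of gene spans (names are gene
#'   symbols), required for gene-mode IBD overlap.
#' @return a [FilterLedger-class].
#' @seealso [writeLedger()], [rankSurvivors()]
#' @export
runCascade <- function(av, pattern, cfg = CascadeConfig(), ibdRegions = NULL,
                       geneSpans = NULL) {
  av <- .sortVariants(av)
  flags <- if (length(av)) segregationFlags(av, pattern)
           else data.frame(het = logical(), hom = logical())
  segKeep <- flags$het | flags$hom
  cur <- av[segKeep]
  mode <- ifelse(flags$het[segKeep], "het", "hom")

  steps <- list()
  record <- function(name, keep) {
    cur <<- cur[keep]
    mode <<- mode[keep]
    steps[[name]] <<- list(av = cur, mode = mode)
  }
  steps[["segregation"]] <- list(av = cur, mode = mode)

  info <- cur@info
  passOk <- if (cfg@requirePass) info$filter_status == "PASS" else TRUE
  consOk <- !is.na(info$consequence) & info$consequence %in% cfg@consequencesKept
  record("pass_consequence", passOk & consOk)

  info <- cur@info
  gaf <- ifelse(is.na(info$gnomad_max_af), 0, info$gnomad_max_af)
  caf <- if (length(cur)) cohortStats(cur)$cohort_af else numeric()
  rareOk <- gaf <= cfg@gnomadMaxAf & !is.nan(caf) & caf <= cfg@cohortAf
  record("rare", rareOk)

  info <- cur@info
  caddOk <- !is.na(info$cadd_phred) & info$cadd_phred >= cfg@caddMin
  record("cadd", caddOk)

  if (cfg@applyIbd) {
    if (is.null(ibdRegions) || length(ibdRegions) == 0L) {
      record("ibd", rep(FALSE, length(cur)))
    } else {
      record("ibd", overlapsRegion(ibdRegions, cur, geneSpans = geneSpans,
                                   mode = cfg@ibdMode))
    }
  }

  counts <- data.frame(
    step = names(steps),
    n = vapply(steps, function(s) length(s$av), 0L),
    n_het = vapply(steps, function(s) sum(s$mode == "het"), 0L),
    n_hom = vapply(steps, function(s) sum(s$mode == "hom"), 0L),
    row.names = NULL)
  new("FilterLedger", counts = counts,
      survivors = lapply(steps, `[[`, "av"),
      modes = lapply(steps, `[[`, "mode"))
}

#' FilterLedger accessors
#'
#' @param x a [FilterLedger-class].
#' @param step step name (default: the final step).
#' @return \code{ledgerCounts}: the per-step count table;
#'   \code{survivors}: the [AnnotatedVariants-class] surviving a step.
#' @name filterledger-accessors
NULL

#' @rdname filterledger-accessors
#' @export
ledgerCounts <- function(x) x@counts

#' @rdname filterledger-accessors
#' @export
survivors <- function(x, step = NULL) {
  if (is.null(step)) x@survivors[[length(x@survivors)]]
  else x@survivors[[step]]
}

setMethod("show", "FilterLedger", function(object) {
  cat("FilterLedger (", nrow(object@counts), " steps)\n", sep = "")
  print(object@counts)
})

#' Write a FilterLedger as TSV
#'
#' One row per step with columns \code{step}, \code{n}, \code{n_het},
#' \code{n_hom}.
#'
#' @param ledger a [FilterLedger-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLedger <- function(ledger, path) {
  utils::write.table(ledger@counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank surviving genes
#'
#' Orders the genes of the final survivors by (membership in
#' \code{seedGenes}, highest CADD phred among the gene's surviving variants,
#' gene name) — a deterministic stand-in for network-based gene
#' prioritisation.
#'
#' @param ledger a [FilterLedger-class].
#' @param seedGenes optional character vector of a-priori candidate genes.
#' @return character vector of gene symbols, best candidate first.
#' @export
rankSurvivors <- function(ledger, seedGenes = NULL) {
  fin <- survivors(ledger)
  if (length(fin) == 0L) return(character())
  info <- fin@info
  cadd <- ifelse(is.na(info$cadd_phred), -Inf, info$cadd_phred)
  maxCadd <- tapply(cadd, info$gene, max)
  genes <- names(maxCadd)
  seeded <- genes %in% (seedGenes %||% character())
  genes[order(-seeded, -as.numeric(maxCadd), genes)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
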