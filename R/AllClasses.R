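#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

.SEXES <- c("male", "female", "unknown")
.PHENOTYPES <- c("affected", "unaffected", "unknown")
.GENO_CODES <- c("homref", "het", "homalt", "missing")
.CONSEQUENCES <- c("missense", "frameshift", "nonsense", "splice", "other")

#' Pedigree of a single family
#'
#' An ordered collection of individuals forming one family: each individual
#' has an identifier, either two named parents (both present in the pedigree)
#' or none (a founder), a sex and an affection status. The graph must be
#' acyclic and loop-free structures are required by the linkage machinery.
#'
#' @slot name single family identifier (the PED FID column).
#' @slot individuals data.frame with columns \code{iid}, \code{father},
#'   \code{mother} (\code{NA} for founders), \code{sex}
#'   (\code{male}/\code{female}/\code{unknown}) and \code{phenotype}
#'   (\code{affected}/\code{unaffected}/\code{unknown}).
#'
#' @seealso [readPed()], [peelingOrder()]
#' @export
setClass("Pedigree",
  representation(name = "character", individuals = "data.frame"))

setValidity("Pedigree", function(object) {
  df <- object@individuals
  msgs <- character()
  need <- c("iid", "father", "mother", "sex", "phenotype")
  if (!all(need %in% names(df)))
    return(paste("individuals must have columns:", paste(need, collapse = ", ")))
  if (length(object@name) != 1L || is.na(object@name))
    msgs <- c(msgs, "name must be a single non-NA string")
  if (anyDuplicated(df$iid))
    msgs <- c(msgs, paste0("duplicate individual id(s): ",
      paste(unique(df$iid[duplicated(df$iid)]), collapse = ", ")))
  if (!all(df$sex %in% .SEXES))
    msgs <- c(msgs, "sex must be one of male/female/unknown")
  if (!all(df$phenotype %in% .PHENOTYPES))
    msgs <- c(msgs, "phenotype must be one of affected/unaffected/unknown")
  both <- is.na(df$father) == is.na(df$mother)
  if (!all(both))
    msgs <- c(msgs, paste0("individual(s) with exactly one parent set: ",
      paste(df$iid[!both], collapse = ", ")))
  known <- df$iid
  for (col in c("father", "mother")) {
    p <- df[[col]]
    bad <- !is.na(p) & !(p %in% known)
    if (any(bad))
      msgs <- c(msgs, paste0("missing ", col, " id(s) ",
        paste(unique(p[bad]), collapse = ", "), " named by ",
        paste(df$iid[bad], collapse = ", ")))
  }
  if (length(msgs) == 0L) {
    # sex consistency of the parental roles
    fa <- df$father[!is.na(df$father)]
    mo <- df$mother[!is.na(df$mother)]
    sex <- stats::setNames(df$sex, df$iid)
    if (any(sex[unique(fa)] == "female"))
      msgs <- c(msgs, "father column names a female individual")
    if (any(sex[unique(mo)] == "male"))
      msgs <- c(msgs, "mother column names a male individual")
    if (length(intersect(fa, mo)))
      msgs <- c(msgs, "same individual used as father and as mother")
    cyc <- .findPedigreeCycle(df)
    if (!is.null(cyc))
      msgs <- c(msgs, paste0("pedigree cycle: individual is its own ancestor (",
        paste(cyc, collapse = " -> "), ")"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of annotated biallelic variants with per-sample genotypes
#'
#' One record per biallelic variant: VCF coordinates and alleles, FILTER
#' status, normalised protein consequence, gene symbol, gnomAD maximum allele
#' frequency, CADD phred score, and a genotype call per sample coded as
#' \code{homref}/\code{het}/\code{homalt}/\code{missing}.
#'
#' @slot info data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{filter_status}, \code{consequence}, \code{gene},
#'   \code{gnomad_max_af}, \code{cadd_phred}.
#' @slot geno character matrix, variants x samples, values
#'   \code{homref}/\code{het}/\code{homalt}/\code{missing}; column names are
#'   sample ids.
#'
#' @seealso [readAnnotatedVcf()], [cohortStats()], [runCascade()]
#' @export
setClass("AnnotatedVariants",
  representation(info = "data.frame", geno = "matrix"))

setValidity("AnnotatedVariants", function(object) {
  info <- object@info
  g <- object@geno
  need <- c("chrom", "pos", "ref", "alt", "filter_status", "consequence",
            "gene", "gnomad_max_af", "cadd_phred")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(info) != nrow(g))
    msgs <- c(msgs, "info and geno must have the same number of rows")
  if (nrow(info)) {
    if (any(info$pos < 1L)) msgs <- c(msgs, "pos must be >= 1")
    if (any(info$ref == info$alt)) msgs <- c(msgs, "ref must differ from alt")
    if (!all(info$consequence %in% c(.CONSEQUENCES, NA)))
      msgs <- c(msgs, "consequence outside controlled vocabulary")
    if (!all(g %in% .GENO_CODES))
      msgs <- c(msgs, "genotype codes must be homref/het/homalt/missing")
  }
  if (ncol(g) > 0L && is.null(colnames(g)))
    msgs <- c(msgs, "geno must have sample ids as column names")
  if (length(msgs)) msgs else TRUE
})

#' Co-segregation pattern
#'
#' Names the affected and unaffected individuals the segregation filter
#' conditions on: a dominant candidate is heterozygous in every affected and
#' wild-type in every unaffected; a recessive candidate is homozygous-alt in
#' every affected with unaffecteds at most carriers.
#'
#' @slot affectedIds,unaffectedIds disjoint, non-empty character vectors of
#'   sample ids.
#' @export
setClass("SegregationPattern",
  representation(affectedIds = "character", unaffectedIds = "character"))

setValidity("SegregationPattern", function(object) {
  msgs <- character()
  if (length(object@affectedIds) == 0L) msgs <- c(msgs, "affectedIds empty")
  if (length(object@unaffectedIds) == 0L) msgs <- c(msgs, "unaffectedIds empty")
  if (length(intersect(object@affectedIds, object@unaffectedIds)))
    msgs <- c(msgs, "affected and unaffected sets must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the rare-damaging-variant cascade
#'
#' Thresholds of the five-step filter: FILTER status plus protein-altering
#' consequence, gnomAD maximum allele frequency, in-cohort allele frequency,
#' CADD phred score, and overlap with IBD regions. All numeric thresholds are
#' inclusive.
#'
#' @slot gnomadMaxAf keep variants with gnomAD max AF <= this (default 0.001).
#' @slot cohortAf keep variants with cohort AF <= this (default 0.02).
#' @slot caddMin keep variants with CADD phred >= this (default 15).
#' @slot consequencesKept consequence classes retained (default missense,
#'   frameshift, nonsense, splice).
#' @slot requirePass require FILTER == PASS (default TRUE).
#' @slot applyIbd apply the IBD-overlap step (default TRUE).
#' @slot ibdMode \code{"gene"} (default: the variant's gene span must overlap
#'   a shared region) or \code{"position"} (the variant position itself must).
#' @export
setClass("CascadeConfig",
  representation(gnomadMaxAf = "numeric", cohortAf = "numeric",
                 caddMin = "numeric", consequencesKept = "character",
                 requirePass = "logical", applyIbd = "logical",
                 ibdMode = "character"),
  prototype(gnomadMaxAf = 0.001, cohortAf = 0.02, caddMin = 15,
            consequencesKept = c("missense", "frameshift", "nonsense", "splice"),
            requirePass = TRUE, applyIbd = TRUE, ibdMode = "gene"))

setValidity("CascadeConfig", function(object) {
  msgs <- character()
  if (object@gnomadMaxAf < 0 || object@cohortAf < 0)
    msgs <- c(msgs, "frequency thresholds must be non-negative")
  if (object@caddMin < 0 && is.finite(object@caddMin))
    msgs <- c(msgs, "caddMin must be non-negative")
  if (!object@ibdMode %in% c("gene", "position"))
    msgs <- c(msgs, "ibdMode must be 'gene' or 'position'")
  if (!all(object@consequencesKept %in% .CONSEQUENCES))
    msgs <- c(msgs, "consequencesKept outside controlled vocabulary")
  if (length(msgs)) msgs else TRUE
})

#' Per-step survivor ledger of the filter cascade
#'
#' Records, for every step of the cascade, how many variants survive (with
#' the heterozygous/homozygous split) and which ones, in deterministic
#' (chrom, pos, ref, alt) order. Counts are monotone non-increasing.
#'
#' @slot counts data.frame with columns \code{step}, \code{n}, \code{n_het},
#'   \code{n_hom}, one row per cascade step in applied order.
#' @slot survivors named list of [AnnotatedVariants] objects, one per step.
#' @slot modes named list of character vectors giving each survivor's
#'   segregation mode (\code{het}/\code{hom}), parallel to \code{survivors}.
#' @export
setClass("FilterLedger",
  representation(counts = "data.frame", survivors = "list", modes = "list"))

setValidity("FilterLedger", function(object) {
  cn <- object@counts
  msgs <- character()
  if (!all(c("step", "n", "n_het", "n_hom") %in% names(cn)))
    return("counts must have columns step, n, n_het, n_hom")
  if (nrow(cn)) {
    if (any(cn$n != cn$n_het + cn$n_hom))
      msgs <- c(msgs, "het + hom split must sum to n at every step")
    if (any(diff(cn$n) > 0))
      msgs <- c(msgs, "survivor counts must be monotone non-increasing")
  }
  if (length(object@survivors) != nrow(cn))
    msgs <- c(msgs, "one survivors entry per counts row required")
  if (length(msgs)) msgs else TRUE
})

#' Parametric disease model
#'
#' Prevalence, penetrance triple and disease-allele frequency of the
#' single-locus liability model used by the linkage computation. When the
#' allele frequency is derived from the prevalence it satisfies
#' \code{f2 p^2 + 2 f1 p (1-p) + f0 (1-p)^2 = K} under Hardy-Weinberg.
#'
#' @slot prevalence population disease prevalence K.
#' @slot penetrances numeric triple (f0, f1, f2): probability of being
#'   affected with 0, 1, 2 copies of the disease allele; f0 is the phenocopy
#'   rate.
#' @slot diseaseAlleleFreq founder frequency of the disease allele.
#' @slot inheritanceLabel free-text label, e.g. \code{"autosomal dominant"}.
#' @slot freqDerived TRUE when the frequency was solved from the prevalence.
#' @seealso [DiseaseModel()], [deriveDiseaseAlleleFreq()]
#' @export
setClass("DiseaseModel",
  representation(prevalence = "numeric", penetrances = "numeric",
                 diseaseAlleleFreq = "numeric", inheritanceLabel = "character",
                 freqDerived = "logical"))

setValidity("DiseaseModel", function(object) {
  f <- object@penetrances
  p <- object@diseaseAlleleFreq
  msgs <- character()
  if (length(f) != 3L)
    return("penetrances must be a triple (f0, f1, f2)")
  if (any(f < 0) || any(f > 1) || is.unsorted(f))
    msgs <- c(msgs, "penetrances must satisfy 0 <= f0 <= f1 <= f2 <= 1")
  if (p <= 0 || p >= 1)
    msgs <- c(msgs, "diseaseAlleleFreq must lie in (0, 1)")
  if (object@prevalence <= 0 || object@prevalence > 1)
    msgs <- c(msgs, "prevalence must lie in (0, 1]")
  if (length(msgs) == 0L && isTRUE(object@freqDerived)) {
    k <- f[3] * p^2 + f[2] * 2 * p * (1 - p) + f[1] * (1 - p)^2
    if (abs(k - object@prevalence) > 1e-9)
      msgs <- c(msgs, "derived allele frequency inconsistent with prevalence")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a single-point parametric linkage computation
#'
#' @slot lod log10 likelihood ratio of linkage at the evaluated recombination
#'   fraction versus free recombination (theta = 0.5).
#' @slot theta recombination fraction the LOD was evaluated at.
#' @slot pValue tail probability from the half-chi-square conversion.
#' @slot loglikLinked,loglikUnlinked natural-log pedigree likelihoods at
#'   \code{theta} and at 0.5.
#' @seealso [singlePointLod()], [lodToPvalue()]
#' @export
setClass("LinkageResult",
  representation(lod = "numeric", theta = "numeric", pValue = "numeric",
                 loglikLinked = "numeric", loglikUnlinked = "numeric"))

#' APOE epsilon-genotype call
#'
#' Epsilon alleles are haplotypes of rs429358 (T>C) and rs7412 (C>T):
#' (T,T) = e2, (T,C) = e3, (C,C) = e4, (C,T) = e1. The rs429358/rs7412 double
#' heterozygote cannot be phased from genotypes alone and is resolved as
#' e2/e4 with \code{ambiguous = TRUE} (the e1/e3 alternative is suppressed by
#' convention given the extreme rarity of e1).
#'
#' @slot rs429358,rs7412 unordered allele pairs.
#' @slot epsilonPair the called pair, e.g. \code{c("e3", "e4")}.
#' @slot ambiguous TRUE when the phase was resolved by convention.
#' @seealso [callApoe()]
#' @export
setClass("ApoeCall",
  representation(rs429358 = "character", rs7412 = "character",
                 epsilonPair = "character", ambiguous = "logical"))

#' Configuration of the gene-dropping family simulator
#'
#' Defines the pedigree (grown at random or taken from a fixed template), the
#' planted causal variant, the disease model used to draw phenotypes, the
#' background-variant annotation distributions and the genetic map.
#'
#' @slot nGenerations generations of a randomly grown pedigree.
#' @slot offspringSpec list with \code{min}/\code{max} children per couple.
#' @slot causalAf founder frequency of the planted allele (random mode).
#' @slot model a [DiseaseModel].
#' @slot nBackgroundVariants background variant count.
#' @slot backgroundAfSpec list describing the founder-AF mixture of
#'   background variants.
#' @slot caddSpec list describing the CADD phred mixture (mass on both sides
#'   of 15 so the score step is always exercised).
#' @slot consequenceMix named probabilities over the consequence vocabulary.
#' @slot markersPerMb marker density of the dense map used for IBD-scan
#'   simulations (default 100/Mb, i.e. 500 markers per 5 Mb).
#' @slot chromosomes named numeric vector of chromosome lengths in Mb.
#' @slot seed integer seed; a fixed seed makes all outputs byte-identical.
#' @slot pedigreeTemplate optional data.frame of individuals (as in
#'   [Pedigree()]) replacing random growth.
#' @slot causalCarriers optional ids that must inherit the causal allele;
#'   the causal-locus gene drop is conditioned on this descent plan.
#' @slot genotypedIds optional ids restricted to appear in the emitted VCF.
#' @slot phenotypeMode \code{"penetrance"} (stochastic draw) or
#'   \code{"deterministic"} (carrier <=> affected, the ascertained-family
#'   configuration).
#' @seealso [simulateFamily()], [studyEmulationPreset()]
#' @export
setClass("SimConfig",
  representation(nGenerations = "numeric", offspringSpec = "list",
                 causalAf = "numeric", model = "DiseaseModel",
                 nBackgroundVariants = "numeric", backgroundAfSpec = "list",
                 caddSpec = "list", consequenceMix = "numeric",
                 markersPerMb = "numeric", chromosomes = "numeric",
                 seed = "numeric", pedigreeTemplate = "ANY",
                 causalCarriers = "ANY", genotypedIds = "ANY",
                 phenotypeMode = "character"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (abs(sum(object@consequenceMix) - 1) > 1e-8)
    msgs <- c(msgs, "consequenceMix probabilities must sum to 1")
  if (!all(names(object@consequenceMix) %in% .CONSEQUENCES))
    msgs <- c(msgs, "consequenceMix names outside controlled vocabulary")
  if (object@markersPerMb <= 0)
    msgs <- c(msgs, "markersPerMb must be positive")
  if (length(object@chromosomes) == 0L || is.null(names(object@chromosomes)))
    msgs <- c(msgs, "chromosomes must be a named vector of Mb lengths")
  if (!object@phenotypeMode %in% c("penetrance", "deterministic"))
    msgs <- c(msgs, "phenotypeMode must be 'penetrance' or 'deterministic'")
  if (length(msgs)) msgs else TRUE
})

#' Human-readable report of a full pipeline run
#'
#' Bundles the configuration echo, the filter ledger, linkage results and the
#' ranked gene list of one end-to-end run; every number in the report is a
#' module output.
#'
#' @slot configEcho the validated configuration as a list.
#' @slot ledger a [FilterLedger].
#' @slot linkage data.frame (site, lod, p_value), possibly empty.
#' @slot rankedGenes character vector of candidate genes, best first.
#' @slot version package version string.
#' @slot seed integer seed used for any randomness.
#' @seealso [runFullPipeline()]
#' @export
setClass("RunReport",
  representation(configEcho = "list", ledger = "FilterLedger",
                 linkage = "data.frame", rankedGenes = "character",
                 version = "character", seed = "numeric"))
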