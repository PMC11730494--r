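# Gene-dropping family simulator: pedigrees, founder haplotypes, Mendelian
# transmission with recombination on a uniform 1 cM/Mb map, penetrance-based
# phenotypes, background variant annotations, and truth IBD tracts derived
# from recorded founder-haplotype descent. This is the package's stand-in
# for real exome data: every other module can be exercised against outputs
# whose ground truth is known by construction.

# -- haplotype mosaics --------------------------------------------------
# A haplotype is a mosaic of founder haplotypes: `breaks` are 1-based
# segment start positions (first is 1), `src` the founder-haplotype id of
# each segment; segment i spans [breaks[i], breaks[i+1] - 1].

.mosaicAt <- function(mos, pos) mos$src[findInterval(pos, mos$breaks)]

.compressMosaic <- function(breaks, src) {
  keep <- c(TRUE, src[-1] != src[-length(src)])
  list(breaks = breaks[keep], src = src[keep])
}

# sub-mosaic of `mos` restricted to [lo, hi], re-anchored at lo
.sliceMosaic <- function(mos, lo, hi) {
  inside <- mos$breaks > lo & mos$breaks <= hi
  breaks <- c(lo, mos$breaks[inside])
  src <- c(.mosaicAt(mos, lo), mos$src[inside])
  list(breaks = breaks, src = src)
}

# one meiosis: recombine the parent's two haplotype mosaics
.meiosis <- function(hapA, hapB, chromLenBp, cmPerMb = 1) {
  lenMorgan <- (chromLenBp / 1e6) * cmPerMb / 100
  nXo <- stats::rpois(1L, lenMorgan)
  xo <- if (nXo > 0L) sort(sample.int(chromLenBp - 1L, nXo) + 1L) else integer()
  strand <- sample(1:2, 1L)
  haps <- list(hapA, hapB)
  bounds <- c(1, xo, chromLenBp + 1)
  breaks <- numeric(); src <- integer()
  for (i in seq_len(length(bounds) - 1L)) {
    piece <- .sliceMosaic(haps[[strand]], bounds[i], bounds[i + 1L] - 1)
    breaks <- c(breaks, piece$breaks)
    src <- c(src, piece$src)
    strand <- 3L - strand
  }
  .compressMosaic(breaks, src)
}

# intervals (IRanges) where two mosaics carry the same founder haplotype
.mosaicSharedIntervals <- function(m1, m2, chromLenBp) {
  cuts <- sort(unique(c(m1$breaks, m2$breaks, chromLenBp + 1)))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1] - 1
  same <- .mosaicAt(m1, lo) == .mosaicAt(m2, lo)
  IRanges::reduce(IRanges::IRanges(lo[same], hi[same]))
}

# -- configuration ------------------------------------------------------

#' Construct a SimConfig
#'
#' Defaults describe a moderately sized multi-generation family segregating
#' one rare dominant variant under the 1\% prevalence / 0.90 penetrance
#' model, 199 background variants whose annotations straddle every cascade
#' decision boundary, a two-chromosome genome and a 1 cM/Mb map.
#'
#' @param nGenerations generations of random pedigree growth (default 4).
#' @param offspringSpec list(min=, max=) children per couple.
#' @param causalAf founder frequency of the causal allele in random mode.
#' @param model a [DiseaseModel-class].
#' @param nBackgroundVariants background variant count (default 199).
#' @param backgroundAfSpec list(pRare=, rareRange=, commonRange=): founder
#'   AF mixture.
#' @param caddSpec list(pHigh=, highRange=, lowRange=): CADD phred mixture
#'   with mass on both sides of 15.
#' @param consequenceMix named probabilities over the consequence classes.
#' @param markersPerMb dense-map marker density (default 100/Mb, i.e. 500
#'   markers per 5 Mb).
#' @param chromosomes named vector of chromosome lengths in Mb.
#' @param seed integer seed.
#' @param pedigreeTemplate optional fixed individuals data.frame.
#' @param causalCarriers optional ids conditioned to carry the causal
#'   allele.
#' @param genotypedIds optional ids appearing in the emitted VCF.
#' @param phenotypeMode \code{"penetrance"} or \code{"deterministic"}.
#' @param nUnrelated unrelated cohort samples added to the VCF so in-cohort
#'   allele frequencies are meaningful (default 300).
#' @param plantedVariants optional data.frame of designed variants (columns
#'   \code{chrom, pos, ref, alt, gene, consequence, gnomad_max_af,
#'   cadd_phred, filter_status, on_causal_hap, founder_af, unrelated_af});
#'   rows with \code{on_causal_hap = TRUE} ride the causal founder
#'   haplotype and therefore co-segregate with the planted variant up to
#'   recombination.
#' @return a validated [SimConfig-class]; extra fields are carried in the
#'   object's attributes.
#' @seealso [simulateFamily()], [studyEmulationPreset()]
#' @export
SimConfig <- function(nGenerations = 4,
                      offspringSpec = list(min = 1, max = 3),
                      causalAf = 2.6e-5,
                      model = DiseaseModel(),
                      nBackgroundVariants = 199,
                      backgroundAfSpec = list(pRare = 0.5,
                                              rareRange = c(1e-4, 1e-3),
                                              commonRange = c(0.02, 0.5)),
                      caddSpec = list(pHigh = 0.4, highRange = c(15, 40),
                                      lowRange = c(0, 14.9)),
                      consequenceMix = c(missense = 0.40, other = 0.35,
                                         frameshift = 0.10, nonsense = 0.07,
                                         splice = 0.08),
                      markersPerMb = 100,
                      chromosomes = c(`1` = 120, `17` = 81),
                      seed = 1L,
                      pedigreeTemplate = NULL,
                      causalCarriers = NULL,
                      genotypedIds = NULL,
                      phenotypeMode = c("penetrance", "deterministic"),
                      nUnrelated = 300,
                      plantedVariants = NULL) {
  cfg <- new("SimConfig", nGenerations = nGenerations,
             offspringSpec = offspringSpec, causalAf = causalAf,
             model = model, nBackgroundVariants = nBackgroundVariants,
             backgroundAfSpec = backgroundAfSpec, caddSpec = caddSpec,
             consequenceMix = consequenceMix, markersPerMb = markersPerMb,
             chromosomes = chromosomes, seed = seed,
             pedigreeTemplate = pedigreeTemplate,
             causalCarriers = causalCarriers, genotypedIds = genotypedIds,
             phenotypeMode = match.arg(phenotypeMode))
  attr(cfg, "nUnrelated") <- nUnrelated
  attr(cfg, "plantedVariants") <- plantedVariants
  cfg
}

# random pedigree growth: founder couple, then `nGenerations` of children
# with married-in founder spouses (always loop-free)
.growPedigree <- function(nGenerations, offspringSpec) {
  rows <- data.frame(iid = c("G1I1", "G1I2"),
                     father = NA_character_, mother = NA_character_,
                     sex = c("male", "female"),
                     phenotype = "unknown", stringsAsFactors = FALSE)
  couples <- list(c("G1I1", "G1I2"))
  counter <- 2L
  for (g in seq(2L, nGenerations)) {
    nextCouples <- list()
    for (cp in couples) {
      nKids <- sample(seq(offspringSpec$min, offspringSpec$max), 1L)
      for (k in seq_len(nKids)) {
        counter <- counter + 1L
        kidSex <- sample(c("male", "female"), 1L)
        kid <- sprintf("G%dI%d", g, counter)
        rows <- rbind(rows, data.frame(iid = kid, father = cp[1],
                                       mother = cp[2], sex = kidSex,
                                       phenotype = "unknown"))
        if (g < nGenerations && stats::runif(1) < 0.75) {
          counter <- counter + 1L
          spouse <- sprintf("G%dI%d", g, counter)
          spouseSex <- if (kidSex == "male") "female" else "male"
          rows <- rbind(rows, data.frame(iid = spouse,
                                         father = NA_character_,
                                         mother = NA_character_,
                                         sex = spouseSex,
                                         phenotype = "unknown"))
          nextCouples[[length(nextCouples) + 1L]] <-
            if (kidSex == "male") c(kid, spouse) else c(spouse, kid)
        }
      }
    }
    couples <- nextCouples
    if (length(couples) == 0L) break
  }
  rows
}

#' Draw phenotypes from causal genotypes under a disease model
#'
#' The simulator's phenotype mechanism: an individual with g copies of the
#' causal allele is affected with probability f_g.
#'
#' @param causalCopies integer vector of 0/1/2 causal-allele counts.
#' @param model a [DiseaseModel-class].
#' @return character vector \code{affected}/\code{unaffected}.
#' @export
drawPhenotypes <- function(causalCopies, model) {
  p <- model@penetrances[causalCopies + 1L]
  stats::setNames(ifelse(stats::runif(length(p)) < p, "affected",
                         "unaffected"),
                  names(causalCopies))
}

#' Simulate a family data set by gene dropping
#'
#' Draws founder haplotypes at the configured allele frequencies, transmits
#' them down the pedigree by Mendelian gene dropping with recombination on a
#' uniform 1 cM/Mb genetic map, assigns phenotypes from the causal genotype
#' under the disease model's penetrances (or deterministically, carrier =
#' affected, in \code{"deterministic"} mode), annotates background variants
#' from the configured mixtures, and derives truth IBD tracts from the
#' recorded founder-haplotype descent. All outputs are cross-consistent and
#' reproducible for a fixed seed. When \code{causalCarriers} is set, the
#' causal-locus transmissions are conditioned (by resampling each meiosis)
#' so exactly those pedigree members inherit the planted allele.
#'
#' @param cfg a [SimConfig-class].
#' @param outDir optional directory; when given, writes \code{family.ped},
#'   \code{variants.vcf}, \code{annotations.tsv}, \code{genes.tsv},
#'   \code{truth.ibd} (truth tracts in the Beagle-style dialect) and
#'   \code{truth.json}.
#' @return list with elements \code{pedigree} ([Pedigree-class]),
#'   \code{variants} ([AnnotatedVariants-class] over the genotyped family
#'   members plus the unrelated cohort), \code{truth} (list: causal key,
#'   carrier ids, causal-copy counts, phenotypes, truth IBD tracts as
#'   \code{GRanges}, gene spans) and \code{files}.
#' @export
simulateFamily <- function(cfg, outDir = NULL) {
  set.seed(cfg@seed)
  model <- cfg@model
  chromBp <- round(cfg@chromosomes * 1e6)

  pedDf <- if (!is.null(cfg@pedigreeTemplate)) cfg@pedigreeTemplate
           else .growPedigree(cfg@nGenerations, cfg@offspringSpec)
  if (sum(is.na(pedDf$father)) == 0L)
    stop("configuration yields a pedigree with no founders")
  ids <- pedDf$iid
  foundersV <- pedDf$iid[is.na(pedDf$father)]

  # ---- variant table ----------------------------------------------------
  planted <- attr(cfg, "plantedVariants")
  nBg <- cfg@nBackgroundVariants
  chromNames <- names(chromBp)
  bgChrom <- sample(chromNames, nBg, replace = TRUE,
                    prob = as.numeric(chromBp) / sum(chromBp))
  bgPos <- vapply(bgChrom, function(ch) sample.int(chromBp[[ch]], 1L), 0L)
  bases <- c("A", "C", "G", "T")
  bgRef <- sample(bases, nBg, replace = TRUE)
  bgAlt <- vapply(bgRef, function(r) sample(setdiff(bases, r), 1L), "")
  spec <- cfg@backgroundAfSpec
  rare <- stats::runif(nBg) < spec$pRare
  bgAf <- ifelse(rare,
                 stats::runif(nBg, spec$rareRange[1], spec$rareRange[2]),
                 stats::runif(nBg, spec$commonRange[1], spec$commonRange[2]))
  cs <- cfg@caddSpec
  high <- stats::runif(nBg) < cs$pHigh
  bgCadd <- round(ifelse(high,
                         stats::runif(nBg, cs$highRange[1], cs$highRange[2]),
                         stats::runif(nBg, cs$lowRange[1], cs$lowRange[2])), 2)
  bgCons <- sample(names(cfg@consequenceMix), nBg, replace = TRUE,
                   prob = cfg@consequenceMix)
  bgFilt <- ifelse(stats::runif(nBg) < 0.9, "PASS", "LowQual")
  # gnomAD max AF loosely tracks the founder AF (rare alleles are rare
  # everywhere); jitter keeps both sides of the 0.001 boundary populated
  bgGnomad <- signif(bgAf * stats::runif(nBg, 0.3, 3), 3)

  vt <- data.frame(chrom = bgChrom, pos = as.integer(bgPos), ref = bgRef,
                   alt = bgAlt, filter_status = bgFilt, consequence = bgCons,
                   gene = paste0("BG", seq_len(nBg)),
                   gnomad_max_af = bgGnomad, cadd_phred = bgCadd,
                   founder_af = bgAf, unrelated_af = bgAf,
                   on_causal_hap = FALSE, stringsAsFactors = FALSE)
  causalRow <- data.frame(chrom = "17", pos = 74842922L, ref = "C", alt = "T",
                          filter_status = "PASS", consequence = "missense",
                          gene = "CAUSAL1", gnomad_max_af = 2.6e-5,
                          cadd_phred = 25.1, founder_af = cfg@causalAf,
                          unrelated_af = cfg@causalAf, on_causal_hap = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(planted)) vt <- rbind(vt, planted)
  vt <- rbind(causalRow, vt)
  vt <- vt[!duplicated(paste(vt$chrom, vt$pos)), ]
  nVar <- nrow(vt)
  causalIdx <- 1L

  # ---- founder haplotypes ----------------------------------------------
  founderHapIds <- stats::setNames(
    lapply(seq_along(foundersV), function(i) c(2L * i - 1L, 2L * i)),
    foundersV)
  nHaps <- 2L * length(foundersV)
  alleleMat <- matrix(0L, nrow = nHaps, ncol = nVar)
  for (j in seq_len(nVar))
    alleleMat[, j] <- stats::rbinom(nHaps, 1L, vt$founder_af[j])
  causalHap <- founderHapIds[[1]][1]
  conditioned <- !is.null(cfg@causalCarriers)
  if (conditioned) {
    # a single designed copy rides the first founder's first haplotype
    alleleMat[, causalIdx] <- 0L
    alleleMat[causalHap, causalIdx] <- 1L
    alleleMat[, which(vt$on_causal_hap)] <- 0L
    alleleMat[causalHap, which(vt$on_causal_hap)] <- 1L
  }

  # ---- gene dropping ----------------------------------------------------
  causalPos <- vt$pos[causalIdx]
  causalChrom <- vt$chrom[causalIdx]
  haps <- list() # haps[[iid]][[chrom]] = list(pat, mat) mosaics
  for (f in foundersV)
    haps[[f]] <- lapply(chromNames, function(ch) {
      hid <- founderHapIds[[f]]
      list(pat = list(breaks = 1, src = hid[1]),
           mat = list(breaks = 1, src = hid[2]))
    })
  for (f in foundersV) names(haps[[f]]) <- chromNames

  hapCausalAllele <- function(mos)
    alleleMat[.mosaicAt(mos, causalPos), causalIdx]
  carrierPlan <- cfg@causalCarriers
  mustTransmit <- function(parent, child) {
    if (!conditioned) return(NA)
    (child %in% carrierPlan) && (parent %in% c(carrierPlan, foundersV[1]))
  }

  ordered <- ids[order(match(pedDf$father, ids), na.last = FALSE)]
  # topological order: parents precede children
  done <- foundersV
  queue <- setdiff(ids, foundersV)
  while (length(queue)) {
    ready <- queue[vapply(queue, function(k) {
      i <- match(k, ids)
      all(c(pedDf$father[i], pedDf$mother[i]) %in% done)
    }, logical(1))]
    if (!length(ready)) stop("pedigree is not acyclic")
    for (k in ready) {
      i <- match(k, ids)
      fa <- pedDf$father[i]; mo <- pedDf$mother[i]
      haps[[k]] <- stats::setNames(vector("list", length(chromNames)),
                                   chromNames)
      for (ch in chromNames) {
        L <- chromBp[[ch]]
        patSide <- .conditionedMeiosis(haps[[fa]][[ch]], L, ch == causalChrom,
          mustTransmit(fa, k), hapCausalAllele)
        matSide <- .conditionedMeiosis(haps[[mo]][[ch]], L, ch == causalChrom,
          if (isTRUE(mustTransmit(fa, k))) FALSE else mustTransmit(mo, k),
          hapCausalAllele)
        haps[[k]][[ch]] <- list(pat = patSide, mat = matSide)
      }
    }
    done <- c(done, ready)
    queue <- setdiff(queue, ready)
  }

  # ---- genotypes ---------------------------------------------------------
  genoFam <- matrix("homref", nrow = nVar, ncol = length(ids),
                    dimnames = list(NULL, ids))
  copies <- matrix(0L, nrow = nVar, ncol = length(ids),
                   dimnames = list(NULL, ids))
  for (k in ids) {
    for (ch in chromNames) {
      jj <- which(vt$chrom == ch)
      if (!length(jj)) next
      srcP <- .mosaicAt(haps[[k]][[ch]]$pat, vt$pos[jj])
      srcM <- .mosaicAt(haps[[k]][[ch]]$mat, vt$pos[jj])
      cp <- alleleMat[cbind(srcP, jj)] + alleleMat[cbind(srcM, jj)]
      copies[jj, k] <- cp
    }
  }
  genoFam[] <- c("homref", "het", "homalt")[copies + 1L]

  # ---- phenotypes --------------------------------------------------------
  causalCopies <- copies[causalIdx, ]
  pheno <- if (cfg@phenotypeMode == "deterministic")
    ifelse(causalCopies > 0L, "affected", "unaffected")
  else drawPhenotypes(causalCopies, model)
  pedDf$phenotype <- unname(pheno[pedDf$iid])
  ped <- Pedigree(pedDf, name = "SIM")

  # ---- unrelated cohort --------------------------------------------------
  nUnrel <- attr(cfg, "nUnrelated") %||% 0
  genoUnrel <- NULL
  if (nUnrel > 0) {
    unrelIds <- sprintf("U%03d", seq_len(nUnrel))
    genoUnrel <- matrix("homref", nrow = nVar, ncol = nUnrel,
                        dimnames = list(NULL, unrelIds))
    for (j in seq_len(nVar)) {
      cp <- stats::rbinom(nUnrel, 2L, vt$unrelated_af[j])
      genoUnrel[j, ] <- c("homref", "het", "homalt")[cp + 1L]
    }
  }

  genotypedIds <- cfg@genotypedIds %||% ids
  geno <- cbind(genoFam[, genotypedIds, drop = FALSE], genoUnrel)
  av <- .sortVariants(AnnotatedVariants(
    vt[c("chrom", "pos", "ref", "alt", "filter_status", "consequence",
         "gene", "gnomad_max_af", "cadd_phred")], geno))

  # ---- gene spans --------------------------------------------------------
  geneSpans <- GenomicRanges::GRanges(vt$chrom,
    IRanges::IRanges(pmax(1L, vt$pos - 25000L), vt$pos + 25000L))
  names(geneSpans) <- vt$gene
  geneSpans <- geneSpans[!duplicated(names(geneSpans))]

  # ---- truth IBD tracts --------------------------------------------------
  tractList <- list()
  gIds <- genotypedIds
  if (length(gIds) >= 2L) {
    prs <- utils::combn(sort(gIds), 2L)
    for (p in seq_len(ncol(prs))) {
      a <- prs[1, p]; b <- prs[2, p]
      for (ch in chromNames) {
        shared <- IRanges::IRanges()
        for (ha in haps[[a]][[ch]]) for (hb in haps[[b]][[ch]])
          shared <- c(shared, .mosaicSharedIntervals(ha, hb, chromBp[[ch]]))
        shared <- IRanges::reduce(shared)
        if (length(shared)) {
          gr <- GenomicRanges::GRanges(ch, shared)
          gr$sample1 <- rep(a, length(gr)); gr$sample2 <- rep(b, length(gr))
          gr$score <- rep(NA_real_, length(gr))
          tractList[[length(tractList) + 1L]] <- gr
        }
      }
    }
  }
  tracts <- if (length(tractList)) suppressWarnings(do.call(c, tractList))
            else GenomicRanges::GRanges()

  truth <- list(
    causal_key = paste(vt$chrom[causalIdx], vt$pos[causalIdx],
                       vt$ref[causalIdx], vt$alt[causalIdx], sep = ":"),
    causal_gene = vt$gene[causalIdx],
    carriers = ids[causalCopies[ids] > 0L],
    causal_copies = causalCopies,
    phenotypes = stats::setNames(pedDf$phenotype, pedDf$iid),
    ibd_tracts = tracts,
    gene_spans = geneSpans,
    genotyped_ids = genotypedIds,
    seed = cfg@seed)

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      ped = file.path(outDir, "family.ped"),
      vcf = file.path(outDir, "variants.vcf"),
      annotations = file.path(outDir, "annotations.tsv"),
      genes = file.path(outDir, "genes.tsv"),
      ibd = file.path(outDir, "truth.ibd"),
      truth = file.path(outDir, "truth.json"))
    writePed(ped, files$ped)
    writeAnnotatedVcf(av, files$vcf, files$annotations)
    writeGeneSpans(geneSpans, files$genes)
    writeIbd(tracts, files$ibd)
    jsonlite::write_json(list(
      causal_key = truth$causal_key, causal_gene = truth$causal_gene,
      carriers = truth$carriers,
      phenotypes = as.list(truth$phenotypes),
      genotyped_ids = genotypedIds, seed = cfg@seed),
      files$truth, auto_unbox = TRUE, pretty = TRUE)
  }
  list(pedigree = ped, variants = av, truth = truth, files = files)
}

# meiosis, optionally conditioned on the causal allele transmitted (TRUE),
# not transmitted (FALSE) or unconstrained (NA)
.conditionedMeiosis <- function(parentHaps, chromLenBp, onCausalChrom,
                                requirement, hapCausalAllele) {
  for (try in seq_len(10000L)) {
    h <- .meiosis(parentHaps$pat, parentHaps$mat, chromLenBp)
    if (!onCausalChrom || is.na(requirement)) return(h)
    if (hapCausalAllele(h) == as.integer(requirement)) return(h)
  }
  stop("conditioned meiosis failed; is the carrier plan consistent?")
}

#' Study-emulation preset
#'
#' A fixed 4-generation, 20-member pedigree with 15 genotyped members, of
#' whom exactly 6 are affected carriers of one planted heterozygous causal
#' variant (gnomAD-like AF 2.6e-5, CADD 25.1, missense, PASS) and 9 are
#' unaffected non-carriers; the causal-locus gene drop is conditioned on
#' this descent plan and phenotypes follow carrier status (the ascertained
#' configuration). Designed decoy variants ride the causal founder
#' haplotype so that each later cascade step has work to do: a
#' non-protein-altering co-segregating variant, a gnomAD-common one, a
#' cohort-common one, a low-CADD one, a non-PASS one, and two full-pass
#' variants with lower CADD than the causal variant. Background variants
#' and the unrelated cohort are drawn from the standard mixtures.
#'
#' @param seed integer seed (default 1).
#' @return list with the [SimConfig-class] (\code{config}) and the
#'   exome-style analysis pattern (\code{pattern}, three affected and two
#'   unaffected genotyped members, mirroring the 3 + 2 exome design).
#' @export
studyEmulationPreset <- function(seed = 1L) {
  rows <- function(iid, father, mother, sex)
    data.frame(iid = iid, father = father, mother = mother, sex = sex,
               phenotype = "unknown", stringsAsFactors = FALSE)
  tmpl <- rbind(
    rows("I1", NA, NA, "male"), rows("I2", NA, NA, "female"),
    rows("II1", "I1", "I2", "male"), rows("II3", "I1", "I2", "female"),
    rows("II5", "I1", "I2", "male"),
    rows("II2", NA, NA, "female"), rows("II4", NA, NA, "male"),
    rows("II6", NA, NA, "female"),
    rows("III1", "II1", "II2", "male"), rows("III2", "II1", "II2", "female"),
    rows("III3", "II4", "II3", "female"), rows("III4", "II4", "II3", "male"),
    rows("III5", "II5", "II6", "unknown"), rows("III6", "II5", "II6", "unknown"),
    rows("III7", NA, NA, "female"), rows("III8", NA, NA, "male"),
    rows("IV1", "III1", "III7", "unknown"), rows("IV2", "III1", "III7", "unknown"),
    rows("IV3", "III8", "III3", "unknown"), rows("IV4", "III8", "III3", "unknown"))
  carriers <- c("II1", "II3", "III1", "III3", "IV1", "IV3")
  genotyped <- c("II1", "II2", "II3", "II4", "II5", "III1", "III2", "III3",
                 "III4", "III5", "III6", "IV1", "IV2", "IV3", "IV4")
  planted <- data.frame(
    chrom = "17",
    pos = c(73400000L, 73900000L, 74300000L, 75300000L, 75800000L,
            76200000L, 76600000L),
    ref = "G", alt = "A",
    gene = paste0("DK", 1:7),
    consequence = c("other", "missense", "missense", "missense", "missense",
                    "missense", "nonsense"),
    gnomad_max_af = c(1e-4, 0.01, 1e-4, 1e-4, 1e-4, 2e-5, 5e-5),
    cadd_phred = c(22, 21, 23, 8, 24, 16.2, 18.4),
    filter_status = c("PASS", "PASS", "PASS", "PASS", "LowQual", "PASS",
                      "PASS"),
    founder_af = 0, unrelated_af = c(0, 0, 0.15, 0, 0, 0, 0),
    on_causal_hap = TRUE, stringsAsFactors = FALSE)
  cfg <- SimConfig(seed = seed, pedigreeTemplate = tmpl,
                   causalCarriers = carriers, genotypedIds = genotyped,
                   phenotypeMode = "deterministic",
                   plantedVariants = planted)
  list(config = cfg,
       pattern = SegregationPattern(affectedIds = c("II1", "III3", "IV1"),
                                    unaffectedIds = c("II5", "III4")))
}
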