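# Small generators shared across tests. All randomness is controlled by the
# caller's set.seed().

# Random loop-free pedigree of exactly n members: a founder couple grown by
# children and married-in founder spouses.
randomPedigree <- function(n, pAffected = 0.3) {
  df <- data.frame(iid = c("A", "B"), father = NA_character_,
                   mother = NA_character_, sex = c("male", "female"),
                   phenotype = "unknown", stringsAsFactors = FALSE)
  couples <- list(c("A", "B"))
  k <- 2L
  while (nrow(df) < n) {
    cp <- couples[[sample(length(couples), 1L)]]
    k <- k + 1L
    kid <- paste0("I", k)
    sx <- sample(c("male", "female"), 1L)
    df <- rbind(df, data.frame(iid = kid, father = cp[1], mother = cp[2],
                               sex = sx, phenotype = "unknown"))
    if (nrow(df) < n && stats::runif(1) < 0.4) {
      k <- k + 1L
      sp <- paste0("I", k)
      df <- rbind(df, data.frame(iid = sp, father = NA_character_,
                                 mother = NA_character_,
                                 sex = if (sx == "male") "female" else "male",
                                 phenotype = "unknown"))
      couples <- c(couples,
                   list(if (sx == "male") c(kid, sp) else c(sp, kid)))
    }
  }
  df$phenotype <- sample(c("affected", "unaffected", "unknown"), nrow(df),
                         replace = TRUE)
  Pedigree(df)
}

# Mendelian-consistent marker genotypes by single-locus gene dropping,
# with a fraction masked as missing.
dropMarkerGenotypes <- function(ped, af, pMissing = 0.2) {
  df <- pedIndividuals(ped)
  ids <- df$iid
  al <- list()
  for (i in seq_along(ids)) {
    if (is.na(df$father[i])) al[[ids[i]]] <- stats::rbinom(2L, 1L, af)
    else al[[ids[i]]] <- c(sample(al[[df$father[i]]], 1L),
                           sample(al[[df$mother[i]]], 1L))
  }
  g <- vapply(al, function(a) c("homref", "het", "homalt")[sum(a) + 1L], "")
  g[stats::runif(length(g)) < pMissing] <- "missing"
  g
}

randomDiseaseModel <- function() {
  f0 <- stats::runif(1, 0, 0.1)
  f1 <- stats::runif(1, f0, 1)
  f2 <- stats::runif(1, f1, 1)
  DiseaseModel(prevalence = 0.01, penetrances = c(f0, f1, f2),
               diseaseAlleleFreq = stats::runif(1, 0.005, 0.2))
}

# Minimal AnnotatedVariants with explicit genotype rows (list of character
# vectors, one per variant, named or in sample order).
makeVariants <- function(genoRows, samples, chrom = "1",
                         pos = NULL, ref = "A", alt = "G",
                         filter_status = "PASS", consequence = "missense",
                         gene = NULL, gnomad_max_af = 1e-4, cadd_phred = 20) {
  nv <- length(genoRows)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = nv)
  if (is.null(gene)) gene <- paste0("GENE", seq_len(nv))
  g <- do.call(rbind, genoRows)
  colnames(g) <- samples
  AnnotatedVariants(
    data.frame(chrom = chrom, pos = pos,
               ref = rep_len(ref, nv), alt = rep_len(alt, nv),
               filter_status = rep_len(filter_status, nv),
               consequence = rep_len(consequence, nv),
               gene = rep_len(gene, nv),
               gnomad_max_af = rep_len(gnomad_max_af, nv),
               cadd_phred = rep_len(cadd_phred, nv)),
    g)
}

# Study-emulation runs are the most expensive fixture; cache them per seed
# so several test files can share one realisation.
cachedPresetSim <- local({
  cache <- list()
  function(seed = 3L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      preset <- studyEmulationPreset(seed = seed)
      cache[[key]] <<- list(preset = preset,
                            sim = simulateFamily(preset$config))
    }
    cache[[key]]
  }
})

# A small, fast simulator configuration for round-trip and consistency tests.
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(nGenerations = 3, nBackgroundVariants = 30, nUnrelated = 20,
               seed = seed, causalAf = 0.3)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(SimConfig, args)
}
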