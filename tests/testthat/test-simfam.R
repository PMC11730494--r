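test_that("a fixed seed reproduces byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateFamily(smallSimConfig(seed = 7), outDir = d1)
  simulateFamily(smallSimConfig(seed = 7), outDir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulateFamily(smallSimConfig(seed = 8), outDir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "variants.vcf"))),
                         unname(tools::md5sum(file.path(d3, "variants.vcf")))))
})

test_that("full penetrance makes carrier status and phenotype coincide", {
  cfg <- smallSimConfig(seed = 5,
                        model = DiseaseModel(penetrances = c(0, 1, 1)))
  sim <- simulateFamily(cfg)
  df <- pedIndividuals(sim$pedigree)
  carriers <- names(sim$truth$causal_copies)[sim$truth$causal_copies > 0]
  expect_setequal(df$iid[df$phenotype == "affected"], carriers)
})

test_that("every simulated child is Mendelian-consistent with its parents", {
  for (seed in c(2, 3)) {
    sim <- simulateFamily(smallSimConfig(seed = seed))
    df <- pedIndividuals(sim$pedigree)
    g <- genotypes(sim$variants)
    copies <- matrix(match(g, c("homref", "het", "homalt")) - 1L,
                     nrow = nrow(g), dimnames = dimnames(g))
    canTransmit <- function(cp) list(`0` = cp <= 1, `1` = cp >= 1)
    for (i in which(!is.na(df$father))) {
      kid <- df$iid[i]
      if (!kid %in% colnames(copies)) next
      fa <- copies[, df$father[i]]
      mo <- copies[, df$mother[i]]
      ck <- copies[, kid]
      ok <- mapply(function(cf, cm, cc) {
        any(vapply(0:1, function(tf) {
          tm <- cc - tf
          tm %in% 0:1 &&
            (if (tf == 1) cf >= 1 else cf <= 1) &&
            (if (tm == 1) cm >= 1 else cm <= 1)
        }, logical(1)))
      }, fa, mo, ck)
      expect_true(all(ok), label = paste("Mendelian consistency for", kid))
    }
  }
})

test_that("founder allele draws are calibrated to the configured frequencies", {
  # fix every background founder AF to 0.2 and pool realised founder allele
  # counts over replicates: the total is Binomial(2 * founders * variants, 0.2)
  af <- 0.2
  total <- 0L; trials <- 0L
  for (seed in 11:15) {
    cfg <- smallSimConfig(seed = seed, causalAf = af,
                          backgroundAfSpec = list(pRare = 0,
                                                  rareRange = c(af, af),
                                                  commonRange = c(af, af)))
    sim <- simulateFamily(cfg)
    df <- pedIndividuals(sim$pedigree)
    founders <- df$iid[is.na(df$father)]
    g <- genotypes(sim$variants)[, founders, drop = FALSE]
    cp <- matrix(match(g, c("homref", "het", "homalt")) - 1L, nrow = nrow(g))
    total <- total + sum(cp)
    trials <- trials + 2L * length(founders) * nrow(g)
  }
  se <- sqrt(af * (1 - af) * trials)
  expect_lt(abs(total - af * trials), 3 * se)
})

test_that("phenotype draws hit the configured penetrance", {
  set.seed(16)
  model <- DiseaseModel() # penetrance 0.90 for carriers
  ph <- drawPhenotypes(rep(1L, 2000L), model)
  fr <- mean(ph == "affected")
  se <- sqrt(0.9 * 0.1 / 2000)
  expect_lt(abs(fr - 0.9), 3 * se)
  # non-carriers with zero phenocopy rate are never affected
  expect_true(all(drawPhenotypes(rep(0L, 500L), model) == "unaffected"))
})

test_that("the study emulation preset realises the 6 + 9 design", {
  ps <- cachedPresetSim()
  sim <- ps$sim
  df <- pedIndividuals(sim$pedigree)
  genotyped <- sim$truth$genotyped_ids
  expect_length(genotyped, 15L)
  status <- setNames(df$phenotype, df$iid)[genotyped]
  carrier <- genotyped %in% sim$truth$carriers
  expect_equal(sum(status == "affected" & carrier), 6L)
  expect_equal(sum(status == "unaffected" & !carrier), 9L)
  expect_equal(sum(carrier != (status == "affected")), 0L)
  # the analysis pattern mirrors the 3 + 2 exome design
  pat <- ps$preset$pattern
  expect_true(all(status[pat@affectedIds] == "affected"))
  expect_true(all(status[pat@unaffectedIds] == "unaffected"))
  # four generations in the template
  depth <- function(id) {
    d <- 0L
    while (!is.na(df$father[match(id, df$iid)])) {
      id <- df$father[match(id, df$iid)]
      d <- d + 1L
    }
    d
  }
  expect_equal(max(vapply(df$iid, depth, 0L)), 3L)
})

test_that("truth IBD tracts cover the causal locus for carrier pairs", {
  ps <- cachedPresetSim()
  sim <- ps$sim
  pos <- as.integer(strsplit(sim$truth$causal_key, ":")[[1]][2])
  tracts <- sim$truth$ibd_tracts
  carriers <- intersect(sim$truth$carriers, sim$truth$genotyped_ids)
  prs <- combn(sort(carriers), 2)
  for (j in seq_len(ncol(prs))) {
    sel <- tracts$sample1 == prs[1, j] & tracts$sample2 == prs[2, j] &
      as.character(GenomicRanges::seqnames(tracts)) == "17"
    covered <- any(GenomicRanges::start(tracts)[sel] <= pos &
                   GenomicRanges::end(tracts)[sel] >= pos)
    expect_true(covered, label = paste("causal tract for pair",
                                       prs[1, j], prs[2, j]))
  }
})

test_that("a preset linkage evaluation at the causal site is positive", {
  ps <- cachedPresetSim()
  sim <- ps$sim
  av <- sim$variants
  i <- match(sim$truth$causal_key, variantKeys(av))
  fam <- intersect(colnames(genotypes(av)), pedIndividuals(sim$pedigree)$iid)
  res <- singlePointLod(sim$pedigree, genotypes(av)[i, fam], DiseaseModel())
  expect_gt(lodScore(res), 0)
  expect_lt(pValue(res), 0.05)
})

test_that("impossible configurations are rejected", {
  tmpl <- data.frame(iid = "X", father = "Y", mother = "Z", sex = "male",
                     phenotype = "unknown")
  expect_error(simulateFamily(SimConfig(pedigreeTemplate = tmpl, seed = 1)),
               "founder")
})
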