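pattern32 <- SegregationPattern(affectedIds = c("A1", "A2", "A3"),
                                unaffectedIds = c("U1", "U2"))
samp5 <- c("A1", "A2", "A3", "U1", "U2")

test_that("the segregation rule matches the dominant and recessive contracts", {
  av <- makeVariants(list(
    c("het", "het", "het", "homref", "homref"),      # dominant candidate
    c("het", "het", "homref", "homref", "homref"),   # sharing violated
    c("homalt", "homalt", "homalt", "het", "homref"),# recessive, carrier ok
    c("het", "het", "het", "het", "homref"),         # unaffected carries: no
    c("het", "het", "missing", "homref", "homref")), # missing disqualifies
    samples = samp5)
  res <- segregationFilter(av, pattern32)
  expect_equal(variantKeys(res$het), variantKeys(av[1]))
  expect_equal(variantKeys(res$hom), variantKeys(av[3]))
})

test_that("exactly one of the 32 homref/het assignments is a het candidate", {
  combos <- expand.grid(rep(list(c("homref", "het")), 5),
                        stringsAsFactors = FALSE)
  av <- makeVariants(lapply(seq_len(nrow(combos)), function(i)
    unlist(combos[i, ])), samples = samp5)
  flags <- segregationFlags(av, pattern32)
  expect_equal(sum(flags$het), 1L)
  hit <- unname(genotypes(av[which(flags$het)])[1, ])
  expect_equal(hit, c("het", "het", "het", "homref", "homref"))
  expect_equal(sum(flags$hom), 0L) # no homalt genotypes in this grid
})

test_that("vectorised segregation equals the per-variant brute-force rule", {
  set.seed(11)
  for (rep in 1:5) {
    g <- replicate(40, sample(c("homref", "het", "homalt", "missing"), 5,
                              replace = TRUE), simplify = FALSE)
    av <- makeVariants(g, samples = samp5)
    expect_equal(segregationFlags(av, pattern32), segregationBrute(av, pattern32))
  }
})

test_that("unknown pattern samples raise a configuration error", {
  av <- makeVariants(list(rep("homref", 5)), samples = samp5)
  expect_error(
    segregationFilter(av, SegregationPattern("A1", c("U1", "NOPE"))),
    "NOPE")
  expect_error(SegregationPattern(c("A1"), c("A1")), "disjoint")
  expect_error(SegregationPattern(character(), "U1"), "empty")
})

test_that("the cascade on the study emulation preset keeps the planted variant", {
  ps <- cachedPresetSim()
  sim <- ps$sim; pattern <- ps$preset$pattern
  regions <- sharedRegions(sim$truth$ibd_tracts, pattern@affectedIds)
  led <- runCascade(sim$variants, pattern, CascadeConfig(),
                    ibdRegions = regions, geneSpans = sim$truth$gene_spans)
  cn <- ledgerCounts(led)
  expect_equal(cn$step, c("segregation", "pass_consequence", "rare", "cadd",
                          "ibd"))
  expect_true(all(diff(cn$n) <= 0))
  expect_true(all(cn$n == cn$n_het + cn$n_hom))
  for (s in cn$step)
    expect_true(sim$truth$causal_key %in% variantKeys(survivors(led, s)))
  # each intermediate step removed something on this fixture
  expect_gt(cn$n[1], cn$n[4])
  # survivor sets are nested step by step
  for (k in 2:nrow(cn))
    expect_true(all(variantKeys(survivors(led, cn$step[k])) %in%
                    variantKeys(survivors(led, cn$step[k - 1]))))
})

test_that("the cascade is idempotent on its own survivors", {
  ps <- cachedPresetSim()
  sim <- ps$sim; pattern <- ps$preset$pattern
  regions <- sharedRegions(sim$truth$ibd_tracts, pattern@affectedIds)
  led <- runCascade(sim$variants, pattern, CascadeConfig(),
                    ibdRegions = regions, geneSpans = sim$truth$gene_spans)
  fin <- survivors(led)
  led2 <- runCascade(fin, pattern, CascadeConfig(), ibdRegions = regions,
                     geneSpans = sim$truth$gene_spans)
  expect_equal(variantKeys(survivors(led2)), variantKeys(fin))
})

test_that("degenerate cascade configurations behave as contracted", {
  ps <- cachedPresetSim()
  sim <- ps$sim; pattern <- ps$preset$pattern
  # an unattainable CADD threshold annihilates the score step
  led <- runCascade(sim$variants, pattern, CascadeConfig(caddMin = Inf),
                    ibdRegions = GenomicRanges::GRanges(),
                    geneSpans = sim$truth$gene_spans)
  expect_equal(ledgerCounts(led)$n[ledgerCounts(led)$step == "cadd"], 0L)
  # empty input -> all-zero ledger
  led0 <- runCascade(sim$variants[integer(0)], pattern, CascadeConfig(),
                     ibdRegions = GenomicRanges::GRanges())
  expect_true(all(ledgerCounts(led0)$n == 0L))
  # empty IBD regions retain nothing at step 5, unless the step is disabled
  ledNoIbd <- runCascade(sim$variants, pattern,
                         CascadeConfig(applyIbd = FALSE))
  expect_false("ibd" %in% ledgerCounts(ledNoIbd)$step)
})

test_that("ledger TSV export has one row per step", {
  ps <- cachedPresetSim()
  led <- runCascade(ps$sim$variants, ps$preset$pattern, CascadeConfig(),
                    ibdRegions = GenomicRanges::GRanges())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLedger(led, f)
  tab <- read.delim(f)
  expect_equal(tab$step, ledgerCounts(led)$step)
  expect_equal(tab$n, ledgerCounts(led)$n)
})

test_that("gene ranking is deterministic: seed genes, then CADD, then name", {
  av <- makeVariants(list(
    c("het", "het", "het", "homref", "homref"),
    c("het", "het", "het", "homref", "homref"),
    c("het", "het", "het", "homref", "homref"),
    c("het", "het", "het", "homref", "homref")),
    samples = samp5, gene = c("ZEB1", "ALPHA", "BETA", "GAMMA"),
    cadd_phred = c(30, 22, 25, 25))
  led <- runCascade(av, pattern32, CascadeConfig(applyIbd = FALSE, cohortAf = 1))
  expect_equal(rankSurvivors(led), c("ZEB1", "BETA", "GAMMA", "ALPHA"))
  expect_equal(rankSurvivors(led, seedGenes = "ALPHA"),
               c("ALPHA", "ZEB1", "BETA", "GAMMA"))
  expect_equal(rankSurvivors(runCascade(av[integer(0)], pattern32,
                                        CascadeConfig(applyIbd = FALSE))),
               character())
})
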