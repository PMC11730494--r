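test_that("disease-allele frequency derivation solves the Hardy-Weinberg identity", {
  # dominant, f = (0, 0.9, 0.9): 0.9 (2p - p^2) = 0.01
  p <- deriveDiseaseAlleleFreq(0.01, c(0, 0.9, 0.9))
  expect_equal(p, 1 - sqrt(1 - 0.01 / 0.9), tolerance = 1e-12)
  expect_equal(p, 0.005571, tolerance = 1e-4)
  # fully penetrant dominant: closed form 1 - sqrt(1 - K)
  expect_equal(deriveDiseaseAlleleFreq(0.01, c(0, 1, 1)),
               1 - sqrt(0.99), tolerance = 1e-12)
  # K -> 0 drives p -> 0
  expect_lt(deriveDiseaseAlleleFreq(1e-8, c(0, 0.9, 0.9)), 1e-7)
  # no admissible root
  expect_error(deriveDiseaseAlleleFreq(0.95, c(0, 0.9, 0.9)), "frequency")
})

test_that("derived frequencies round-trip to the prevalence within 1e-9", {
  set.seed(12)
  for (rep in 1:25) {
    f0 <- runif(1, 0, 0.05)
    f1 <- runif(1, max(f0, 0.2), 1)
    f2 <- runif(1, f1, 1)
    K <- runif(1, f0 + 1e-4, min(0.2, f1))
    p <- deriveDiseaseAlleleFreq(K, c(f0, f1, f2))
    back <- f2 * p^2 + f1 * 2 * p * (1 - p) + f0 * (1 - p)^2
    expect_lt(abs(back - K), 1e-9)
    # the DiseaseModel validity re-checks the same identity
    expect_s4_class(DiseaseModel(K, c(f0, f1, f2)), "DiseaseModel")
  }
})

test_that("LOD to p-value follows the half-chi-square conversion", {
  expect_equal(lodToPvalue(0), 0.5)
  # independent route: half upper tail of chi-square = normal tail at sqrt
  for (lod in c(0.5, 1, 2.070, 3)) {
    chi <- lod * 2 * log(10)
    expect_equal(lodToPvalue(lod), pnorm(-sqrt(chi)), tolerance = 1e-12)
  }
  expect_lt(abs(lodToPvalue(3.0) - 1.0e-4), 2e-6)
  # strictly decreasing in the LOD
  grid <- lodToPvalue(seq(0, 6, by = 0.25))
  expect_true(all(diff(grid) < 0))
  expect_error(lodToPvalue(-0.1), "non-negative")
})

test_that("two-tailed t probabilities are symmetric and correct", {
  expect_equal(tTwoTailed(0, 10), 1.0)
  expect_equal(tTwoTailed(2.5, 30), tTwoTailed(-2.5, 30))
  # cross-check against the regularised incomplete beta route
  t <- 2.2; df <- 17
  ib <- pbeta(df / (df + t^2), df / 2, 0.5)
  expect_equal(tTwoTailed(t, df), ib, tolerance = 1e-12)
  expect_error(tTwoTailed(1, 0.5), "df")
})

test_that("a lone founder's marker likelihood is the Hardy-Weinberg term", {
  single <- Pedigree(data.frame(iid = "A", father = NA, mother = NA,
                                sex = "male", phenotype = "unknown"))
  m <- DiseaseModel()
  for (q in c(0.001, 0.1, 0.4)) {
    expect_equal(pedigreeLoglik(single, c(A = "het"), m, q), log(2 * q * (1 - q)),
                 tolerance = 1e-12)
    expect_equal(pedigreeLoglik(single, c(A = "homalt"), m, q), log(q^2),
                 tolerance = 1e-12)
  }
  expect_error(pedigreeLoglik(single, c(A = "het"), m, 0.1, theta = 0.7),
               "theta")
})

test_that("an uninformative family carries no linkage information", {
  ped <- Pedigree(data.frame(
    iid = c("F", "M", "C"), father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
    sex = c("male", "female", "female"), phenotype = "unknown"))
  res <- singlePointLod(ped, c(F = "missing", M = "missing", C = "missing"),
                        DiseaseModel(), markerAf = 0.01)
  expect_equal(lodScore(res), 0, tolerance = 1e-12)
  expect_equal(pValue(res), 0.5, tolerance = 1e-12)
})

test_that("peeling equals exhaustive enumeration on random small pedigrees", {
  set.seed(606)
  for (rep in 1:30) {
    ped <- randomPedigree(sample(3:5, 1))
    q <- runif(1, 0.05, 0.4)
    mg <- dropMarkerGenotypes(ped, q)
    m <- randomDiseaseModel()
    th <- sample(c(0, 0.08, 0.23, 0.5), 1)
    a <- pedigreeLoglik(ped, mg, m, q, theta = th)
    b <- enumLoglik(ped, mg, m, q, theta = th)
    if (is.finite(a) || is.finite(b)) expect_lt(abs(a - b), 1e-9)
  }
})

test_that("at free recombination the likelihood factorises over loci", {
  set.seed(707)
  for (rep in 1:20) {
    ped <- randomPedigree(sample(4:8, 1))
    q <- runif(1, 0.05, 0.4)
    mg <- dropMarkerGenotypes(ped, q)
    m <- randomDiseaseModel()
    joint <- pedigreeLoglik(ped, mg, m, q, theta = 0.5)
    disease <- enumSingleLocusLoglik(ped, "disease", model = m,
                                     alleleFreq = m@diseaseAlleleFreq)
    marker <- enumSingleLocusLoglik(ped, "marker", markerGeno = mg,
                                    alleleFreq = q)
    expect_lt(abs(joint - (disease + marker)), 1e-9)
  }
})

test_that("each added observation can only lower the likelihood", {
  set.seed(808)
  for (rep in 1:10) {
    ped <- randomPedigree(sample(4:7, 1))
    q <- 0.2
    mg <- dropMarkerGenotypes(ped, q, pMissing = 0)
    m <- randomDiseaseModel()
    ids <- pedIndividuals(ped)$iid
    masked <- mg
    base <- pedigreeLoglik(ped, masked[0], m, q)
    for (k in seq_along(ids)) {
      ll <- pedigreeLoglik(ped, mg[seq_len(k)], m, q)
      expect_lte(ll, base + 1e-12)
      base <- ll
    }
  }
})

test_that("looped pedigrees are rejected by the likelihood evaluator", {
  loop <- Pedigree(data.frame(
    iid = c("GF", "GM", "A", "B", "WA", "HB", "X", "Y", "Z"),
    father = c(NA, NA, "GF", "GF", NA, NA, "A", "HB", "X"),
    mother = c(NA, NA, "GM", "GM", NA, NA, "WA", "B", "Y"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "male"),
    phenotype = "unknown"))
  expect_error(pedigreeLoglik(loop, c(Z = "het"), DiseaseModel(), 0.1),
               "loop")
})
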