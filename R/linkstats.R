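# Single-point parametric linkage under a configurable penetrance model.
#
# The pedigree likelihood sums over joint two-locus (disease, marker)
# diplotypes. Each individual's latent state is an ordered pair of
# haplotypes (paternal, maternal); a haplotype carries one disease allele
# (D/d) and one marker allele (M/m), so there are 4 haplotypes and 16
# ordered states. Founders are weighted by Hardy-Weinberg and linkage
# equilibrium; each meiosis transmits a parental haplotype intact with
# probability (1-theta)/2 per strand or a recombinant with theta/2; each
# individual contributes a penetrance factor (f_g if affected, 1-f_g if
# unaffected, 1 if unknown) and an indicator matching its observed marker
# genotype. The sum is evaluated exactly by Elston-Stewart peeling over the
# nuclear-family order from peelingOrder(), with per-family rescaling so deep
# pedigrees never underflow.

# haplotype h in 1:4 <-> (disease allele, marker allele) bits
.HAP_D <- c(0L, 0L, 1L, 1L)
.HAP_M <- c(0L, 1L, 0L, 1L)
# ordered state s in 1:16 <-> (paternal hap, maternal hap)
.ST_PAT <- rep(1:4, each = 4)
.ST_MAT <- rep(1:4, times = 4)
.ST_NDIS <- .HAP_D[.ST_PAT] + .HAP_D[.ST_MAT] # disease-allele copies
.ST_NMRK <- .HAP_M[.ST_PAT] + .HAP_M[.ST_MAT] # marker-alt copies

# P(parent in state s transmits haplotype h), 4 x 16
.transmitMatrix <- function(theta) {
  tm <- matrix(0, 4L, 16L)
  for (s in 1:16) {
    h1 <- .ST_PAT[s]; h2 <- .ST_MAT[s]
    nonrec1 <- h1; nonrec2 <- h2
    rec1 <- .HAP_D[h1] * 2L + .HAP_M[h2] + 1L # disease of h1, marker of h2
    rec2 <- .HAP_D[h2] * 2L + .HAP_M[h1] + 1L
    tm[nonrec1, s] <- tm[nonrec1, s] + (1 - theta) / 2
    tm[nonrec2, s] <- tm[nonrec2, s] + (1 - theta) / 2
    tm[rec1, s] <- tm[rec1, s] + theta / 2
    tm[rec2, s] <- tm[rec2, s] + theta / 2
  }
  tm
}

# T[s_child, (s_father, s_mother)] as a 16 x 256 matrix
.transmissionKernel <- function(theta) {
  tm <- .transmitMatrix(theta)
  kern <- matrix(0, 16L, 256L)
  for (sf in 1:16) for (sm in 1:16) {
    col <- (sf - 1L) * 16L + sm
    # child paternal hap from father, maternal hap from mother
    kern[, col] <- tm[.ST_PAT, sf] * tm[.ST_MAT, sm]
  }
  kern
}

.founderPrior <- function(diseaseAf, markerAf) {
  hapFreq <- ifelse(.HAP_D == 1L, diseaseAf, 1 - diseaseAf) *
             ifelse(.HAP_M == 1L, markerAf, 1 - markerAf)
  hapFreq[.ST_PAT] * hapFreq[.ST_MAT]
}

.penetranceVec <- function(phenotype, penetrances) {
  switch(phenotype,
    affected = penetrances[.ST_NDIS + 1L],
    unaffected = 1 - penetrances[.ST_NDIS + 1L],
    unknown = rep(1, 16L),
    stop("unknown phenotype code: ", phenotype))
}

.markerIndicator <- function(code) {
  if (is.na(code) || code == "missing") return(rep(1, 16L))
  n <- switch(code, homref = 0L, het = 1L, homalt = 2L,
              stop("unknown genotype code: ", code))
  as.numeric(.ST_NMRK == n)
}

#' Derive the disease-allele frequency from prevalence and penetrances
#'
#' Solves \eqn{f_2 p^2 + 2 f_1 p (1-p) + f_0 (1-p)^2 = K} for the allele
#' frequency p under Hardy-Weinberg founders, returning the smaller root in
#' (0, 1).
#'
#' @param prevalence population prevalence K, in (0, f2].
#' @param penetrances numeric triple (f0, f1, f2).
#' @return the disease-allele frequency.
#' @examples
#' deriveDiseaseAlleleFreq(0.01, c(0, 0.9, 0.9)) # ~0.005571
#' deriveDiseaseAlleleFreq(0.01, c(0, 1, 1))     # 1 - sqrt(0.99)
#' @export
deriveDiseaseAlleleFreq <- function(prevalence, penetrances) {
  stopifnot(length(penetrances) == 3L)
  f0 <- penetrances[1]; f1 <- penetrances[2]; f2 <- penetrances[3]
  if (f1 <= 0 && f2 <= 0) stop("f1 or f2 must be positive")
  a <- f2 - 2 * f1 + f0
  b <- 2 * (f1 - f0)
  cc <- f0 - prevalence
  if (abs(a) < 1e-14) {
    p <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real solution for the disease-allele frequency")
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    roots <- roots[roots > 0 & roots < 1]
    if (length(roots) == 0L)
      stop("no disease-allele frequency in (0, 1) is consistent with the model")
    p <- min(roots)
  }
  if (p <= 0 || p >= 1)
    stop("no disease-allele frequency in (0, 1) is consistent with the model")
  p
}

#' Construct a DiseaseModel
#'
#' When \code{diseaseAlleleFreq} is \code{NULL} (the usual case) it is
#' derived from the prevalence with [deriveDiseaseAlleleFreq()].
#'
#' @param prevalence population prevalence (default 0.01, a moderately rare
#'   trait).
#' @param penetrances triple (f0, f1, f2); the default
#'   \code{c(0, 0.9, 0.9)} is the dominant model with penetrance 0.90 for
#'   both carrier genotypes and no phenocopies. Note that the phenocopy rate
#'   f0 directly affects LOD scores from unaffected individuals.
#' @param diseaseAlleleFreq optional explicit allele frequency.
#' @param inheritanceLabel free-text label.
#' @return a validated [DiseaseModel-class].
#' @export
DiseaseModel <- function(prevalence = 0.01, penetrances = c(0, 0.9, 0.9),
                         diseaseAlleleFreq = NULL,
                         inheritanceLabel = "autosomal dominant") {
  derived <- is.null(diseaseAlleleFreq)
  if (derived)
    diseaseAlleleFreq <- deriveDiseaseAlleleFreq(prevalence, penetrances)
  new("DiseaseModel", prevalence = prevalence, penetrances = penetrances,
      diseaseAlleleFreq = diseaseAlleleFreq,
      inheritanceLabel = inheritanceLabel, freqDerived = derived)
}

setMethod("show", "DiseaseModel", function(object) {
  cat("DiseaseModel: ", object@inheritanceLabel,
      "; K = ", object@prevalence,
      "; penetrances (f0,f1,f2) = (",
      paste(object@penetrances, collapse = ", "),
      "); disease-allele freq = ", signif(object@diseaseAlleleFreq, 6),
      if (object@freqDerived) " (derived)" else " (supplied)", "\n", sep = "")
})

#' Exact pedigree log-likelihood of phenotypes and marker genotypes
#'
#' Evaluates, by Elston-Stewart peeling, the natural-log likelihood of the
#' observed phenotypes and single-marker genotypes under the two-locus
#' (disease, marker) model at recombination fraction \code{theta}. Missing
#' marker genotypes contribute a factor of 1, as do unknown phenotypes.
#'
#' @param ped a loop-free [Pedigree-class].
#' @param markerGenotypes named character vector (ids to
#'   \code{homref}/\code{het}/\code{homalt}/\code{missing}); individuals
#'   absent from the vector are treated as missing.
#' @param model a [DiseaseModel-class].
#' @param markerAf marker alt-allele frequency in founders.
#' @param theta recombination fraction in \[0, 0.5\].
#' @return the natural-log likelihood (\code{-Inf} if the data are
#'   impossible under the model).
#' @seealso [singlePointLod()]
#' @export
pedigreeLoglik <- function(ped, markerGenotypes, model, markerAf,
                           theta = 0) {
  if (theta < 0 || theta > 0.5)
    stop("theta must lie in [0, 0.5]")
  stopifnot(markerAf > 0, markerAf < 1)
  df <- ped@individuals
  ids <- df$iid
  isFounder <- stats::setNames(is.na(df$father), ids)
  prior <- .founderPrior(model@diseaseAlleleFreq, markerAf)
  kern <- .transmissionKernel(theta)

  base <- matrix(1, nrow = length(ids), ncol = 16L,
                 dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    mg <- if (ids[i] %in% names(markerGenotypes)) markerGenotypes[[ids[i]]]
          else "missing"
    v <- .penetranceVec(df$phenotype[i], model@penetrances) *
         .markerIndicator(mg)
    if (isFounder[[ids[i]]]) v <- v * prior
    base[i, ] <- v
  }

  fams <- peelingOrder(ped)
  R <- matrix(1, nrow = length(ids), ncol = 16L, dimnames = list(ids, NULL))
  logScale <- 0
  touched <- character()

  famSum <- function(fam, pivot) {
    aF <- if (identical(fam$father, pivot)) rep(1, 16L)
          else base[fam$father, ] * R[fam$father, ]
    aM <- if (identical(fam$mother, pivot)) rep(1, 16L)
          else base[fam$mother, ] * R[fam$mother, ]
    childPart <- matrix(1, 16L, 16L) # (s_father, s_mother)
    pivotChild <- NULL
    for (ch in fam$children) {
      if (identical(ch, pivot)) { pivotChild <- ch; next }
      aC <- base[ch, ] * R[ch, ]
      childPart <- childPart * matrix(as.vector(aC %*% kern), 16L, 16L,
                                      byrow = TRUE)
    }
    W <- outer(aF, aM) * childPart
    list(W = W, pivotChild = pivotChild)
  }

  for (fam in fams) {
    touched <- union(touched, c(fam$father, fam$mother, fam$children))
    pivot <- fam$pivot
    fs <- famSum(fam, pivot)
    if (is.na(pivot)) {
      tot <- sum(fs$W)
      if (tot <= 0) return(-Inf)
      logScale <- logScale + log(tot)
    } else if (!is.null(fs$pivotChild)) {
      g <- as.vector(kern %*% as.vector(t(fs$W)))
    } else {
      if (identical(fam$father, pivot)) g <- as.vector(fs$W %*% rep(1, 16L))
      else g <- as.vector(rep(1, 16L) %*% fs$W)
    }
    if (!is.na(pivot)) {
      mx <- max(g)
      if (mx <= 0) return(-Inf)
      R[pivot, ] <- R[pivot, ] * (g / mx)
      logScale <- logScale + log(mx)
    }
  }
  # individuals in no nuclear family (isolated founders) contribute
  # independent sums
  for (iid in setdiff(ids, touched)) {
    tot <- sum(base[iid, ] * R[iid, ])
    if (tot <= 0) return(-Inf)
    logScale <- logScale + log(tot)
  }
  logScale
}

#' Single-point parametric LOD score
#'
#' LOD = [loglik(theta) - loglik(0.5)] / ln(10); by construction the LOD at
#' theta = 0.5 is exactly 0. The associated p-value uses the half-chi-square
#' conversion of [lodToPvalue()].
#'
#' @inheritParams pedigreeLoglik
#' @param theta recombination fraction the LOD is evaluated at (default 0,
#'   the single-point test of the candidate variant itself).
#' @return a [LinkageResult-class].
#' @export
singlePointLod <- function(ped, markerGenotypes, model, markerAf = 0.001,
                           theta = 0) {
  l0 <- pedigreeLoglik(ped, markerGenotypes, model, markerAf, theta = theta)
  l5 <- if (theta == 0.5) l0
        else pedigreeLoglik(ped, markerGenotypes, model, markerAf, theta = 0.5)
  lod <- if (theta == 0.5) 0 else (l0 - l5) / log(10)
  pv <- if (lod >= 0) lodToPvalue(lod) else NA_real_
  new("LinkageResult", lod = lod, theta = theta, pValue = pv,
      loglikLinked = l0, loglikUnlinked = l5)
}

setMethod("show", "LinkageResult", function(object) {
  cat(sprintf("LinkageResult: LOD = %.4f at theta = %g (p = %.4g)\n",
              object@lod, object@theta, object@pValue))
})

#' LinkageResult accessors
#'
#' @param x a [LinkageResult-class].
#' @name linkageresult-accessors
#' @return the corresponding slot value.
NULL

#' @rdname linkageresult-accessors
#' @export
lodScore <- function(x) x@lod

#' @rdname linkageresult-accessors
#' @export
pValue <- function(x) x@pValue

#' LOD score over a grid of recombination fractions
#'
#' Diagnostic evaluator; no maximisation over theta is performed.
#'
#' @inheritParams pedigreeLoglik
#' @param thetas recombination fractions to evaluate.
#' @return data.frame with columns \code{theta} and \code{lod}.
#' @export
lodCurve <- function(ped, markerGenotypes, model, markerAf = 0.001,
                     thetas = seq(0, 0.5, by = 0.05)) {
  l5 <- pedigreeLoglik(ped, markerGenotypes, model, markerAf, theta = 0.5)
  lods <- vapply(thetas, function(th) {
    if (th == 0.5) 0
    else (pedigreeLoglik(ped, markerGenotypes, model, markerAf,
                         theta = th) - l5) / log(10)
  }, numeric(1))
  data.frame(theta = thetas, lod = lods)
}

#' Convert a LOD score to a p-value
#'
#' Half the upper tail of a 1-df chi-square evaluated at
#' \code{2 ln(10) lod}: \code{pchisq(lod * 2 * log(10), df = 1,
#' lower.tail = FALSE) / 2}. A LOD of 0 gives p = 0.5.
#'
#' @param lod non-negative LOD score.
#' @return p-value in (0, 0.5].
#' @examples
#' lodToPvalue(2.070) # ~0.001
#' @export
lodToPvalue <- function(lod) {
  if (any(lod < 0)) stop("lod must be non-negative")
  stats::pchisq(lod * (2 * log(10)), df = 1, lower.tail = FALSE) / 2
}

#' Two-tailed Student-t p-value
#'
#' @param t t statistic (sign is irrelevant).
#' @param df degrees of freedom (>= 1).
#' @return p-value in (0, 1].
#' @examples
#' tTwoTailed(2.693, 53) # ~0.0095
#' @export
tTwoTailed <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(-abs(t), df = df)
}
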