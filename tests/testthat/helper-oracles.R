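# Independent reference implementations used to validate the package's
# algorithms. These deliberately take the brute-force route (exhaustive
# enumeration, per-base membership) and share no code with the implementation
# they check.

# Exhaustive two-locus pedigree likelihood: sums over all 16^n joint ordered
# (paternal, maternal) haplotype-pair assignments, building every factor
# (founder priors, meiosis-by-meiosis transmission with explicit
# recombination events, penetrance, marker indicator) directly from the
# model definition.
enumLoglik <- function(ped, markerGeno, model, markerAf, theta) {
  df <- pedIndividuals(ped)
  n <- nrow(df)
  ids <- df$iid
  hd <- c(0, 0, 1, 1); hm <- c(0, 1, 0, 1)       # hap 1..4 = (disease, marker)
  pat <- rep(1:4, each = 4); mat <- rep(1:4, times = 4)
  ndis <- hd[pat] + hd[mat]; nmrk <- hm[pat] + hm[mat]
  pd <- model@diseaseAlleleFreq; pm <- markerAf
  hapf <- ifelse(hd == 1, pd, 1 - pd) * ifelse(hm == 1, pm, 1 - pm)
  prior <- hapf[pat] * hapf[mat]
  # transmission by enumerating strand choice and recombination event
  tr <- matrix(0, 4, 16)
  for (s in 1:16) for (strand in 1:2) for (rec in 0:1) {
    hs <- c(pat[s], mat[s]); other <- c(mat[s], pat[s])
    d <- hd[hs[strand]]
    m <- if (rec) hm[other[strand]] else hm[hs[strand]]
    h <- d * 2 + m + 1
    tr[h, s] <- tr[h, s] + 0.5 * (if (rec) theta else 1 - theta)
  }
  pen <- model@penetrances
  fvec <- function(i) {
    v <- switch(df$phenotype[i], affected = pen[ndis + 1],
                unaffected = 1 - pen[ndis + 1], unknown = rep(1, 16))
    mg <- if (ids[i] %in% names(markerGeno)) markerGeno[[ids[i]]] else "missing"
    if (!is.na(mg) && mg != "missing")
      v <- v * (nmrk == c(homref = 0, het = 1, homalt = 2)[[mg]])
    v
  }
  fidx <- match(df$father, ids); midx <- match(df$mother, ids)
  trPat <- as.vector(tr[pat, ])  # [s_child + 16*(s_father-1)]
  trMat <- as.vector(tr[mat, ])
  idx0 <- 0:(16^n - 1)
  states <- lapply(1:n, function(i) (idx0 %/% 16^(i - 1)) %% 16 + 1)
  lik <- rep(1, length(idx0))
  for (i in 1:n) {
    si <- states[[i]]
    lik <- lik * fvec(i)[si]
    if (is.na(fidx[i])) {
      lik <- lik * prior[si]
    } else {
      lik <- lik * trPat[si + 16 * (states[[fidx[i]]] - 1)]
      lik <- lik * trMat[si + 16 * (states[[midx[i]]] - 1)]
    }
  }
  log(sum(lik))
}

# Exhaustive single-locus pedigree likelihood over 3^n genotype (allele
# count) assignments; `kind` selects which observed layer the factors use.
enumSingleLocusLoglik <- function(ped, kind = c("disease", "marker"),
                                  markerGeno = NULL, model = NULL,
                                  alleleFreq) {
  kind <- match.arg(kind)
  df <- pedIndividuals(ped)
  n <- nrow(df); ids <- df$iid
  prior <- c((1 - alleleFreq)^2, 2 * alleleFreq * (1 - alleleFreq),
             alleleFreq^2)
  trans <- array(0, c(3, 3, 3)) # [child+1, father+1, mother+1]
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    pf <- gf / 2; pm2 <- gm / 2
    p <- switch(gc + 1,
                (1 - pf) * (1 - pm2),
                pf * (1 - pm2) + (1 - pf) * pm2,
                pf * pm2)
    trans[gc + 1, gf + 1, gm + 1] <- p
  }
  fvec <- function(i) {
    if (kind == "disease") {
      pen <- model@penetrances
      switch(df$phenotype[i], affected = pen, unaffected = 1 - pen,
             unknown = rep(1, 3))
    } else {
      mg <- if (ids[i] %in% names(markerGeno)) markerGeno[[ids[i]]]
            else "missing"
      if (is.na(mg) || mg == "missing") rep(1, 3)
      else as.numeric(0:2 == c(homref = 0, het = 1, homalt = 2)[[mg]])
    }
  }
  fidx <- match(df$father, ids); midx <- match(df$mother, ids)
  idx0 <- 0:(3^n - 1)
  states <- lapply(1:n, function(i) (idx0 %/% 3^(i - 1)) %% 3 + 1)
  lik <- rep(1, length(idx0))
  for (i in 1:n) {
    si <- states[[i]]
    lik <- lik * fvec(i)[si]
    if (is.na(fidx[i])) lik <- lik * prior[si]
    else lik <- lik * trans[cbind(si, states[[fidx[i]]], states[[midx[i]]])]
  }
  log(sum(lik))
}

# Per-base membership oracle for multi-way IBD sharing: a position belongs
# to the shared set when, for at least `minPairs` of the required pairs,
# some segment of that pair covers it.
sharedRegionsBrute <- function(segments, requiredSamples, maxPos,
                               minPairs = NULL) {
  prs <- utils::combn(sort(unique(requiredSamples)), 2)
  pairKeys <- paste(prs[1, ], prs[2, ], sep = "|")
  if (is.null(minPairs)) minPairs <- length(pairKeys)
  segKey <- paste(pmin(segments$sample1, segments$sample2),
                  pmax(segments$sample1, segments$sample2), sep = "|")
  out <- list()
  for (ch in unique(as.character(GenomicRanges::seqnames(segments)))) {
    onCh <- as.character(GenomicRanges::seqnames(segments)) == ch
    covered <- matrix(FALSE, nrow = maxPos, ncol = length(pairKeys))
    for (j in seq_along(pairKeys)) {
      idx <- which(onCh & segKey == pairKeys[j])
      for (i in idx) {
        lo <- GenomicRanges::start(segments)[i]
        hi <- min(GenomicRanges::end(segments)[i], maxPos)
        if (lo <= hi) covered[lo:hi, j] <- TRUE
      }
    }
    hit <- rowSums(covered) >= minPairs
    if (any(hit)) {
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values
      out[[ch]] <- GenomicRanges::GRanges(ch,
        IRanges::IRanges(starts[keep], ends[keep]))
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::sort(suppressWarnings(do.call(c, unname(out))))
}

# Direct per-variant restatement of the segregation rule, written as an
# explicit loop rather than matrix logic.
segregationBrute <- function(av, pattern) {
  g <- genotypes(av)
  aff <- pattern@affectedIds; una <- pattern@unaffectedIds
  het <- hom <- logical(length(av))
  for (i in seq_len(length(av))) {
    row <- g[i, ]
    if (any(row[c(aff, una)] == "missing")) next
    het[i] <- all(row[aff] == "het") && all(row[una] == "homref")
    hom[i] <- all(row[aff] == "homalt") && all(row[una] %in% c("homref", "het"))
  }
  data.frame(het = het, hom = hom)
}
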