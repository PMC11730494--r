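# Beagle-style IBD segment I/O, multi-way shared-region intersection,
# variant/gene overlap and a naive opposite-homozygote IBD scan for
# synthetic data. Interval arithmetic goes through GenomicRanges/IRanges;
# coordinates are 1-based inclusive at every interface, BED output converts
# at the boundary.

#' @importFrom GenomicRanges GRanges reduce intersect coverage sort
#' @importFrom IRanges IRanges CharacterList
NULL

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Read Beagle-style IBD segments
#'
#' Parses the tab-delimited Beagle \code{.ibd} dialect (columns sample1,
#' hap1, sample2, hap2, chrom, start, end, and optionally a LOD-style
#' support score; haplotype columns are ignored). Segments are normalised so
#' that sample1 < sample2 lexicographically.
#'
#' @param path file path.
#' @return \code{GRanges} with metadata columns \code{sample1},
#'   \code{sample2} and \code{score}.
#' @seealso [writeIbd()], [sharedRegions()]
#' @export
readIbd <- function(path) {
  if (!file.exists(path)) stop("IBD file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = "character")
  if (nrow(tab) == 0L)
    return(GenomicRanges::GRanges(sample1 = character(), sample2 = character(),
                                  score = numeric()))
  if (ncol(tab) < 7L)
    stop("IBD file must have at least 7 columns (sample1 hap1 sample2 hap2 ",
         "chrom start end [score])")
  start <- as.numeric(tab[[6]])
  end <- as.numeric(tab[[7]])
  bad <- which(start > end)
  if (length(bad))
    stop("IBD record(s) with start > end at line(s): ",
         paste(bad, collapse = ", "))
  s1 <- tab[[1]]; s2 <- tab[[3]]
  gr <- GenomicRanges::GRanges(tab[[5]], IRanges::IRanges(start, end))
  gr$sample1 <- pmin(s1, s2)
  gr$sample2 <- pmax(s1, s2)
  gr$score <- if (ncol(tab) >= 8L) {
    sc <- tab[[8]]
    sc[sc == "."] <- NA
    as.numeric(sc)
  } else rep(NA_real_, length(gr))
  gr
}

#' Write IBD segments in the Beagle-style dialect
#'
#' Haplotype columns are written as 0 (unknown).
#'
#' @param segments \code{GRanges} with \code{sample1}, \code{sample2} and
#'   optionally \code{score} metadata.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIbd <- function(segments, path) {
  score <- segments$score
  if (is.null(score)) score <- rep(NA_real_, length(segments))
  lines <- paste(segments$sample1, 0L, segments$sample2, 0L,
                 as.character(GenomicRanges::seqnames(segments)),
                 GenomicRanges::start(segments),
                 GenomicRanges::end(segments),
                 ifelse(is.na(score), ".", format(score, trim = TRUE)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Regions shared identically-by-descent across a sample set
#'
#' Computes, per chromosome, the maximal intervals covered by at least one
#' IBD segment for every unordered pair of \code{requiredSamples} (pairwise-
#' complete sharing, the strictest reading), or, with \code{minPairs}, the
#' relaxation requiring coverage by at least that many of the pairs. Output
#' intervals are disjoint, sorted, and 1-based inclusive.
#'
#' @param segments \code{GRanges} of pairwise segments as from [readIbd()].
#' @param requiredSamples character vector (>= 2 samples).
#' @param minPairs minimum number of supporting pairs; default all
#'   \code{choose(k, 2)} pairs.
#' @return \code{GRanges} with a \code{supportingPairs} \code{CharacterList}
#'   column listing, per region, the pairs whose merged segments cover it
#'   entirely.
#' @examples
#' segs <- GenomicRanges::GRanges("17", IRanges::IRanges(
#'   c(100, 200, 250), c(300, 400, 350)))
#' segs$sample1 <- c("A", "A", "B"); segs$sample2 <- c("B", "C", "C")
#' sharedRegions(segs, c("A", "B", "C")) # 17:250-300
#' @export
sharedRegions <- function(segments, requiredSamples, minPairs = NULL) {
  requiredSamples <- unique(as.character(requiredSamples))
  if (length(requiredSamples) < 2L)
    stop("sharedRegions requires at least 2 samples")
  pairs <- utils::combn(sort(requiredSamples), 2L)
  pairKeys <- .pairKey(pairs[1, ], pairs[2, ])
  if (is.null(minPairs)) minPairs <- length(pairKeys)
  minPairs <- max(1L, min(as.integer(minPairs), length(pairKeys)))

  empty <- GenomicRanges::GRanges()
  empty$supportingPairs <- IRanges::CharacterList()
  if (length(segments) == 0L) return(empty)
  segKey <- .pairKey(segments$sample1, segments$sample2)
  perPair <- lapply(pairKeys, function(k)
    GenomicRanges::reduce(segments[segKey == k]))
  # stack one range-set per pair and keep bases covered by >= minPairs of them
  stacked <- do.call(c, perPair)
  if (length(stacked) == 0L) return(empty)
  cov <- GenomicRanges::coverage(stacked)
  hit <- GenomicRanges::GRanges(IRanges::slice(cov, lower = minPairs,
                                               rangesOnly = TRUE))
  hit <- GenomicRanges::sort(hit)
  if (length(hit) == 0L) return(empty)
  sup <- lapply(seq_along(hit), function(i) {
    covering <- vapply(seq_along(perPair), function(j) {
      ov <- GenomicRanges::intersect(perPair[[j]], hit[i])
      sum(GenomicRanges::width(ov)) == GenomicRanges::width(hit[i])
    }, logical(1))
    pairKeys[covering]
  })
  hit$supportingPairs <- IRanges::CharacterList(sup)
  hit
}

#' Overlap of variants with shared regions
#'
#' Position mode tests whether each variant's position lies inside a region
#' (1-based inclusive boundaries). Gene mode tests whether the variant's
#' gene span overlaps a region at all ("variants in genes within IBD
#' segments"); a gene absent from \code{geneSpans} is treated as
#' non-overlapping, with a message.
#'
#' @param regions \code{GRanges} of shared regions.
#' @param av an [AnnotatedVariants-class].
#' @param geneSpans named \code{GRanges} of gene spans (gene mode only).
#' @param mode \code{"position"} or \code{"gene"}.
#' @return logical vector, one element per variant.
#' @export
overlapsRegion <- function(regions, av, geneSpans = NULL,
                           mode = c("gene", "position")) {
  mode <- match.arg(mode)
  info <- av@info
  if (nrow(info) == 0L) return(logical())
  if (mode == "position") {
    pts <- GenomicRanges::GRanges(info$chrom,
                                  IRanges::IRanges(info$pos, info$pos))
    return(IRanges::overlapsAny(pts, regions))
  }
  if (is.null(geneSpans))
    stop("gene-mode overlap requires geneSpans")
  idx <- match(info$gene, names(geneSpans))
  missing <- is.na(idx) | is.na(info$gene)
  if (any(missing))
    message(sum(missing), " variant(s) in gene(s) without a span entry; ",
            "treated as non-overlapping")
  out <- rep(FALSE, nrow(info))
  if (any(!missing))
    out[!missing] <- IRanges::overlapsAny(geneSpans[idx[!missing]], regions)
  out
}

#' Write shared regions as BED
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open convention
#' at the boundary.
#'
#' @param regions \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedRegions <- function(regions, path) {
  lines <- paste(as.character(GenomicRanges::seqnames(regions)),
                 GenomicRanges::start(regions) - 1L,
                 GenomicRanges::end(regions), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-span table
#'
#' Accepts a TSV with header \code{GENE CHROM START END} (1-based inclusive)
#' or a 4-column BED file (chrom, start, end, name; 0-based half-open,
#' converted on read).
#'
#' @param path file path.
#' @return named \code{GRanges}.
#' @export
readGeneSpans <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^GENE\t", first)) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(CHROM = "character"))
    gr <- GenomicRanges::GRanges(tab$CHROM,
                                 IRanges::IRanges(tab$START, tab$END))
    names(gr) <- tab$GENE
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             colClasses = c("character", "numeric", "numeric",
                                            "character"))
    gr <- GenomicRanges::GRanges(tab[[1]],
                                 IRanges::IRanges(tab[[2]] + 1L, tab[[3]]))
    names(gr) <- tab[[4]]
  }
  gr
}

#' Write a gene-span table as TSV
#'
#' @param geneSpans named \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSpans <- function(geneSpans, path) {
  tab <- data.frame(GENE = names(geneSpans),
                    CHROM = as.character(GenomicRanges::seqnames(geneSpans)),
                    START = GenomicRanges::start(geneSpans),
                    END = GenomicRanges::end(geneSpans))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Naive exclusion-based IBD scan for one sample pair
#'
#' A lightweight alternative to model-based IBD detection, intended for
#' synthetic data: along position-sorted markers, it reports the maximal
#' runs of at least \code{window} markers that contain at most
#' \code{maxOppositeHom} opposite-homozygote sites (one sample homref, the
#' other homalt) — the classical exclusion signal, since opposite
#' homozygotes are impossible on a shared haplotype apart from genotyping
#' error. Missing genotypes are uninformative and never count as opposite.
#'
#' @param geno matrix with 2 columns (one per sample) of genotype codes
#'   (\code{homref}/\code{het}/\code{homalt}/\code{missing}) or 0/1/2/NA alt
#'   allele counts, rows sorted by position.
#' @param positions numeric vector of 1-based marker positions.
#' @param chrom chromosome name (single value).
#' @param window minimum run length in markers (default 50).
#' @param maxOppositeHom opposite-homozygote tolerance per run (default 1).
#' @param samples length-2 character vector of sample ids.
#' @return \code{GRanges} of candidate segments with \code{sample1},
#'   \code{sample2}, \code{score} (= marker count) metadata.
#' @export
naiveIbdScan <- function(geno, positions, chrom = "1", window = 50L,
                         maxOppositeHom = 1L, samples = c("S1", "S2")) {
  stopifnot(ncol(geno) == 2L, nrow(geno) == length(positions),
            !is.unsorted(positions))
  if (is.character(geno)) {
    m <- matrix(c(homref = 0, het = 1, homalt = 2, missing = NA)[geno],
                ncol = 2L)
  } else m <- geno
  n <- nrow(m)
  empty <- GenomicRanges::GRanges(sample1 = character(),
                                  sample2 = character(), score = numeric())
  if (n == 0L) return(empty)
  opp <- !is.na(m[, 1]) & !is.na(m[, 2]) & abs(m[, 1] - m[, 2]) == 2
  informative <- !(is.na(m[, 1]) | is.na(m[, 2]))
  if (!any(informative)) return(empty)
  # A maximal run with <= k opposite-homozygote markers runs from just after
  # the t-th opposite site to just before the (t+k+1)-th (sentinels at both
  # ends); with m opposite sites overall there are max(1, m-k) such runs.
  bad <- which(opp)
  k <- as.integer(maxOppositeHom)
  m_ <- length(bad)
  bounds <- c(0L, bad, rep(n + 1L, k + 1L)) # pad so index t+k+2 always exists
  tMax <- max(0L, m_ - k)
  lo <- bounds[0:tMax + 1L] + 1L
  hi <- bounds[0:tMax + k + 2L] - 1L
  keep <- (hi - lo + 1L) >= window
  if (!any(keep)) return(empty)
  lo <- lo[keep]; hi <- hi[keep]
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(positions[lo], positions[hi]))
  gr$sample1 <- rep(pmin(samples[1], samples[2]), length(gr))
  gr$sample2 <- rep(pmax(samples[1], samples[2]), length(gr))
  gr$score <- hi - lo + 1
  gr
}
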