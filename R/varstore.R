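# Multi-sample VCF + annotation ingestion, cohort allele statistics and
# marker QC. Reading goes through VariantAnnotation; the writer emits plain
# VCF 4.2 text so the simulator's outputs stay human-readable.

#' @importFrom VariantAnnotation readVcf geno ref alt info
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

# VEP-style consequence terms -> controlled vocabulary.
.normalizeConsequence <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[grepl("missense", x)] <- "missense"
  out[grepl("frameshift", x)] <- "frameshift"
  out[grepl("stop_gained|stopgain|nonsense", x)] <- "nonsense"
  out[grepl("splice", x)] <- "splice"
  out[x %in% .CONSEQUENCES] <- x[x %in% .CONSEQUENCES]
  out[is.na(x) | x == "na"] <- NA_character_
  out
}

# One GT string -> genotype code for a given alt-allele index.
.gtToCode <- function(gt, altIndex, recordLabel) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  parts <- strsplit(gt, "[/|]", fixed = FALSE)[[1]]
  if (length(parts) != 2L || any(!grepl("^[0-9.]+$", parts)))
    stop("malformed GT '", gt, "' at record ", recordLabel)
  if (any(parts == ".")) return("missing")
  n <- sum(as.integer(parts) == altIndex)
  c("homref", "het", "homalt")[n + 1L]
}

#' Construct an AnnotatedVariants object
#'
#' @param info data.frame of per-variant fields (see
#'   [AnnotatedVariants-class]); missing annotation columns are added as
#'   \code{NA}.
#' @param geno character matrix (variants x samples) of
#'   \code{homref}/\code{het}/\code{homalt}/\code{missing} codes.
#' @return a validated [AnnotatedVariants-class].
#' @export
AnnotatedVariants <- function(info, geno) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  for (col in c("filter_status", "consequence", "gene"))
    if (is.null(info[[col]])) info[[col]] <- rep(NA_character_, nrow(info))
  for (col in c("gnomad_max_af", "cadd_phred"))
    if (is.null(info[[col]])) info[[col]] <- rep(NA_real_, nrow(info))
  info$chrom <- as.character(info$chrom)
  info$pos <- as.integer(info$pos)
  info <- info[, c("chrom", "pos", "ref", "alt", "filter_status",
                   "consequence", "gene", "gnomad_max_af", "cadd_phred")]
  rownames(info) <- NULL
  geno <- as.matrix(geno)
  if (nrow(info) == 0L && length(geno) == 0L)
    geno <- matrix(character(), nrow = 0L, ncol = ncol(geno),
                   dimnames = dimnames(geno))
  new("AnnotatedVariants", info = info, geno = geno)
}

#' @describeIn AnnotatedVariants number of variant records.
#' @param x,object an AnnotatedVariants object.
#' @export
setMethod("length", "AnnotatedVariants", function(x) nrow(x@info))

#' @describeIn AnnotatedVariants subset variant records.
#' @param i index vector over variants.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "AnnotatedVariants", function(x, i, j, ..., drop = FALSE) {
  AnnotatedVariants(x@info[i, , drop = FALSE],
                    x@geno[i, , drop = FALSE])
})

setMethod("show", "AnnotatedVariants", function(object) {
  cat("AnnotatedVariants: ", nrow(object@info), " biallelic records, ",
      ncol(object@geno), " samples\n", sep = "")
  if (nrow(object@info))
    print(utils::head(object@info, 5L))
})

#' AnnotatedVariants accessors
#'
#' @param x an [AnnotatedVariants-class].
#' @return \code{variantInfo}: the per-variant annotation data.frame;
#'   \code{genotypes}: the variants x samples genotype-code matrix;
#'   \code{sampleIds}: sample ids; \code{variantKeys}: the
#'   \code{chrom:pos:ref:alt} key of each record.
#' @name annotatedvariants-accessors
NULL

#' @rdname annotatedvariants-accessors
#' @export
variantInfo <- function(x) x@info

#' @rdname annotatedvariants-accessors
#' @export
genotypes <- function(x) x@geno

#' @rdname annotatedvariants-accessors
#' @export
sampleIds <- function(x) colnames(x@geno)

#' @rdname annotatedvariants-accessors
#' @export
variantKeys <- function(x)
  with(x@info, paste(chrom, pos, ref, alt, sep = ":"))

# Deterministic variant order: chrom, pos, ref, alt.
.sortVariants <- function(x) {
  o <- with(x@info, order(chrom, pos, ref, alt))
  x[o]
}

#' Read a multi-sample VCF with annotations
#'
#' Reads a VCF 4.x file (plain or gzipped; the GT FORMAT field is required),
#' decomposes multi-allelic sites into biallelic records (a genotype's code
#' counts copies of the record's own alt allele; other alt alleles count as
#' reference) and joins per-variant annotations. Annotations come either
#' from a side TSV with header
#' \code{CHROM POS REF ALT GENE CONSEQUENCE GNOMAD_MAX_AF CADD_PHRED} keyed
#' on (chrom, pos, ref, alt), or, when \code{annotationPath} is \code{NULL},
#' from same-named INFO fields if present. Consequence terms are normalised
#' to the controlled vocabulary (\code{stop_gained} to nonsense, splice
#' donor/acceptor/region to splice, ...). Records that fail the annotation
#' join get \code{NA} annotations with a warning, not an error.
#'
#' @param vcfPath VCF file path.
#' @param annotationPath optional annotation TSV path.
#' @return an [AnnotatedVariants-class], sorted by (chrom, pos, ref, alt).
#' @seealso [writeAnnotatedVcf()]
#' @export
readAnnotatedVcf <- function(vcfPath, annotationPath = NULL) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = "unknown"))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field: ", vcfPath)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  filt <- rr$FILTER
  samples <- colnames(gt)

  rows <- list()
  genoRows <- list()
  for (i in seq_along(rr)) {
    alts <- as.character(altList[[i]])
    alts <- alts[alts != "" & !is.na(alts)]
    for (k in seq_along(alts)) {
      codes <- vapply(gt[i, ], .gtToCode, "", altIndex = k,
                      recordLabel = paste0(chrom[i], ":", pos[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = refs[i], alt = alts[k],
        filter_status = if (is.na(filt[i]) || filt[i] == ".") "other" else filt[i],
        stringsAsFactors = FALSE)
      genoRows[[length(genoRows) + 1L]] <- codes
    }
  }
  if (length(rows) == 0L) {
    av <- AnnotatedVariants(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), filter_status = character()),
      matrix(character(), 0L, length(samples), dimnames = list(NULL, samples)))
    return(av)
  }
  info <- do.call(rbind, rows)
  genoM <- do.call(rbind, genoRows)
  colnames(genoM) <- samples

  ann <- NULL
  if (!is.null(annotationPath)) {
    ann <- utils::read.delim(annotationPath, header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(CHROM = "character"))
  } else {
    # fall back to simple INFO keys if the VCF carries them
    inf <- VariantAnnotation::info(vcf)
    keys <- intersect(c("GENE", "CONSEQUENCE", "GNOMAD_MAX_AF", "CADD_PHRED"),
                      colnames(inf))
    if (length(keys) == 4L && length(altList) == length(rr) &&
        all(lengths(altList) == 1L)) {
      ann <- data.frame(CHROM = chrom, POS = pos, REF = refs,
                        ALT = vapply(altList, function(a) as.character(a)[1], ""),
                        GENE = as.character(inf$GENE),
                        CONSEQUENCE = as.character(inf$CONSEQUENCE),
                        GNOMAD_MAX_AF = as.numeric(inf$GNOMAD_MAX_AF),
                        CADD_PHRED = as.numeric(inf$CADD_PHRED),
                        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ann)) {
    key <- paste(info$chrom, info$pos, info$ref, info$alt, sep = ":")
    akey <- paste(ann$CHROM, ann$POS, ann$REF, ann$ALT, sep = ":")
    idx <- match(key, akey)
    if (anyNA(idx))
      warning(sum(is.na(idx)), " variant record(s) missing from the ",
              "annotation table; annotations set to NA")
    info$gene <- ann$GENE[idx]
    info$consequence <- .normalizeConsequence(ann$CONSEQUENCE[idx])
    info$gnomad_max_af <- as.numeric(ann$GNOMAD_MAX_AF[idx])
    info$cadd_phred <- as.numeric(ann$CADD_PHRED[idx])
  }
  .sortVariants(AnnotatedVariants(info, genoM))
}

#' Write an AnnotatedVariants object as VCF text plus annotation TSV
#'
#' Emits a minimal VCF 4.2 file (GT-only FORMAT) and, optionally, the side
#' annotation TSV that [readAnnotatedVcf()] consumes.
#'
#' @param av an [AnnotatedVariants-class].
#' @param vcfPath output VCF path.
#' @param annotationPath optional output TSV path.
#' @return \code{vcfPath}, invisibly.
#' @export
writeAnnotatedVcf <- function(av, vcfPath, annotationPath = NULL) {
  info <- av@info
  g <- av@geno
  gtStr <- matrix(c(homref = "0/0", het = "0/1", homalt = "1/1",
                    missing = "./.")[g], nrow = nrow(g),
                  dimnames = dimnames(g))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=famcascade",
           paste0("##contig=<ID=", unique(info$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    body[i] <- paste(c(info$chrom[i], info$pos[i], ".", info$ref[i],
                       info$alt[i], ".", info$filter_status[i], ".", "GT",
                       gtStr[i, ]), collapse = "\t")
  }
  writeLines(c(hdr, body), vcfPath)
  if (!is.null(annotationPath)) {
    ann <- data.frame(CHROM = info$chrom, POS = info$pos, REF = info$ref,
                      ALT = info$alt, GENE = info$gene,
                      CONSEQUENCE = info$consequence,
                      GNOMAD_MAX_AF = info$gnomad_max_af,
                      CADD_PHRED = info$cadd_phred)
    utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(vcfPath)
}

#' Cohort allele statistics per variant
#'
#' Counts alt alleles over non-missing genotypes (het contributes 1, homalt
#' 2) and computes the cohort allele frequency and the genotyping rate. A
#' variant with all genotypes missing has an undefined (\code{NaN}) cohort
#' frequency and is treated downstream as failing every frequency filter, so
#' batch runs never abort on one bad site.
#'
#' @param av an [AnnotatedVariants-class].
#' @return data.frame with one row per variant: \code{alt_allele_count},
#'   \code{called_allele_count}, \code{cohort_af}, \code{genotyping_rate},
#'   \code{n_carriers}.
#' @examples
#' av <- AnnotatedVariants(
#'   data.frame(chrom = "1", pos = 100, ref = "A", alt = "G"),
#'   matrix(c("het", "homref", "homref", "homref", "homref"), 1,
#'          dimnames = list(NULL, paste0("S", 1:5))))
#' cohortStats(av) # cohort_af 0.1, genotyping_rate 1
#' @export
cohortStats <- function(av) {
  g <- av@geno
  if (ncol(g) == 0L) stop("cohortStats requires at least one sample")
  called <- g != "missing"
  altCopies <- (g == "het") + 2L * (g == "homalt")
  altCount <- rowSums(altCopies * called)
  calledAlleles <- 2L * rowSums(called)
  data.frame(
    alt_allele_count = as.integer(altCount),
    called_allele_count = as.integer(calledAlleles),
    cohort_af = altCount / calledAlleles,
    genotyping_rate = rowSums(called) / ncol(g),
    n_carriers = as.integer(rowSums((g == "het" | g == "homalt") & called)))
}

#' Marker quality filter
#'
#' Retains biallelic records genotyped in \emph{more than} \code{minRate} of
#' the samples (strict inequality) whose alt allele is carried by at least
#' \code{minCarriers} individuals. These are the marker-pruning rules applied
#' before IBD segment detection.
#'
#' @param av an [AnnotatedVariants-class].
#' @param minRate genotyping-rate threshold in \[0, 1\] (default 0.9).
#' @param minCarriers minimum number of carrier individuals (default 2).
#' @return the filtered [AnnotatedVariants-class].
#' @export
markerQcFilter <- function(av, minRate = 0.9, minCarriers = 2L) {
  stopifnot(minRate >= 0, minRate <= 1)
  if (length(av) == 0L) return(av)
  st <- cohortStats(av)
  av[st$genotyping_rate > minRate & st$n_carriers >= minCarriers]
}
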