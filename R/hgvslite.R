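# Coding-position codon arithmetic, substitution translation under the
# standard genetic code, and APOE epsilon-haplotype calling.

#' @importFrom Biostrings GENETIC_CODE
NULL

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

#' Map a CDS position to its codon
#'
#' A 1-based coding-sequence position c falls in codon \code{ceiling(c/3)}
#' at within-codon offset \code{c - 3*(codon-1)} (1 to 3). This is the
#' arithmetic linking an HGVS c. position to its p. residue number.
#'
#' @param cdsPos 1-based coding-sequence position(s).
#' @return data.frame with columns \code{codon_index} and
#'   \code{within_codon_pos}.
#' @examples
#' cdsToCodon(3215) # codon 1072, offset 2
#' @export
cdsToCodon <- function(cdsPos) {
  if (any(cdsPos < 1)) stop("cdsPos must be >= 1")
  codon <- ceiling(cdsPos / 3)
  data.frame(codon_index = as.integer(codon),
             within_codon_pos = as.integer(cdsPos - 3 * (codon - 1)))
}

#' Translate a single-base substitution
#'
#' Substitutes \code{altBase} at the given within-codon offset of
#' \code{refCodon} and translates both codons under the standard genetic
#' code. A stop gain is returned as \code{"*"}, not an error.
#'
#' @param refCodon reference codon (3 bases, A/C/G/T).
#' @param withinCodonPos offset 1 to 3.
#' @param altBase substituted base; must differ from the reference base at
#'   that offset.
#' @return list with \code{aa_ref}, \code{aa_alt} (one-letter) and
#'   \code{label} (three-letter, e.g. \code{"AlaVal"} style fragment).
#' @examples
#' translateSubstitution("GCC", 2, "T") # Ala -> Val
#' @export
translateSubstitution <- function(refCodon, withinCodonPos, altBase) {
  refCodon <- toupper(refCodon)
  altBase <- toupper(altBase)
  if (nchar(refCodon) != 3L || grepl("[^ACGT]", refCodon))
    stop("refCodon must be 3 bases of A/C/G/T")
  if (!withinCodonPos %in% 1:3) stop("withinCodonPos must be 1, 2 or 3")
  if (!altBase %in% c("A", "C", "G", "T")) stop("invalid altBase")
  refBase <- substr(refCodon, withinCodonPos, withinCodonPos)
  if (refBase == altBase)
    stop("reference and alternate base are identical at offset ",
         withinCodonPos)
  altCodon <- refCodon
  substr(altCodon, withinCodonPos, withinCodonPos) <- altBase
  aaRef <- unname(Biostrings::GENETIC_CODE[[refCodon]])
  aaAlt <- unname(Biostrings::GENETIC_CODE[[altCodon]])
  list(aa_ref = aaRef, aa_alt = aaAlt,
       label = paste0(.AA3[[aaRef]], .AA3[[aaAlt]]))
}

#' Describe a coding substitution
#'
#' Combines [cdsToCodon()] and, when the reference codon is known,
#' [translateSubstitution()] into an HGVS-like protein label.
#'
#' @param cdsPos 1-based CDS position.
#' @param refBase,altBase substitution bases.
#' @param refCodon optional reference codon.
#' @return list with \code{codon_index}, \code{within_codon_pos},
#'   \code{cds_label} and, when \code{refCodon} is given,
#'   \code{protein_label} like \code{"p.Ala1072Val"}.
#' @export
describeCodingChange <- function(cdsPos, refBase, altBase, refCodon = NULL) {
  cc <- cdsToCodon(cdsPos)
  out <- list(codon_index = cc$codon_index,
              within_codon_pos = cc$within_codon_pos,
              cds_label = paste0("c.", cdsPos, refBase, ">", altBase))
  if (!is.null(refCodon)) {
    tr <- translateSubstitution(refCodon, cc$within_codon_pos, altBase)
    out$protein_label <- paste0("p.", .AA3[[tr$aa_ref]], cc$codon_index,
                                .AA3[[tr$aa_alt]])
  }
  out
}

.EPS_FROM_HAP <- c("T|C" = "e3", "T|T" = "e2", "C|C" = "e4", "C|T" = "e1")

.parseGt <- function(gt, alleles, what) {
  if (is.character(gt) && length(gt) == 1L)
    gt <- strsplit(gt, "/", fixed = TRUE)[[1]]
  gt <- toupper(gt)
  if (length(gt) != 2L || !all(gt %in% alleles))
    stop("invalid ", what, " genotype; alleles must be among ",
         paste(alleles, collapse = "/"))
  gt
}

#' Call the APOE epsilon genotype from two SNPs
#'
#' Phases rs429358 (T>C) and rs7412 (C>T) genotypes into epsilon alleles:
#' on the (rs429358, rs7412) haplotype, (T,T) = e2, (T,C) = e3, (C,C) = e4
#' and (C,T) = e1. Whenever at most one SNP is heterozygous the phase is
#' determined and the call is exact. The double heterozygote is compatible
#' with both e2/e4 and e1/e3; it is resolved as e2/e4 with
#' \code{ambiguous = TRUE}, the universal convention given the extreme
#' rarity of e1.
#'
#' @param rs429358 genotype over \{T, C\}, as \code{"T/C"} or a length-2
#'   vector; allele order is irrelevant.
#' @param rs7412 genotype over \{C, T\}, same forms.
#' @return an [ApoeCall-class].
#' @examples
#' callApoe("T/T", "C/C") # e3/e3
#' callApoe("T/C", "C/C") # e3/e4
#' callApoe("T/C", "C/T") # e2/e4, ambiguous
#' @export
callApoe <- function(rs429358, rs7412) {
  g1 <- .parseGt(rs429358, c("T", "C"), "rs429358")
  g2 <- .parseGt(rs7412, c("C", "T"), "rs7412")
  het1 <- g1[1] != g1[2]
  het2 <- g2[1] != g2[2]
  if (het1 && het2) {
    eps <- c("e2", "e4")
    ambiguous <- TRUE
  } else {
    # at most one SNP heterozygous: haplotypes are determined
    a1 <- sort(g1, decreasing = TRUE) # put T first for stable pairing
    a2 <- sort(g2, decreasing = TRUE)
    if (!het1 && het2) a2 <- g2[order(g2 != "C")] # fixed SNP1: any pairing
    haps <- paste(a1, a2, sep = "|")
    eps <- sort(unname(.EPS_FROM_HAP[haps]))
    ambiguous <- FALSE
  }
  new("ApoeCall", rs429358 = g1, rs7412 = g2, epsilonPair = eps,
      ambiguous = ambiguous)
}

setMethod("show", "ApoeCall", function(object) {
  cat("ApoeCall: ", paste(object@epsilonPair, collapse = "/"),
      if (object@ambiguous) " (phase ambiguous, e1/e3 suppressed)" else "",
      "\n", sep = "")
})
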