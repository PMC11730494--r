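# Pedigree construction, PED I/O and nuclear-family peeling order.

# Detect whether any individual is its own ancestor; returns the offending
# path (child ... ancestor==child) or NULL. Used by the Pedigree validity
# method, so it must work on a raw individuals data.frame.
.findPedigreeCycle <- function(df) {
  parents <- stats::setNames(
    lapply(seq_len(nrow(df)), function(i) {
      p <- c(df$father[i], df$mother[i])
      p[!is.na(p)]
    }), df$iid)
  state <- stats::setNames(rep(0L, nrow(df)), df$iid) # 0 new, 1 open, 2 done
  path <- character()
  found <- NULL
  visit <- function(iid) {
    if (!is.null(found)) return(invisible())
    if (state[[iid]] == 1L) {
      found <<- c(path[seq(match(iid, path), length(path))], iid)
      return(invisible())
    }
    if (state[[iid]] == 2L) return(invisible())
    state[[iid]] <<- 1L
    path <<- c(path, iid)
    for (p in parents[[iid]]) visit(p)
    path <<- path[-length(path)]
    state[[iid]] <<- 2L
  }
  for (iid in df$iid) visit(iid)
  found
}

#' Construct a Pedigree
#'
#' @param individuals data.frame with columns \code{iid}, \code{father},
#'   \code{mother}, \code{sex}, \code{phenotype} (see
#'   [Pedigree-class]); \code{father}/\code{mother} are \code{NA} for
#'   founders.
#' @param name family identifier.
#' @return a validated [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(data.frame(
#'   iid = c("P1", "M1", "C1"),
#'   father = c(NA, NA, "P1"), mother = c(NA, NA, "M1"),
#'   sex = c("male", "female", "female"),
#'   phenotype = c("unaffected", "unaffected", "affected")))
#' founderIds(trio)
#' @export
Pedigree <- function(individuals, name = "FAM") {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  for (col in c("iid", "father", "mother", "sex", "phenotype"))
    if (col %in% names(individuals))
      individuals[[col]] <- as.character(individuals[[col]])
  rownames(individuals) <- NULL
  new("Pedigree", name = name, individuals = individuals)
}

#' @describeIn Pedigree number of individuals.
#' @param x,object a Pedigree.
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@individuals))

#' Pedigree accessors
#'
#' @param x a [Pedigree-class].
#' @return character vectors of individual ids (or, for
#'   \code{pedIndividuals}, the underlying data.frame).
#' @name pedigree-accessors
NULL

#' @rdname pedigree-accessors
#' @export
pedIndividuals <- function(x) x@individuals

#' @rdname pedigree-accessors
#' @export
pedName <- function(x) x@name

#' @rdname pedigree-accessors
#' @export
founderIds <- function(x) x@individuals$iid[is.na(x@individuals$father)]

#' @rdname pedigree-accessors
#' @export
nonfounderIds <- function(x) x@individuals$iid[!is.na(x@individuals$father)]

#' @rdname pedigree-accessors
#' @export
affectedIds <- function(x) x@individuals$iid[x@individuals$phenotype == "affected"]

#' @rdname pedigree-accessors
#' @export
unaffectedIds <- function(x) x@individuals$iid[x@individuals$phenotype == "unaffected"]

setMethod("show", "Pedigree", function(object) {
  df <- object@individuals
  cat("Pedigree '", object@name, "': ", nrow(df), " individuals (",
      sum(is.na(df$father)), " founders, ",
      sum(df$phenotype == "affected"), " affected)\n", sep = "")
})

.SEX_FROM_PED <- c("1" = "male", "2" = "female", "0" = "unknown")
.PHENO_FROM_PED <- c("1" = "unaffected", "2" = "affected",
                     "0" = "unknown", "-9" = "unknown")

#' Read a 6-column PED file
#'
#' Reads one family from a whitespace-delimited PLINK/Merlin PED file
#' (columns FID IID PAT MAT SEX PHENO; parent code \code{"0"} marks a
#' founder; sex 1 = male, 2 = female, 0 = unknown; phenotype 1 = unaffected,
#' 2 = affected, 0 or -9 = unknown). All pedigree invariants are checked on
#' construction: unknown parent ids, duplicate ids and ancestry cycles are
#' errors naming the offending individuals.
#'
#' @param path PED file path.
#' @return a [Pedigree-class].
#' @seealso [writePed()]
#' @export
readPed <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 6L)
    stop("PED file must have 6 whitespace-delimited columns, got ", ncol(tab))
  tab <- tab[, 1:6]
  names(tab) <- c("fid", "iid", "father", "mother", "sex", "pheno")
  fids <- unique(tab$fid)
  if (length(fids) > 1L)
    stop("PED file contains more than one family: ", paste(fids, collapse = ", "))
  sex <- .SEX_FROM_PED[tab$sex]
  if (anyNA(sex)) stop("invalid sex code(s): ",
    paste(unique(tab$sex[is.na(sex)]), collapse = ", "))
  pheno <- .PHENO_FROM_PED[tab$pheno]
  if (anyNA(pheno)) stop("invalid phenotype code(s): ",
    paste(unique(tab$pheno[is.na(pheno)]), collapse = ", "))
  Pedigree(data.frame(
    iid = tab$iid,
    father = ifelse(tab$father == "0", NA_character_, tab$father),
    mother = ifelse(tab$mother == "0", NA_character_, tab$mother),
    sex = unname(sex), phenotype = unname(pheno)), name = fids)
}

#' Write a Pedigree as a 6-column PED file
#'
#' Inverse of [readPed()]; unknown sex and phenotype are written as 0.
#'
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePed <- function(ped, path) {
  df <- ped@individuals
  sex <- c(male = "1", female = "2", unknown = "0")[df$sex]
  pheno <- c(unaffected = "1", affected = "2", unknown = "0")[df$phenotype]
  lines <- paste(ped@name, df$iid,
                 ifelse(is.na(df$father), "0", df$father),
                 ifelse(is.na(df$mother), "0", df$mother),
                 sex, pheno)
  writeLines(lines, path)
  invisible(path)
}

# Nuclear families of a pedigree: one entry per parent couple, with the
# couple's children. Deterministic order (father then mother id).
.nuclearFamilies <- function(ped) {
  df <- ped@individuals
  kids <- df[!is.na(df$father), , drop = FALSE]
  if (nrow(kids) == 0L) return(list())
  key <- paste(kids$father, kids$mother, sep = "\r")
  fams <- lapply(split(seq_len(nrow(kids)), key), function(i)
    list(father = kids$father[i[1]], mother = kids$mother[i[1]],
         children = sort(kids$iid[i])))
  ord <- order(vapply(fams, `[[`, "", "father"),
               vapply(fams, `[[`, "", "mother"))
  unname(fams[ord])
}

#' Peeling order of nuclear families
#'
#' Decomposes a loop-free pedigree into its nuclear families and orders them
#' so that eliminating each family in turn, folding its information onto the
#' single \emph{pivot} individual it shares with the not-yet-eliminated
#' remainder, reduces the pedigree to a single individual. This is the
#' elimination schedule Elston-Stewart peeling follows. The order is
#' deterministic: among simultaneously peelable families the one with the
#' lexicographically smallest (father, mother) founder pair goes first.
#'
#' Pedigrees with marriage or inbreeding loops have no such schedule and are
#' rejected with an unsupported-structure error rather than approximated.
#'
#' @param ped a [Pedigree-class].
#' @return list of nuclear-family units, each a list with elements
#'   \code{father}, \code{mother}, \code{children} and \code{pivot} (the
#'   shared individual, or \code{NA} for the final family).
#' @export
peelingOrder <- function(ped) {
  fams <- .nuclearFamilies(ped)
  if (length(fams) == 0L) return(list())
  df <- ped@individuals
  depth <- stats::setNames(rep(0L, nrow(df)), df$iid)
  repeat {
    d <- ifelse(is.na(df$father), 0L,
                pmax(depth[df$father], depth[df$mother]) + 1L)
    if (all(d == depth)) break
    depth <- stats::setNames(as.integer(d), df$iid)
  }
  famDepth <- vapply(fams, function(f) max(depth[f$children]), 0L)
  members <- lapply(fams, function(f) c(f$father, f$mother, f$children))
  remaining <- rep(TRUE, length(fams))
  out <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    cand <- integer()
    pivots <- character()
    for (i in which(remaining)) {
      others <- unlist(members[setdiff(which(remaining), i)])
      shared <- intersect(members[[i]], others)
      if (length(shared) <= 1L) {
        cand <- c(cand, i)
        pivots <- c(pivots, if (length(shared)) shared else NA_character_)
      }
    }
    if (length(cand) == 0L)
      stop("unsupported pedigree structure: marriage/inbreeding loop ",
           "prevents nuclear-family peeling")
    # deepest (leaf-most) family first; ties already lexicographic by the
    # (father, mother) ordering of .nuclearFamilies
    j <- which.max(famDepth[cand])
    fam <- fams[[cand[j]]]
    fam$pivot <- pivots[j]
    out[[k]] <- fam
    remaining[cand[j]] <- FALSE
  }
  out
}
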