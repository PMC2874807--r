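#' Build a Pedigree from its columns
#'
#' @param famId,id,fatherId,motherId character vectors (recycled
#'   \code{famId} allowed); \code{"0"} marks a missing parent.
#' @param sex integer or character codes (1 = male, 2 = female, 0 =
#'   unknown).
#' @param phenotype preserved verbatim; defaults to \code{"0"}.
#' @return a validated \code{\linkS4class{Pedigree}}.
#' @examples
#' Pedigree(famId = "1", id = c("f", "m", "c"),
#'          fatherId = c("0", "0", "f"), motherId = c("0", "0", "m"),
#'          sex = c(1, 2, 1))
#' @export
Pedigree <- function(famId, id, fatherId, motherId, sex = 0L,
                     phenotype = "0") {
  n <- length(id)
  famId <- rep_len(as.character(famId), n)
  id <- as.character(id)
  fatherId <- as.character(fatherId)
  motherId <- as.character(motherId)
  sex <- rep_len(as.integer(sex), n)
  sex[is.na(sex) | !sex %in% 0:2] <- 0L
  phenotype <- rep_len(as.character(phenotype), n)
  father <- match(fatherId, id, nomatch = 0L)
  mother <- match(motherId, id, nomatch = 0L)
  father[fatherId == "0"] <- 0L
  mother[motherId == "0"] <- 0L
  new("Pedigree", famId = famId, id = id, fatherId = fatherId,
      motherId = motherId, sex = sex, phenotype = phenotype,
      father = father, mother = mother)
}

#' Read a linkage-format pedfile
#'
#' Expects a whitespace-delimited file with at least six columns: family
#' id, individual id, father id, mother id, sex and phenotype; \code{"0"}
#' denotes a missing parent.  Structural problems (duplicate ids, a
#' reference to an absent parent, cyclic parentage) are errors naming the
#' offending individual; consanguinity loops are allowed.
#'
#' @param path path to the pedfile.
#' @return a \code{\linkS4class{Pedigree}}.
#' @seealso \code{\link{writePedfile}}
#' @export
readPedfile <- function(path) {
  if (!file.exists(path)) stop("pedfile not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 6L) {
    stop("pedfile must have >= 6 columns (fam id father mother sex pheno)")
  }
  Pedigree(famId = tab[[1L]], id = tab[[2L]], fatherId = tab[[3L]],
           motherId = tab[[4L]], sex = suppressWarnings(as.integer(tab[[5L]])),
           phenotype = tab[[6L]])
}

#' Write a linkage-format pedfile
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @param path output path.
#' @export
writePedfile <- function(pedigree, path) {
  tab <- cbind(pedigree@famId, pedigree@id, pedigree@fatherId,
               pedigree@motherId, pedigree@sex, pedigree@phenotype)
  writeLines(apply(tab, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' @describeIn Pedigree number of individuals
#' @param object,pedigree a \code{Pedigree}.
#' @export
nIndividuals <- function(pedigree) length(pedigree@id)

#' @describeIn Pedigree individual ids in pedfile order
#' @export
individualIds <- function(pedigree) pedigree@id

#' @describeIn Pedigree ids of individuals without parents in the pedigree
#' @export
founders <- function(pedigree) {
  pedigree@id[pedigree@father == 0L & pedigree@mother == 0L]
}

.idx <- function(pedigree, id) {
  i <- match(id, pedigree@id)
  if (anyNA(i)) stop("unknown individual id: ", id[which(is.na(i))[1L]])
  i
}

#' @describeIn Pedigree ids of the parents of \code{id} (father first)
#' @param id an individual id.
#' @export
parentsOf <- function(pedigree, id) {
  i <- .idx(pedigree, id)
  pedigree@id[c(pedigree@father[i], pedigree@mother[i])[
    c(pedigree@father[i], pedigree@mother[i]) > 0L]]
}

#' @describeIn Pedigree ids of the children of \code{id}, pedfile order
#' @export
childrenOf <- function(pedigree, id) {
  i <- .idx(pedigree, id)
  pedigree@id[pedigree@father == i | pedigree@mother == i]
}

#' @describeIn Pedigree ids of full siblings (sharing both parents)
#' @export
fullSiblingsOf <- function(pedigree, id) {
  i <- .idx(pedigree, id)
  if (pedigree@father[i] == 0L) return(character())
  sib <- pedigree@father == pedigree@father[i] &
    pedigree@mother == pedigree@mother[i]
  sib[i] <- FALSE
  pedigree@id[sib]
}

#' @describeIn Pedigree ids of co-parents of at least one child of \code{id}
#' @export
spousesOf <- function(pedigree, id) {
  i <- .idx(pedigree, id)
  ch <- pedigree@father == i | pedigree@mother == i
  other <- ifelse(pedigree@father[ch] == i, pedigree@mother[ch],
                  pedigree@father[ch])
  unique(pedigree@id[other[other > 0L]])
}

#' @export
setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "individuals in",
      length(unique(object@famId)), "family(ies);",
      sum(object@father == 0L), "founders\n")
})

# index structures consumed by the C++ engine: 1-based parent indices
# (0 = absent) plus CSR adjacency for children and full siblings
.pedIndices <- function(pedigree) {
  n <- length(pedigree@id)
  fa <- pedigree@father
  mo <- pedigree@mother
  kids <- lapply(seq_len(n), function(i) which(fa == i | mo == i))
  key <- paste(fa, mo)
  sibs <- lapply(seq_len(n), function(i) {
    if (fa[i] == 0L) return(integer())
    s <- which(key == key[i])
    s[s != i]
  })
  list(father = fa, mother = mo,
       child_ptr = c(0L, cumsum(lengths(kids))),
       child_idx = as.integer(unlist(kids)),
       sib_ptr = c(0L, cumsum(lengths(sibs))),
       sib_idx = as.integer(unlist(sibs)))
}

# nuclear families: distinct co-parent pairs with their common children
.nuclearFamilies <- function(pedigree) {
  fa <- pedigree@father
  mo <- pedigree@mother
  has <- which(fa > 0L)
  if (!length(has)) {
    return(list(father = integer(), mother = integer(),
                child_ptr = 0L, child_idx = integer()))
  }
  key <- paste(fa[has], mo[has])
  grp <- split(has, factor(key, levels = unique(key)))
  fam_fa <- vapply(grp, function(ix) fa[ix[1L]], integer(1L))
  fam_mo <- vapply(grp, function(ix) mo[ix[1L]], integer(1L))
  list(father = as.integer(fam_fa), mother = as.integer(fam_mo),
       child_ptr = c(0L, cumsum(lengths(grp))),
       child_idx = as.integer(unlist(grp)))
}
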