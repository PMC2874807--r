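#' Mendelian consistency of a parent-offspring trio
#'
#' A child's partitioned CN genotype is consistent when its two alleles
#' can be split so that one comes from each parent's allele pair.
#' Sentinel genotypes (\code{"-1,-1"}, \code{"-2,-2"} or \code{NA}) act as
#' wildcards and are compatible with anything.
#'
#' @param father,mother,child CN genotype strings.
#' @return logical.
#' @examples
#' consistentTrio("A1,B1", "A2,B2", "A1,A2")   # TRUE
#' consistentTrio("A1,A1", "A1,A1", "A2,N")    # FALSE
#' @export
consistentTrio <- function(father, mother, child) {
  enc <- function(g) {
    if (is.na(g)) return(NULL)
    e <- .encodeCN(g)
    if (is.na(e$g1)) stop("malformed CN genotype: ", g)
    if (e$g1 < 0L) return(NULL)
    c(e$g1, e$g2)
  }
  f <- enc(father)
  m <- enc(mother)
  ch <- enc(child)
  if (is.null(ch) || (is.null(f) && is.null(m))) return(TRUE)
  fromPair <- function(x, p) is.null(p) || x %in% p
  (fromPair(ch[1L], f) && fromPair(ch[2L], m)) ||
    (fromPair(ch[2L], f) && fromPair(ch[1L], m))
}

#' Check every nuclear family of a pedigree for Mendelian consistency
#'
#' For each marker and each nuclear family (a co-parent pair with their
#' common children), joint consistency is tested: there must exist an
#' assignment of one transmitted allele per parent per child compatible
#' with all non-sentinel genotypes simultaneously.  Parents with sentinel
#' genotypes are treated as unknown, in which case a genotype is searched
#' for them over the alleles observed in the children; this makes the
#' check strictly stronger than trio-wise checking when several children
#' constrain an unknown parent jointly.
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"};
#'   individuals absent from the matrix are treated as unknown.
#' @param maxTotalCopies optional cap on the total copy number of the
#'   genotypes searched for unknown parents; the default (\code{Inf})
#'   allows any pairing of observed alleles, matching the genotype
#'   universe of gene-dropped data, where offspring of copy-capped
#'   founders may total up to twice the founder cap.
#' @return a \code{\linkS4class{ConsistencyReport}}.
#' @export
checkPedigree <- function(pedigree, x, maxTotalCopies = Inf) {
  maxTotal <- if (is.finite(maxTotalCopies)) as.integer(maxTotalCopies) else 0L
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "cn")
  .checkSamples(x, pedigree)
  ids <- pedigree@id
  markers <- rownames(x@calls)
  cells <- matrix("-1,-1", nrow = length(markers), ncol = length(ids),
                  dimnames = list(markers, ids))
  present <- intersect(ids, colnames(x@calls))
  cells[, present] <- x@calls[, present]
  enc <- .encodeCN(as.vector(cells))
  g1 <- t(matrix(enc$g1, nrow = length(markers)))
  g2 <- t(matrix(enc$g2, nrow = length(markers)))
  fams <- .nuclearFamilies(pedigree)
  if (!length(fams$father)) {
    return(new("ConsistencyReport",
               failures = data.frame(marker = character(),
                                     famId = character(),
                                     father = character(),
                                     mother = character(),
                                     members = character(),
                                     stringsAsFactors = FALSE),
               markerFailed = stats::setNames(logical(length(markers)),
                                              markers)))
  }
  fail <- .cpp_check_batch(g1, g2, fams$father, fams$mother,
                           fams$child_ptr, fams$child_idx, maxTotal)
  hit <- which(fail, arr.ind = TRUE)
  members <- vapply(seq_along(fams$father), function(f) {
    kids <- fams$child_idx[(fams$child_ptr[f] + 1L):fams$child_ptr[f + 1L]]
    paste(ids[c(fams$father[f], fams$mother[f], kids)], collapse = ",")
  }, character(1L))
  failures <- data.frame(marker = markers[hit[, 2L]],
                         famId = pedigree@famId[fams$father[hit[, 1L]]],
                         father = ids[fams$father[hit[, 1L]]],
                         mother = ids[fams$mother[hit[, 1L]]],
                         members = members[hit[, 1L]],
                         stringsAsFactors = FALSE)
  failures <- failures[order(match(failures$marker, markers)), ,
                       drop = FALSE]
  rownames(failures) <- NULL
  new("ConsistencyReport", failures = failures,
      markerFailed = stats::setNames(colSums(fail) > 0L, markers))
}

#' Blank the members of inconsistent nuclear families
#'
#' Sets every member of each flagged nuclear family to the undefined
#' genotype \code{"-1,-1"} at the flagged marker, mirroring the common
#' practice of setting inconsistent transmissions to missing before
#' linkage analysis.  Idempotent; unflagged cells are untouched.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}.
#' @param report a \code{\linkS4class{ConsistencyReport}} from
#'   \code{\link{checkPedigree}}.
#' @return the blanked \code{GenotypeMatrix}.
#' @export
blankFailingFamilies <- function(x, report) {
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "cn")
  cells <- x@calls
  fl <- report@failures
  for (r in seq_len(nrow(fl))) {
    members <- intersect(strsplit(fl$members[r], ",", fixed = TRUE)[[1L]],
                         colnames(cells))
    cells[fl$marker[r], members] <- "-1,-1"
  }
  GenotypeMatrix(cells, kind = "cn")
}

#' @export
setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport:", nrow(object@failures),
      "failing (marker, family) pairs over", length(object@markerFailed),
      "markers\n")
  if (nrow(object@failures)) {
    print(utils::head(object@failures, 10L))
  }
})
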