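#' Construct a GenotypeMatrix
#'
#' @param calls character matrix (markers in rows, samples in columns)
#'   with row and column names; cells are \code{"a,b"} integrated calls or
#'   serialized CN genotypes depending on \code{kind}.
#' @param kind \code{"fawkes"} or \code{"cn"}.
#' @param pedigree optional \code{\linkS4class{Pedigree}}; when given,
#'   every sample id must resolve to a pedigree member.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
GenotypeMatrix <- function(calls, kind = c("fawkes", "cn"), pedigree = NULL) {
  kind <- match.arg(kind)
  obj <- new("GenotypeMatrix", calls = calls, kind = kind)
  .validateCells(obj)
  if (!is.null(pedigree)) .checkSamples(obj, pedigree)
  obj
}

.validateCells <- function(object) {
  x <- object@calls
  if (object@kind == "fawkes") {
    parsed <- .parseFawkesCells(as.vector(x))
    bad <- is.na(parsed$a)
  } else {
    bad <- is.na(.encodeCN(as.vector(x))$g1)
  }
  if (any(bad)) {
    w <- which(bad)[1L]
    i <- (w - 1L) %% nrow(x) + 1L
    j <- (w - 1L) %/% nrow(x) + 1L
    stop("malformed ", object@kind, " cell '", x[i, j], "' at marker ",
         rownames(x)[i], ", sample ", colnames(x)[j])
  }
  invisible(object)
}

.checkSamples <- function(object, pedigree) {
  missing <- setdiff(colnames(object@calls), pedigree@id)
  if (length(missing)) {
    stop("sample id(s) not in pedigree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  invisible(object)
}

#' @describeIn GenotypeMatrix marker ids (row order)
#' @param x a \code{GenotypeMatrix}.
#' @export
markerIds <- function(x) rownames(x@calls)

#' @describeIn GenotypeMatrix sample ids (column order)
#' @export
sampleIds <- function(x) colnames(x@calls)

#' @describeIn GenotypeMatrix the underlying character matrix of calls
#' @export
genotypeCalls <- function(x) x@calls

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix (", object@kind, "): ", nrow(object@calls),
      " markers x ", ncol(object@calls), " samples\n", sep = "")
})

.readMatrixFile <- function(path, kind, pedigree, annotationCols) {
  if (!file.exists(path)) stop("genotype matrix file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nfld <- length(header)
  if (nfld < 2L + annotationCols) stop("header has no sample columns")
  body <- fields[-1L]
  ragged <- lengths(body) != nfld
  if (any(ragged)) {
    stop("ragged row at line ", which(ragged)[1L] + 1L, " of ", path,
         " (expected ", nfld, " fields, found ",
         lengths(body)[which(ragged)[1L]], ")")
  }
  keep <- -(seq_len(1L + annotationCols))
  samples <- header[keep]
  markers <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, keep)),
                  nrow = length(body), byrow = TRUE,
                  dimnames = list(markers, samples))
  GenotypeMatrix(cells, kind = kind, pedigree = pedigree)
}

#' Read a tab-delimited integrated-call matrix
#'
#' The first row is a header holding sample ids; the first column holds
#' marker (probe-set) ids; every remaining cell is a comma-separated
#' \code{"a,b"} call, with \code{"-1,-1"} for undefined calls.  A
#' malformed cell is an error reporting its marker and sample.
#'
#' @param path input path.
#' @param pedigree optional \code{\linkS4class{Pedigree}} to check sample
#'   ids against.
#' @param annotationCols number of extra annotation columns between the
#'   marker id and the first sample column (skipped).
#' @return a \code{\linkS4class{GenotypeMatrix}} of kind \code{"fawkes"}.
#' @export
readFawkesMatrix <- function(path, pedigree = NULL, annotationCols = 0L) {
  .readMatrixFile(path, "fawkes", pedigree, as.integer(annotationCols))
}

#' Read a partitioned CN genotype matrix
#'
#' @inheritParams readFawkesMatrix
#' @return a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}.
#' @export
readCNMatrix <- function(path, pedigree = NULL, annotationCols = 0L) {
  .readMatrixFile(path, "cn", pedigree, as.integer(annotationCols))
}

#' Write a genotype matrix
#'
#' Writes the tab-delimited dialect read by \code{\link{readFawkesMatrix}}
#' and \code{\link{readCNMatrix}}: a header row of sample ids preceded by
#' a marker-id column.  CN cells are written in canonical serialization;
#' sentinels appear as \code{"-1,-1"} and \code{"-2,-2"}.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param path output path.
#' @param idColumn name of the marker-id header field.
#' @export
writeCNMatrix <- function(x, path, idColumn = "probeset_id") {
  calls <- x@calls
  if (x@kind == "cn") {
    enc <- .encodeCN(as.vector(calls))
    calls <- matrix(.decodeCN(enc$g1, enc$g2), nrow = nrow(calls),
                    dimnames = dimnames(calls))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(calls)), collapse = "\t"), con)
  writeLines(paste(rownames(calls),
                   apply(calls, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Recode partitioned CN genotypes as multi-allelic linkage markers
#'
#' For every marker the distinct observed CN alleles are mapped to the
#' integer codes 1..k used by linkage software, in deterministic order: A
#' alleles by ascending count, then B alleles by ascending count, then N.
#' Undefined and unresolved genotypes become the missing genotype
#' \code{"0 0"}.  The result is a pre-makeped linkage ped table (family,
#' individual, father, mother, sex, phenotype, then two allele columns per
#' marker) plus an allele-map sidecar.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}.
#' @param pedigree the \code{\linkS4class{Pedigree}} the samples belong
#'   to; individuals absent from the matrix are coded as missing.
#' @return list with \code{ped} (data.frame, one row per individual) and
#'   \code{alleleMap} (data.frame with columns \code{marker},
#'   \code{allele}, \code{code}).
#' @seealso \code{\link{decodeMultiallelic}}, \code{\link{writeRecoded}}
#' @export
recodeToMultiallelic <- function(x, pedigree) {
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "cn")
  .checkSamples(x, pedigree)
  calls <- x@calls
  markers <- rownames(calls)
  n <- length(pedigree@id)
  enc <- .encodeCN(as.vector(calls))
  g1 <- matrix(enc$g1, nrow = nrow(calls))
  g2 <- matrix(enc$g2, nrow = nrow(calls))
  col <- match(pedigree@id, colnames(calls))      # NA -> not in matrix
  maps <- vector("list", length(markers))
  geno <- matrix("0 0", nrow = n, ncol = length(markers))
  for (m in seq_along(markers)) {
    a1 <- g1[m, col]
    a2 <- g2[m, col]
    obs <- sort(unique(c(a1, a2)))
    obs <- obs[!is.na(obs) & obs >= 0L]           # codes sort A < B < N
    codeOf <- function(v) match(v, obs)
    ok <- !is.na(a1) & a1 >= 0L
    geno[ok, m] <- paste(codeOf(a1[ok]), codeOf(a2[ok]))
    if (length(obs)) {
      maps[[m]] <- data.frame(marker = markers[m],
                              allele = .alleleString(obs),
                              code = seq_along(obs),
                              stringsAsFactors = FALSE)
    }
  }
  colnames(geno) <- markers
  ped <- data.frame(famId = pedigree@famId, id = pedigree@id,
                    fatherId = pedigree@fatherId,
                    motherId = pedigree@motherId, sex = pedigree@sex,
                    phenotype = pedigree@phenotype,
                    geno, check.names = FALSE, stringsAsFactors = FALSE)
  list(ped = ped, alleleMap = do.call(rbind, maps[!vapply(maps, is.null,
                                                          logical(1L))]))
}

#' Write recoded linkage files
#'
#' Writes the pre-makeped ped file and the tab-delimited allele-map
#' sidecar produced by \code{\link{recodeToMultiallelic}}.
#'
#' @param recoded result of \code{\link{recodeToMultiallelic}}.
#' @param prefix output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.allelemap}.
#' @return the two paths, invisibly.
#' @export
writeRecoded <- function(recoded, prefix) {
  pedPath <- paste0(prefix, ".ped")
  mapPath <- paste0(prefix, ".allelemap")
  utils::write.table(recoded$ped, pedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(recoded$alleleMap, mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(pedPath, mapPath))
}

#' Decode multi-allelic linkage genotypes back to CN genotypes
#'
#' Inverts \code{\link{recodeToMultiallelic}} using the allele-map
#' sidecar; missing genotypes (\code{"0 0"}) decode to \code{"-1,-1"}.
#'
#' @param recoded result of \code{\link{recodeToMultiallelic}}.
#' @return a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"} with
#'   one column per individual of the recoded ped table.
#' @export
decodeMultiallelic <- function(recoded) {
  ped <- recoded$ped
  map <- recoded$alleleMap
  markers <- colnames(ped)[-(1:6)]
  out <- matrix("-1,-1", nrow = length(markers), ncol = nrow(ped),
                dimnames = list(markers, ped$id))
  for (m in markers) {
    mm <- map[map$marker == m, ]
    codes <- strsplit(ped[[m]], " ", fixed = TRUE)
    c1 <- vapply(codes, `[[`, character(1L), 1L)
    c2 <- vapply(codes, `[[`, character(1L), 2L)
    ok <- c1 != "0"
    if (any(ok)) {
      al1 <- mm$allele[match(as.integer(c1[ok]), mm$code)]
      al2 <- mm$allele[match(as.integer(c2[ok]), mm$code)]
      out[m, ok] <- serializeCN(cbind(al1, al2))
    }
  }
  GenotypeMatrix(out, kind = "cn")
}
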