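#' Classify integrated copy-number calls
#'
#' An integrated (Fawkes-style) call is a pair \code{[a, b]} giving the
#' number of copies of SNP allele A and allele B summed over both
#' chromosomes.  Five mutually exclusive classes exist: the undefined call
#' \code{[-1,-1]}, heterozygous calls (both counts non-zero), the null call
#' \code{[0,0]}, single hemizygous calls (one copy of one allele), and
#' homozygous calls (two or more copies of a single allele).
#'
#' @param a,b integer vectors of allele copy counts; the undefined call is
#'   exactly \code{c(-1, -1)}.
#' @return a factor with levels \code{undefined}, \code{heterozygous},
#'   \code{null}, \code{hemizygous}, \code{homozygous}.
#' @examples
#' classifyFawkes(c(-1, 1, 0, 1, 3), c(-1, 2, 0, 0, 0))
#' @export
classifyFawkes <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  bad <- is.na(a) | is.na(b) |
    !((a >= 0L & b >= 0L) | (a == -1L & b == -1L))
  if (any(bad)) {
    stop("malformed call [", a[which(bad)[1L]], ",", b[which(bad)[1L]],
         "]: negative counts other than the undefined call [-1,-1]")
  }
  cls <- character(length(a))
  cls[a == -1L] <- "undefined"
  cls[a > 0L & b > 0L] <- "heterozygous"
  cls[a == 0L & b == 0L] <- "null"
  cls[a + b == 1L & a >= 0L & b >= 0L] <- "hemizygous"
  cls[(a == 0L & b > 1L) | (b == 0L & a > 1L)] <- "homozygous"
  factor(cls, levels = c("undefined", "heterozygous", "null",
                         "hemizygous", "homozygous"))
}

#' Direct conversion of non-homozygous calls
#'
#' First pass of the partitioning algorithm: undefined calls stay
#' undefined, the null call becomes \code{"N,N"}, single hemizygous calls
#' place the single copy on one chromosome and a null allele on the other,
#' and heterozygous calls put all copies of each allele on its own
#' chromosome.  Homozygous calls cannot be partitioned directly and are
#' returned as \code{NA} (they are deferred to the family-based rules).
#'
#' @inheritParams classifyFawkes
#' @return character vector of canonical CN genotype strings with \code{NA}
#'   for homozygous (not directly convertible) calls.
#' @examples
#' step1Direct(c(2, 0, 1, 4), c(1, 0, 0, 0))
#' @export
step1Direct <- function(a, b) {
  cls <- classifyFawkes(a, b)
  a <- as.integer(a)
  b <- as.integer(b)
  out <- rep(NA_character_, length(a))
  out[cls == "undefined"] <- "-1,-1"
  out[cls == "null"] <- "N,N"
  hemi <- cls == "hemizygous"
  out[hemi & a == 1L] <- "A1,N"
  out[hemi & b == 1L] <- "B1,N"
  het <- cls == "heterozygous"
  out[het] <- paste0("A", a[het], ",B", b[het])
  out
}

#' Collapse partitioned CN genotypes back to integrated calls
#'
#' Sums the copies of allele A and of allele B over the two chromosomes of
#' a partitioned CN genotype, e.g. \code{"A1,A2"} collapses to
#' \code{[3, 0]} and \code{"B2,N"} to \code{[0, 2]}.
#'
#' @param g character vector of CN genotype strings; sentinel genotypes
#'   (\code{"-1,-1"}, \code{"-2,-2"}) are an error.
#' @return integer matrix with columns \code{a} and \code{b}.
#' @examples
#' cnToFawkes(c("A1,A2", "N,N", "B2,N"))
#' @export
cnToFawkes <- function(g) {
  enc <- .encodeCN(g)
  if (anyNA(enc$g1)) {
    stop("malformed CN genotype: ", g[which(is.na(enc$g1))[1L]])
  }
  if (any(enc$g1 < 0L)) {
    stop("sentinel CN genotype cannot be collapsed: ",
         g[which(enc$g1 < 0L)[1L]])
  }
  fw <- .codeToFawkes(enc$g1, enc$g2)
  cbind(a = fw$a, b = fw$b)
}

#' Parse and serialize CN genotype strings
#'
#' A CN genotype is written as two comma-separated allele tokens, each
#' either a typed copy count (\code{"A2"}, \code{"B1"}) or the null allele
#' \code{"N"}; the sentinels are \code{"-1,-1"} (undefined) and
#' \code{"-2,-2"} (unresolved).  \code{parseCN} accepts alleles in any
#' order and returns them in canonical order (A alleles by ascending
#' count, then B alleles, then N); \code{serializeCN} renders the
#' canonical string, so \code{serializeCN(parseCN(x))} is the canonical
#' form of \code{x}.
#'
#' @param x character vector of genotype strings.
#' @param alleles two-column character matrix of allele tokens as returned
#'   by \code{parseCN} (sentinel rows use \code{"-1"} or \code{"-2"}).
#' @return \code{parseCN}: a two-column character matrix of allele tokens
#'   in canonical order; \code{serializeCN}: a character vector.
#' @examples
#' parseCN("B2,A1")
#' serializeCN(parseCN("B2,A1"))
#' @export
parseCN <- function(x) {
  enc <- .encodeCN(x)
  if (anyNA(enc$g1)) {
    stop("malformed CN genotype: ", x[which(is.na(enc$g1))[1L]])
  }
  a1 <- ifelse(enc$g1 < 0L, as.character(enc$g1), .alleleString(enc$g1))
  a2 <- ifelse(enc$g2 < 0L, as.character(enc$g2), .alleleString(enc$g2))
  cbind(allele1 = a1, allele2 = a2)
}

#' @rdname parseCN
#' @export
serializeCN <- function(alleles) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, ncol = 2L)
  sent <- alleles[, 1L] %in% c("-1", "-2")
  c1 <- .alleleCode(ifelse(sent, "N", alleles[, 1L]))
  c2 <- .alleleCode(ifelse(sent, "N", alleles[, 2L]))
  if (anyNA(c1) || anyNA(c2)) {
    bad <- which(is.na(c1) | is.na(c2))[1L]
    stop("malformed allele token in genotype ",
         paste(alleles[bad, ], collapse = ","))
  }
  out <- .decodeCN(pmin(c1, c2), pmax(c1, c2))
  out[sent] <- paste0(alleles[sent, 1L], ",", alleles[sent, 1L])
  out
}
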