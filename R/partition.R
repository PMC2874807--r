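# Context assembly shared by tryType1()/tryType2(): builds the index
# structures and genotype-code arrays for a synthetic family around one
# index individual.
.ruleContext <- function(fawkes, parents, children, spouses, siblings) {
  if (is.character(fawkes) && length(fawkes) == 1L) {
    pf <- .parseFawkesCells(fawkes)
    if (is.na(pf$a)) stop("malformed call: ", fawkes)
    fawkes <- c(pf$a, pf$b)
  }
  a <- as.integer(fawkes[1L])
  b <- as.integer(fawkes[2L])
  if (classifyFawkes(a, b) != "homozygous") {
    stop("index call [", a, ",", b, "] is not homozygous")
  }
  np <- length(parents)
  nc <- length(children)
  ns <- length(siblings)
  if (np > 2L) stop("at most two parents")
  if (length(spouses) && length(spouses) != nc) {
    stop("'spouses' must parallel 'children'")
  }
  # layout: index, parents, children, spouse-per-child, siblings, and two
  # synthetic grandparents tying the index to its siblings
  gp <- if (ns) 2L else 0L
  n <- 1L + np + nc + nc + ns + gp
  geno <- c(NA, parents, children,
            if (nc) (if (length(spouses)) spouses else rep(NA, nc)),
            siblings, if (gp) rep(NA, gp))
  i_par <- if (np) 2L:(1L + np) else integer()
  i_ch <- if (nc) (1L + np) + seq_len(nc) else integer()
  i_sp <- if (nc) (1L + np + nc) + seq_len(nc) else integer()
  i_sib <- if (ns) (1L + np + 2L * nc) + seq_len(ns) else integer()
  i_gp <- if (gp) (n - 1L):n else integer()
  father <- mother <- integer(n)
  # the index's parents: explicit ones win, otherwise synthetic ones so
  # that provided siblings share both parents with the index
  fam <- c(i_par, i_gp)
  if (length(fam) >= 1L) father[c(1L, i_sib)] <- fam[1L]
  if (length(fam) >= 2L) mother[c(1L, i_sib)] <- fam[2L]
  father[i_ch] <- 1L
  mother[i_ch] <- i_sp
  kids <- lapply(seq_len(n), function(i) which(father == i | mother == i))
  key <- paste(father, mother)
  sibs <- lapply(seq_len(n), function(i) {
    if (father[i] == 0L) return(integer())
    s <- which(key == key[i])
    s[s != i]
  })
  enc <- .encodeCN(as.character(geno))
  status <- integer(n)
  status[is.na(geno) | (!is.na(enc$g1) & enc$g1 == -1L)] <- 2L
  status[!is.na(enc$g1) & enc$g1 == -2L] <- 3L
  valid <- !is.na(geno) & !is.na(enc$g1) & enc$g1 >= 0L
  status[valid] <- 1L
  bad <- !is.na(geno) & is.na(enc$g1)
  if (any(bad)) stop("malformed CN genotype: ", geno[which(bad)[1L]])
  enc$g1[is.na(enc$g1) | enc$g1 < 0L] <- -1L
  enc$g2[is.na(enc$g2) | enc$g2 < 0L] <- -1L
  status[1L] <- 0L
  list(a = a, b = b,
       idx = list(father = father, mother = mother,
                  child_ptr = c(0L, cumsum(lengths(kids))),
                  child_idx = as.integer(unlist(kids)),
                  sib_ptr = c(0L, cumsum(lengths(sibs))),
                  sib_idx = as.integer(unlist(sibs))),
       g1 = as.integer(enc$g1), g2 = as.integer(enc$g2),
       status = status)
}

.ruleNames <- c("step1", "2a", "2b", "2c", "3a", "3b", "3c", "3d",
                "3e", "3f", "3g", "3h")

.ruleResult <- function(res) {
  if (res$code == 1L) {
    list(genotype = .decodeCN(res$g1, res$g2),
         rule = .ruleNames[res$rule + 1L], inconsistent = FALSE)
  } else if (res$code == 2L) {
    list(genotype = "-2,-2", rule = .ruleNames[res$rule + 1L],
         inconsistent = TRUE)
  } else {
    list(genotype = NA_character_, rule = NA_character_,
         inconsistent = FALSE)
  }
}

#' Resolve a homozygous call from heterozygous first-degree relatives
#'
#' Attempts the three heterozygous-relative rules in their fixed priority:
#' a heterozygous parent, then a heterozygous child, then a pair of full
#' siblings with distinct heterozygous CN genotypes whose same-type allele
#' counts differ and sum to the index total.  The relative's same-type
#' allele count m gives the index genotype \{Tm, T(tot-m)\}, the second
#' allele becoming N when the remainder is zero; a negative remainder is a
#' Mendelian inconsistency and yields the unresolved sentinel.
#'
#' @param fawkes the index call, as \code{"a,b"} or an integer pair; must
#'   be homozygous.
#' @param parents,children,siblings CN genotype strings of the relatives
#'   (pedfile order); \code{NA} or \code{"-1,-1"} marks an unknown
#'   genotype, which is skipped.
#' @param strict when TRUE, all candidates of the winning rule are
#'   cross-checked and a conflict is flagged as an inconsistency.
#' @return list with \code{genotype} (canonical CN string, \code{"-2,-2"}
#'   on inconsistency, or \code{NA} when not converted), \code{rule}, and
#'   \code{inconsistent}.
#' @examples
#' tryType1("3,0", parents = "A1,B2")          # -> A1,A2 via the parent
#' tryType1("3,0", siblings = c("A1,B1", "A2,B1"))
#' @export
tryType1 <- function(fawkes, parents = character(), children = character(),
                     siblings = character(), strict = FALSE) {
  ctx <- .ruleContext(fawkes, parents, children, NULL, siblings)
  .ruleResult(.cpp_try_rules(1L, ctx$a, ctx$b, ctx$idx, ctx$g1, ctx$g2,
                             ctx$status, 1L, strict))
}

#' Resolve a homozygous call from homozygous relatives
#'
#' Attempts the eight sequential nuclear-family rules for calls that no
#' heterozygous first-degree relative could resolve: a parent (3a) or
#' child (3b) with two identical CN alleles of the index type or
#' \code{"N,N"}; a heterozygous sibling paired with a sibling homozygous
#' for the opposite allele type (3c); a child and co-parent spouse sharing
#' exactly one allele (3d); two homozygous parents with distinct
#' genotypes, resolved through the four transmission sums (3e); two
#' homozygous parents with identical genotypes (3f); a single parent
#' carrying the index allele type when the total matches its minimum typed
#' count (3g); and a parent of the form \{opposite-type allele, N\}, whose
#' N is transmitted (3h).  The first applicable rule wins.
#'
#' @inheritParams tryType1
#' @param spouses CN genotypes of each child's other parent, parallel to
#'   \code{children} (used by rule 3d); \code{NA} for unknown.
#' @return as \code{\link{tryType1}}.
#' @examples
#' tryType2("5,0", parents = c("A1,A2", "A3,A5"))  # 3e, unique sum
#' tryType2("2,0", parents = c("B1,N", "A1,A2"))   # 3h, N transmitted
#' @export
tryType2 <- function(fawkes, parents = character(), children = character(),
                     spouses = NULL, siblings = character(),
                     strict = FALSE) {
  ctx <- .ruleContext(fawkes, parents, children, spouses, siblings)
  .ruleResult(.cpp_try_rules(2L, ctx$a, ctx$b, ctx$idx, ctx$g1, ctx$g2,
                             ctx$status, 1L, strict))
}

# core batch call: a, b are nInd x nMarkers integer matrices in pedigree
# row order; returns engine output plus tallies
.partitionCodes <- function(pedidx, a, b, strict = FALSE) {
  .cpp_partition_batch(a, b, pedidx, strict)
}

.makeReport <- function(markers, res, nInd) {
  rc <- res$ruleCounts
  cc <- res$classCounts
  rownames(rc) <- .ruleNames
  rownames(cc) <- c("undefined", "heterozygous", "null", "hemizygous",
                    "homozygous")
  unres <- colSums(res$g1 == -2L)
  perMarker <- data.frame(marker = markers, t(cc), t(rc),
                          converted = colSums(rc),
                          unresolved = as.integer(unres),
                          inconsistencies = res$inconsistencies,
                          passes = res$passes,
                          check.names = FALSE, stringsAsFactors = FALSE)
  new("ConversionReport",
      nCells = as.integer(nInd * length(markers)),
      classCounts = as.integer(rowSums(cc)) |>
        stats::setNames(rownames(cc)),
      ruleCounts = as.integer(rowSums(rc)) |> stats::setNames(.ruleNames),
      nUnresolved = as.integer(sum(unres)),
      nInconsistencies = as.integer(sum(res$inconsistencies)),
      perMarker = perMarker)
}

#' Partition one marker over a pedigree
#'
#' Runs the full per-marker procedure: direct conversion of undefined,
#' heterozygous, null and hemizygous calls; one pass of the heterozygous-
#' relative rules over homozygotes in pedfile order; then repeated passes
#' of the homozygous-relative rules while at least one call is converted
#' per pass.  At the fixpoint all remaining homozygotes and all
#' inconsistency-flagged calls become the unresolved sentinel
#' \code{"-2,-2"}.
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @param calls named character vector of \code{"a,b"} calls; names are
#'   individual ids.  Members absent from \code{calls} are treated as
#'   undefined.
#' @param strict see \code{\link{tryType1}}.
#' @return list with \code{genotypes} (named character vector of CN
#'   genotype strings) and \code{report} (one-row data.frame of tallies).
#' @export
partitionMarker <- function(pedigree, calls, strict = FALSE) {
  ids <- pedigree@id
  x <- rep("-1,-1", length(ids))
  names(x) <- ids
  if (is.null(names(calls))) {
    if (length(calls) != length(ids)) {
      stop("unnamed 'calls' must cover the whole pedigree")
    }
    x[] <- calls
  } else {
    unknown <- setdiff(names(calls), ids)
    if (length(unknown)) stop("calls for unknown individual: ", unknown[1L])
    x[names(calls)] <- calls
  }
  pf <- .parseFawkesCells(x)
  if (anyNA(pf$a)) {
    stop("malformed call '", x[which(is.na(pf$a))[1L]], "' for individual ",
         ids[which(is.na(pf$a))[1L]])
  }
  pf$a[pf$a == -2L] <- -1L          # unresolved input behaves as undefined
  pf$b[pf$b == -2L] <- -1L
  res <- .partitionCodes(.pedIndices(pedigree),
                         matrix(pf$a, ncol = 1L), matrix(pf$b, ncol = 1L),
                         strict)
  genotypes <- .decodeCN(res$g1[, 1L], res$g2[, 1L])
  names(genotypes) <- ids
  rep1 <- .makeReport("marker", res, length(ids))
  list(genotypes = genotypes, report = rep1@perMarker)
}

#' Partition every marker of an integrated-call matrix
#'
#' Applies \code{\link{partitionMarker}} row-wise and aggregates the
#' conversion statistics.  The output matrix has the shape and sample
#' order of the input, with cells in canonical CN serialization and the
#' sentinels \code{"-1,-1"} (undefined input) and \code{"-2,-2"}
#' (unresolved or obligate Mendelian inconsistency).
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind
#'   \code{"fawkes"}; all sample ids must be pedigree members, and
#'   members absent from the matrix are treated as undefined.
#' @param strict see \code{\link{tryType1}}.
#' @param logFile optional path; when given, a per-marker and global
#'   summary block is written there.
#' @return list with \code{matrix} (a CN \code{GenotypeMatrix} over all
#'   pedigree members) and \code{report} (a
#'   \code{\linkS4class{ConversionReport}}).
#' @export
partitionAll <- function(pedigree, x, strict = FALSE, logFile = NULL) {
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "fawkes")
  .checkSamples(x, pedigree)
  ids <- pedigree@id
  markers <- rownames(x@calls)
  cells <- matrix("-1,-1", nrow = length(markers), ncol = length(ids),
                  dimnames = list(markers, ids))
  present <- intersect(ids, colnames(x@calls))
  cells[, present] <- x@calls[, present]
  pf <- .parseFawkesCells(as.vector(cells))
  pf$a[pf$a == -2L] <- -1L
  pf$b[pf$b == -2L] <- -1L
  a <- matrix(pf$a, nrow = length(markers))
  b <- matrix(pf$b, nrow = length(markers))
  res <- .partitionCodes(.pedIndices(pedigree), t(a), t(b), strict)
  out <- matrix(.decodeCN(as.vector(res$g1), as.vector(res$g2)),
                nrow = length(ids))
  out <- t(out)
  dimnames(out) <- list(markers, ids)
  report <- .makeReport(markers, res, length(ids))
  if (!is.null(logFile)) writeConversionLog(report, logFile)
  list(matrix = GenotypeMatrix(out, kind = "cn"), report = report)
}

#' Write the conversion log
#'
#' One summary line per marker followed by the global summary block that
#' \code{show} prints for a \code{\linkS4class{ConversionReport}}.
#'
#' @param report a \code{\linkS4class{ConversionReport}}.
#' @param path output path.
#' @export
writeConversionLog <- function(report, path) {
  pm <- report@perMarker
  lines <- sprintf(paste0("marker %s: undefined=%d heterozygous=%d ",
                          "null=%d hemizygous=%d homozygous=%d ",
                          "converted=%d unresolved=%d inconsistencies=%d"),
                   pm$marker, pm$undefined, pm$heterozygous, pm$null,
                   pm$hemizygous, pm$homozygous, pm$converted,
                   pm$unresolved, pm$inconsistencies)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  writeLines(utils::capture.output(show(report)), con)
  invisible(path)
}

#' @export
setMethod("show", "ConversionReport", function(object) {
  n <- object@nCells
  pct <- function(x) sprintf("%.2f%%", 100 * x / max(n, 1L))
  cat("Partitioning summary over", n, "calls\n")
  cc <- object@classCounts
  for (k in names(cc)) cat(sprintf("  %-13s %9d  %s\n", k, cc[[k]], pct(cc[[k]])))
  conv <- sum(object@ruleCounts)
  cat(sprintf("  %-13s %9d  %s\n", "converted", conv, pct(conv)))
  cat("  by rule:", paste(sprintf("%s=%d", names(object@ruleCounts),
                                  object@ruleCounts), collapse = " "), "\n")
  cat(sprintf("  %-13s %9d  %s\n", "unresolved", object@nUnresolved,
              pct(object@nUnresolved)))
  cat("  Mendelian inconsistencies:", object@nInconsistencies, "\n")
})
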