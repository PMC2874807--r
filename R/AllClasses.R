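#' @import methods
NULL

#' Pedigree of one or more families
#'
#' Holds the rows of a linkage-format pedfile (family id, individual id,
#' father id, mother id, sex, phenotype) together with resolved parent
#' indices.  Individual ids must be globally unique; parents are either
#' both present or both absent (founders); parent references must resolve
#' within the same family and parentage must be acyclic.  Consanguinity
#' loops (mating between relatives) are permitted.
#'
#' @slot famId,id,fatherId,motherId character vectors, one entry per
#'   individual; \code{"0"} denotes a missing parent.
#' @slot sex integer, 1 = male, 2 = female, 0 = unknown (read but never
#'   used by the partitioning rules).
#' @slot phenotype character, preserved verbatim.
#' @slot father,mother integer indices into the pedigree (0 = founder).
#' @export
setClass("Pedigree",
  representation(famId = "character", id = "character",
                 fatherId = "character", motherId = "character",
                 sex = "integer", phenotype = "character",
                 father = "integer", mother = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  lens <- c(length(object@famId), length(object@fatherId),
            length(object@motherId), length(object@sex),
            length(object@phenotype), length(object@father),
            length(object@mother))
  if (any(lens != n)) return("slot lengths differ")
  if (anyDuplicated(object@id)) {
    return(paste0("duplicate individual id: ",
                  object@id[anyDuplicated(object@id)]))
  }
  miss <- (object@fatherId == "0") != (object@motherId == "0")
  if (any(miss)) {
    return(paste0("individual ", object@id[which(miss)[1L]],
                  " has exactly one parent; founders must have none"))
  }
  for (sl in c("father", "mother")) {
    idx <- slot(object, sl)
    ids <- slot(object, paste0(sl, "Id"))
    bad <- ids != "0" & (idx < 1L | idx > n | is.na(idx))
    if (any(bad)) {
      return(paste0("individual ", object@id[which(bad)[1L]],
                    " references absent ", sl, " '", ids[which(bad)[1L]], "'"))
    }
    samefam <- idx == 0L | object@famId[pmax(idx, 1L)] == object@famId
    if (!all(samefam)) {
      return(paste0("individual ", object@id[which(!samefam)[1L]],
                    " references a parent in a different family"))
    }
  }
  # acyclicity via repeated stripping of parentless individuals
  remaining <- rep(TRUE, n)
  repeat {
    free <- remaining &
      (object@father == 0L | !remaining[pmax(object@father, 1L)]) &
      (object@mother == 0L | !remaining[pmax(object@mother, 1L)])
    if (!any(free)) break
    remaining[free] <- FALSE
  }
  if (any(remaining)) {
    return(paste0("cyclic parentage involving individual ",
                  object@id[which(remaining)[1L]]))
  }
  TRUE
})

#' Marker-by-sample genotype matrix
#'
#' A rectangular matrix of genotype calls with markers in rows and samples
#' in columns, either integrated (Fawkes-style) \code{"a,b"} calls
#' (\code{kind = "fawkes"}) or partitioned CN genotypes (\code{kind =
#' "cn"}).  Cells are stored in their serialized text dialect.
#'
#' @slot calls character matrix with marker ids as row names and sample
#'   ids as column names.
#' @slot kind \code{"fawkes"} or \code{"cn"}.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", kind = "character"))

setValidity("GenotypeMatrix", function(object) {
  if (!is.character(object@calls)) return("calls must be a character matrix")
  if (length(object@kind) != 1L || !object@kind %in% c("fawkes", "cn")) {
    return("kind must be \"fawkes\" or \"cn\"")
  }
  dn <- dimnames(object@calls)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]])) {
    return("calls must have marker row names and sample column names")
  }
  if (anyDuplicated(dn[[1L]])) return("duplicate marker ids")
  if (anyDuplicated(dn[[2L]])) return("duplicate sample ids")
  TRUE
})

#' Summary of a partitioning run
#'
#' Tallies accumulated by \code{\link{partitionAll}}: input calls by
#' class, conversions by rule (direct conversion, the three heterozygous-
#' relative rules, the eight homozygous-relative rules), unresolved calls
#' and Mendelian inconsistencies, plus per-marker rows.
#'
#' @slot nCells total number of cells processed.
#' @slot classCounts named integer, input call classes.
#' @slot ruleCounts named integer, successful conversions per rule.
#' @slot nUnresolved number of cells set to \code{"-2,-2"}.
#' @slot nInconsistencies Mendelian inconsistencies flagged by the rules.
#' @slot perMarker data.frame with one row per marker.
#' @export
setClass("ConversionReport",
  representation(nCells = "integer", classCounts = "integer",
                 ruleCounts = "integer", nUnresolved = "integer",
                 nInconsistencies = "integer", perMarker = "data.frame"))

#' Nuclear-family Mendelian consistency report
#'
#' One row per (marker, nuclear family) combination failing the joint
#' transmission check of \code{\link{checkPedigree}}.
#'
#' @slot failures data.frame with columns \code{marker}, \code{famId},
#'   \code{father}, \code{mother}, \code{members} (comma-separated ids of
#'   the family members).
#' @slot markerFailed named logical, per-marker pass/fail.
#' @export
setClass("ConsistencyReport",
  representation(failures = "data.frame", markerFailed = "logical"))

#' Configuration of a gene-dropping validation experiment
#'
#' @slot proportions named numeric of founder state probabilities in the
#'   order null, hemizygous, heterozygous, homozygous; normalized to sum
#'   to one before sampling.
#' @slot maxTotalCopies maximum total copy number a genotype may carry.
#' @slot maskRate fraction of cells recoded as undefined after the truth
#'   is archived.
#' @slot errorMode when TRUE, one genotype per run is substituted and the
#'   consistency checker is applied after partitioning.
#' @slot seed,nRuns integer.
#' @slot pedigree the \code{\linkS4class{Pedigree}} simulated over.
#' @export
setClass("SimulationConfig",
  representation(proportions = "numeric", maxTotalCopies = "integer",
                 maskRate = "numeric", errorMode = "logical",
                 seed = "integer", nRuns = "integer", pedigree = "Pedigree"))

setValidity("SimulationConfig", function(object) {
  p <- object@proportions
  if (length(p) != 4L || any(p < 0) || sum(p) <= 0) {
    return("proportions must be 4 non-negative values with a positive sum")
  }
  if (object@maskRate < 0 || object@maskRate >= 1) {
    return("maskRate must be in [0, 1)")
  }
  if (object@maxTotalCopies < 2L) return("maxTotalCopies must be >= 2")
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  TRUE
})

#' Result of a gene-dropping validation experiment
#'
#' Accuracy tallies of \code{\link{runValidation}}: each run simulates one
#' marker on the configured pedigree, collapses the truth to integrated
#' calls, partitions them back and scores the result against the archived
#' truth.  In error mode one genotype per run is substituted beforehand
#' and the detection channels (rule-level inconsistency flags, an
#' unresolved output at the substituted individual, a nuclear family
#' flagged by the consistency checker) are tallied.
#'
#' @slot runs,nIndividuals integer.
#' @slot errorMode logical.
#' @slot conversionsAttempted,conversionsSucceeded,mismatches numeric
#'   call-level tallies (mismatches compare non-sentinel outputs with the
#'   archived truth).
#' @slot ruleCounts named numeric, conversions per rule over all runs.
#' @slot inconsistencies total Mendelian inconsistencies flagged.
#' @slot detectedFrac fraction of runs in which the injected error was
#'   detected by any channel (error mode).
#' @slot checkerDetectedFrac fraction of runs with at least one family
#'   flagged by the consistency checker.
#' @slot unresolvedAtSubstitutedFrac fraction of runs with an unresolved
#'   output at the substituted individual.
#' @slot wrongAssignmentFrac fraction of runs with a wrong non-sentinel
#'   output at the substituted individual or a first-degree relative.
#' @slot engineUndefinedCallFrac,checkerUndefinedCallFrac fraction of all
#'   calls left undefined by the engine and additionally blanked by the
#'   checker.
#' @slot injectedErrorCallRate injected errors per call (error mode).
#' @export
setClass("ValidationReport",
  representation(runs = "integer", nIndividuals = "integer",
                 errorMode = "logical",
                 conversionsAttempted = "numeric",
                 conversionsSucceeded = "numeric",
                 mismatches = "numeric",
                 ruleCounts = "numeric",
                 inconsistencies = "numeric",
                 detectedFrac = "numeric",
                 checkerDetectedFrac = "numeric",
                 unresolvedAtSubstitutedFrac = "numeric",
                 wrongAssignmentFrac = "numeric",
                 engineUndefinedCallFrac = "numeric",
                 checkerUndefinedCallFrac = "numeric",
                 injectedErrorCallRate = "numeric"))
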