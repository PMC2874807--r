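# ---- genotype sets per founder state ------------------------------------

# All CN genotypes a founder in a given state may carry, as canonical code
# pairs.  The sets are the uniform-within-state model that reproduces the
# simulated allele-frequency table: null {N,N}; hemizygous one single
# copy; heterozygous {Am,Bn} with m,n >= 1 and m+n <= max; homozygous
# {Tm,Tn} with m >= n >= 1, m+n <= max, plus {Tt,N} for t = 2..max.
.stateGenotypeCodes <- function(state, maxTotalCopies = 5L) {
  mx <- as.integer(maxTotalCopies)
  if (mx < 2L) stop("maxTotalCopies must be >= 2")
  A <- function(m) as.integer(m)
  B <- function(n) 1000L + as.integer(n)
  pair <- function(x, y) cbind(pmin(x, y), pmax(x, y))
  switch(state,
    null = pair(.NCODE, .NCODE),
    hemizygous = rbind(pair(A(1L), .NCODE), pair(B(1L), .NCODE)),
    heterozygous = {
      mn <- expand.grid(m = seq_len(mx - 1L), n = seq_len(mx - 1L))
      mn <- mn[mn$m + mn$n <= mx, ]
      mn <- mn[order(mn$m, mn$n), ]
      pair(A(mn$m), B(mn$n))
    },
    homozygous = {
      mn <- expand.grid(m = seq_len(mx - 1L), n = seq_len(mx - 1L))
      mn <- mn[mn$m >= mn$n & mn$m + mn$n <= mx, ]
      mn <- mn[order(mn$m, mn$n), ]
      do.call(rbind, list(pair(A(mn$m), A(mn$n)),
                          pair(A(2:mx), rep(.NCODE, mx - 1L)),
                          pair(B(mn$m), B(mn$n)),
                          pair(B(2:mx), rep(.NCODE, mx - 1L))))
    },
    stop("unknown founder state: ", state))
}

#' Enumerate the CN genotypes of a founder state
#'
#' The four founder states and their genotype sets (with total copies
#' capped at \code{maxTotalCopies}): \code{null} has only \code{"N,N"};
#' \code{hemizygous} one single copy of either allele; \code{heterozygous}
#' every \{Am,Bn\} with both counts positive; \code{homozygous} every
#' same-type pair \{Tm,Tn\} plus the single-chromosome forms \{Tt,N\}
#' with t of at least 2.
#'
#' @param state one of \code{"null"}, \code{"hemizygous"},
#'   \code{"heterozygous"}, \code{"homozygous"}.
#' @param maxTotalCopies cap on total copy number (>= 2).
#' @return character vector of canonical CN genotype strings.
#' @examples
#' enumerateStateGenotypes("heterozygous")   # 10 genotypes at the cap of 5
#' @export
enumerateStateGenotypes <- function(state = c("null", "hemizygous",
                                              "heterozygous", "homozygous"),
                                    maxTotalCopies = 5L) {
  state <- match.arg(state)
  g <- .stateGenotypeCodes(state, maxTotalCopies)
  .decodeCN(g[, 1L], g[, 2L])
}

.stateNames <- c("null", "hemizygous", "heterozygous", "homozygous")

# concatenated state tables for fast uniform-within-state sampling
.founderTables <- function(maxTotalCopies) {
  tabs <- lapply(.stateNames, .stateGenotypeCodes, maxTotalCopies)
  sizes <- vapply(tabs, nrow, integer(1L))
  all <- do.call(rbind, tabs)
  list(g1 = all[, 1L], g2 = all[, 2L], sizes = sizes,
       offset = c(0L, cumsum(sizes))[1:4])
}

# n founder genotypes: state by proportions, genotype uniform in state
.sampleFounderCodes <- function(n, prop, tables) {
  state <- sample.int(4L, n, replace = TRUE, prob = prop)
  row <- ceiling(stats::runif(n) * tables$sizes[state])
  row[row < 1L] <- 1L
  at <- tables$offset[state] + row
  list(g1 = tables$g1[at], g2 = tables$g2[at])
}

# ---- configuration -------------------------------------------------------

#' Configure a gene-dropping validation experiment
#'
#' Defaults reproduce the validation design: founder states drawn with
#' proportions 0.0337\%, 2.14\%, 26.9\% and 70.9\% for the null,
#' hemizygous, heterozygous and homozygous states, total copies capped at
#' 5, and 1\% of genotypes masked as undefined (10\% in error mode, where
#' additionally one genotype per run is substituted).
#'
#' @param nRuns number of runs; each run simulates one marker.
#' @param seed integer seed used by \code{\link{runValidation}}.
#' @param errorMode logical; substitute one genotype per run and apply
#'   the consistency checker after partitioning.
#' @param maskRate fraction of genotypes recoded as undefined; defaults
#'   to 0.01, or 0.1 in error mode.
#' @param proportions founder state probabilities in the order null,
#'   hemizygous, heterozygous, homozygous (normalized internally).
#' @param maxTotalCopies cap on total copy number.
#' @param pedigree the pedigree simulated over; defaults to the 47-member
#'   validation pedigree.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(nRuns = 1000L, seed = 1L, errorMode = FALSE,
                             maskRate = if (errorMode) 0.1 else 0.01,
                             proportions = c(null = 0.000337,
                                             hemizygous = 0.0214,
                                             heterozygous = 0.269,
                                             homozygous = 0.709),
                             maxTotalCopies = 5L,
                             pedigree = makeValidationPedigree()) {
  new("SimulationConfig", proportions = proportions,
      maxTotalCopies = as.integer(maxTotalCopies),
      maskRate = maskRate, errorMode = errorMode,
      seed = as.integer(seed), nRuns = as.integer(nRuns),
      pedigree = pedigree)
}

#' Sample founder CN genotypes
#'
#' Draws a founder state with the configured proportions and a genotype
#' uniformly within the state's genotype set.  Uses the current RNG
#' state.
#'
#' @param n number of genotypes to draw.
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return character vector of canonical CN genotype strings.
#' @export
sampleFounders <- function(n, config = simulationConfig()) {
  tabs <- .founderTables(config@maxTotalCopies)
  g <- .sampleFounderCodes(n, config@proportions / sum(config@proportions),
                           tabs)
  .decodeCN(g$g1, g$g2)
}

# ---- gene dropping -------------------------------------------------------

.topoOrder <- function(pedigree) {
  n <- length(pedigree@id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  while (length(ord) < n) {
    free <- !placed &
      (pedigree@father == 0L | placed[pmax(pedigree@father, 1L)]) &
      (pedigree@mother == 0L | placed[pmax(pedigree@mother, 1L)])
    if (!any(free)) stop("pedigree is not acyclic")
    ord <- c(ord, which(free))
    placed[free] <- TRUE
  }
  ord
}

# founder genotypes fg1/fg2 are nFounder x nMarker code matrices in the
# row order of founders(pedigree); one uniform allele per parent per child
.geneDropCodes <- function(pedigree, fg1, fg2) {
  n <- length(pedigree@id)
  m <- ncol(fg1)
  g1 <- matrix(0L, n, m)
  g2 <- matrix(0L, n, m)
  frow <- which(pedigree@father == 0L)
  g1[frow, ] <- fg1
  g2[frow, ] <- fg2
  for (i in .topoOrder(pedigree)) {
    fa <- pedigree@father[i]
    if (fa == 0L) next
    mo <- pedigree@mother[i]
    af <- ifelse(stats::runif(m) < 0.5, g1[fa, ], g2[fa, ])
    am <- ifelse(stats::runif(m) < 0.5, g1[mo, ], g2[mo, ])
    g1[i, ] <- pmin(af, am)
    g2[i, ] <- pmax(af, am)
  }
  list(g1 = g1, g2 = g2)
}

#' Drop founder genotypes through a pedigree
#'
#' Assigns CN genotypes to every non-founder by Mendelian segregation:
#' one allele chosen uniformly from each parent's pair, parents always
#' resolved before their children (so consanguinity loops are handled by
#' construction).  Uses the current RNG state.
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @param founderGenotypes canonical CN genotype strings for all
#'   founders: a named character vector (one marker) or a character
#'   matrix with markers in rows and founder ids as column names.
#' @return a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"} over
#'   all pedigree members (the simulated truth).
#' @export
geneDrop <- function(pedigree, founderGenotypes) {
  fid <- founders(pedigree)
  if (is.null(dim(founderGenotypes))) {
    founderGenotypes <- matrix(founderGenotypes, nrow = 1L,
                               dimnames = list("m1",
                                               names(founderGenotypes)))
  }
  if (!setequal(colnames(founderGenotypes), fid)) {
    stop("founderGenotypes must cover exactly the founders")
  }
  enc <- .encodeCN(as.vector(founderGenotypes[, fid, drop = FALSE]))
  if (anyNA(enc$g1) || any(enc$g1 < 0L)) {
    stop("founder genotypes must be valid non-sentinel CN genotypes")
  }
  m <- nrow(founderGenotypes)
  g <- .geneDropCodes(pedigree,
                      t(matrix(enc$g1, nrow = m)), t(matrix(enc$g2, nrow = m)))
  out <- t(matrix(.decodeCN(as.vector(g$g1), as.vector(g$g2)),
                  nrow = length(pedigree@id)))
  dimnames(out) <- list(rownames(founderGenotypes), pedigree@id)
  GenotypeMatrix(out, kind = "cn")
}

#' Mask genotypes as undefined
#'
#' Recodes a random fraction of cells as the undefined genotype, as done
#' to emulate unresolved calls.  Uses the current RNG state.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param rate fraction of cells to mask, in [0, 1).
#' @return the masked \code{GenotypeMatrix}.
#' @export
maskUndefined <- function(x, rate) {
  stopifnot(rate >= 0, rate < 1)
  cells <- x@calls
  hit <- stats::runif(length(cells)) < rate
  cells[hit] <- "-1,-1"
  initialize(x, calls = cells)
}

#' Collapse a CN genotype matrix to integrated calls
#'
#' Cell-wise application of \code{\link{cnToFawkes}}; sentinel genotypes
#' pass through unchanged.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}.
#' @return a \code{\linkS4class{GenotypeMatrix}} of kind \code{"fawkes"}.
#' @export
collapseToFawkes <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "cn")
  enc <- .encodeCN(as.vector(x@calls))
  fw <- .codeToFawkes(enc$g1, enc$g2)
  out <- paste0(fw$a, ",", fw$b)
  sent <- enc$g1 < 0L
  out[sent] <- x@calls[sent]
  GenotypeMatrix(matrix(out, nrow = nrow(x@calls),
                        dimnames = dimnames(x@calls)), kind = "fawkes")
}

#' Substitute one genotype per marker with a random different one
#'
#' Emulates a genotyping error: for every marker one pedigree member is
#' chosen uniformly and its CN genotype replaced by a draw from the
#' founder sampling law conditioned on differing from the original.
#' Uses the current RNG state.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}
#'   (the simulated truth, before masking).
#' @param config a \code{\linkS4class{SimulationConfig}} providing the
#'   state proportions and copy cap of the replacement draw.
#' @return list with \code{matrix} (modified \code{GenotypeMatrix}) and
#'   \code{info} (data.frame with columns \code{marker},
#'   \code{individual}, \code{old}, \code{new}).
#' @export
injectError <- function(x, config = simulationConfig()) {
  cells <- x@calls
  m <- nrow(cells)
  n <- ncol(cells)
  ind <- sample.int(n, m, replace = TRUE)
  old <- cells[cbind(seq_len(m), ind)]
  tabs <- .founderTables(config@maxTotalCopies)
  prop <- config@proportions / sum(config@proportions)
  new <- old
  todo <- seq_len(m)
  while (length(todo)) {
    g <- .sampleFounderCodes(length(todo), prop, tabs)
    new[todo] <- .decodeCN(g$g1, g$g2)
    todo <- todo[new[todo] == old[todo]]
  }
  cells[cbind(seq_len(m), ind)] <- new
  list(matrix = initialize(x, calls = cells),
       info = data.frame(marker = rownames(cells),
                         individual = colnames(cells)[ind],
                         old = old, new = new, stringsAsFactors = FALSE))
}

# ---- the validation pedigree --------------------------------------------

#' The 47-member validation pedigree
#'
#' A deterministic multi-generational pedigree with 47 individuals, 14
#' founders and one consanguinity loop (individuals 30 and 34, first
#' cousins through the founder couple 1 x 2, mate and have two children).
#' Four founder couples head sibships of 5, 4, 3 and 3; six spouses marry
#' in; seven grandchildren sibships follow.  It emulates the stated
#' characteristics of the complex pedigree used for validation, whose
#' exact topology is not public.
#'
#' @return a \code{\linkS4class{Pedigree}} (family id \code{"1"}, ids
#'   \code{"1"}..\code{"47"}).
#' @export
makeValidationPedigree <- function() {
  # id, father, mother, sex
  def <- matrix(c(
    1, 0, 0, 1,   2, 0, 0, 2,   3, 0, 0, 1,   4, 0, 0, 2,
    5, 0, 0, 1,   6, 0, 0, 2,   7, 0, 0, 1,   8, 0, 0, 2,
    9, 0, 0, 2,  10, 0, 0, 2,  11, 0, 0, 2,  12, 0, 0, 2,
    13, 0, 0, 2, 14, 0, 0, 2,
    15, 1, 2, 1, 16, 1, 2, 1, 17, 1, 2, 2, 18, 1, 2, 1, 19, 1, 2, 2,
    20, 3, 4, 1, 21, 3, 4, 2, 22, 3, 4, 1, 23, 3, 4, 2,
    24, 5, 6, 1, 25, 5, 6, 1, 26, 5, 6, 2,
    27, 7, 8, 1, 28, 7, 8, 1, 29, 7, 8, 2,
    30, 15, 9, 1, 31, 15, 9, 2, 32, 15, 9, 1, 33, 15, 9, 2,
    34, 16, 21, 2, 35, 16, 21, 1, 36, 16, 21, 2,
    37, 20, 10, 1, 38, 20, 10, 2, 39, 20, 10, 1,
    40, 24, 11, 2, 41, 24, 11, 1,
    42, 27, 12, 1, 43, 27, 12, 2,
    44, 25, 13, 1, 45, 28, 14, 2,
    46, 30, 34, 1, 47, 30, 34, 2), ncol = 4L, byrow = TRUE)
  Pedigree(famId = "1", id = as.character(def[, 1L]),
           fatherId = as.character(def[, 2L]),
           motherId = as.character(def[, 3L]),
           sex = def[, 4L], phenotype = "0")
}

# ---- analytic allele frequencies ----------------------------------------

#' Expected allele frequencies of the founder sampling law
#'
#' Exact enumeration over the per-state genotype sets: the probability
#' that a uniformly chosen chromosome slot of a sampled genotype carries a
#' given allele, optionally thinned by the masking rate (a masked
#' genotype contributes the pseudo-allele \code{"-1"} on both slots).
#' Gene dropping preserves these frequencies in expectation, so they
#' apply to founders and non-founders alike.
#'
#' @param proportions founder state probabilities (null, hemizygous,
#'   heterozygous, homozygous); normalized internally.
#' @param maxTotalCopies cap on total copy number.
#' @param maskRate masking rate applied after sampling.
#' @return named numeric over \code{A1..Amax}, \code{B1..Bmax}, \code{N}
#'   and \code{-1}, summing to one.
#' @export
expectedAlleleFrequencies <- function(proportions = c(null = 0.000337,
                                                      hemizygous = 0.0214,
                                                      heterozygous = 0.269,
                                                      homozygous = 0.709),
                                      maxTotalCopies = 5L,
                                      maskRate = 0) {
  prop <- proportions / sum(proportions)
  mx <- as.integer(maxTotalCopies)
  labels <- c(paste0("A", seq_len(mx)), paste0("B", seq_len(mx)), "N", "-1")
  freq <- stats::setNames(numeric(length(labels)), labels)
  for (s in seq_along(.stateNames)) {
    g <- .stateGenotypeCodes(.stateNames[s], mx)
    w <- prop[s] / (2 * nrow(g))
    for (code in c(g[, 1L], g[, 2L])) {
      freq[.alleleString(code)] <- freq[.alleleString(code)] + w
    }
  }
  freq <- freq * (1 - maskRate)
  freq["-1"] <- maskRate
  freq
}

# fast allele tabulation of code matrices
.alleleTab <- function(codes, mx) {
  id <- integer(length(codes))
  id[codes >= 1L & codes < 1000L] <- codes[codes >= 1L & codes < 1000L]
  isB <- codes >= 1000L & codes < .NCODE
  id[isB] <- mx + (codes[isB] - 1000L)
  id[codes == .NCODE] <- 2L * mx + 1L
  id[codes == -1L] <- 2L * mx + 2L
  id[codes == -2L] <- 2L * mx + 3L
  counts <- tabulate(id, nbins = 2L * mx + 3L)
  stats::setNames(counts, c(paste0("A", seq_len(mx)),
                            paste0("B", seq_len(mx)), "N", "-1", "-2"))
}

#' Observed allele frequencies of a CN genotype matrix
#'
#' Counts the two chromosome slots of every cell; undefined and
#' unresolved cells contribute two \code{"-1"} / \code{"-2"} slots.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} of kind \code{"cn"}.
#' @param individuals optional character vector restricting the columns
#'   (e.g. the founders).
#' @param maxTotalCopies cap used for the label range.
#' @return named numeric of frequencies over \code{A1..Amax},
#'   \code{B1..Bmax}, \code{N}, \code{-1}, \code{-2}.
#' @export
alleleFrequencies <- function(x, individuals = NULL, maxTotalCopies = 5L) {
  stopifnot(is(x, "GenotypeMatrix"), x@kind == "cn")
  cells <- x@calls
  if (!is.null(individuals)) cells <- cells[, individuals, drop = FALSE]
  enc <- .encodeCN(as.vector(cells))
  counts <- .alleleTab(c(enc$g1, enc$g2), as.integer(maxTotalCopies))
  counts / sum(counts)
}

# ---- the validation harness ----------------------------------------------

# one simulated batch in code space; returns everything run-level scoring
# needs.  nInd x m matrices throughout.
.simulateChunk <- function(m, ped, pedidx, fams, prop, tabs, maskRate,
                           errorMode) {
  n <- length(ped@id)
  nF <- sum(ped@father == 0L)
  fg <- .sampleFounderCodes(nF * m, prop, tabs)
  truth <- .geneDropCodes(ped, matrix(fg$g1, nF, m), matrix(fg$g2, nF, m))
  o1 <- truth$g1
  o2 <- truth$g2
  sub <- NULL
  if (errorMode) {
    sub <- sample.int(n, m, replace = TRUE)
    at <- cbind(sub, seq_len(m))
    old1 <- o1[at]
    old2 <- o2[at]
    new1 <- old1
    new2 <- old2
    todo <- seq_len(m)
    while (length(todo)) {
      g <- .sampleFounderCodes(length(todo), prop, tabs)
      new1[todo] <- pmin(g$g1, g$g2)
      new2[todo] <- pmax(g$g1, g$g2)
      todo <- todo[new1[todo] == old1[todo] & new2[todo] == old2[todo]]
    }
    o1[at] <- new1
    o2[at] <- new2
  }
  if (maskRate > 0) {
    hit <- stats::runif(n * m) < maskRate
    o1[hit] <- -1L
    o2[hit] <- -1L
  }
  fw <- .codeToFawkes(pmax(o1, 0L), pmax(o2, 0L))
  a <- matrix(fw$a, n, m)
  b <- matrix(fw$b, n, m)
  a[o1 < 0L] <- -1L
  b[o1 < 0L] <- -1L
  res <- .cpp_partition_batch(a, b, pedidx, FALSE)
  list(truth = truth, a = a, res = res, sub = sub)
}

#' Run the gene-dropping validation experiment
#'
#' Each run simulates one marker on the configured pedigree: founder
#' genotypes are sampled, dropped through the pedigree, the truth is
#' archived, (in error mode) one genotype is substituted, a fraction of
#' genotypes is masked as undefined, the matrix is collapsed to
#' integrated calls and partitioned back, and the result is scored
#' against the truth.  In error mode the nuclear-family consistency
#' checker is then applied, failing families are blanked, and the
#' detection channels are tallied.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param chunkSize runs simulated per batch (fixed so that results are
#'   reproducible for a given seed regardless of memory).
#' @return a \code{\linkS4class{ValidationReport}}.
#' @export
runValidation <- function(config, chunkSize = 5000L) {
  ped <- config@pedigree
  n <- length(ped@id)
  pedidx <- .pedIndices(ped)
  fams <- .nuclearFamilies(ped)
  nfam <- length(fams$father)
  famMember <- matrix(FALSE, nfam, n)
  for (f in seq_len(nfam)) {
    kids <- fams$child_idx[(fams$child_ptr[f] + 1L):fams$child_ptr[f + 1L]]
    famMember[f, c(fams$father[f], fams$mother[f], kids)] <- TRUE
  }
  relMember <- diag(n) > 0      # self + parents + children + full sibs
  key <- paste(ped@father, ped@mother)
  for (i in seq_len(n)) {
    rel <- c(ped@father[i], ped@mother[i],
             which(ped@father == i | ped@mother == i),
             if (ped@father[i] > 0L) which(key == key[i]))
    relMember[rel[rel > 0L], i] <- TRUE
  }
  prop <- config@proportions / sum(config@proportions)
  tabs <- .founderTables(config@maxTotalCopies)
  set.seed(config@seed)
  tot <- list(attempted = 0, succeeded = 0, mismatch = 0, incons = 0,
              rules = numeric(length(.ruleNames)),
              detected = 0, checkerRuns = 0, unresSub = 0, wrongRuns = 0,
              engineUndef = 0, checkerUndef = 0)
  left <- config@nRuns
  while (left > 0L) {
    m <- min(chunkSize, left)
    left <- left - m
    ch <- .simulateChunk(m, ped, pedidx, fams, prop, tabs,
                         config@maskRate, config@errorMode)
    g1 <- ch$res$g1
    g2 <- ch$res$g2
    conv <- g1 >= 0L
    tot$attempted <- tot$attempted + sum(ch$a != -1L)
    tot$succeeded <- tot$succeeded + sum(conv)
    tot$mismatch <- tot$mismatch +
      sum(conv & (g1 != ch$truth$g1 | g2 != ch$truth$g2))
    tot$incons <- tot$incons + sum(ch$res$inconsistencies)
    tot$rules <- tot$rules + rowSums(ch$res$ruleCounts)
    tot$engineUndef <- tot$engineUndef + sum(!conv)
    if (config@errorMode) {
      fail <- .cpp_check_batch(g1, g2, fams$father, fams$mother,
                               fams$child_ptr, fams$child_idx, 0L)
      checkerAny <- colSums(fail) > 0L
      blank <- (crossprod(famMember + 0, fail + 0) > 0)
      tot$checkerUndef <- tot$checkerUndef + sum(blank & conv)
      p1 <- g1
      p2 <- g2
      p1[blank] <- -1L
      p2[blank] <- -1L
      at <- cbind(ch$sub, seq_len(m))
      unresSub <- g1[at] == -2L
      inconsRun <- ch$res$inconsistencies > 0L
      wrong <- (p1 >= 0L) & (p1 != ch$truth$g1 | p2 != ch$truth$g2)
      wrongRun <- colSums(wrong & relMember[, ch$sub, drop = FALSE]) > 0L
      tot$detected <- tot$detected +
        sum(checkerAny | unresSub | inconsRun)
      tot$checkerRuns <- tot$checkerRuns + sum(checkerAny)
      tot$unresSub <- tot$unresSub + sum(unresSub)
      tot$wrongRuns <- tot$wrongRuns + sum(wrongRun)
    }
  }
  calls <- as.numeric(config@nRuns) * n
  frac <- function(x) if (config@errorMode) x / config@nRuns else NA_real_
  new("ValidationReport", runs = config@nRuns, nIndividuals = as.integer(n),
      errorMode = config@errorMode,
      conversionsAttempted = tot$attempted,
      conversionsSucceeded = tot$succeeded,
      mismatches = tot$mismatch,
      ruleCounts = stats::setNames(tot$rules, .ruleNames),
      inconsistencies = tot$incons,
      detectedFrac = frac(tot$detected),
      checkerDetectedFrac = frac(tot$checkerRuns),
      unresolvedAtSubstitutedFrac = frac(tot$unresSub),
      wrongAssignmentFrac = frac(tot$wrongRuns),
      engineUndefinedCallFrac = tot$engineUndef / calls,
      checkerUndefinedCallFrac = if (config@errorMode)
        tot$checkerUndef / calls else NA_real_,
      injectedErrorCallRate = if (config@errorMode) 1 / n else NA_real_)
}

#' Simulated allele frequencies of the truth matrices
#'
#' Samples founders, gene-drops and masks exactly as
#' \code{\link{runValidation}} does (without partitioning) and tallies
#' the allele slots of the truth-after-masking matrices, separately for
#' founders and for all individuals.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param chunkSize runs per batch.
#' @return list with \code{founder} and \code{all} named frequency
#'   vectors (over \code{A1..Amax}, \code{B1..Bmax}, \code{N},
#'   \code{-1}, \code{-2}) and \code{runs}.
#' @export
simulateAlleleFrequencies <- function(config, chunkSize = 5000L) {
  ped <- config@pedigree
  n <- length(ped@id)
  nF <- sum(ped@father == 0L)
  frow <- which(ped@father == 0L)
  prop <- config@proportions / sum(config@proportions)
  tabs <- .founderTables(config@maxTotalCopies)
  mx <- config@maxTotalCopies
  set.seed(config@seed)
  cf <- ca <- numeric(2L * mx + 3L)
  left <- config@nRuns
  while (left > 0L) {
    m <- min(chunkSize, left)
    left <- left - m
    fg <- .sampleFounderCodes(nF * m, prop, tabs)
    g <- .geneDropCodes(ped, matrix(fg$g1, nF, m), matrix(fg$g2, nF, m))
    if (config@maskRate > 0) {
      hit <- stats::runif(n * m) < config@maskRate
      g$g1[hit] <- -1L
      g$g2[hit] <- -1L
    }
    cf <- cf + .alleleTab(c(g$g1[frow, ], g$g2[frow, ]), mx)
    ca <- ca + .alleleTab(c(g$g1, g$g2), mx)
  }
  labels <- c(paste0("A", seq_len(mx)), paste0("B", seq_len(mx)),
              "N", "-1", "-2")
  list(founder = stats::setNames(cf / sum(cf), labels),
       all = stats::setNames(ca / sum(ca), labels),
       runs = config@nRuns)
}

#' @export
setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", object@runs, "runs x", object@nIndividuals,
      "individuals", if (object@errorMode) "(error mode)" else "(clean)",
      "\n")
  cat(sprintf("  conversions: %.0f attempted, %.0f non-sentinel, %.0f mismatches vs truth\n",
              object@conversionsAttempted, object@conversionsSucceeded,
              object@mismatches))
  cat("  rule usage:", paste(sprintf("%s=%.0f", names(object@ruleCounts),
                                     object@ruleCounts), collapse = " "), "\n")
  cat("  Mendelian inconsistencies flagged:", object@inconsistencies, "\n")
  if (object@errorMode) {
    cat(sprintf("  injected error detected: %.1f%% of runs\n",
                100 * object@detectedFrac))
    cat(sprintf("  checker flagged a family: %.1f%% of runs\n",
                100 * object@checkerDetectedFrac))
    cat(sprintf("  unresolved at substituted individual: %.1f%% of runs\n",
                100 * object@unresolvedAtSubstitutedFrac))
    cat(sprintf("  wrong assignment near substitution: %.1f%% of runs\n",
                100 * object@wrongAssignmentFrac))
    cat(sprintf("  undefined calls: %.1f%% engine + %.1f%% checker\n",
                100 * object@engineUndefinedCallFrac,
                100 * object@checkerUndefinedCallFrac))
  }
})
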