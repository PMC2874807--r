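# Brute-force oracles, independent of the package internals: genotypes are
# handled as strings of two allele tokens, enumeration is explicit.

or_key <- function(tok) {
  ifelse(tok == "N", 200L,
         ifelse(substr(tok, 1L, 1L) == "A", as.integer(substring(tok, 2L)),
                100L + as.integer(substring(tok, 2L))))
}

or_split <- function(g) strsplit(g, ",", fixed = TRUE)[[1L]]

or_geno <- function(x, y) {
  toks <- c(x, y)[order(or_key(c(x, y)))]
  paste(toks, collapse = ",")
}

or_tot <- function(tok) ifelse(tok == "N", 0L, as.integer(substring(tok, 2L)))

or_collapse <- function(g) {
  toks <- or_split(g)
  ty <- substr(toks, 1L, 1L)
  c(sum(or_tot(toks)[ty == "A"]), sum(or_tot(toks)[ty == "B"]))
}

# all genotypes whose alleles carry at most max copies each (offspring of
# capped founders can total up to 2 * max)
or_universe <- function(max = 5L) {
  al <- c(paste0("A", 1:max), paste0("B", 1:max), "N")
  gs <- expand.grid(x = al, y = al, stringsAsFactors = FALSE)
  gs <- gs[or_key(gs$x) <= or_key(gs$y), ]
  paste(gs$x, gs$y, sep = ",")
}

# genotypes compatible with an integrated call (a,b); undefined -> universe
or_candidates <- function(a, b, max = 5L) {
  u <- or_universe(max)
  if (a == -1L) return(u)
  u[vapply(u, function(g) all(or_collapse(g) == c(a, b)), logical(1L))]
}

# the four possible child genotypes of two parents
or_children <- function(f, m) {
  ft <- or_split(f)
  mt <- or_split(m)
  unique(c(or_geno(ft[1L], mt[1L]), or_geno(ft[1L], mt[2L]),
           or_geno(ft[2L], mt[1L]), or_geno(ft[2L], mt[2L])))
}

or_sentinel <- function(g) is.na(g) || g %in% c("-1,-1", "-2,-2")

# exhaustive joint consistency of one nuclear family; unknown parents
# range over the full genotype universe (total <= max)
or_fam_consistent <- function(father, mother, children, max = 5L) {
  kids <- children[!vapply(children, or_sentinel, logical(1L))]
  if (!length(kids)) return(TRUE)
  u <- or_universe(max)
  fc <- if (or_sentinel(father)) u else father
  mc <- if (or_sentinel(mother)) u else mother
  kt <- lapply(kids, or_split)
  for (f in fc) {
    fp <- or_split(f)
    for (m in mc) {
      mp <- or_split(m)
      ok <- all(vapply(kt, function(k) {
        (k[1L] %in% fp && k[2L] %in% mp) || (k[2L] %in% fp && k[1L] %in% mp)
      }, logical(1L)))
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# all Mendelian-consistent genotype configurations of a nuclear family
# given its integrated calls; returns a list of configurations (father,
# mother, then children), used to verify that an engine conversion is
# consistent with at least one configuration
or_nuclear_configs <- function(callF, callM, callKids, max = 5L) {
  cf <- or_candidates(callF[1L], callF[2L], max)
  cm <- or_candidates(callM[1L], callM[2L], max)
  ck <- lapply(callKids, function(cc) or_candidates(cc[1L], cc[2L], max))
  out <- list()
  for (f in cf) {
    fp <- or_split(f)
    for (m in cm) {
      mp <- or_split(m)
      sets <- lapply(ck, function(cand) {
        cand[vapply(cand, function(g) {
          k <- or_split(g)
          (k[1L] %in% fp && k[2L] %in% mp) ||
            (k[2L] %in% fp && k[1L] %in% mp)
        }, logical(1L))]
      })
      if (any(lengths(sets) == 0L)) next
      grid <- do.call(expand.grid,
                      c(sets, list(stringsAsFactors = FALSE)))
      for (r in seq_len(nrow(grid))) {
        out[[length(out) + 1L]] <- c(f, m, unlist(grid[r, ],
                                                  use.names = FALSE))
      }
    }
  }
  out
}
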