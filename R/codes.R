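# Internal integer encoding of CN alleles, shared with src/engine.cpp:
#   A with m copies -> m, B with n copies -> 1000 + n, N -> 2000.
# Genotypes are pairs of codes stored canonically (g1 <= g2), which orders
# A alleles before B alleles before N.  Sentinels are genotype-level:
# both slots -1 (undefined) or -2 (unresolved).

.NCODE <- 2000L

.alleleType <- function(code) {
  ifelse(code == .NCODE, "N", ifelse(code >= 1000L, "B", "A"))
}

.alleleCount <- function(code) {
  ifelse(code == .NCODE, 0L, ifelse(code >= 1000L, code - 1000L, code))
}

.alleleCode <- function(token) {
  out <- rep(NA_integer_, length(token))
  out[token == "N"] <- .NCODE
  ia <- grepl("^A[1-9][0-9]*$", token)
  ib <- grepl("^B[1-9][0-9]*$", token)
  out[ia] <- as.integer(substring(token[ia], 2L))
  out[ib] <- 1000L + as.integer(substring(token[ib], 2L))
  out
}

.alleleString <- function(code) {
  ifelse(code == .NCODE, "N",
         ifelse(code >= 1000L, paste0("B", code - 1000L), paste0("A", code)))
}

# character CN genotypes -> canonical code pairs; malformed cells become NA
.encodeCN <- function(x) {
  n <- length(x)
  g1 <- rep(NA_integer_, n)
  g2 <- rep(NA_integer_, n)
  und <- !is.na(x) & x == "-1,-1"
  unr <- !is.na(x) & x == "-2,-2"
  g1[und] <- -1L; g2[und] <- -1L
  g1[unr] <- -2L; g2[unr] <- -2L
  rest <- which(!is.na(x) & !und & !unr)
  if (length(rest)) {
    parts <- strsplit(x[rest], ",", fixed = TRUE)
    okn <- lengths(parts) == 2L
    a1 <- rep(NA_integer_, length(rest))
    a2 <- rep(NA_integer_, length(rest))
    if (any(okn)) {
      pm <- matrix(unlist(parts[okn]), nrow = 2L)
      a1[okn] <- .alleleCode(pm[1L, ])
      a2[okn] <- .alleleCode(pm[2L, ])
    }
    lo <- pmin(a1, a2)
    hi <- pmax(a1, a2)
    g1[rest] <- lo
    g2[rest] <- hi
  }
  list(g1 = g1, g2 = g2)
}

# code pairs -> canonical CN genotype strings
.decodeCN <- function(g1, g2) {
  out <- character(length(g1))
  und <- g1 == -1L
  unr <- g1 == -2L
  out[und] <- "-1,-1"
  out[unr] <- "-2,-2"
  ok <- !und & !unr
  if (any(ok)) {
    lo <- pmin(g1[ok], g2[ok])
    hi <- pmax(g1[ok], g2[ok])
    out[ok] <- paste0(.alleleString(lo), ",", .alleleString(hi))
  }
  out[is.na(g1)] <- NA_character_
  out
}

# "a,b" Fawkes cells -> integer a, b; malformed cells become NA
.parseFawkesCells <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)
  ok <- lengths(parts) == 2L & !is.na(x)
  a <- rep(NA_integer_, length(x))
  b <- rep(NA_integer_, length(x))
  if (any(ok)) {
    pm <- matrix(unlist(parts[ok]), nrow = 2L)
    num <- grepl("^-?[0-9]+$", pm[1L, ]) & grepl("^-?[0-9]+$", pm[2L, ])
    av <- suppressWarnings(as.integer(pm[1L, ]))
    bv <- suppressWarnings(as.integer(pm[2L, ]))
    av[!num] <- NA_integer_
    bv[!num] <- NA_integer_
    a[ok] <- av
    b[ok] <- bv
  }
  bad <- !is.na(a) & !is.na(b) &
    !((a >= 0L & b >= 0L) | (a == -1L & b == -1L) | (a == -2L & b == -2L))
  a[bad] <- NA_integer_
  b[bad] <- NA_integer_
  list(a = a, b = b)
}

# total copies of A and of B carried by a code-pair genotype
.codeToFawkes <- function(g1, g2) {
  cntA <- function(g) ifelse(g >= 1L & g < 1000L, g, 0L)
  cntB <- function(g) ifelse(g >= 1000L & g < .NCODE, g - 1000L, 0L)
  list(a = cntA(g1) + cntA(g2), b = cntB(g1) + cntB(g2))
}
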