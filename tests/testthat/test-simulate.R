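test_that("state genotype sets have the expected size and content", {
  expect_equal(enumerateStateGenotypes("null"), "N,N")
  expect_equal(sort(enumerateStateGenotypes("hemizygous")),
               c("A1,N", "B1,N"))
  het <- enumerateStateGenotypes("heterozygous")
  expect_length(het, 10L)
  expect_true(all(c("A1,B1", "A1,B4", "A4,B1", "A2,B3") %in% het))
  expect_false("A1,B5" %in% het)   # total would exceed the cap
  hom <- enumerateStateGenotypes("homozygous")
  expect_length(hom, 20L)
  expect_true(all(c("A1,A1", "A2,A3", "A2,N", "A5,N",
                    "B1,B1", "B5,N") %in% hom))
  expect_false("A3,A3" %in% hom)
  # the cap is configurable
  expect_length(enumerateStateGenotypes("heterozygous", 3L), 3L)
  expect_length(enumerateStateGenotypes("homozygous", 2L), 4L)
})

test_that("exact enumeration reproduces the derived allele frequencies", {
  f <- expectedAlleleFrequencies()
  # frozen values from the closed-form derivation: e.g. A1 receives
  # p_hemi/4 + p_het * 4/20 + p_hom * 2.5/20 before normalization
  expect_equal(round(unname(f[c("A1", "A2", "A3", "A4", "A5", "N")]), 4),
               c(0.1478, 0.1290, 0.0801, 0.0489, 0.0177, 0.1529))
  expect_equal(unname(f[paste0("A", 1:5)]), unname(f[paste0("B", 1:5)]))
  expect_equal(sum(f), 1)
  fm <- expectedAlleleFrequencies(maskRate = 0.01)
  expect_equal(unname(fm["-1"]), 0.01)
  expect_equal(unname(fm["A3"]), unname(f[["A3"]] * 0.99))
  # the published table (three significant digits) is matched
  printed <- c(A1 = 0.146, A2 = 0.128, A3 = 0.0793, A4 = 0.0484,
               A5 = 0.0175, N = 0.151)
  expect_true(all(abs(fm[names(printed)] - printed) < 5e-4))
})

test_that("founder sampling follows the configured state proportions", {
  cfg <- simulationConfig(proportions = c(0, 0, 1, 0))
  set.seed(1)
  g <- sampleFounders(500L, cfg)
  expect_true(all(g %in% enumerateStateGenotypes("heterozygous")))
  # state frequencies over many draws match the configured proportions
  cfg <- simulationConfig()
  set.seed(2)
  g <- sampleFounders(1e5L, cfg)
  states <- vapply(strsplit(g, ","), function(t) {
    ty <- substr(t, 1L, 1L)
    tot <- sum(ifelse(t == "N", 0L, as.integer(substring(t, 2L))))
    if (tot == 0L) "null" else if (tot == 1L) "hemizygous"
    else if (all(c("A", "B") %in% ty)) "heterozygous" else "homozygous"
  }, character(1L))
  p <- c(null = 0.000337, hemizygous = 0.0214, heterozygous = 0.269,
         homozygous = 0.709) / 0.999737
  for (s in names(p)) {
    se <- sqrt(p[[s]] * (1 - p[[s]]) / 1e5)
    expect_lt(abs(mean(states == s) - p[[s]]), 4 * se + 1e-4)
  }
  # seeded draws are reproducible
  set.seed(3); a <- sampleFounders(100L, cfg)
  set.seed(3); b <- sampleFounders(100L, cfg)
  expect_identical(a, b)
})

test_that("gene dropping transmits one allele from each parent", {
  ped <- readPedfile(fx_trio_ped())
  # homozygous founders force the child genotype
  g <- geneDrop(ped, c(dad = "A1,A1", mom = "B2,B2"))
  expect_equal(genotypeCalls(g)[1L, "kid"], "A1,B2")
  # a heterozygous parent transmits each allele half the time
  set.seed(4)
  founderG <- matrix(rep(c("A1,B1", "N,N"), each = 1e4L), ncol = 2L,
                     dimnames = list(NULL, c("dad", "mom")))
  rownames(founderG) <- sprintf("m%05d", seq_len(1e4L))
  kid <- genotypeCalls(geneDrop(ped, founderG))[, "kid"]
  expect_true(all(kid %in% c("A1,N", "B1,N")))
  pA <- mean(kid == "A1,N")
  expect_lt(abs(pA - 0.5), 4 * sqrt(0.25 / 1e4))
})

test_that("gene dropping handles the consanguinity loop", {
  ped <- makeValidationPedigree()
  # the loop couple are first cousins through founders 1 and 2
  expect_true("34" %in% spousesOf(ped, "30"))
  anc <- function(id) {
    out <- character()
    todo <- id
    while (length(todo)) {
      p <- unlist(lapply(todo, parentsOf, pedigree = ped))
      out <- union(out, p)
      todo <- p
    }
    out
  }
  expect_true(length(intersect(anc("30"), anc("34"))) >= 2L)
  set.seed(6)
  founderG <- matrix(sampleFounders(14L * 50L), nrow = 50L,
                     dimnames = list(sprintf("m%02d", 1:50),
                                     founders(ped)))
  truth <- geneDrop(ped, founderG)
  # every loop child is consistent with its parents
  tr <- genotypeCalls(truth)
  for (m in seq_len(50L)) {
    expect_true(consistentTrio(tr[m, "30"], tr[m, "34"], tr[m, "46"]))
    expect_true(consistentTrio(tr[m, "30"], tr[m, "34"], tr[m, "47"]))
  }
})

test_that("masking recodes the requested fraction as undefined", {
  ped <- makeValidationPedigree()
  set.seed(9)
  founderG <- matrix(sampleFounders(14L * 2000L), nrow = 2000L,
                     dimnames = list(sprintf("m%04d", 1:2000),
                                     founders(ped)))
  truth <- geneDrop(ped, founderG)
  expect_identical(genotypeCalls(maskUndefined(truth, 0)),
                   genotypeCalls(truth))
  masked <- maskUndefined(truth, 0.01)
  frac <- mean(genotypeCalls(masked) == "-1,-1")
  expect_lt(abs(frac - 0.01), 4 * sqrt(0.01 * 0.99 / (2000 * 47)))
  # the truth copy is untouched (masking is not in place)
  expect_false(any(genotypeCalls(truth) == "-1,-1"))
})

test_that("collapsing to integrated calls passes sentinels through", {
  x <- GenotypeMatrix(
    matrix(c("A2,A3", "A1,B2", "-1,-1", "-2,-2", "B2,N", "N,N"),
           nrow = 2L, dimnames = list(c("m1", "m2"),
                                      c("s1", "s2", "s3"))), kind = "cn")
  fw <- genotypeCalls(collapseToFawkes(x))
  expect_equal(as.vector(fw), c("5,0", "1,2", "-1,-1", "-2,-2",
                                "0,2", "0,0"))
})

test_that("error injection substitutes exactly one differing genotype", {
  ped <- makeValidationPedigree()
  set.seed(10)
  founderG <- matrix(sampleFounders(14L * 500L), nrow = 500L,
                     dimnames = list(sprintf("m%03d", 1:500),
                                     founders(ped)))
  truth <- geneDrop(ped, founderG)
  inj <- injectError(truth)
  changed <- genotypeCalls(inj$matrix) != genotypeCalls(truth)
  expect_equal(rowSums(changed), rep(1, 500), ignore_attr = TRUE)
  expect_equal(nrow(inj$info), 500L)
  expect_true(all(inj$info$new != inj$info$old))
  at <- cbind(match(inj$info$marker, rownames(changed)),
              match(inj$info$individual, colnames(changed)))
  expect_true(all(changed[at]))
})

test_that("the clean validation recovers the truth exactly", {
  rep <- runValidation(simulationConfig(nRuns = 3000L, seed = 99L))
  expect_equal(rep@mismatches, 0)
  expect_equal(rep@inconsistencies, 0)
  expect_gt(rep@conversionsSucceeded, 0)
  # reproducibility: identical seeds give identical reports
  rep2 <- runValidation(simulationConfig(nRuns = 3000L, seed = 99L))
  expect_equal(rep@conversionsSucceeded, rep2@conversionsSucceeded)
  expect_equal(rep@ruleCounts, rep2@ruleCounts)
})

test_that("simulated allele frequencies match the analytic expectation", {
  cfg <- simulationConfig(nRuns = 4000L, seed = 13L)
  sim <- simulateAlleleFrequencies(cfg)
  expected <- expectedAlleleFrequencies(maskRate = 0.01)
  for (al in names(expected)) {
    expect_lt(abs(sim$founder[[al]] - expected[[al]]), 0.01)
    expect_lt(abs(sim$all[[al]] - expected[[al]]), 0.01)
  }
  # gene dropping preserves frequencies: founders vs all individuals
  expect_lt(max(abs(sim$founder - sim$all)), 0.01)
})
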