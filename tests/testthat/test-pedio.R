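test_that("a trio pedfile reads into a validated pedigree", {
  ped <- readPedfile(fx_trio_ped())
  expect_s4_class(ped, "Pedigree")
  expect_equal(nIndividuals(ped), 3L)
  expect_equal(sort(founders(ped)), c("dad", "mom"))
  expect_equal(parentsOf(ped, "kid"), c("dad", "mom"))
  expect_equal(childrenOf(ped, "dad"), "kid")
  expect_equal(spousesOf(ped, "dad"), "mom")
  expect_equal(fullSiblingsOf(ped, "kid"), character())
})

test_that("structural pedfile errors name the offending individual", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.ped")
  writeLines(c("1 dad 0 0 1 0", "1 kid dad ghost 1 2"), bad)
  expect_error(readPedfile(bad), "ghost")
  writeLines(c("1 a 0 0 1 0", "1 a 0 0 2 0"), bad)
  expect_error(readPedfile(bad), "duplicate")
  writeLines(c("1 a b c 1 0", "1 b a c 1 0", "1 c a b 2 0"), bad)
  expect_error(readPedfile(bad), "cyclic|absent|parent")
  writeLines("1 solo 0 0", bad)
  expect_error(readPedfile(bad), "6 columns")
  expect_error(readPedfile(file.path(dir, "nope.ped")), "not found")
  # exactly one parent set is rejected
  writeLines(c("1 dad 0 0 1 0", "1 kid dad 0 1 2"), bad)
  expect_error(readPedfile(bad), "one parent")
})

test_that("the validation pedigree fixture round-trips through a pedfile", {
  ped <- makeValidationPedigree()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "validation.ped")
  writePedfile(ped, path)
  ped2 <- readPedfile(path)
  expect_equal(nIndividuals(ped2), 47L)
  expect_equal(length(founders(ped2)), 14L)
  expect_equal(ped2@id, ped@id)
  expect_equal(ped2@father, ped@father)
})

test_that("fawkes matrices read with cell validation and coordinates", {
  ped <- readPedfile(fx_trio_ped())
  path <- fx_fawkes_file(fx_trio_calls())
  gm <- readFawkesMatrix(path, pedigree = ped)
  expect_equal(markerIds(gm), c("rs1", "rs2", "rs3"))
  expect_equal(sampleIds(gm), c("dad", "mom", "kid"))
  expect_equal(genotypeCalls(gm)["rs1", "kid"], "2,0")
  expect_equal(genotypeCalls(gm)["rs2", "dad"], "0,0")
  cells <- fx_trio_calls()
  cells["rs2", "mom"] <- "-1,-1"
  gm <- readFawkesMatrix(fx_fawkes_file(cells, name = "c2.txt"))
  expect_equal(genotypeCalls(gm)["rs2", "mom"], "-1,-1")
  cells["rs3", "kid"] <- "2,x"
  expect_error(readFawkesMatrix(fx_fawkes_file(cells, name = "c3.txt")),
               "rs3.*kid")
  # ragged rows are rejected with the line number
  dir <- withr::local_tempdir()
  ragged <- file.path(dir, "ragged.txt")
  writeLines(c("probeset_id\tdad\tmom", "rs1\t1,1"), ragged)
  expect_error(readFawkesMatrix(ragged), "ragged")
  # sample ids must resolve to pedigree members when a pedigree is given
  cells <- fx_trio_calls()
  colnames(cells)[3L] <- "stranger"
  expect_error(readFawkesMatrix(fx_fawkes_file(cells, name = "c4.txt"),
                                pedigree = ped), "stranger")
})

test_that("matrix write/read round-trip is byte-stable on canonical files", {
  cn <- GenotypeMatrix(
    matrix(c("A1,B2", "N,N", "-2,-2", "A2,N"), nrow = 2L,
           dimnames = list(c("rs1", "rs2"), c("s1", "s2"))), kind = "cn")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "cn1.txt")
  p2 <- file.path(dir, "cn2.txt")
  writeCNMatrix(cn, p1)
  back <- readCNMatrix(p1)
  expect_equal(genotypeCalls(back), genotypeCalls(cn))
  writeCNMatrix(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # non-canonical cells are canonicalized on write
  messy <- GenotypeMatrix(
    matrix("B2,A1", 1L, 1L, dimnames = list("rs1", "s1")), kind = "cn")
  p3 <- file.path(dir, "cn3.txt")
  writeCNMatrix(messy, p3)
  expect_equal(genotypeCalls(readCNMatrix(p3))[1L, 1L], "A1,B2")
})

test_that("annotation columns can be skipped on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "annot.txt")
  writeLines(c("probeset_id\tchrom\ts1\ts2",
               "rs1\t7\t1,1\t2,0"), path)
  gm <- readFawkesMatrix(path, annotationCols = 1L)
  expect_equal(sampleIds(gm), c("s1", "s2"))
  expect_equal(genotypeCalls(gm)["rs1", "s1"], "1,1")
})

test_that("multi-allelic recoding uses the deterministic allele order", {
  ped <- readPedfile(fx_trio_ped())
  cn <- GenotypeMatrix(
    matrix(c("A1,A2", "A2,N", "A1,N",
             "A1,B1", "-2,-2", "B1,B1"),
           nrow = 2L, byrow = TRUE,
           dimnames = list(c("m1", "m2"), c("dad", "mom", "kid"))),
    kind = "cn")
  rec <- recodeToMultiallelic(cn, ped)
  m1 <- rec$alleleMap[rec$alleleMap$marker == "m1", ]
  expect_equal(m1$allele, c("A1", "A2", "N"))
  expect_equal(m1$code, 1:3)
  expect_equal(rec$ped[rec$ped$id == "dad", "m1"], "1 2")
  expect_equal(rec$ped[rec$ped$id == "mom", "m1"], "2 3")
  m2 <- rec$alleleMap[rec$alleleMap$marker == "m2", ]
  expect_equal(m2$allele, c("A1", "B1"))
  expect_equal(rec$ped[rec$ped$id == "dad", "m2"], "1 2")
  # sentinels become the missing genotype
  expect_equal(rec$ped[rec$ped$id == "mom", "m2"], "0 0")
  # phenotype and structure columns are preserved verbatim
  expect_equal(rec$ped$phenotype, c("0", "0", "2"))
  expect_equal(rec$ped$fatherId, c("0", "0", "dad"))
})

test_that("recoding is invertible on non-sentinel cells via the sidecar", {
  ped <- makeValidationPedigree()
  set.seed(5)
  founderG <- matrix(sampleFounders(14L * 6L), nrow = 6L,
                     dimnames = list(paste0("m", 1:6), founders(ped)))
  truth <- geneDrop(ped, founderG)
  masked <- maskUndefined(truth, 0.1)
  rec <- recodeToMultiallelic(masked, ped)
  dec <- decodeMultiallelic(rec)
  orig <- genotypeCalls(masked)[, colnames(genotypeCalls(dec))]
  back <- genotypeCalls(dec)
  nonsent <- orig != "-1,-1" & orig != "-2,-2"
  expect_true(all(back[nonsent] == orig[nonsent]))
  expect_true(all(back[!nonsent] == "-1,-1"))
  # per-marker codes are injective on observed alleles
  for (m in unique(rec$alleleMap$marker)) {
    mm <- rec$alleleMap[rec$alleleMap$marker == m, ]
    expect_false(anyDuplicated(mm$code) > 0L)
    expect_false(anyDuplicated(mm$allele) > 0L)
  }
})

test_that("recoded linkage files are written and re-readable", {
  ped <- readPedfile(fx_trio_ped())
  cn <- GenotypeMatrix(
    matrix(c("A1,A2", "A2,N", "A1,N"), nrow = 1L,
           dimnames = list("m1", c("dad", "mom", "kid"))), kind = "cn")
  rec <- recodeToMultiallelic(cn, ped)
  dir <- withr::local_tempdir()
  paths <- writeRecoded(rec, file.path(dir, "out"))
  expect_true(all(file.exists(file.path(dir, c("out.ped",
                                               "out.allelemap")))))
  pedtab <- read.table(file.path(dir, "out.ped"), sep = "\t",
                       colClasses = "character")
  expect_equal(nrow(pedtab), 3L)
  expect_equal(pedtab[[7L]], c("1 2", "2 3", "1 3"))
})
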