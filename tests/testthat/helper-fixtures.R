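# File fixtures are generated in code at test time.

fx_dir <- function() {
  dir <- tempfile("fx")
  dir.create(dir)
  dir
}

fx_trio_ped <- function(dir = fx_dir()) {
  path <- file.path(dir, "trio.ped")
  writeLines(c("1\tdad\t0\t0\t1\t0",
               "1\tmom\t0\t0\t2\t0",
               "1\tkid\tdad\tmom\t1\t2"), path)
  path
}

fx_fawkes_file <- function(cells, dir = fx_dir(), name = "calls.txt") {
  path <- file.path(dir, name)
  lines <- c(paste(c("probeset_id", colnames(cells)), collapse = "\t"),
             paste(rownames(cells),
                   apply(cells, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  path
}

fx_trio_calls <- function() {
  matrix(c("2,1", "1,1", "2,0",
           "0,0", "1,0", "0,1",
           "3,0", "1,2", "2,0"),
         nrow = 3L, byrow = TRUE,
         dimnames = list(c("rs1", "rs2", "rs3"), c("dad", "mom", "kid")))
}

# random nuclear-family draw used by rule-soundness tests
fx_random_family <- function(maxKids = 4L, max = 5L) {
  u <- or_universe(max)
  f <- sample(u, 1L)
  m <- sample(u, 1L)
  nk <- sample.int(maxKids, 1L)
  kids <- vapply(seq_len(nk), function(i) {
    ch <- or_children(f, m)
    ch[sample.int(length(ch), 1L)]
  }, character(1L))
  list(father = f, mother = m, kids = kids)
}
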