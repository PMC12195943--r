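test_that("the default enzyme table encodes the three-protease system", {
  enz <- load_enzyme_table()
  expect_named(enz, c("pepsin", "trypsin", "chymotrypsin A"))
  expect_equal(vapply(enz, function(e) length(e$rules), integer(1)),
               c(pepsin = 2L, trypsin = 2L, `chymotrypsin A` = 8L))
  ct <- enz[["chymotrypsin A"]]
  nterm <- Filter(function(r) r$side == "N-terminal", ct$rules)
  expect_length(nterm, 1L)
  expect_equal(nterm[[1]]$residue, "I")
})

test_that("malformed enzyme tables are rejected with the key path", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("enzymes:", "  - name: broken", "    rules: []"), f)
  expect_error(load_enzyme_table(f), "broken.*empty rule list")

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("enzymes:",
               "  - name: odd",
               "    rules:",
               "      - residue: ZZ",
               "        side: C-terminal"), f2)
  expect_error(load_enzyme_table(f2), "'odd', rule 1")

  expect_error(enzyme("dup", rules = list(
    cleavage_rule("K", "C-terminal"), cleavage_rule("K", "C-terminal"))),
    "duplicate")
})

test_that("blocked_by_next suppresses vetoed cuts", {
  tryp_p <- enzyme("trypsin-P", rules = list(
    cleavage_rule("K", "C-terminal", blocked_by_next = "P"),
    cleavage_rule("R", "C-terminal")))
  # K|P vetoed, only the R site fires (and terminal R gives no site)
  expect_equal(cut_sites("AKPR", list(tryp_p)), integer(0))
  expect_equal(cut_sites("AKPRG", list(tryp_p)), 4L)
  expect_equal(cut_sites("AKGRG", list(tryp_p)), c(2L, 4L))
})

test_that("cut_sites matches the stated single-enzyme examples", {
  enz <- default_enzymes()
  expect_equal(cut_sites("AKF", enz["trypsin"]), 2L)
  expect_equal(cut_sites("AFLG", enz["pepsin"]), c(2L, 3L))
  # terminal matches yield no site
  expect_equal(cut_sites("KAK", enz["trypsin"]), 1L)
  expect_equal(cut_sites("IAI", enz["chymotrypsin A"]), 2L)
})

test_that("cut_sites equals the per-boundary brute-force oracle", {
  enz <- default_enzymes()
  set.seed(101)
  for (i in 1:50) {
    s <- random_residues(30)
    expect_equal(cut_sites(s, enz), oracle_cut_sites(s, enz), info = s)
  }
})

test_that("complete digestion partitions the source", {
  enz <- default_enzymes()
  d1 <- digest("AKF", enz["trypsin"])
  expect_equal(d1$peptides$peptide, c("AK", "F"))
  d2 <- digest("AFLG", enz["pepsin"])
  expect_equal(d2$peptides$peptide, c("AF", "L", "G"))
  set.seed(102)
  for (i in 1:25) {
    s <- random_residues(sample(5:60, 1))
    d <- digest(s, enz, mode = "complete")
    expect_equal(paste(d$peptides$peptide, collapse = ""), s)
    expect_equal(nrow(d$peptides), length(d$cut_sites) + 1L)
    expect_true(all(d$peptides$peptide ==
                      substring(s, d$peptides$start, d$peptides$end)))
  }
})

test_that("partial digestion enumerates all cut-bounded intervals", {
  enz <- default_enzymes()
  d <- digest("AKRG", enz["trypsin"], mode = "partial")
  expect_setequal(d$peptides$peptide, c("AK", "R", "G", "AKR", "RG", "AKRG"))
  set.seed(103)
  for (i in 1:25) {
    s <- random_residues(sample(5:40, 1))
    d <- digest(s, enz, mode = "partial")
    k <- length(d$cut_sites)
    expect_equal(nrow(d$peptides), choose(k + 2L, 2L))
    want <- oracle_partial_intervals(s, d$cut_sites)
    expect_equal(d$peptides$start, unname(want[, 1]))
    expect_equal(d$peptides$end, unname(want[, 2]))
    # complete-mode peptides are a subset of partial output
    dc <- digest(s, enz, mode = "complete")
    expect_true(all(paste(dc$peptides$start, dc$peptides$end) %in%
                      paste(d$peptides$start, d$peptides$end)))
  }
})

test_that("adding an enzyme never removes a cut site", {
  enz <- default_enzymes()
  set.seed(104)
  for (i in 1:20) {
    s <- random_residues(40)
    s1 <- cut_sites(s, enz["trypsin"])
    s2 <- cut_sites(s, enz[c("trypsin", "pepsin")])
    s3 <- cut_sites(s, enz)
    expect_true(all(s1 %in% s2))
    expect_true(all(s2 %in% s3))
  }
})

test_that("rule-free sequences release one whole-sequence peptide", {
  enz <- default_enzymes()
  d <- digest("GAGAG", enz) # no F/L/K/R/Y/W/N/H/M/I
  expect_equal(d$cut_sites, integer(0))
  expect_equal(d$peptides$peptide, "GAGAG")
  expect_equal(digest("GAGAG", enz, mode = "partial")$peptides$peptide,
               "GAGAG")
})

test_that("digestion is deterministic", {
  enz <- default_enzymes()
  s <- protein_sequence("x", random_residues(50))
  expect_identical(digest(s, enz, "partial"), digest(s, enz, "partial"))
})

test_that("digest TSV output has stable coordinates", {
  enz <- default_enzymes()
  d <- digest(protein_sequence("x", "AKFGK", gene = "G", allele = "a"),
              enz["trypsin"])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_digest_tsv(d, f)
  back <- read.delim(f)
  expect_equal(back$peptide, d$peptides$peptide)
  expect_equal(back$length, nchar(d$peptides$peptide))
})
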