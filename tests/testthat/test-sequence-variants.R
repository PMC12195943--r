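test_that("FASTA records are parsed, normalised and validated", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "PLGPV", ">y gene=CSN2 allele=A", "plg pv"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]]$id, "x")
  expect_equal(seqs[[1]]$residues, "PLGPV")
  expect_equal(seqs[[1]]$N, 5L)
  expect_equal(seqs[[2]]$residues, "PLGPV")
  expect_equal(seqs[[2]]$gene, "CSN2")
  expect_equal(seqs[[2]]$allele, "A")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">z", "PLJPV"), bad)
  expect_error(read_fasta(bad), "invalid residue 'J'.*position 3")

  notfasta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("PLGPV"), notfasta)
  expect_error(read_fasta(notfasta), "malformed FASTA.*line 1")
})

test_that("terminal stop symbol is stripped with a message", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "PLGPV*"), f)
  expect_message(seqs <- read_fasta(f), "stop symbol")
  expect_equal(seqs[[1]]$residues, "PLGPV")
})

test_that("FASTA write/read round trip preserves id, residues and metadata", {
  s <- protein_sequence("acc1", "MKLVFS", gene = "CSN1S1", allele = "E")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(s), f)
  back <- read_fasta(f)[[1]]
  expect_equal(back$id, s$id)
  expect_equal(back$residues, s$residues)
  expect_equal(back$gene, s$gene)
  expect_equal(back$allele, s$allele)
})

test_that("apply_edits handles identity, substitutions and deletions", {
  ref <- protein_sequence("ref", "ACDEF", gene = "G", allele = "ref")
  expect_equal(apply_edits(ref, list(), "copy")$residues, ref$residues)

  # adjacent double substitution converting a TTM context into AAM
  r2 <- protein_sequence("r2", "GGTTMGG", gene = "G", allele = "A")
  edits <- list(variant_edit("substitution", 3, ref = "T", alt = "A"),
                variant_edit("substitution", 4, ref = "T", alt = "A"))
  v <- apply_edits(r2, edits, "E")
  expect_equal(v$residues, "GGAAMGG")
  expect_equal(v$allele, "E")
  expect_equal(r2$residues, "GGTTMGG") # input untouched

  del <- apply_edits(ref, list(variant_edit("deletion", 3, ref = "D")), "d")
  expect_equal(del$residues, "ACEF")
  expect_equal(del$N, 4L)

  expect_error(
    apply_edits(ref, list(variant_edit("substitution", 2, "D", "A")), "x"),
    "expected 'D' but reference .* has 'C'")
  expect_error(
    apply_edits(ref, list(variant_edit("deletion", 9, ref = "A")), "x"),
    "out of range")
})

test_that("diff_alleles recovers substitutions and single indels", {
  a <- protein_sequence("a", "AGAFQQ", gene = "CSN1S2", allele = "A")
  f <- protein_sequence("f", "AGPFQQ", gene = "CSN1S2", allele = "F")
  expect_length(diff_alleles(a, a), 0L)
  d <- diff_alleles(a, f)
  expect_length(d, 1L)
  expect_equal(d[[1]]$kind, "substitution")
  expect_equal(d[[1]]$position, 3L)
  expect_equal(d[[1]]$ref, "A")
  expect_equal(d[[1]]$alt, "P")

  # single contiguous indel
  long <- protein_sequence("l", "ACDEF", gene = "G", allele = "l")
  short <- protein_sequence("s", "ACEF", gene = "G", allele = "s")
  d2 <- diff_alleles(long, short)
  expect_length(d2, 1L)
  expect_equal(d2[[1]]$kind, "deletion")
  expect_equal(apply_edits(long, d2, "s")$residues, short$residues)
  d3 <- diff_alleles(short, long)
  expect_equal(apply_edits(short, d3, "l")$residues, long$residues)

  expect_error(diff_alleles(
    protein_sequence("x", "AAAA", gene = "G1"),
    protein_sequence("y", "AAAA", gene = "G2")), "one gene")
})

test_that("diff then apply round-trips on random equal-length pairs", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    ra <- random_residues(n)
    a <- protein_sequence("a", ra, gene = "G", allele = "a")
    k <- sample(0:4, 1)
    pos <- sort(sample(n, k))
    chars <- strsplit(ra, "")[[1]]
    edits <- lapply(pos, function(p) {
      variant_edit("substitution", p, ref = chars[p],
                   alt = sample(setdiff(aa_alphabet(), chars[p]), 1))
    })
    b <- apply_edits(a, edits, "b")
    d <- diff_alleles(a, b)
    expect_equal(apply_edits(a, d, "b")$residues, b$residues)
    expect_length(d, sum(strsplit(b$residues, "")[[1]] != chars))
  }
})

test_that("incomparable unequal-length pairs raise an explicit error", {
  a <- protein_sequence("a", "ACDEFGHIK", gene = "G")
  b <- protein_sequence("b", "AWDEGYK", gene = "G")
  expect_error(diff_alleles(a, b), "not comparable")
})

test_that("edit lists load from TSV and apply", {
  edits <- read_edit_table(pep_example("edits_synthetic_example.tsv"))
  expect_length(edits, 2L)
  expect_equal(vapply(edits, `[[`, integer(1), "position"), c(209L, 210L))
  ref <- protein_sequence("ref", paste(c(rep("G", 208), "T", "T", "M"),
                                       collapse = ""), gene = "CSN1S1")
  v <- apply_edits(ref, edits, "E")
  expect_equal(substr(v$residues, 209, 211), "AAM")
})

test_that("allele_set enforces its invariants", {
  r <- protein_sequence("r", "ACDEF", gene = "G", allele = "ref")
  v <- protein_sequence("v", "ACDEH", gene = "G", allele = "v1")
  expect_s3_class(allele_set("G", "ref", list(ref = r, v1 = v)), "allele_set")
  expect_error(allele_set("G", "zz", list(ref = r)), "not among")
  w <- protein_sequence("w", "ACDEH", gene = "OTHER", allele = "w")
  expect_error(allele_set("G", "ref", list(ref = r, w = w)), "share gene")
})
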