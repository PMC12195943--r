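test_that("generators are pure functions of the seed", {
  spec <- synthetic_spec(seed = 42)
  g1 <- generate_protein(spec)
  g2 <- generate_protein(spec)
  expect_identical(g1$seq$residues, g2$seq$residues)
  expect_identical(g1$occurrences, g2$occurrences)
  f1 <- generate_allele_family(spec)
  f2 <- generate_allele_family(spec)
  expect_identical(
    lapply(f1$alleles$alleles, `[[`, "residues"),
    lapply(f2$alleles$alleles, `[[`, "residues"))
  expect_false(identical(g1$seq$residues,
                         generate_protein(synthetic_spec(seed = 43))$seq$residues))
})

test_that("planted fragments occur exactly at their stated multiplicity", {
  spec <- synthetic_spec(seed = 9, protein_length = 50,
                         planted_fragments = list(
                           list(peptide = "GY", activity = "ACE-I",
                                multiplicity = 2L)),
                         planted_cut_residues = list(
                           list(residue = "K", count = 3L)))
  gen <- generate_protein(spec)
  db <- bioactive_db(list(GY = "ACE-I"))
  occ <- find_occurrences(gen$seq, db)
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$start, gen$occurrences$start)
  expect_equal(compute_A(gen$seq, db, "ACE-I"), 2 / 50)
})

test_that("planted cleavage residues drive the engine's cut sites", {
  spec <- synthetic_spec(seed = 10, protein_length = 50,
                         planted_cut_residues = list(
                           list(residue = "K", count = 3L)))
  gen <- generate_protein(spec)
  enz <- synthetic_enzymes(spec)
  expect_identical(cut_sites(gen$seq, enz), gen$cut_sites)
  # planted K count equals sites unless a K is terminal
  chars <- strsplit(gen$seq$residues, "")[[1]]
  expect_equal(length(gen$cut_sites),
               sum(chars == "K") - (chars[length(chars)] == "K"))
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(protein_length = 5), "too small")
  expect_error(synthetic_spec(planted_fragments = list(
    list(peptide = "GY", activity = "A", multiplicity = 1L)),
    planted_cut_residues = list(list(residue = "G", count = 1L))),
    "disjoint")
})

test_that("allele families record edits that explain every difference", {
  spec <- synthetic_spec(seed = 11, n_alleles = 4, protein_length = 80)
  fam <- generate_allele_family(spec)
  ref <- fam$alleles$alleles$ref
  for (lab in setdiff(names(fam$alleles$alleles), "ref")) {
    v <- fam$alleles$alleles[[lab]]
    # recorded edits reproduce the variant from the reference
    expect_identical(apply_edits(ref, fam$edits[[lab]], lab)$residues,
                     v$residues)
    # diff recovers the same substitution set
    d <- diff_alleles(ref, v)
    expect_setequal(
      vapply(d, function(e) paste(e$position, e$ref, e$alt), character(1)),
      vapply(fam$edits[[lab]], function(e) paste(e$position, e$ref, e$alt),
             character(1)))
  }
})

test_that("variant edits create or destroy planted content as recorded", {
  spec <- synthetic_spec(seed = 12, n_alleles = 4, protein_length = 80)
  fam <- generate_allele_family(spec)
  enz <- synthetic_enzymes(spec)
  db <- bioactive_db(list(GY = "ACE-I", PW = "DPP-IV-I"))
  for (lab in names(fam$alleles$alleles)) {
    s <- fam$alleles$alleles[[lab]]
    tr <- fam$ground_truth[[lab]]
    expect_identical(cut_sites(s, enz), tr$cut_sites, info = lab)
    got <- find_occurrences(s, db)
    expect_equal(nrow(got), nrow(tr$occurrences), info = lab)
    if (nrow(got) > 0) expect_equal(got$start, tr$occurrences$start)
  }
  # at least one variant differs from the reference in truth
  n_ref <- nrow(fam$ground_truth$ref$occurrences) +
    length(fam$ground_truth$ref$cut_sites)
  others <- vapply(setdiff(names(fam$ground_truth), "ref"), function(l) {
    nrow(fam$ground_truth[[l]]$occurrences) +
      length(fam$ground_truth[[l]]$cut_sites)
  }, numeric(1))
  expect_true(any(others != n_ref))
})

test_that("synthetic databases contain decoys that never occur", {
  spec <- synthetic_spec(seed = 13)
  gen <- generate_db_and_scores(spec, dir = withr::local_tempdir())
  fam <- generate_allele_family(spec)
  planted <- vapply(spec$planted_fragments, `[[`, character(1), "peptide")
  decoys <- setdiff(names(gen$db$records), planted)
  expect_gte(length(decoys), 1L)
  for (s in fam$alleles$alleles) {
    occ <- find_occurrences(s, gen$db)
    expect_true(all(occ$peptide %in% planted))
  }
  # written tables round-trip through the standard loaders
  db2 <- suppressMessages(load_peptide_db(gen$db_path))
  expect_identical(db2$records, gen$db$records)
  sc2 <- load_scores(gen$score_path)
  expect_equal(sc2[names(gen$scores)], gen$scores)
})

test_that("sub-threshold planted peptides are excluded downstream", {
  spec <- synthetic_spec(
    seed = 14, flank_fragments = TRUE,
    planted_fragments = list(
      list(peptide = "GY", activity = "ACE-I", multiplicity = 2L,
           score = 0.9),
      list(peptide = "PW", activity = "DPP-IV-I", multiplicity = 1L,
           score = 0.4)))
  sim <- simulate_study(spec)
  for (al in names(sim$candidates)) {
    expect_false("PW" %in% sim$candidates[[al]]$peptide)
  }
  expect_true(sim$exact_recovery)
})
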