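test_that("the occurrence frequency equals count over length", {
  db <- bioactive_db(list(GY = "ACE-I"))
  expect_equal(compute_A("GYGY", db, "ACE-I"), 0.5)
  expect_equal(compute_A("AAAA", db, "ACE-I"), 0)
  expect_error(compute_A("GYGY", db, "NOPE"), "unknown activity")
})

test_that("A times N recovers the brute-force occurrence count exactly", {
  set.seed(301)
  for (i in 1:30) {
    records <- random_db_records(8)
    db <- bioactive_db(records)
    s <- random_residues(sample(20:50, 1))
    occ <- oracle_occurrences(s, db$records)
    for (act in unique(unlist(records))) {
      a_val <- compute_A(s, db, act)
      expect_identical(a_val * nchar(s), as.numeric(sum(occ$activity == act)))
    }
  }
})

test_that("profiles sum A over activities and omit zero activities", {
  # two activities on disjoint planted fragments, once each in a 10-mer
  db <- bioactive_db(list(GY = "ACT1", PW = "ACT2"))
  prof <- compute_profile("AGYAAPWAAA", db)
  expect_equal(prof$sigma_A, 0.2)
  expect_equal(unname(prof$A_by_activity), c(0.1, 0.1))

  empty <- compute_profile("AGYAAPWAAA", bioactive_db(list()))
  expect_equal(empty$sigma_A, 0)
  expect_length(empty$A_by_activity, 0L)

  none <- compute_profile("AAAA", db)
  expect_length(none$A_by_activity, 0L) # zero-occurrence codes omitted
})

test_that("sigma_A equals the oracle sum over all occurrence triples", {
  set.seed(302)
  for (i in 1:30) {
    db <- bioactive_db(random_db_records(10))
    s <- random_residues(sample(20:60, 1))
    prof <- compute_profile(s, db)
    occ <- oracle_occurrences(s, db$records)
    expect_equal(prof$sigma_A, nrow(occ) / nchar(s), tolerance = 1e-12)
    expect_equal(sum(prof$A_by_activity), prof$sigma_A, tolerance = 1e-12)
  }
})

test_that("planted fragments give A exactly k over N", {
  spec <- synthetic_spec(seed = 5, protein_length = 40,
                         planted_fragments = list(
                           list(peptide = "GY", activity = "ACE-I",
                                multiplicity = 2L)))
  gen <- generate_protein(spec)
  db <- bioactive_db(list(GY = "ACE-I"))
  expect_identical(compute_A(gen$seq, db, "ACE-I"), 2 / 40)
})

test_that("annotation keeps unregistered peptides visible", {
  db <- fixture_db()
  ann <- annotate_peptides(c("AIPPK", "ACL"), db)
  expect_setequal(strsplit(ann$activities[1], ";")[[1]],
                  c("A-A-I", "ACE-I", "AT", "AO", "A-I", "DPP-IV-I", "A-G-I",
                    "ACE2-I"))
  expect_true(ann$registered[1])
  expect_false(ann$registered[2])
  expect_equal(ann$n_activities[2], 0L)
  expect_equal(nrow(annotate_peptides(character(0), db)), 0L)
})

test_that("matrix cells count distinct peptide sequences per activity", {
  db <- fixture_db()
  ann <- annotate_peptides(c("PL", "PF"), db)
  m <- build_matrix(list(al1 = ann))
  expect_equal(m["al1", "ACE-I"], 1L)
  expect_equal(m["al1", "DPP-IV-I"], 2L)
  expect_equal(m["al1", "DPP-III-I"], 1L)
  expect_equal(m["al1", "X-P-I"], 1L)
  expect_equal(m["al1", "L-I"], 1L)
  expect_equal(m["al1", "ACE2-I"], 1L)

  # duplicate sequences count once; empty annotation gives a zero row
  ann_dup <- annotate_peptides(c("PL", "PL"), db)
  m2 <- build_matrix(list(x = ann_dup, y = annotate_peptides(character(0), db)),
                     registry = colnames(m))
  expect_equal(m2["x", "ACE-I"], 1L)
  expect_true(all(m2["y", ] == 0L))

  # row sums equal the summed activity-set sizes of distinct peptides
  expect_equal(sum(m["al1", ]),
               length(lookup(db, "PL")) + length(lookup(db, "PF")))
})

test_that("matrix and profiles are invariant to allele input order", {
  db <- fixture_db()
  a1 <- annotate_peptides(c("PL", "GY"), db)
  a2 <- annotate_peptides(c("PF", "QF"), db)
  reg <- load_activity_registry()$code
  m12 <- build_matrix(list(x = a1, y = a2), registry = reg)
  m21 <- build_matrix(list(y = a2, x = a1), registry = reg)
  expect_equal(m12["x", ], m21["x", ])
  expect_equal(m12["y", ], m21["y", ])
})

test_that("registry fixes the matrix column set including zero columns", {
  db <- fixture_db()
  reg <- load_activity_registry()
  m <- build_matrix(list(a = annotate_peptides("PL", db)),
                    registry = reg$code)
  expect_equal(colnames(m), reg$code)
  expect_true(all(m[, "CaMPDE-I"] == 0L))
})

test_that("allele-specific peptides are those present in exactly one allele", {
  sets <- list(A = c("PL", "GY", "QF"), B = c("PL", "QF"), C = c("PL", "STF"))
  sp <- allele_specific_peptides(sets)
  expect_equal(sp$peptide, c("GY", "STF"))
  expect_equal(sp$allele, c("A", "C"))
  expect_equal(nrow(allele_specific_peptides(list(A = "PL", B = "PL"))), 0L)
})
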