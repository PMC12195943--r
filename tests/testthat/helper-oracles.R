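# Independent brute-force oracles: deliberately naive implementations used to
# cross-check the package, never calling the code paths they verify.

# Cut sites by testing every inter-residue boundary against every rule.
oracle_cut_sites <- function(residues, enzymes) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  fires <- function(p) {
    for (enz in enzymes) {
      for (rule in enz$rules) {
        if (rule$side == "C-terminal") {
          if (chars[p] == rule$residue &&
              !(chars[p + 1L] %in% rule$blocked_by_next)) return(TRUE)
        } else {
          if (chars[p + 1L] == rule$residue &&
              !(chars[p] %in% rule$blocked_by_next)) return(TRUE)
        }
      }
    }
    FALSE
  }
  which(vapply(seq_len(n - 1L), fires, logical(1)))
}

# Exhaustive substring scan: every (peptide, activity, start) triple.
oracle_occurrences <- function(residues, records) {
  n <- nchar(residues)
  rows <- list()
  for (pep in names(records)) {
    L <- nchar(pep)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      if (substr(residues, i, i + L - 1L) == pep) {
        for (act in records[[pep]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = pep, activity = act, start = i, end = i + L - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), activity = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$peptide, out$activity), , drop = FALSE]
}

# All cut-bounded intervals by brute-force boundary-pair enumeration.
oracle_partial_intervals <- function(residues, sites) {
  bounds <- c(0L, sites, nchar(residues))
  out <- list()
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (bounds[i] < bounds[j]) {
        out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j])
      }
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Naive overlapping-substring start positions.
match_starts_oracle <- function(residues, pattern) {
  L <- nchar(pattern)
  n <- nchar(residues)
  if (L > n) return(integer(0))
  which(vapply(seq_len(n - L + 1L), function(i) {
    substr(residues, i, i + L - 1L) == pattern
  }, logical(1)))
}

random_residues <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_db_records <- function(n_peptides, activities = c("X1", "X2", "X3"),
                              len_range = 2:3) {
  peps <- unique(replicate(n_peptides, random_residues(sample(len_range, 1))))
  stats::setNames(
    lapply(peps, function(p) sample(activities, sample(1:2, 1))), peps)
}

fixture_db <- function() {
  suppressMessages(load_peptide_db(pep_example("peptide_activity_db.tsv")))
}

fixture_scores <- function() load_scores(pep_example("peptide_scores.tsv"))
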