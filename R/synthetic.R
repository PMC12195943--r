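#' Specification for synthetic proteins with planted ground truth
#'
#' The generator reserves disjoint residue alphabets for background filler,
#' planted bioactive fragments, planted cleavage residues and database decoys.
#' Because the alphabets are disjoint and planted tokens are separated by at
#' least one background residue, every downstream quantity (occurrence counts,
#' cut sites, released peptides) is known exactly a priori — recovery tests
#' assert equality, not statistics. A fragment's residues may repeat within
#' itself, but fragments cannot arise by accident in background or decoys.
#'
#' @param seed Integer seed; all generators are pure functions of it.
#' @param protein_length Total residues per generated protein.
#' @param n_alleles Number of alleles in a generated family (>= 2 for
#'   [generate_allele_family()]); the first is the reference.
#' @param n_edits_per_allele Edits applied to each non-reference variant.
#' @param planted_fragments List of fragment descriptors: `list(peptide =,
#'   activity =, multiplicity =, score =)`; `score` defaults to 0.9.
#' @param planted_cut_residues List of `list(residue =, count =)` entries;
#'   each planted residue is a C-terminal cleavage target.
#' @param flank_fragments If `TRUE`, each planted fragment is laid out between
#'   a `flank_open` residue (C-terminal cleavage target) and a `flank_close`
#'   residue (N-terminal cleavage target), so complete digestion with
#'   [synthetic_enzymes()] releases the planted peptide exactly — the setting
#'   used for end-to-end pipeline recovery.
#' @param flank_open,flank_close Reserved flank residues (only used when
#'   `flank_fragments = TRUE`).
#' @param decoy_alphabet Residues reserved for database decoys (never used in
#'   generated proteins).
#' @param n_decoys Number of decoy peptides written to the synthetic database.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           protein_length = 60L,
                           n_alleles = 3L,
                           n_edits_per_allele = 1L,
                           planted_fragments = list(
                             list(peptide = "GY", activity = "ACE-I",
                                  multiplicity = 2L),
                             list(peptide = "PW", activity = "DPP-IV-I",
                                  multiplicity = 1L)),
                           planted_cut_residues = list(
                             list(residue = "K", count = 2L)),
                           flank_fragments = FALSE,
                           flank_open = "R",
                           flank_close = "I",
                           decoy_alphabet = c("C", "H", "M"),
                           n_decoys = 3L) {
  planted_fragments <- lapply(planted_fragments, function(f) {
    f$multiplicity <- as.integer(f$multiplicity %||% 1L)
    f$score <- f$score %||% 0.9
    stopifnot(nchar(f$peptide) >= 2L, f$multiplicity >= 1L,
              f$score >= 0, f$score <= 1, !is.null(f$activity))
    f
  })
  frag_alpha <- sort(unique(unlist(strsplit(
    vapply(planted_fragments, `[[`, character(1), "peptide"), ""))))
  cut_alpha <- sort(unique(vapply(planted_cut_residues, `[[`, character(1),
                                  "residue")))
  flank_alpha <- if (flank_fragments) c(flank_open, flank_close)
                 else character(0)
  reserved <- c(frag_alpha, cut_alpha, flank_alpha, decoy_alphabet)
  if (anyDuplicated(reserved)) {
    stop("fragment, cleavage and decoy alphabets must be disjoint; shared: ",
         paste(unique(reserved[duplicated(reserved)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(reserved, aa_alphabet())) > 0L) {
    stop("reserved alphabets contain invalid residue codes", call. = FALSE)
  }
  background <- setdiff(aa_alphabet(), reserved)
  if (length(background) < 2L) {
    stop("background alphabet too small after reserving planted residues",
         call. = FALSE)
  }
  flank_pad <- if (flank_fragments) 2L else 0L
  tokens_len <- sum(vapply(planted_fragments, function(f) {
    (nchar(f$peptide) + flank_pad) * f$multiplicity
  }, numeric(1))) +
    sum(vapply(planted_cut_residues, function(cr) cr$count, numeric(1)))
  n_tokens <- sum(vapply(planted_fragments, `[[`, integer(1),
                         "multiplicity")) +
    sum(vapply(planted_cut_residues, function(cr) as.integer(cr$count),
               integer(1)))
  if (protein_length < tokens_len + (n_tokens - 1L)) {
    stop("protein_length (", protein_length, ") too small for ", n_tokens,
         " planted token(s) of total length ", tokens_len,
         " with separating gaps", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), protein_length = as.integer(protein_length),
         n_alleles = as.integer(n_alleles),
         n_edits_per_allele = as.integer(n_edits_per_allele),
         planted_fragments = planted_fragments,
         planted_cut_residues = planted_cut_residues,
         flank_fragments = isTRUE(flank_fragments),
         flank_open = flank_open, flank_close = flank_close,
         fragment_alphabet = frag_alpha, cut_alphabet = cut_alpha,
         decoy_alphabet = decoy_alphabet, background_alphabet = background,
         n_decoys = as.integer(n_decoys)),
    class = "synthetic_spec"
  )
}

# Lay out planted tokens separated by >= 1 background residue; returns the
# residue string plus the 1-based start of every token.
layout_tokens <- function(spec) {
  tokens <- list()
  for (f in spec$planted_fragments) {
    emitted <- if (spec$flank_fragments) {
      paste0(spec$flank_open, f$peptide, spec$flank_close)
    } else {
      f$peptide
    }
    for (i in seq_len(f$multiplicity)) {
      tokens[[length(tokens) + 1L]] <- list(
        type = "fragment", string = emitted, peptide = f$peptide,
        pep_offset = if (spec$flank_fragments) 1L else 0L,
        activity = f$activity)
    }
  }
  for (cr in spec$planted_cut_residues) {
    for (i in seq_len(cr$count)) {
      tokens[[length(tokens) + 1L]] <- list(type = "cut", string = cr$residue,
                                            activity = NA_character_)
    }
  }
  tokens <- tokens[sample.int(length(tokens))]
  n_tok <- length(tokens)
  tok_len <- sum(vapply(tokens, function(t) nchar(t$string), integer(1)))
  bg_total <- spec$protein_length - tok_len
  # gap sizes: internal gaps >= 1, terminal gaps >= 0
  gaps <- c(0L, rep(1L, n_tok - 1L), 0L)
  extra <- bg_total - sum(gaps)
  if (extra > 0L) {
    add <- tabulate(sample.int(n_tok + 1L, extra, replace = TRUE),
                    nbins = n_tok + 1L)
    gaps <- gaps + add
  }
  bg <- function(k) if (k == 0L) "" else
    paste(sample(spec$background_alphabet, k, replace = TRUE), collapse = "")
  pieces <- character(0)
  starts <- integer(n_tok)
  pos <- 0L
  for (i in seq_len(n_tok)) {
    g <- bg(gaps[i])
    pieces <- c(pieces, g)
    pos <- pos + nchar(g)
    starts[i] <- pos + 1L
    pieces <- c(pieces, tokens[[i]]$string)
    pos <- pos + nchar(tokens[[i]]$string)
  }
  pieces <- c(pieces, bg(gaps[n_tok + 1L]))
  pep_starts <- starts + vapply(tokens, function(t) t$pep_offset %||% 0L,
                                integer(1))
  list(residues = paste(pieces, collapse = ""), tokens = tokens,
       starts = starts, pep_starts = pep_starts)
}

# Ground truth for a residue string built from a spec: planted-fragment
# occurrences and expected C-terminal cut sites, read off the reserved
# alphabets (valid because they are disjoint from the background).
ground_truth_from_residues <- function(spec, residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  occ <- list()
  for (f in spec$planted_fragments) {
    L <- nchar(f$peptide)
    if (L > n) next
    starts <- which(vapply(seq_len(n - L + 1L), function(i) {
      substr(residues, i, i + L - 1L) == f$peptide
    }, logical(1)))
    if (length(starts) > 0L) {
      occ[[length(occ) + 1L]] <- data.frame(
        peptide = f$peptide, activity = f$activity, start = starts,
        end = starts + L - 1L, stringsAsFactors = FALSE)
    }
  }
  occ <- if (length(occ)) do.call(rbind, occ) else
    data.frame(peptide = character(0), activity = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  occ <- occ[order(occ$start, occ$peptide, occ$activity), , drop = FALSE]
  rownames(occ) <- NULL
  c_targets <- spec$cut_alphabet
  if (spec$flank_fragments) c_targets <- c(c_targets, spec$flank_open)
  cut_idx <- which(chars %in% c_targets)
  sites <- cut_idx[cut_idx < n]
  if (spec$flank_fragments) {
    n_idx <- which(chars == spec$flank_close)
    sites <- sort(unique(c(sites, n_idx[n_idx > 1L] - 1L)))
  }
  bounds <- c(0L, sites, n)
  peptides <- substring(residues, bounds[-length(bounds)] + 1L, bounds[-1L])
  list(occurrences = occ, cut_sites = sites, complete_peptides = peptides)
}

#' Generate one synthetic protein with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param id,allele Labels for the generated sequence.
#' @return List with `seq` (a `protein_seq`), `occurrences` (data frame:
#'   peptide, activity, start, end of every planted fragment), `cut_sites`
#'   (expected cleavage sites for C-terminal rules on the planted cleavage
#'   residues), and `complete_peptides` (expected complete-digest fragments).
#' @export
generate_protein <- function(spec, id = "synthetic", allele = "ref") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lay <- layout_tokens(spec)
    truth <- ground_truth_from_residues(spec, lay$residues)
    c(list(seq = protein_sequence(id, lay$residues, gene = "SYNT",
                                  allele = allele)),
      truth)
  })
}

#' Generate an allele family with recorded edits and per-allele ground truth
#'
#' The reference is generated as in [generate_protein()]; each further allele
#' applies `n_edits_per_allele` substitutions that deterministically create or
#' destroy planted content, cycling through three edit kinds: destroying a
#' planted fragment occurrence (first residue -> background), destroying a
#' planted cleavage residue (-> background), and creating a cleavage site
#' (background residue -> cleavage residue). Per-allele differences in
#' occurrences, cut sites and released peptides are therefore known a priori.
#'
#' @param spec A [synthetic_spec()] with `n_alleles >= 2`.
#' @return List with `alleles` (an [allele_set()]), `edits` (named list of
#'   [variant_edit()] lists), and `ground_truth` (named list per allele:
#'   occurrences, cut_sites, complete_peptides).
#' @export
generate_allele_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_alleles >= 2L)
  with_seed(spec$seed, {
    lay <- layout_tokens(spec)
    ref <- protein_sequence("synthetic", lay$residues, gene = "SYNT",
                            allele = "ref")
    alleles <- list(ref = ref)
    edits <- list(ref = list())
    kinds <- c("destroy_fragment", "destroy_cut", "create_cut")
    frag_idx <- which(vapply(lay$tokens, `[[`, character(1), "type") ==
                        "fragment")
    cut_idx <- which(vapply(lay$tokens, `[[`, character(1), "type") == "cut")
    chars <- strsplit(lay$residues, "", fixed = TRUE)[[1]]
    pick1 <- function(x) x[sample.int(length(x), 1L)]
    kind_i <- 0L
    for (v in seq_len(spec$n_alleles - 1L)) {
      label <- paste0("var", v)
      elist <- list()
      used_pos <- integer(0)
      for (e in seq_len(spec$n_edits_per_allele)) {
        kind_i <- kind_i + 1L
        kind <- kinds[(kind_i - 1L) %% length(kinds) + 1L]
        edit <- NULL
        if (kind == "destroy_fragment" && length(frag_idx) > 0L) {
          tk <- pick1(frag_idx)
          p <- lay$pep_starts[tk]
          if (!(p %in% used_pos)) {
            edit <- variant_edit("substitution", p, ref = chars[p],
                                 alt = sample(spec$background_alphabet, 1L))
          }
        } else if (kind == "destroy_cut" && length(cut_idx) > 0L) {
          tk <- pick1(cut_idx)
          p <- lay$starts[tk]
          if (!(p %in% used_pos)) {
            edit <- variant_edit("substitution", p, ref = chars[p],
                                 alt = sample(spec$background_alphabet, 1L))
          }
        }
        if (is.null(edit)) { # create_cut, or fallback when position taken
          bg_pos <- setdiff(which(chars %in% spec$background_alphabet),
                            used_pos)
          p <- pick1(bg_pos)
          alt_cut <- if (length(spec$cut_alphabet) > 0L) spec$cut_alphabet[1]
                     else if (spec$flank_fragments) spec$flank_open
                     else pick1(setdiff(spec$background_alphabet, chars[p]))
          edit <- variant_edit("substitution", p, ref = chars[p],
                               alt = alt_cut)
        }
        used_pos <- c(used_pos, edit$position)
        elist[[length(elist) + 1L]] <- edit
      }
      alleles[[label]] <- apply_edits(ref, elist, new_allele = label,
                                      new_id = paste0("synthetic:", label))
      edits[[label]] <- elist
    }
    truth <- lapply(alleles, function(s) {
      ground_truth_from_residues(spec, s$residues)
    })
    list(alleles = allele_set("SYNT", "ref", alleles), edits = edits,
         ground_truth = truth)
  })
}

#' Synthetic enzymes matching the planted cleavage residues
#'
#' One enzyme with a C-terminal rule per planted cleavage residue, so the
#' engine's cut sites are exactly the planted positions.
#'
#' @param spec A [synthetic_spec()].
#' @return List with one [enzyme()].
#' @export
synthetic_enzymes <- function(spec) {
  targets <- spec$cut_alphabet
  if (spec$flank_fragments) targets <- unique(c(targets, spec$flank_open))
  rules <- lapply(targets, cleavage_rule, side = "C-terminal")
  if (spec$flank_fragments) {
    rules <- c(rules, list(cleavage_rule(spec$flank_close,
                                         side = "N-terminal")))
  }
  list(synthase = enzyme("synthetic-protease", "0.0.0.0", rules))
}

#' Write a synthetic peptide database and score table
#'
#' The database holds every planted fragment with its activity plus decoy
#' peptides over the reserved decoy alphabet (which never occurs in any
#' generated protein, so decoys have zero occurrences by construction). The
#' score table carries each planted fragment's configured score and 0.9 for
#' decoys.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Directory for the two TSV files.
#' @return List with `db` (a [bioactive_db()]), `scores` (named numeric),
#'   `db_path`, `score_path`.
#' @export
generate_db_and_scores <- function(spec, dir = tempdir()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    records <- list()
    scores <- numeric(0)
    for (f in spec$planted_fragments) {
      records[[f$peptide]] <- unique(c(records[[f$peptide]], f$activity))
      scores[f$peptide] <- f$score
    }
    for (i in seq_len(spec$n_decoys)) {
      len <- sample(2:4, 1L)
      pep <- paste(sample(spec$decoy_alphabet, len, replace = TRUE),
                   collapse = "")
      records[[pep]] <- unique(c(records[[pep]], "DECOY"))
      scores[pep] <- 0.9
    }
    db <- bioactive_db(records, source = "synthetic")
    db_df <- do.call(rbind, lapply(names(db$records), function(p) {
      data.frame(peptide = p, activity_code = db$records[[p]],
                 stringsAsFactors = FALSE)
    }))
    db_path <- file.path(dir, sprintf("synthetic_db_seed%d.tsv", spec$seed))
    score_path <- file.path(dir,
                            sprintf("synthetic_scores_seed%d.tsv", spec$seed))
    write_tsv(db_df, db_path)
    write_tsv(data.frame(peptide = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE), score_path)
    list(db = db, scores = scores, db_path = db_path, score_path = score_path)
  })
}
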