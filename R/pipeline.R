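#' Validated pipeline configuration
#'
#' Collects every input of the end-to-end analysis. All referenced paths are
#' checked at construction time so failures happen before any computation.
#'
#' @param fasta Character vector of FASTA paths with the allele sequences
#'   (header dialect `>id gene=<g> allele=<a>`).
#' @param edits Optional list of `list(reference_id =, new_allele =, path =)`
#'   entries: each applies an edit-list file to a loaded reference sequence to
#'   construct a variant not present in the FASTA input (e.g. alleles known
#'   only from literature-described substitutions).
#' @param enzyme_table Path to a YAML specificity table; default bundled
#'   three-enzyme table.
#' @param db Path to the peptide-activity TSV.
#' @param scores Path to the peptide-score TSV.
#' @param registry Optional path to an activity-registry TSV fixing the
#'   matrix columns.
#' @param policy A [filter_policy()].
#' @param mode Digestion mode, `"complete"` (default) or `"partial"`.
#' @param signal_peptide_trim Residues to drop from each N-terminus before
#'   analysis (0 = precursor frame); the frame is recorded in the manifest.
#' @param outdir Output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, db, scores,
                            edits = list(),
                            enzyme_table = pep_example("enzymes.yaml"),
                            registry = pep_example("activity_registry.tsv"),
                            policy = filter_policy(),
                            mode = c("complete", "partial"),
                            signal_peptide_trim = 0L,
                            outdir = tempfile("pepdigest_run_")) {
  mode <- match.arg(mode)
  for (p in c(fasta, enzyme_table, db, scores,
              vapply(edits, `[[`, character(1), "path"),
              if (!is.null(registry)) registry)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outdir, call. = FALSE)
  }
  stopifnot(inherits(policy, "filter_policy"))
  structure(
    list(fasta = fasta, edits = edits, enzyme_table = enzyme_table,
         db = db, scores = scores, registry = registry, policy = policy,
         mode = mode, signal_peptide_trim = as.integer(signal_peptide_trim),
         outdir = outdir),
    class = "pipeline_config"
  )
}

allele_label <- function(s) {
  if (!is.na(s$gene) && !is.na(s$allele)) paste(s$gene, s$allele, sep = ":")
  else s$id
}

#' Run the end-to-end analysis
#'
#' Stages: load sequences (and construct edited variants), trim signal
#' peptides, digest each allele, filter candidates by score and length,
#' annotate with database activities, compute per-allele occurrence profiles
#' (A and its sum), build the allele-by-activity matrix, and report
#' allele-specific released peptides per gene. All tables are written to
#' `config$outdir` with stable sort orders, so re-running an identical
#' configuration produces byte-identical output; a JSON manifest records
#' input hashes, parameters and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-allele digests, candidates,
#'   annotations, profiles, the matrix, the allele-specific peptide table and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seqs <- unlist(lapply(config$fasta, read_fasta), recursive = FALSE)
  names(seqs) <- vapply(seqs, `[[`, character(1), "id")
  for (ed in config$edits) {
    ref <- seqs[[ed$reference_id]]
    if (is.null(ref)) {
      stop("edits stage: reference '", ed$reference_id, "' not found among ",
           "loaded sequences", call. = FALSE)
    }
    variant <- apply_edits(ref, read_edit_table(ed$path),
                           new_allele = ed$new_allele)
    seqs[[variant$id]] <- variant
  }
  if (config$signal_peptide_trim > 0L) {
    seqs <- lapply(seqs, trim_signal_peptide, n_trim = config$signal_peptide_trim)
  }
  labels <- vapply(seqs, allele_label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate gene:allele labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- labels
  seqs <- seqs[order(labels)]

  enzymes <- load_enzyme_table(config$enzyme_table)
  db <- load_peptide_db(config$db)
  scores <- load_scores(config$scores)
  registry <- if (!is.null(config$registry)) {
    load_activity_registry(config$registry)$code
  }

  digests <- lapply(seqs, digest, enzymes = enzymes, mode = config$mode)
  candidates <- lapply(digests, filter_candidates, scores = scores,
                       policy = config$policy)
  annotations <- lapply(candidates, annotate_peptides, db = db)
  profiles <- lapply(seqs, compute_profile, db = db)
  m <- build_matrix(annotations, registry = registry)

  genes <- vapply(seqs, `[[`, character(1), "gene")
  specific <- do.call(rbind, lapply(sort(unique(genes)), function(g) {
    members <- names(seqs)[genes == g]
    if (length(members) < 2L) return(NULL)
    released <- lapply(digests[members], function(d) unique(d$peptides$peptide))
    sp <- allele_specific_peptides(released)
    if (nrow(sp) == 0L) return(NULL)
    data.frame(gene = g, sp, stringsAsFactors = FALSE)
  }))
  if (is.null(specific)) {
    specific <- data.frame(gene = character(0), peptide = character(0),
                           allele = character(0), stringsAsFactors = FALSE)
  }

  out <- config$outdir
  digest_tbl <- do.call(rbind, lapply(names(digests), function(lab) {
    d <- digests[[lab]]
    data.frame(allele = lab, peptide = d$peptides$peptide,
               start = d$peptides$start, end = d$peptides$end,
               length = d$peptides$end - d$peptides$start + 1L,
               stringsAsFactors = FALSE)
  }))
  write_tsv(digest_tbl, file.path(out, "digests.tsv"))
  bind_with_allele <- function(tbls, template_cols) {
    rows <- lapply(names(tbls), function(lab) {
      if (nrow(tbls[[lab]]) == 0L) return(NULL)
      data.frame(allele = lab, tbls[[lab]], stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0L) return(do.call(rbind, rows))
    empty <- c(list(allele = character(0)),
               lapply(template_cols, function(x) x[0]))
    as.data.frame(empty, stringsAsFactors = FALSE)
  }
  cand_tbl <- bind_with_allele(candidates, candidates[[1]])
  write_tsv(cand_tbl, file.path(out, "candidates.tsv"))
  ann_tbl <- bind_with_allele(annotations, annotations[[1]])
  write_tsv(ann_tbl, file.path(out, "annotations.tsv"))
  for (i in seq_along(profiles)) {
    profiles[[i]]$sequence_id <- names(profiles)[i]
  }
  write_profiles_tsv(profiles, file.path(out, "activity"))
  write_matrix_tsv(m, file.path(out, "bioactivity_matrix"))
  write_tsv(specific, file.path(out, "allele_specific_peptides.tsv"))

  stage_counts <- lapply(names(seqs), function(lab) {
    list(n_residues = seqs[[lab]]$N,
         n_cut_sites = length(digests[[lab]]$cut_sites),
         n_fragments_intervals = digests[[lab]]$n_intervals,
         n_fragments_distinct = digests[[lab]]$n_distinct_sequences,
         n_candidates = nrow(candidates[[lab]]),
         n_registered = sum(annotations[[lab]]$registered),
         sigma_A = profiles[[lab]]$sigma_A)
  })
  names(stage_counts) <- names(seqs)
  manifest <- list(
    package = "pepdigest",
    version = as.character(utils::packageVersion("pepdigest")),
    mode = config$mode,
    signal_peptide_trim = config$signal_peptide_trim,
    position_frame = if (config$signal_peptide_trim > 0L) "mature"
                     else "precursor",
    policy = unclass(config$policy),
    inputs = lapply(
      stats::setNames(nm = c("fasta", "enzyme_table", "db", "scores")),
      function(k) {
        paths <- config[[k]]
        list(paths = basename(paths), md5 = unname(tools::md5sum(paths)))
      }),
    alleles = stage_counts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sequences = seqs, digests = digests, candidates = candidates,
                 annotations = annotations, profiles = profiles, matrix = m,
                 allele_specific = specific, manifest = manifest,
                 outdir = out))
}

#' Load per-allele release marks
#'
#' Long-format table saying which gene/allele releases which peptide — the
#' shape of a published release table. Columns: `peptide`, `gene`, `allele`.
#' The bundled fixture (`pep_example("allele_release_marks.tsv")`) encodes the
#' published release marks of the candidate peptides across the goat casein
#' alleles.
#'
#' @param path TSV file.
#' @return Data frame with columns peptide, gene, allele.
#' @export
load_release_marks <- function(path = pep_example("allele_release_marks.tsv")) {
  read_tsv_strict(path, c("peptide", "gene", "allele"))
}

#' Replay a precomputed released-peptide table
#'
#' Entry point for running the filter/annotate/matrix stages on a published
#' peptide table (peptide sequences, external scores, per-allele release
#' marks) without any sequence digestion — the route used to check the
#' pipeline's downstream stages against published per-allele candidate
#' counts.
#'
#' @param scores Named numeric score vector ([load_scores()]) or a path.
#' @param marks Release-marks data frame ([load_release_marks()]) or a path.
#' @param db A [bioactive_db()] or a path.
#' @param policy A [filter_policy()].
#' @param registry Optional activity-code character vector (or registry TSV
#'   path) fixing the matrix columns.
#' @param outdir Optional output directory for the TSV reports.
#' @return List with `candidates` (annotated candidate table), `per_gene` and
#'   `per_allele` candidate counts, `n_candidates`, `n_registered`,
#'   `n_multifunctional`, the bioactivity `matrix`, and `allele_specific`
#'   peptides per gene.
#' @export
replay_peptide_table <- function(scores, marks, db,
                                 policy = filter_policy(),
                                 registry = pep_example("activity_registry.tsv"),
                                 outdir = NULL) {
  if (is.character(scores)) scores <- load_scores(scores)
  if (is.character(marks)) marks <- load_release_marks(marks)
  if (is.character(db)) db <- load_peptide_db(db)
  if (is.character(registry)) registry <- load_activity_registry(registry)$code
  stopifnot(all(c("peptide", "gene", "allele") %in% names(marks)))

  cand <- filter_candidates(names(scores), scores, policy)
  cand <- annotate_peptides(cand, db)
  marks <- marks[marks$peptide %in% cand$peptide, , drop = FALSE]

  per_gene <- vapply(split(marks$peptide, marks$gene),
                     function(p) length(unique(p)), integer(1))
  lab <- paste(marks$gene, marks$allele, sep = ":")
  per_allele <- vapply(split(marks$peptide, lab),
                       function(p) length(unique(p)), integer(1))

  peps_by_allele <- split(marks$peptide, lab)
  ann_by_allele <- lapply(peps_by_allele, function(p) {
    cand[cand$peptide %in% p, , drop = FALSE]
  })
  m <- build_matrix(ann_by_allele, registry = registry)

  specific <- do.call(rbind, lapply(sort(unique(marks$gene)), function(g) {
    sub <- marks[marks$gene == g, , drop = FALSE]
    sp <- allele_specific_peptides(split(sub$peptide, sub$allele))
    if (nrow(sp) == 0L) return(NULL)
    data.frame(gene = g, sp, stringsAsFactors = FALSE)
  }))
  if (is.null(specific)) {
    specific <- data.frame(gene = character(0), peptide = character(0),
                           allele = character(0), stringsAsFactors = FALSE)
  }

  res <- list(candidates = cand,
              per_gene = per_gene[order(names(per_gene))],
              per_allele = per_allele[order(names(per_allele))],
              n_candidates = nrow(cand),
              n_registered = sum(cand$registered),
              n_multifunctional = sum(cand$n_activities >= 2L),
              matrix = m,
              allele_specific = specific)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_tsv(cand, file.path(outdir, "replay_candidates.tsv"))
    write_matrix_tsv(m, file.path(outdir, "replay_bioactivity_matrix"))
    write_tsv(specific, file.path(outdir, "replay_allele_specific.tsv"))
    counts <- data.frame(
      group = c("total", "registered", "multifunctional",
                paste0("gene:", names(res$per_gene)),
                paste0("allele:", names(res$per_allele))),
      n = c(res$n_candidates, res$n_registered, res$n_multifunctional,
            unname(res$per_gene), unname(res$per_allele)),
      stringsAsFactors = FALSE)
    write_tsv(counts, file.path(outdir, "replay_counts.tsv"))
  }
  res
}

#' Synthetic end-to-end study with exact ground-truth comparison
#'
#' Generates an allele family, a matching database/score table and enzymes
#' from one [synthetic_spec()] (with fragment flanks enabled so planted
#' peptides are released), runs digest -> filter -> annotate -> matrix ->
#' profiles, and compares every stage against the planted ground truth.
#'
#' @param spec A [synthetic_spec()]; `flank_fragments` is forced on.
#' @param outdir Optional output directory for TSV reports.
#' @return List with the pipeline results, the ground truth, and logical
#'   `exact_recovery` (TRUE iff every allele's candidate set, A values,
#'   matrix row and cut sites equal the planted truth).
#' @export
simulate_study <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$flank_fragments) {
    spec_args <- list(
      seed = spec$seed, protein_length = spec$protein_length,
      n_alleles = spec$n_alleles,
      n_edits_per_allele = spec$n_edits_per_allele,
      planted_fragments = spec$planted_fragments,
      planted_cut_residues = spec$planted_cut_residues,
      flank_fragments = TRUE, decoy_alphabet = spec$decoy_alphabet,
      n_decoys = spec$n_decoys)
    spec <- do.call(synthetic_spec, spec_args)
  }
  fam <- generate_allele_family(spec)
  gen <- generate_db_and_scores(spec)
  enzymes <- synthetic_enzymes(spec)
  alleles <- fam$alleles$alleles

  digests <- lapply(alleles, digest, enzymes = enzymes, mode = "complete")
  candidates <- lapply(digests, filter_candidates, scores = gen$scores,
                       policy = filter_policy())
  annotations <- lapply(candidates, annotate_peptides, db = gen$db)
  profiles <- lapply(alleles, compute_profile, db = gen$db)
  registry <- sort(unique(unlist(gen$db$records, use.names = FALSE)))
  m <- build_matrix(annotations, registry = registry)

  truth <- fam$ground_truth
  above <- names(gen$scores)[gen$scores > 0.5]
  expected_cand <- lapply(truth, function(tr) {
    peps <- unique(tr$occurrences$peptide)
    sort(peps[peps %in% above &
                nchar(peps) >= 2L & nchar(peps) <= 6L])
  })
  expected_A <- lapply(names(alleles), function(al) {
    tr <- truth[[al]]$occurrences
    n <- alleles[[al]]$N
    if (nrow(tr) == 0L) return(stats::setNames(numeric(0), character(0)))
    counts <- table(tr$activity)
    stats::setNames(as.numeric(counts) / n, names(counts))
  })
  names(expected_A) <- names(alleles)

  ok_cut <- all(vapply(names(alleles), function(al) {
    identical(digests[[al]]$cut_sites, truth[[al]]$cut_sites)
  }, logical(1)))
  ok_cand <- all(vapply(names(alleles), function(al) {
    identical(sort(candidates[[al]]$peptide), expected_cand[[al]])
  }, logical(1)))
  ok_A <- all(vapply(names(alleles), function(al) {
    got <- profiles[[al]]$A_by_activity
    want <- expected_A[[al]][order(names(expected_A[[al]]))]
    length(got) == length(want) && all(names(got) == names(want)) &&
      all(got == want)
  }, logical(1)))
  expected_matrix <- m * 0L
  for (al in names(alleles)) {
    for (p in expected_cand[[al]]) {
      acts <- intersect(gen$db$records[[p]], colnames(expected_matrix))
      expected_matrix[al, acts] <- expected_matrix[al, acts] + 1L
    }
  }
  ok_matrix <- identical(m, expected_matrix)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_matrix_tsv(m, file.path(outdir, "synthetic_bioactivity_matrix"))
    for (i in seq_along(profiles)) {
      profiles[[i]]$sequence_id <- names(profiles)[i]
    }
    write_profiles_tsv(profiles, file.path(outdir, "synthetic_activity"))
  }
  list(spec = spec, family = fam, db = gen$db, scores = gen$scores,
       digests = digests, candidates = candidates, annotations = annotations,
       profiles = profiles, matrix = m,
       expected_candidates = expected_cand, expected_A = expected_A,
       expected_matrix = expected_matrix,
       checks = c(cut_sites = ok_cut, candidates = ok_cand, A_values = ok_A,
                  matrix = ok_matrix),
       exact_recovery = ok_cut && ok_cand && ok_A && ok_matrix)
}
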