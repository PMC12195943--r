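#' Frequency of occurrence of bioactive fragments with one activity
#'
#' The occurrence-frequency statistic `A = a / N`, where `a` is the number of
#' positional occurrences of database fragments carrying the given activity in
#' the sequence (overlaps counted) and `N` is the residue count of the
#' sequence. Dimensionless, zero when no fragment occurs.
#'
#' @param seq A `protein_seq` or amino-acid string.
#' @param db A [bioactive_db()].
#' @param activity Activity code; must exist in the database.
#' @return A single nonnegative number, exactly `a / N`.
#' @export
compute_A <- function(seq, db, activity) {
  residues <- as_residues(seq)
  occ <- find_occurrences(residues, db, activity = activity)
  nrow(occ) / nchar(residues)
}

#' Per-activity occurrence profile and its unweighted sum
#'
#' Computes `A` for every activity present in the database and the unweighted
#' sum over activities (the sequence's overall bioactive-fragment load).
#' Activities with zero occurrences are omitted from the map (they contribute
#' 0 to the sum).
#'
#' @param seq A `protein_seq` or amino-acid string.
#' @param db A [bioactive_db()].
#' @return An object of class `activity_profile` with fields `sequence_id`,
#'   `A_by_activity` (named numeric), `sigma_A`, and `N`.
#' @export
compute_profile <- function(seq, db) {
  residues <- as_residues(seq)
  n <- nchar(residues)
  occ <- find_occurrences(residues, db)
  if (nrow(occ) == 0L) {
    a_by <- stats::setNames(numeric(0), character(0))
  } else {
    counts <- table(occ$activity)
    a_by <- as.numeric(counts) / n
    names(a_by) <- names(counts)
    a_by <- a_by[order(names(a_by))]
  }
  structure(
    list(sequence_id = seq_id(seq), A_by_activity = a_by,
         sigma_A = sum(a_by), N = n),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s (N=%d): sigma_A = %.4f over %d activit(ies)\n",
              x$sequence_id, x$N, x$sigma_A, length(x$A_by_activity)))
  invisible(x)
}

#' Annotate released peptides with database activities
#'
#' Each peptide is looked up exactly; unregistered peptides are retained with
#' an empty activity string and `registered = FALSE`, so filtering decisions
#' stay visible downstream.
#'
#' @param peptides Character vector of peptide sequences, or a data frame with
#'   a `peptide` column (e.g. `digest_result$peptides`); extra columns are
#'   carried through.
#' @param db A [bioactive_db()].
#' @return Data frame with columns peptide (plus any carried columns),
#'   activities (semicolon-joined codes), n_activities, registered.
#' @export
annotate_peptides <- function(peptides, db) {
  if (is.character(peptides)) {
    df <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(peptides), "peptide" %in% names(peptides))
    df <- peptides
  }
  acts <- lapply(df$peptide, function(p) lookup(db, p))
  df$activities <- vapply(acts, paste, character(1), collapse = ";")
  df$n_activities <- vapply(acts, length, integer(1))
  df$registered <- df$n_activities > 0L
  df
}

#' Allele-by-activity bioactivity matrix
#'
#' Each cell counts the *distinct peptide sequences* of an allele whose
#' annotation carries the activity — the quantitative content of a
#' bioactivity heatmap. Two alleles releasing the same peptide at different
#' positions contribute equally; duplicate sequences within an allele count
#' once. With a registry, the column set is fixed (zero columns kept) so
#' matrices from different inputs are comparable.
#'
#' @param annotations_by_allele Named list (allele label -> annotation data
#'   frame from [annotate_peptides()]).
#' @param registry Optional character vector of activity codes fixing the
#'   columns; defaults to all codes observed.
#' @return Integer matrix, rows = alleles, columns = activity codes.
#' @export
build_matrix <- function(annotations_by_allele, registry = NULL) {
  stopifnot(is.list(annotations_by_allele),
            length(annotations_by_allele) >= 1L,
            !is.null(names(annotations_by_allele)))
  split_acts <- function(s) if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]]
                            else character(0)
  per_allele <- lapply(annotations_by_allele, function(ann) {
    ann <- ann[!duplicated(ann$peptide), , drop = FALSE]
    lapply(stats::setNames(ann$activities, ann$peptide), split_acts)
  })
  if (is.null(registry)) {
    registry <- sort(unique(unlist(per_allele, use.names = FALSE)))
  }
  alleles <- names(annotations_by_allele)
  m <- matrix(0L, nrow = length(alleles), ncol = length(registry),
              dimnames = list(alleles, registry))
  for (al in alleles) {
    for (acts in per_allele[[al]]) {
      acts <- intersect(acts, registry)
      m[al, acts] <- m[al, acts] + 1L
    }
  }
  m
}

#' Peptides released by exactly one allele of a gene
#'
#' Mirrors per-allele release comparisons where allele-specific peptides mark
#' the functional consequence of a variant (e.g. an exon-loss allele releasing
#' a fragment no other allele does).
#'
#' @param peptides_by_allele Named list (allele label -> character vector of
#'   released peptide sequences).
#' @return Data frame with columns peptide, allele, sorted by peptide.
#' @export
allele_specific_peptides <- function(peptides_by_allele) {
  stopifnot(is.list(peptides_by_allele), !is.null(names(peptides_by_allele)))
  sets <- lapply(peptides_by_allele, unique)
  all_peps <- sort(unique(unlist(sets, use.names = FALSE)))
  rows <- lapply(all_peps, function(p) {
    carriers <- names(sets)[vapply(sets, function(s) p %in% s, logical(1))]
    if (length(carriers) == 1L) {
      data.frame(peptide = p, allele = carriers, stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), allele = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-activity profiles and their sums as TSV
#'
#' Two files: `<stem>_profile.tsv` (sequence_id, activity, A) and
#' `<stem>_summary.tsv` (sequence_id, sigma_A, N). `A` values are written with
#' 4 decimal places (full precision is kept in the objects).
#'
#' @param profiles List of [compute_profile()] results.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_profiles_tsv <- function(profiles, stem) {
  long <- do.call(rbind, lapply(profiles, function(p) {
    if (length(p$A_by_activity) == 0L) return(NULL)
    data.frame(sequence_id = p$sequence_id,
               activity = names(p$A_by_activity),
               A = sprintf("%.4f", p$A_by_activity),
               stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    long <- data.frame(sequence_id = character(0), activity = character(0),
                       A = character(0), stringsAsFactors = FALSE)
  }
  summary <- data.frame(
    sequence_id = vapply(profiles, `[[`, character(1), "sequence_id"),
    sigma_A = sprintf("%.4f", vapply(profiles, `[[`, numeric(1), "sigma_A")),
    N = vapply(profiles, `[[`, integer(1), "N"),
    stringsAsFactors = FALSE)
  p1 <- paste0(stem, "_profile.tsv")
  p2 <- paste0(stem, "_summary.tsv")
  write_tsv(long, p1)
  write_tsv(summary, p2)
  invisible(c(p1, p2))
}

#' Write a bioactivity matrix as TSV (wide and long form)
#'
#' @param m Matrix from [build_matrix()].
#' @param stem Output path stem; writes `<stem>.tsv` (wide, allele rows) and
#'   `<stem>_long.tsv` (allele, activity, count) for plotting.
#' @return Character vector of the two paths, invisibly.
#' @export
write_matrix_tsv <- function(m, stem) {
  wide <- data.frame(allele = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  long <- data.frame(
    allele = rep(rownames(m), times = ncol(m)),
    activity = rep(colnames(m), each = nrow(m)),
    count = as.integer(m), stringsAsFactors = FALSE)
  long <- long[order(long$allele, long$activity), , drop = FALSE]
  p1 <- paste0(stem, ".tsv")
  p2 <- paste0(stem, "_long.tsv")
  write_tsv(wide, p1)
  write_tsv(long, p2)
  invisible(c(p1, p2))
}

#' Heatmap of a bioactivity matrix
#'
#' Thin wrapper over `pheatmap` (if installed): white = activity absent,
#' shading proportional to the count. Intended for quick inspection, not
#' publication styling.
#'
#' @param m Matrix from [build_matrix()].
#' @param ... Passed to `pheatmap::pheatmap()`.
#' @return The pheatmap object, invisibly.
#' @export
plot_bioactivity_matrix <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_bioactivity_matrix needs the 'pheatmap' package", call. = FALSE)
  }
  invisible(pheatmap::pheatmap(
    m, cluster_rows = FALSE, cluster_cols = FALSE,
    color = grDevices::colorRampPalette(c("white", "#b2182b"))(32), ...))
}
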