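#' Construct a peptide-activity database
#'
#' Maps peptide sequences to sets of activity codes. Used both for
#' fragment-occurrence counting (the `A` statistic) and for annotating
#' released peptides. Matching is exact-sequence only: no Leu/Ile
#' equivalence, no modified residues.
#'
#' @param records Named list: peptide sequence -> character vector of activity
#'   codes. Peptides must be valid amino-acid strings of length >= 2.
#' @param source Label recorded in the metadata.
#' @return An object of class `bioactive_db`.
#' @export
bioactive_db <- function(records, source = "user") {
  stopifnot(is.list(records))
  if (length(records) > 0L && is.null(names(records))) {
    stop("records must be a named list (names = peptide sequences)",
         call. = FALSE)
  }
  for (pep in names(records)) {
    if (nchar(pep) < 2L) {
      stop("db peptide '", pep, "' is shorter than 2 residues", call. = FALSE)
    }
    bad <- invalid_residue_positions(pep)
    if (length(bad) > 0L) {
      stop("db peptide '", pep, "' has an invalid residue at position ",
           bad[1], call. = FALSE)
    }
    records[[pep]] <- sort(unique(as.character(records[[pep]])))
  }
  if (length(records) > 0L) {
    records <- records[order(names(records))] # stable iteration order
  }
  structure(list(records = records, source = source,
                 n_records = length(records)),
            class = "bioactive_db")
}

#' @export
print.bioactive_db <- function(x, ...) {
  acts <- sort(unique(unlist(x$records, use.names = FALSE)))
  cat(sprintf("<bioactive_db> %s: %d peptide(s), %d activit(ies)\n",
              x$source, x$n_records, length(acts)))
  invisible(x)
}

#' Load a peptide-activity database from TSV
#'
#' One row per peptide-activity pair, columns `peptide` and `activity_code`
#' (optional `description`, `reference` columns are ignored here but
#' tolerated). Duplicate rows collapse to one record. The bundled fixture
#' (`pep_example("peptide_activity_db.tsv")`) holds the registered candidate
#' peptides released by in silico digestion of the goat casein alleles with
#' their curated activities; it is a small excerpt, not a full bioactive-
#' peptide database, so whole-protein occurrence sums computed against it are
#' not comparable to values computed against the complete databases.
#'
#' @param path TSV file.
#' @param source Metadata label; defaults to the file name.
#' @return A [bioactive_db()].
#' @export
load_peptide_db <- function(path, source = basename(path)) {
  df <- read_tsv_strict(path, c("peptide", "activity_code"))
  for (i in seq_len(nrow(df))) {
    bad <- invalid_residue_positions(df$peptide[i])
    if (length(bad) > 0L) {
      stop("invalid peptide character in ", path, " at row ", i, " ('",
           df$peptide[i], "')", call. = FALSE)
    }
  }
  records <- split(df$activity_code, df$peptide)
  message("load_peptide_db: ", length(records), " peptide record(s) from ",
          nrow(df), " row(s) in ", basename(path))
  bioactive_db(lapply(records, function(a) sort(unique(a))), source = source)
}

#' Load an activity registry (code -> description)
#'
#' The registry fixes the column set of the bioactivity matrix, so activities
#' absent from every allele still appear as explicit zero columns. The bundled
#' registry (`pep_example("activity_registry.tsv")`) mirrors the activity
#' abbreviations observed for casein-derived peptides (ACE-I, DPP-IV-I, ...).
#'
#' @param path TSV with columns `code`, `description`.
#' @return Data frame with columns code, description.
#' @export
load_activity_registry <- function(path = pep_example("activity_registry.tsv")) {
  df <- read_tsv_strict(path, c("code", "description"))
  if (anyDuplicated(df$code)) {
    stop("duplicate activity code(s) in ", path, ": ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Activity codes of one peptide
#'
#' Exact-sequence lookup; an empty character vector means the peptide is not
#' registered in the database.
#'
#' @param db A [bioactive_db()].
#' @param peptide Peptide sequence.
#' @return Character vector of activity codes (possibly empty), sorted.
#' @export
lookup <- function(db, peptide) {
  stopifnot(inherits(db, "bioactive_db"), nchar(peptide) >= 1L)
  db$records[[toupper(peptide)]] %||% character(0)
}

# All 1-based start positions of `pattern` in `residues`, overlapping
# occurrences included.
match_starts <- function(residues, pattern) {
  if (nchar(pattern) > nchar(residues)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::BString(residues))
  as.integer(Biostrings::start(m))
}

#' Locate every database fragment inside a sequence
#'
#' Every (peptide, position) pair where a database peptide occurs as a
#' substring of the sequence is reported, overlapping occurrences included,
#' one row per (peptide, activity, start). This positional convention is what
#' the occurrence-frequency statistic `A` counts.
#'
#' @param seq A `protein_seq` or amino-acid string.
#' @param db A [bioactive_db()].
#' @param activity Optional activity code to restrict to; must exist in the
#'   database.
#' @return Data frame with columns peptide, activity, start, end, sorted by
#'   start then peptide then activity.
#' @export
find_occurrences <- function(seq, db, activity = NULL) {
  residues <- as_residues(seq)
  stopifnot(inherits(db, "bioactive_db"), nchar(residues) >= 1L)
  all_codes <- sort(unique(unlist(db$records, use.names = FALSE)))
  if (!is.null(activity) && !(activity %in% all_codes)) {
    stop("unknown activity code '", activity, "'", call. = FALSE)
  }
  rows <- list()
  for (pep in names(db$records)) {
    codes <- db$records[[pep]]
    if (!is.null(activity)) {
      if (!(activity %in% codes)) next
      codes <- activity
    }
    starts <- match_starts(residues, pep)
    if (length(starts) == 0L) next
    for (code in codes) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, activity = code, start = starts,
        end = starts + nchar(pep) - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), activity = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$peptide, out$activity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
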