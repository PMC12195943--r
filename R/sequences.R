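#' Protein sequence with gene/allele metadata
#'
#' The basic unit of the pipeline: an identified amino-acid string, optionally
#' tagged with the casein gene it comes from (CSN1S1, CSN2, CSN1S2, CSN3 for
#' the goat caseins, or any label for synthetic proteins) and an allele label.
#' Residue count `N` is the denominator of the occurrence frequency
#' `A = a / N`, so it is stored explicitly and always equals
#' `nchar(residues)`.
#'
#' @param id Sequence identifier (accession or allele label).
#' @param residues Amino-acid string over the one-letter alphabet.
#' @param gene Gene label, or `NA`.
#' @param allele Allele label, or `NA`.
#' @param alphabet Permitted residue codes; defaults to the 20 unambiguous
#'   codes, so B, Z and X are rejected.
#' @return An object of class `protein_seq`.
#' @export
protein_sequence <- function(id, residues, gene = NA_character_,
                             allele = NA_character_, alphabet = aa_alphabet()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) == 0L) {
    stop("protein sequence '", id, "' is empty", call. = FALSE)
  }
  bad <- invalid_residue_positions(residues, alphabet)
  if (length(bad) > 0L) {
    stop("invalid residue '", substr(residues, bad[1], bad[1]),
         "' in record '", id, "' at position ", bad[1], call. = FALSE)
  }
  structure(
    list(id = id, gene = as.character(gene), allele = as.character(allele),
         residues = residues, N = nchar(residues)),
    class = "protein_seq"
  )
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (gene=%s, allele=%s), N=%d\n",
              x$id, x$gene, x$allele, x$N))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

# Coerce a protein_seq or plain string to a residue string.
as_residues <- function(x) {
  if (inherits(x, "protein_seq")) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a protein_seq or a single amino-acid string", call. = FALSE)
}

seq_id <- function(x) if (inherits(x, "protein_seq")) x$id else "seq"

#' Read protein sequences from a FASTA file
#'
#' Headers may carry metadata in the dialect `>id gene=<g> allele=<a>`;
#' missing fields default to `NA`. Residues are uppercased, whitespace is
#' stripped, and a terminal stop-codon symbol `*` is removed (with a message).
#'
#' @param path FASTA file.
#' @param alphabet Permitted residue codes (see [protein_sequence()]).
#' @return A list of [protein_sequence()] objects.
#' @export
read_fasta <- function(path, alphabet = aa_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L || !startsWith(trimws(first[nonblank[1]]), ">")) {
    stop("malformed FASTA in ", path, ": expected '>' header at line ",
         if (length(nonblank)) nonblank[1] else 1L, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    tokens <- strsplit(trimws(header), "[[:space:]]+")[[1]]
    id <- tokens[1]
    gene <- sub("^gene=", "", grep("^gene=", tokens, value = TRUE))
    allele <- sub("^allele=", "", grep("^allele=", tokens, value = TRUE))
    residues <- toupper(gsub("[[:space:]]", "", as.character(set[[i]])))
    if (endsWith(residues, "*")) {
      message("read_fasta: removed terminal stop symbol '*' from record '",
              id, "'")
      residues <- substr(residues, 1L, nchar(residues) - 1L)
    }
    out[[i]] <- protein_sequence(
      id, residues,
      gene = if (length(gene)) gene[1] else NA_character_,
      allele = if (length(allele)) allele[1] else NA_character_,
      alphabet = alphabet
    )
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' Uses the same header dialect as [read_fasta()], so a write/read round trip
#' preserves id, residues, gene and allele.
#'
#' @param seqs A list of `protein_seq` objects (or a single one).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_seq")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s) {
    h <- s$id
    if (!is.na(s$gene)) h <- paste0(h, " gene=", s$gene)
    if (!is.na(s$allele)) h <- paste0(h, " allele=", s$allele)
    h
  }, character(1))
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Trim an N-terminal signal peptide
#'
#' Literature positions for casein variants sometimes refer to the precursor
#' (signal peptide included) and sometimes to the mature protein; this helper
#' switches frames. Reports downstream state which frame was used.
#'
#' @param seq A `protein_seq`.
#' @param n_trim Number of N-terminal residues to drop (0 = precursor frame).
#' @return A new `protein_seq`.
#' @export
trim_signal_peptide <- function(seq, n_trim = 0L) {
  stopifnot(inherits(seq, "protein_seq"), n_trim >= 0L)
  if (n_trim == 0L) return(seq)
  if (n_trim >= seq$N) {
    stop("signal peptide trim (", n_trim, ") >= sequence length (", seq$N, ")",
         call. = FALSE)
  }
  protein_sequence(seq$id, substr(seq$residues, n_trim + 1L, seq$N),
                   gene = seq$gene, allele = seq$allele)
}
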