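#' Standard amino-acid alphabet
#'
#' The 20 unambiguous one-letter residue codes. Ambiguity codes (B, Z, X) and
#' the rare extensions (U, O, J) are rejected by default throughout the
#' package; pass a custom `alphabet` to the constructors to widen it.
#'
#' @return Character vector of 20 one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run expr with a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed so generators behave as pure functions of their seed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Positions (1-based) where any invalid residue occurs; integer(0) if clean.
invalid_residue_positions <- function(residues, alphabet = aa_alphabet()) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  which(!(chars %in% alphabet))
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# All TSV output goes through one writer so reruns are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param name File name under the package's `extdata` directory; with no
#'   arguments, lists the available files.
#' @return Full path to the file.
#' @export
pep_example <- function(name = NULL) {
  if (is.null(name)) {
    return(list.files(system.file("extdata", package = "pepdigest")))
  }
  path <- system.file("extdata", name, package = "pepdigest")
  if (!nzchar(path)) {
    stop("no bundled file named '", name, "'", call. = FALSE)
  }
  path
}
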