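#' Load a peptide-score table
#'
#' Scores are bioactivity likelihoods in [0, 1] supplied by an external
#' predictor (the package deliberately does not reimplement any published
#' neural scorer; scores enter only through this table). Duplicate peptides
#' must agree to within 1e-9.
#'
#' @param path TSV with columns `peptide`, `score`.
#' @return Named numeric vector: peptide -> score.
#' @export
load_scores <- function(path) {
  df <- read_tsv_strict(path, c("peptide", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad) > 0L) {
    stop("score out of [0, 1] (or non-numeric) in ", path, " at row ", bad[1],
         ": peptide '", df$peptide[bad[1]], "', score '", df$score[bad[1]],
         "'", call. = FALSE)
  }
  if (anyDuplicated(df$peptide)) {
    for (p in unique(df$peptide[duplicated(df$peptide)])) {
      vals <- score[df$peptide == p]
      if (diff(range(vals)) > 1e-9) {
        stop("conflicting scores for peptide '", p, "' in ", path,
             call. = FALSE)
      }
    }
    keep <- !duplicated(df$peptide)
    df <- df[keep, , drop = FALSE]
    score <- score[keep]
  }
  stats::setNames(score, df$peptide)
}

#' Candidate-retention policy: score threshold plus length window
#'
#' Defaults follow common practice for screening released fragments: retain
#' peptides of 2-6 residues whose bioactivity-likelihood score strictly
#' exceeds 0.5 ("exceeds" = strict inequality; a greater-or-equal variant is
#' available). Peptides missing from the score table are excluded by default
#' (and logged) rather than silently scored 0, so absence stays visible.
#'
#' @param threshold Score cutoff in [0, 1].
#' @param min_length,max_length Inclusive length window (residues).
#' @param keep_rule `"greater"` (strict, default) or `"geq"`.
#' @param missing_score `"exclude"` (default) or `"zero"`.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(threshold = 0.5, min_length = 2L, max_length = 6L,
                          keep_rule = c("greater", "geq"),
                          missing_score = c("exclude", "zero")) {
  keep_rule <- match.arg(keep_rule)
  missing_score <- match.arg(missing_score)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  if (!(min_length >= 1L && min_length <= max_length)) {
    stop("need 1 <= min_length <= max_length", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(list(threshold = threshold, min_length = min_length,
                 max_length = max_length, keep_rule = keep_rule,
                 missing_score = missing_score),
            class = "filter_policy")
}

#' Filter released peptides by score and length
#'
#' Applies the length window and the score rule of the policy to digestion
#' output. The result is deduplicated by peptide sequence; the positional
#' intervals of each retained sequence are preserved in the `positions`
#' column (semicolon-joined `start-end` pairs, empty when no positions were
#' supplied).
#'
#' @param digest A `digest_result`, a data frame with a `peptide` column
#'   (optionally `start`, `end`), or a character vector of peptides.
#' @param scores Named numeric vector from [load_scores()].
#' @param policy A [filter_policy()].
#' @return Data frame with columns peptide, score, length, positions; sorted
#'   by peptide.
#' @export
filter_candidates <- function(digest, scores, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (inherits(digest, "digest_result")) {
    df <- digest$peptides
  } else if (is.character(digest)) {
    df <- data.frame(peptide = digest, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(digest), "peptide" %in% names(digest))
    df <- digest
  }
  len <- nchar(df$peptide)
  df <- df[len >= policy$min_length & len <= policy$max_length, , drop = FALSE]
  sc <- unname(scores[df$peptide])
  missing <- is.na(sc)
  if (any(missing)) {
    if (policy$missing_score == "exclude") {
      message("filter_candidates: excluding ",
              length(unique(df$peptide[missing])),
              " peptide(s) with no score: ",
              paste(sort(unique(df$peptide[missing])), collapse = ", "))
      df <- df[!missing, , drop = FALSE]
      sc <- sc[!missing]
    } else {
      sc[missing] <- 0
    }
  }
  keep <- if (policy$keep_rule == "greater") sc > policy$threshold
          else sc >= policy$threshold
  df <- df[keep, , drop = FALSE]
  sc <- sc[keep]
  has_pos <- all(c("start", "end") %in% names(df))
  peps <- sort(unique(df$peptide))
  out <- data.frame(
    peptide = peps,
    score = vapply(peps, function(p) sc[match(p, df$peptide)], numeric(1)),
    length = nchar(peps),
    positions = vapply(peps, function(p) {
      if (!has_pos) return("")
      rows <- df[df$peptide == p, , drop = FALSE]
      rows <- rows[order(rows$start, rows$end), , drop = FALSE]
      paste(sprintf("%d-%d", rows$start, rows$end), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Length-normalised heuristic peptide score
#'
#' A deliberately simple stand-in scorer for synthetic tests: score rises with
#' the fraction of aromatic/proline residues and is clipped to [0, 1]. It is
#' NOT equivalent to any published bioactivity predictor and must never be
#' used to reproduce published score-dependent results.
#'
#' @param peptides Character vector.
#' @return Named numeric vector of scores in [0, 1].
#' @export
heuristic_scores <- function(peptides) {
  sc <- vapply(peptides, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    min(1, 0.25 + 0.9 * mean(chars %in% c("F", "W", "Y", "P")))
  }, numeric(1))
  stats::setNames(pmin(pmax(sc, 0), 1), peptides)
}
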