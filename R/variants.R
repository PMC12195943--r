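#' A single edit against a reference protein sequence
#'
#' Edits use 1-based positions in the *reference* frame (the convention used
#' when variants are described as, e.g., "A to P at position 134"). A
#' substitution replaces the residue at `position`; a deletion removes it; an
#' insertion places `alt` immediately before the current residue at
#' `position` (`position` may be `reference length + 1` to append).
#'
#' @param kind One of `"substitution"`, `"deletion"`, `"insertion"`.
#' @param position 1-based residue index into the reference.
#' @param ref Expected reference residue (empty string for insertions).
#' @param alt Replacement/inserted residue (empty string for deletions).
#' @return An object of class `variant_edit`.
#' @export
variant_edit <- function(kind = c("substitution", "deletion", "insertion"),
                         position, ref = "", alt = "") {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("edit position must be a positive integer", call. = FALSE)
  }
  check_code <- function(x, what) {
    if (nchar(x) != 1L || !(x %in% aa_alphabet())) {
      stop(what, " must be a single valid residue code, got '", x, "'",
           call. = FALSE)
    }
  }
  if (kind %in% c("substitution", "deletion")) check_code(ref, "ref residue")
  if (kind %in% c("substitution", "insertion")) check_code(alt, "alt residue")
  if (kind == "insertion" && nchar(ref) > 0L) {
    stop("insertions carry no ref residue", call. = FALSE)
  }
  if (kind == "deletion" && nchar(alt) > 0L) {
    stop("deletions carry no alt residue", call. = FALSE)
  }
  structure(list(kind = kind, position = position, ref = ref, alt = alt),
            class = "variant_edit")
}

#' @export
print.variant_edit <- function(x, ...) {
  cat(sprintf("<variant_edit> %s %s%d%s\n", x$kind,
              x$ref, x$position, x$alt))
  invisible(x)
}

#' Read an edit list from a TSV or YAML file
#'
#' TSV needs columns `kind`, `position`, `ref`, `alt`; YAML is a list of maps
#' with the same keys. Empty `ref`/`alt` fields follow the [variant_edit()]
#' rules for each kind.
#'
#' @param path File path (`.tsv`/`.txt` or `.yml`/`.yaml`).
#' @return A list of `variant_edit` objects.
#' @export
read_edit_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    rows <- yaml::read_yaml(path)
    if (!is.null(rows$edits)) rows <- rows$edits
  } else {
    df <- read_tsv_strict(path, c("kind", "position", "ref", "alt"))
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  lapply(rows, function(r) {
    variant_edit(kind = r$kind, position = r$position,
                 ref = r$ref %||% "", alt = r$alt %||% "")
  })
}

#' Apply an edit list to a reference sequence
#'
#' Positions refer to the original reference: edits are applied in descending
#' position order, so upstream indices are unaffected by downstream
#' insertions/deletions. Multiple insertions at the same position compose
#' right-to-left (list the block C-terminal residue first). The reference is
#' never modified.
#'
#' @param reference A `protein_seq`.
#' @param edits List of [variant_edit()] objects (may be empty).
#' @param new_allele Allele label for the derived sequence.
#' @param new_id Identifier for the derived sequence; defaults to
#'   `"<reference id>:<new_allele>"`.
#' @return A new `protein_seq` carrying `allele = new_allele`.
#' @export
apply_edits <- function(reference, edits, new_allele,
                        new_id = paste0(reference$id, ":", new_allele)) {
  stopifnot(inherits(reference, "protein_seq"))
  for (e in edits) {
    if (!inherits(e, "variant_edit")) {
      stop("edits must be variant_edit objects", call. = FALSE)
    }
    limit <- if (e$kind == "insertion") reference$N + 1L else reference$N
    if (e$position > limit) {
      stop("edit position ", e$position, " out of range for reference '",
           reference$id, "' (N=", reference$N, ")", call. = FALSE)
    }
  }
  chars <- strsplit(reference$residues, "", fixed = TRUE)[[1]]
  ord <- order(vapply(edits, `[[`, integer(1), "position"), decreasing = TRUE)
  for (e in edits[ord]) {
    p <- e$position
    if (e$kind != "insertion" && chars[p] != e$ref) {
      stop("edit conflict at position ", p, ": expected '", e$ref,
           "' but reference '", reference$id, "' has '", chars[p], "'",
           call. = FALSE)
    }
    chars <- switch(e$kind,
      substitution = { chars[p] <- e$alt; chars },
      deletion = chars[-p],
      insertion = append(chars, e$alt, after = p - 1L)
    )
  }
  protein_sequence(new_id, paste(chars, collapse = ""),
                   gene = reference$gene, allele = new_allele)
}

#' Positional difference between two alleles of one gene
#'
#' Equal-length sequences are compared position by position and yield
#' substitutions. Unequal lengths are handled only for a single contiguous
#' indel (longest common prefix + suffix covering the shorter sequence) —
#' sufficient for exon-loss variants such as the alpha-S1 casein F allele;
#' anything more divergent raises a "sequences not comparable" error rather
#' than silently attempting an alignment.
#'
#' @param a,b `protein_seq` objects sharing the same gene label.
#' @return A list of [variant_edit()] objects such that
#'   `apply_edits(a, result, b$allele)` reproduces `b`; empty iff identical.
#' @export
diff_alleles <- function(a, b) {
  stopifnot(inherits(a, "protein_seq"), inherits(b, "protein_seq"))
  if (!identical(a$gene, b$gene)) {
    stop("diff_alleles compares alleles of one gene (got '", a$gene,
         "' vs '", b$gene, "')", call. = FALSE)
  }
  ca <- strsplit(a$residues, "", fixed = TRUE)[[1]]
  cb <- strsplit(b$residues, "", fixed = TRUE)[[1]]
  if (length(ca) == length(cb)) {
    idx <- which(ca != cb)
    return(lapply(idx, function(i) {
      variant_edit("substitution", i, ref = ca[i], alt = cb[i])
    }))
  }
  # single contiguous indel heuristic
  nmin <- min(length(ca), length(cb))
  pre <- 0L
  while (pre < nmin && ca[pre + 1L] == cb[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre &&
         ca[length(ca) - suf] == cb[length(cb) - suf]) suf <- suf + 1L
  if (pre + suf < nmin) {
    stop("sequences not comparable: lengths differ (", length(ca), " vs ",
         length(cb), ") and the difference is not a single contiguous indel",
         call. = FALSE)
  }
  if (length(ca) > length(cb)) {
    gap <- length(ca) - length(cb)
    lapply(seq(pre + gap, pre + 1L), function(p) {
      variant_edit("deletion", p, ref = ca[p])
    })
  } else {
    gap <- length(cb) - length(ca)
    # insertions at one reference position compose right-to-left
    lapply(seq(pre + gap, pre + 1L), function(q) {
      variant_edit("insertion", pre + 1L, alt = cb[q])
    })
  }
}

#' A reference allele plus derived variants of one gene
#'
#' @param gene Gene label shared by all members.
#' @param reference_id Allele label of the reference; must be a name of
#'   `alleles`.
#' @param alleles Named list of `protein_seq` objects (names = allele labels).
#' @return An object of class `allele_set`.
#' @export
allele_set <- function(gene, reference_id, alleles) {
  stopifnot(is.list(alleles), length(alleles) >= 1L)
  if (!(reference_id %in% names(alleles))) {
    stop("reference_id '", reference_id, "' is not among the alleles",
         call. = FALSE)
  }
  genes <- vapply(alleles, `[[`, character(1), "gene")
  if (!all(genes == gene)) {
    stop("all members of an allele_set must share gene '", gene, "'",
         call. = FALSE)
  }
  structure(list(gene = gene, reference_id = reference_id, alleles = alleles),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("<allele_set> gene %s: %d allele(s) [%s], reference %s\n",
              x$gene, length(x$alleles),
              paste(names(x$alleles), collapse = ", "), x$reference_id))
  invisible(x)
}
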