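# Score-set input: the six metadata fields describing a MAVE target, plus
# the per-variant score table. Variant strings are parsed lazily (at mapping
# time), so a score set loads even if individual rows are malformed.

#' Infer whether a residue string is DNA or protein
#'
#' Fallback used when metadata omits the target sequence type; an explicit
#' metadata value always wins. A sequence is called `dna` iff every
#' character is in `A,C,G,T,N`; any other IUPAC amino-acid character makes
#' it `protein`; anything else is an error.
#'
#' @param seq Non-empty uppercase residue string.
#' @return `"dna"` or `"protein"`.
#' @export
infer_sequence_type <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  if (all(chars %in% DNA_ALPHABET)) {
    return("dna")
  }
  bad <- setdiff(chars, union(AA_ALPHABET, DNA_ALPHABET))
  if (length(bad) > 0) {
    abort(sprintf("invalid residue character(s): %s", paste(bad, collapse = ", ")),
      class = "mavemap_alphabet_error"
    )
  }
  "protein"
}

#' Convert a parsed variant to interbase coordinates
#'
#' Adds `start0`/`end0` columns (0-based, half-open). Substitutions,
#' deletions and delins map 1-based inclusive `[start, end]` to
#' `(start-1, end)`; an insertion between positions `p` and `p+1` becomes
#' the zero-length interval `(p, p)`.
#'
#' @param variants Tibble from [parse_mave_hgvs()].
#' @return The tibble with `start0`, `end0` columns added.
#' @export
variant_interbase <- function(variants) {
  variants |>
    dplyr::mutate(
      start0 = dplyr::if_else(.data$kind == "insertion", .data$start, .data$start - 1L),
      end0 = dplyr::if_else(.data$kind == "insertion", .data$start, .data$end)
    )
}

#' Validate parsed variants against a target sequence
#'
#' Adds a `status` column: `out_of_bounds` when the interbase interval
#' extends past the target; `ref_mismatch` when a stated reference
#' residue run disagrees with the target (positions written `?` for
#' interior residues of ranged protein edits are not compared); `ok`
#' otherwise. Statuses are values, not exceptions: mismatching rows are
#' still carried through mapping with their status recorded.
#'
#' @param variants Tibble from [parse_mave_hgvs()] (interbase columns are
#'   added if absent).
#' @param target Target residue string.
#' @return The tibble with a `status` column.
#' @export
validate_variants <- function(variants, target) {
  stopifnot(nzchar(target))
  if (!"start0" %in% names(variants)) {
    variants <- variant_interbase(variants)
  }
  n <- nchar(target)
  status <- purrr::pmap_chr(
    variants[c("start0", "end0", "ref", "no_change")],
    function(start0, end0, ref, no_change) {
      if (isTRUE(no_change)) {
        return("ok")
      }
      if (end0 > n || start0 < 0) {
        return("out_of_bounds")
      }
      if (nzchar(ref)) {
        obs <- substr(target, start0 + 1L, end0)
        exp_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
        obs_chars <- strsplit(obs, "", fixed = TRUE)[[1]]
        if (length(exp_chars) != length(obs_chars)) {
          return("ref_mismatch")
        }
        cmp <- exp_chars == obs_chars | exp_chars == "?"
        if (!all(cmp)) {
          return("ref_mismatch")
        }
      }
      "ok"
    }
  )
  variants$status <- status
  variants
}

REQUIRED_META <- c("urn", "target_name", "target_sequence", "target_type")

#' Read score-set metadata from a JSON document
#'
#' The document carries the six fields extracted from score-set metadata:
#' `urn`, `target_name`, `target_sequence`, `target_sequence_type`
#' (`dna`/`protein`; inferred from the sequence when absent), `target_type`
#' (`protein_coding`, `regulatory`, `other_noncoding`), and optional
#' `uniprot_id` and `gene_hint`.
#'
#' @param x Path to a JSON file, or an already-parsed named list.
#' @return A `score_set_meta` list.
#' @export
read_score_meta <- function(x) {
  meta <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  missing <- setdiff(REQUIRED_META, names(meta)[vapply(meta, function(v) {
    !is.null(v) && !all(is.na(v)) && any(nzchar(as.character(v)))
  }, logical(1))])
  if (length(missing) > 0) {
    abort(sprintf(
      "missing required metadata field(s): %s",
      paste(missing, collapse = ", ")
    ), class = "mavemap_meta_error")
  }
  meta$target_sequence <- toupper(meta$target_sequence)
  inferred <- infer_sequence_type(meta$target_sequence)
  meta$target_sequence_type <- meta$target_sequence_type %||% inferred
  check_alphabet(meta$target_sequence, meta$target_sequence_type)
  if (!meta$target_type %in% c("protein_coding", "regulatory", "other_noncoding")) {
    abort(sprintf("unknown target_type '%s'", meta$target_type),
      class = "mavemap_meta_error"
    )
  }
  structure(
    list(
      urn = meta$urn,
      target_name = meta$target_name,
      target_sequence = meta$target_sequence,
      target_sequence_type = meta$target_sequence_type,
      target_type = meta$target_type,
      uniprot_id = meta$uniprot_id %||% NULL,
      gene_hint = meta$gene_hint %||% NULL
    ),
    class = "score_set_meta"
  )
}

#' Read a per-variant score table
#'
#' CSV with header; must contain `accession`, a `score` column, and at
#' least one of `hgvs_nt` / `hgvs_pro`. Extra columns are preserved as
#' opaque payload. Missing scores stay `NA`.
#'
#' @param x Path to a CSV file, or a data frame.
#' @return A tibble in file order.
#' @export
read_score_table <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(x)
  }
  if (!"accession" %in% names(tab)) {
    abort("score table lacks an 'accession' column", class = "mavemap_table_error")
  }
  if (!any(c("hgvs_nt", "hgvs_pro") %in% names(tab))) {
    abort("score table needs at least one of hgvs_nt / hgvs_pro",
      class = "mavemap_table_error"
    )
  }
  if (!"score" %in% names(tab)) {
    abort("score table lacks a 'score' column", class = "mavemap_table_error")
  }
  for (col in c("hgvs_nt", "hgvs_pro")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab$score <- as.numeric(tab$score)
  dup <- tab$accession[duplicated(tab$accession)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate accession(s): %s", paste(unique(dup), collapse = ", ")),
      class = "mavemap_table_error"
    )
  }
  no_variant <- is.na(tab$hgvs_nt) & is.na(tab$hgvs_pro)
  if (any(no_variant)) {
    abort(sprintf(
      "%d row(s) carry neither hgvs_nt nor hgvs_pro", sum(no_variant)
    ), class = "mavemap_table_error")
  }
  tab
}

#' Load a score set (metadata plus variant records)
#'
#' Variant strings are *not* parsed here; parsing happens when the score
#' set is mapped, so that one malformed row does not block loading.
#'
#' @param meta Path to the metadata JSON, or a named list (see
#'   [read_score_meta()]).
#' @param table Path to the score CSV, or a data frame (see
#'   [read_score_table()]).
#' @return A `score_set` object: list with `meta` and a `records` tibble.
#' @export
load_score_set <- function(meta, table) {
  meta <- if (inherits(meta, "score_set_meta")) meta else read_score_meta(meta)
  records <- read_score_table(table)
  if (nrow(records) < 1) {
    abort("score set has no records", class = "mavemap_table_error")
  }
  structure(list(meta = meta, records = records), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set ", x$meta$urn, ": ", nrow(x$records), " records on ",
    nchar(x$meta$target_sequence), "-residue ", x$meta$target_sequence_type,
    " target>\n",
    sep = ""
  )
  invisible(x)
}
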