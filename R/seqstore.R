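# Content-addressed sequence registry. Sequences are identified by a
# truncated SHA-512 digest of their residues, so identical sequences always
# receive identical identifiers regardless of registration order or source.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*"
)

#' Truncated SHA-512 digest (sha512t24u)
#'
#' URL-safe base64 encoding (RFC 4648 section 5, padding stripped) of the
#' first 24 bytes of the SHA-512 hash of `data`. This is the content-derived
#' digest underlying all computed sequence, location and allele identifiers
#' in the package; the result is always 32 characters over `[A-Za-z0-9_-]`.
#'
#' @param data A character scalar (hashed as its UTF-8 bytes) or a raw vector.
#' @return A 32-character digest string.
#' @examples
#' sha512t24u("")     # "z4PhNX7vuL3xVChQ1m2AB9Yg5AULVxXc"
#' sha512t24u("ACGT")
#' @export
sha512t24u <- function(data) {
  if (is.character(data)) {
    stopifnot(length(data) == 1L)
    data <- charToRaw(enc2utf8(data))
  }
  stopifnot(is.raw(data))
  h <- openssl::sha512(data)
  sub("=+$", "", jsonlite::base64url_enc(h[1:24]))
}

#' Create an empty sequence store
#'
#' The store maps `"SQ."`-prefixed digests to residue strings and keeps an
#' accession-to-digest lookup for externally named sequences (e.g. RefSeq
#' accessions or fixture chromosome names).
#'
#' @return A `seq_store` object (environment-backed; modified in place).
#' @export
seq_store <- function() {
  env <- new.env(parent = emptyenv())
  env$seqs <- new.env(parent = emptyenv()) # seq_id -> list(residues, kind, accession)
  env$acc <- new.env(parent = emptyenv())  # accession -> seq_id
  structure(env, class = "seq_store")
}

#' @export
print.seq_store <- function(x, ...) {
  cat("<seq_store: ", length(ls(x$seqs)), " sequences, ",
    length(ls(x$acc)), " accessions>\n",
    sep = ""
  )
  invisible(x)
}

check_alphabet <- function(residues, kind) {
  chars <- unique(strsplit(residues, "", fixed = TRUE)[[1]])
  allowed <- if (kind == "dna") DNA_ALPHABET else AA_ALPHABET
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s residue(s): %s", kind,
      paste(bad, collapse = ", ")
    ), class = "mavemap_alphabet_error")
  }
  invisible(TRUE)
}

#' Register a sequence in the store
#'
#' Computes `seq_id = "SQ." + sha512t24u(residues)` over the uppercased
#' residues and installs the sequence. Registration is idempotent: the same
#' residues always yield the same record. When `accession` is given, an
#' accession lookup is installed; re-binding an accession to different
#' residues is an error.
#'
#' @param store A [seq_store()].
#' @param residues Residue string (DNA or protein); lowercase is uppercased.
#' @param kind `"dna"` or `"protein"`.
#' @param accession Optional external accession to bind.
#' @return A list with `seq_id`, `residues`, `kind`, `accession` (a
#'   `sequence_record`).
#' @export
register_sequence <- function(store, residues, kind = c("dna", "protein"),
                              accession = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(store, "seq_store"), is.character(residues), nzchar(residues))
  residues <- toupper(residues)
  check_alphabet(residues, kind)
  seq_id <- paste0("SQ.", sha512t24u(residues))
  if (!is.null(accession)) {
    prev <- store$acc[[accession]]
    if (!is.null(prev) && !identical(prev, seq_id)) {
      abort(sprintf(
        "accession '%s' already bound to a different sequence", accession
      ), class = "mavemap_accession_conflict")
    }
    store$acc[[accession]] <- seq_id
  }
  existing <- store$seqs[[seq_id]]
  if (is.null(existing)) {
    store$seqs[[seq_id]] <- list(residues = residues, kind = kind, accession = accession)
  } else if (is.null(existing$accession) && !is.null(accession)) {
    existing$accession <- accession
    store$seqs[[seq_id]] <- existing
  }
  rec <- store$seqs[[seq_id]]
  structure(
    list(
      seq_id = seq_id, residues = rec$residues, kind = rec$kind,
      accession = accession %||% rec$accession
    ),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record ", x$seq_id, " (", x$kind, ", ",
    nchar(x$residues), " residues",
    if (!is.null(x$accession)) paste0(", ", x$accession) else "",
    ")>\n",
    sep = ""
  )
  invisible(x)
}

resolve_seq_id <- function(store, id) {
  if (!is.null(store$seqs[[id]])) {
    return(id)
  }
  via_acc <- store$acc[[id]]
  if (!is.null(via_acc)) {
    return(via_acc)
  }
  abort(sprintf("unknown sequence id or accession: '%s'", id),
    class = "mavemap_unknown_sequence"
  )
}

#' Fetch a subsequence by interbase coordinates
#'
#' @param store A [seq_store()].
#' @param seq_id A registered `"SQ."` digest or bound accession.
#' @param start0,end0 Interbase (0-based, half-open) interval; `end0 = NULL`
#'   means the sequence end.
#' @return The residue string `residues[start0:end0)`.
#' @export
fetch_subseq <- function(store, seq_id, start0 = 0L, end0 = NULL) {
  id <- resolve_seq_id(store, seq_id)
  res <- store$seqs[[id]]$residues
  n <- nchar(res)
  end0 <- end0 %||% n
  if (start0 < 0 || end0 < start0 || end0 > n) {
    abort(sprintf(
      "interval (%d, %d) out of range for sequence of length %d",
      start0, end0, n
    ), class = "mavemap_range_error")
  }
  if (end0 == start0) {
    return("")
  }
  substr(res, start0 + 1L, end0)
}

#' Sequence length by id or accession
#' @inheritParams fetch_subseq
#' @export
seq_length <- function(store, seq_id) {
  nchar(store$seqs[[resolve_seq_id(store, seq_id)]]$residues)
}

seq_kind <- function(store, seq_id) {
  store$seqs[[resolve_seq_id(store, seq_id)]]$kind
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  check_alphabet(toupper(seq), "dna")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Translate a DNA string with the standard genetic code
#'
#' Complete codons starting at `offset0` are translated; a trailing partial
#' codon is ignored. Stop codons are written `"*"`.
#'
#' @param dna DNA string.
#' @param offset0 0-based offset of the first codon.
#' @return Protein string.
#' @export
translate_dna <- function(dna, offset0 = 0L) {
  dna <- toupper(dna)
  n <- nchar(dna) - offset0
  stopifnot(n >= 3)
  n_codons <- n %/% 3L
  sub <- substr(dna, offset0 + 1L, offset0 + 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
    no.init.codon = TRUE
  ))
}

#' Load a multi-record FASTA into a sequence store
#'
#' Record ids (first whitespace-delimited token) are bound as accessions.
#'
#' @param store A [seq_store()].
#' @param path FASTA file path.
#' @param kind `"dna"` or `"protein"`.
#' @return Invisibly, a tibble of `accession`, `seq_id`, `length`.
#' @export
load_fasta <- function(store, path, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  set <- if (kind == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  recs <- purrr::map2(as.character(set), ids, function(s, id) {
    register_sequence(store, s, kind, accession = id)
  })
  invisible(tibble(
    accession = ids,
    seq_id = purrr::map_chr(recs, "seq_id"),
    length = nchar(as.character(set))
  ))
}
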