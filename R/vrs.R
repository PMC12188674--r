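# Variant-representation core: interbase sequence locations, literal
# sequence alleles, full-justification normalization, content-derived
# identifiers, and cis-phased blocks. Identifiers are truncated SHA-512
# digests over a canonical serialization (key-sorted compact JSON, UTF-8,
# embedded digests as bare 32-character strings), so the same allele built
# twice -- in any field order -- always receives the same id.

#' Construct an (unnormalized) allele
#'
#' Structural construction only: ids are unset until [digest_allele()], and
#' the allele is not normalized until [normalize_allele()]. The reference
#' allele is retrievable as `fetch_subseq(store, seq_id, start0, end0)`.
#'
#' @param store [seq_store()] holding the sequence.
#' @param seq_id Registered `"SQ."` digest (or bound accession, which is
#'   resolved).
#' @param start0,end0 Interbase interval on the sequence (zero-length for a
#'   pure insertion point).
#' @param alt Literal alternate residue string (may be empty for deletion).
#' @return An `allele` object.
#' @export
make_allele <- function(store, seq_id, start0, end0, alt) {
  id <- resolve_seq_id(store, seq_id)
  n <- seq_length(store, id)
  if (start0 < 0 || end0 < start0 || end0 > n) {
    abort(sprintf(
      "interval (%d, %d) out of range for sequence of length %d",
      start0, end0, n
    ), class = "mavemap_range_error")
  }
  structure(
    list(
      seq_id = id, start0 = as.integer(start0), end0 = as.integer(end0),
      state = toupper(alt), normalized = FALSE,
      location_id = NULL, allele_id = NULL
    ),
    class = "allele"
  )
}

#' @export
print.allele <- function(x, ...) {
  cat("<allele ", x$seq_id, ":(", x$start0, ",", x$end0, ") -> \"", x$state,
    "\"", if (!is.null(x$allele_id)) paste0(" [", x$allele_id, "]") else "",
    ">\n",
    sep = ""
  )
  invisible(x)
}

lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0) {
    return(0L)
  }
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Normalize an allele to full justification
#'
#' The longest common prefix, then the longest common suffix, of the
#' (reference, alternate) pair are trimmed, shrinking the interval. If both
#' trimmed strings are non-empty (substitution / delins) the allele is
#' already unambiguous. Otherwise the remaining inserted or deleted
#' sequence is rolled left and right over the flanking sequence as far as
#' the edit can shift, and the allele is expanded to cover the entire
#' ambiguity region (full justification). Idempotent: normalized alleles
#' are fixed points.
#'
#' @param allele A [make_allele()] result.
#' @param store The [seq_store()] holding the allele's sequence.
#' @return The normalized `allele` (ids cleared; call [digest_allele()]
#'   afterwards).
#' @export
normalize_allele <- function(allele, store) {
  s <- strsplit(store$seqs[[allele$seq_id]]$residues, "", fixed = TRUE)[[1]]
  start0 <- allele$start0
  end0 <- allele$end0
  ref <- if (end0 > start0) s[(start0 + 1L):end0] else character(0)
  alt <- if (nzchar(allele$state)) {
    strsplit(allele$state, "", fixed = TRUE)[[1]]
  } else {
    character(0)
  }

  p <- lcp_len(ref, alt)
  if (p > 0) {
    ref <- ref[-seq_len(p)]
    alt <- alt[-seq_len(p)]
    start0 <- start0 + p
  }
  sfx <- lcp_len(rev(ref), rev(alt))
  if (sfx > 0) {
    ref <- ref[seq_len(length(ref) - sfx)]
    alt <- alt[seq_len(length(alt) - sfx)]
    end0 <- end0 - sfx
  }

  if (length(ref) == 0 || length(alt) == 0) {
    b <- if (length(ref) > 0) ref else alt
    m <- length(b)
    if (m > 0) {
      n <- length(s)
      r <- 0L
      while (end0 + r < n && s[end0 + r + 1L] == b[(r %% m) + 1L]) r <- r + 1L
      l <- 0L
      while (start0 - l > 0L && s[start0 - l] == b[m - (l %% m)]) l <- l + 1L
      left <- if (l > 0) s[(start0 - l + 1L):start0] else character(0)
      right <- if (r > 0) s[(end0 + 1L):(end0 + r)] else character(0)
      alt <- c(left, alt, right)
      start0 <- start0 - l
      end0 <- end0 + r
    }
  }

  allele$start0 <- as.integer(start0)
  allele$end0 <- as.integer(end0)
  allele$state <- paste(alt, collapse = "")
  allele$normalized <- TRUE
  allele$location_id <- NULL
  allele$allele_id <- NULL
  allele
}

bare_digest <- function(id) sub("^(SQ\\.|ga4gh:SL\\.|ga4gh:VA\\.|ga4gh:CPB\\.)", "", id)

json_string <- function(x) {
  # canonical JSON string escaping (our payloads are plain ASCII residues)
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

location_serial <- function(allele) {
  sprintf(
    '{"end":%d,"sequence":%s,"start":%d,"type":"SequenceLocation"}',
    allele$end0, json_string(bare_digest(allele$seq_id)), allele$start0
  )
}

allele_serial <- function(loc_digest, state) {
  sprintf(
    '{"location":%s,"state":{"sequence":%s,"type":"LiteralSequenceExpression"},"type":"Allele"}',
    json_string(loc_digest), json_string(state)
  )
}

#' Compute location and allele identifiers
#'
#' `location_id = "ga4gh:SL." + sha512t24u(serialized location)` and
#' `allele_id = "ga4gh:VA." + sha512t24u(serialized allele)`, with the
#' canonical serialization described in the package vignette (key-sorted
#' compact JSON, digests embedded as bare 32-character strings). Only
#' normalized alleles may be digested.
#'
#' @param allele A normalized allele.
#' @return The allele with `location_id` and `allele_id` set.
#' @export
digest_allele <- function(allele) {
  if (!isTRUE(allele$normalized)) {
    abort("refusing to digest an unnormalized allele; call normalize_allele() first",
      class = "mavemap_unnormalized"
    )
  }
  loc_digest <- sha512t24u(location_serial(allele))
  allele$location_id <- paste0("ga4gh:SL.", loc_digest)
  allele$allele_id <- paste0(
    "ga4gh:VA.",
    sha512t24u(allele_serial(loc_digest, allele$state))
  )
  allele
}

#' Combine in-cis alleles into a cis-phased block
#'
#' Members are sorted by `allele_id` so block identity is order-invariant;
#' the block id is a digest over the sorted member ids.
#'
#' @param alleles List of >= 2 normalized, digested alleles on the same
#'   sequence.
#' @return A `cis_phased_block` with `members` (sorted) and `block_id`.
#' @export
make_cpb <- function(alleles) {
  if (length(alleles) < 2) {
    abort("a cis-phased block needs at least 2 member alleles",
      class = "mavemap_cpb_arity"
    )
  }
  ids <- purrr::map_chr(alleles, function(a) {
    if (is.null(a$allele_id)) {
      abort("all members must be digested", class = "mavemap_unnormalized")
    }
    a$allele_id
  })
  if (anyDuplicated(ids)) {
    abort("duplicate member allele ids in cis-phased block",
      class = "mavemap_cpb_duplicate"
    )
  }
  ord <- order(ids)
  serial <- sprintf(
    '{"members":[%s],"type":"CisPhasedBlock"}',
    paste(json_string(bare_digest(ids[ord])), collapse = ",")
  )
  structure(
    list(
      members = alleles[ord],
      block_id = paste0("ga4gh:CPB.", sha512t24u(serial))
    ),
    class = "cis_phased_block"
  )
}

#' @export
print.cis_phased_block <- function(x, ...) {
  cat("<cis_phased_block of ", length(x$members), " [", x$block_id, "]>\n",
    sep = ""
  )
  invisible(x)
}

variant_id <- function(x) {
  if (inherits(x, "allele")) x$allele_id else x$block_id
}

#' Emit a minimal-form HGVS description of an allele
#'
#' Stored alleles are fully justified; for HGVS the allele is re-trimmed to
#' its minimal, 3'-most representation per HGVS convention (the common
#' prefix is removed first, then the common suffix), and emitted as a
#' substitution, deletion, insertion or delins. Coordinates are 1-based;
#' protein output uses 3-letter amino-acid codes.
#'
#' @param allele Normalized allele.
#' @param accession Accession string to prefix (must be bound to the
#'   allele's sequence in `store`).
#' @param level `"g"`, `"n"`, `"c"` or `"p"`.
#' @param store [seq_store()].
#' @return An HGVS string like `"NC_TEST.1:g.6del"`.
#' @export
allele_hgvs <- function(allele, accession, level = c("g", "p", "n", "c"), store) {
  level <- match.arg(level)
  if (!identical(resolve_seq_id(store, accession), allele$seq_id)) {
    abort(sprintf("accession '%s' is not bound to the allele's sequence", accession),
      class = "mavemap_accession_conflict"
    )
  }
  s <- strsplit(store$seqs[[allele$seq_id]]$residues, "", fixed = TRUE)[[1]]
  start0 <- allele$start0
  end0 <- allele$end0
  ref <- if (end0 > start0) s[(start0 + 1L):end0] else character(0)
  alt <- if (nzchar(allele$state)) {
    strsplit(allele$state, "", fixed = TRUE)[[1]]
  } else {
    character(0)
  }
  p <- lcp_len(ref, alt)
  if (p > 0) {
    ref <- ref[-seq_len(p)]
    alt <- alt[-seq_len(p)]
    start0 <- start0 + p
  }
  sfx <- lcp_len(rev(ref), rev(alt))
  if (sfx > 0) {
    ref <- ref[seq_len(length(ref) - sfx)]
    alt <- alt[seq_len(length(alt) - sfx)]
    end0 <- end0 - sfx
  }
  pro <- level == "p"
  fmt_res <- function(chars) {
    if (pro) aa_to3(paste(chars, collapse = "")) else paste(chars, collapse = "")
  }
  pos1 <- function(i0) as.character(i0) # 1-based position of 0-based index i0 is i0+1
  s1 <- start0 + 1L
  e1 <- end0
  body <- if (length(ref) == 1 && length(alt) == 1) {
    if (pro) {
      paste0(fmt_res(ref), s1, fmt_res(alt))
    } else {
      paste0(s1, ref, ">", alt)
    }
  } else if (length(alt) == 0 && length(ref) > 0) {
    if (pro) {
      if (s1 == e1) {
        paste0(fmt_res(ref[1]), s1, "del")
      } else {
        paste0(fmt_res(ref[1]), s1, "_", fmt_res(ref[length(ref)]), e1, "del")
      }
    } else {
      if (s1 == e1) paste0(s1, "del") else paste0(s1, "_", e1, "del")
    }
  } else if (length(ref) == 0 && length(alt) > 0) {
    left1 <- start0 # 1-based position of residue 5' of insertion point
    if (pro) {
      lres <- if (left1 >= 1) fmt_res(s[left1]) else ""
      rres <- if (left1 + 1L <= length(s)) fmt_res(s[left1 + 1L]) else ""
      paste0(lres, left1, "_", rres, left1 + 1L, "ins", fmt_res(alt))
    } else {
      paste0(left1, "_", left1 + 1L, "ins", paste(alt, collapse = ""))
    }
  } else if (length(ref) == 0 && length(alt) == 0) {
    "="
  } else {
    if (pro) {
      if (s1 == e1) {
        paste0(fmt_res(ref[1]), s1, "delins", fmt_res(alt))
      } else {
        paste0(
          fmt_res(ref[1]), s1, "_", fmt_res(ref[length(ref)]), e1,
          "delins", fmt_res(alt)
        )
      }
    } else {
      if (s1 == e1) {
        paste0(s1, "delins", paste(alt, collapse = ""))
      } else {
        paste0(s1, "_", e1, "delins", paste(alt, collapse = ""))
      }
    }
  }
  paste0(accession, ":", level, ".", body)
}

#' Resolve an HGVS string back to a digested allele
#'
#' Parses `"ACC:g..."` / `"ACC:p..."` expressions, resolves the accession
#' through the store, and returns the normalized, digested allele. Used for
#' round-trip checks on emitted HGVS.
#'
#' @param s HGVS string with accession prefix.
#' @param store [seq_store()] with the accession bound.
#' @return A digested `allele`.
#' @export
resolve_hgvs <- function(s, store) {
  parts <- regmatches(s, regexec("^([^:]+):(.*)$", s))[[1]]
  if (!length(parts)) {
    abort(sprintf("expected 'accession:description', got '%s'", s),
      class = "mavemap_parse_error"
    )
  }
  acc <- parts[2]
  v <- variant_interbase(parse_mave_hgvs(parts[3]))
  if (nrow(v) != 1) {
    abort("resolve_hgvs() handles single-edit expressions only",
      class = "mavemap_parse_error"
    )
  }
  a <- make_allele(store, acc, v$start0[1], v$end0[1], v$alt[1])
  digest_allele(normalize_allele(a, store))
}
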