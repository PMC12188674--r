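# MAVE-HGVS parsing and emission for the four edit kinds used by MAVE score
# sets: substitution, deletion, insertion, delins, at nucleotide (c./n./g.)
# or protein (p.) level, including bracketed in-cis multi-variants and
# wild-type / synonymous placeholders.

AA3 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)
AA1 <- stats::setNames(names(AA3), unname(AA3))

AA3_RE <- paste0("(?:", paste(names(AA3), collapse = "|"), ")")
AA1_RE <- "[ACDEFGHIKLMNPQRSTVWY*]"
NT_RE <- "[ACGTN]"

aa_to1 <- function(x) {
  # accepts a run of 3-letter codes, a run of 1-letter codes, or ""
  if (x == "") {
    return("")
  }
  if (grepl(paste0("^(", AA3_RE, ")+$"), x)) {
    codes <- regmatches(x, gregexpr(AA3_RE, x))[[1]]
    return(paste(AA3[codes], collapse = ""))
  }
  if (grepl(paste0("^(", AA1_RE, ")+$"), x)) {
    return(x)
  }
  abort(sprintf("unrecognized amino-acid code(s) in '%s'", x),
    class = "mavemap_parse_error"
  )
}

aa_to3 <- function(x) {
  if (x == "") {
    return("")
  }
  paste(AA1[strsplit(x, "", fixed = TRUE)[[1]]], collapse = "")
}

variant_row <- function(prefix, level, kind, start, end, ref, alt,
                        no_change = FALSE, flank = "") {
  tibble(
    prefix = prefix, level = level, kind = kind,
    start = as.integer(start), end = as.integer(end),
    ref = ref, alt = alt, no_change = no_change, flank = flank
  )
}

parse_one_nt <- function(body, prefix, token) {
  if (body == "=") {
    return(variant_row(prefix, "nucleotide", "no_change", NA, NA, "", "", TRUE))
  }
  m <- regmatches(body, regexec(paste0("^(\\d+)(", NT_RE, ")>(", NT_RE, ")$"), body))[[1]]
  if (length(m)) {
    p <- as.integer(m[2])
    return(variant_row(prefix, "nucleotide", "substitution", p, p, m[3], m[4]))
  }
  m <- regmatches(body, regexec(paste0("^(\\d+)(?:_(\\d+))?del(", NT_RE, "*)$"), body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (m[3] == "") s else as.integer(m[3])
    if (e < s) abort(sprintf("deletion range %s reversed", token), class = "mavemap_parse_error")
    return(variant_row(prefix, "nucleotide", "deletion", s, e, m[4], ""))
  }
  m <- regmatches(body, regexec(paste0("^(\\d+)_(\\d+)ins(", NT_RE, "+)$"), body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- as.integer(m[3])
    if (e != s + 1L) {
      abort(sprintf("insertion flanks must be adjacent in '%s'", token),
        class = "mavemap_parse_error"
      )
    }
    return(variant_row(prefix, "nucleotide", "insertion", s, e, "", m[4]))
  }
  m <- regmatches(body, regexec(paste0("^(\\d+)(?:_(\\d+))?delins(", NT_RE, "+)$"), body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (m[3] == "") s else as.integer(m[3])
    if (e < s) abort(sprintf("delins range %s reversed", token), class = "mavemap_parse_error")
    return(variant_row(prefix, "nucleotide", "delins", s, e, "", m[4]))
  }
  abort(sprintf("cannot parse MAVE-HGVS token '%s'", token), class = "mavemap_parse_error")
}

parse_one_pro <- function(body, token) {
  if (body %in% c("=", "(=)")) {
    return(variant_row("p", "protein", "no_change", NA, NA, "", "", TRUE))
  }
  AA_RE <- paste0("(", AA3_RE, "|", AA1_RE, ")")
  # synonymous (p.Trp24=) -> explicit no-change marker
  m <- regmatches(body, regexec(paste0("^", AA_RE, "(\\d+)=$"), body))[[1]]
  if (length(m)) {
    return(variant_row("p", "protein", "no_change", NA, NA, aa_to1(m[2]), "", TRUE))
  }
  # substitution (p.Trp24Cys / p.W24C); m: [2]=ref aa, [3]=pos, [4]=alt aa
  m <- regmatches(body, regexec(paste0("^", AA_RE, "(\\d+)", AA_RE, "$"), body))[[1]]
  if (length(m)) {
    p <- as.integer(m[3])
    return(variant_row("p", "protein", "substitution", p, p, aa_to1(m[2]), aa_to1(m[4])))
  }
  # deletion; m: [2]=aa1, [3]=pos1, [4]=aa2, [5]=pos2
  m <- regmatches(body, regexec(
    paste0("^", AA_RE, "(\\d+)(?:_", AA_RE, "(\\d+))?del$"), body
  ))[[1]]
  if (length(m)) {
    s <- as.integer(m[3])
    if (m[5] == "") {
      return(variant_row("p", "protein", "deletion", s, s, aa_to1(m[2]), ""))
    }
    e <- as.integer(m[5])
    if (e < s) abort(sprintf("deletion range %s reversed", token), class = "mavemap_parse_error")
    ref <- paste0(aa_to1(m[2]), strrep("?", e - s - 1L), aa_to1(m[4]))
    return(variant_row("p", "protein", "deletion", s, e, ref, ""))
  }
  # insertion; m: [2]=aa1, [3]=pos1, [4]=aa2, [5]=pos2, [6]=inserted run
  m <- regmatches(body, regexec(
    paste0("^", AA_RE, "(\\d+)_", AA_RE, "(\\d+)ins((?:", AA3_RE, ")+|(?:", AA1_RE, ")+)$"),
    body
  ))[[1]]
  if (length(m)) {
    s <- as.integer(m[3])
    e <- as.integer(m[5])
    if (e != s + 1L) {
      abort(sprintf("insertion flanks must be adjacent in '%s'", token),
        class = "mavemap_parse_error"
      )
    }
    return(variant_row("p", "protein", "insertion", s, e, "", aa_to1(m[6]),
      flank = paste0(aa_to1(m[2]), aa_to1(m[4]))
    ))
  }
  # delins; m: [2]=aa1, [3]=pos1, [4]=aa2, [5]=pos2, [6]=replacement run
  m <- regmatches(body, regexec(
    paste0("^", AA_RE, "(\\d+)(?:_", AA_RE, "(\\d+))?delins((?:", AA3_RE, ")+|(?:", AA1_RE, ")+)$"),
    body
  ))[[1]]
  if (length(m)) {
    s <- as.integer(m[3])
    e <- if (m[5] == "") s else as.integer(m[5])
    if (e < s) abort(sprintf("delins range %s reversed", token), class = "mavemap_parse_error")
    ref <- if (e == s) {
      aa_to1(m[2])
    } else {
      paste0(aa_to1(m[2]), strrep("?", e - s - 1L), aa_to1(m[4]))
    }
    return(variant_row("p", "protein", "delins", s, e, ref, aa_to1(m[6])))
  }
  abort(sprintf("cannot parse MAVE-HGVS token '%s'", token), class = "mavemap_parse_error")
}

#' Parse a MAVE-HGVS variant string
#'
#' Handles single edits (`c.4G>T`, `p.Trp24Cys`, `g.5_7del`, `c.5_6insTT`,
#' `c.4_6delinsAT`, `p.Ala2_Gly4delinsTrp`), bracketed in-cis multi-variants
#' (`[c.1A>T;c.9_10del]`, `c.[1A>T;9_10del]`), and wild-type / synonymous
#' placeholders (`p.=`, `c.=`, `_wt`, `_sy`, `p.Trp24=`), which are returned
#' with `no_change = TRUE` so callers can count but not map them. Amino
#' acids are accepted in 1- or 3-letter code and stored 1-letter internally
#' (stop = `"*"`).
#'
#' @param s A MAVE-HGVS expression.
#' @return A tibble with one row per component edit, in textual order, with
#'   columns `prefix` (`c`/`n`/`g`/`p`), `level`, `kind`, `start`, `end`
#'   (1-based inclusive; insertion flanks), `ref`, `alt`, `no_change`, and
#'   `cis` (`TRUE` when the expression described multiple in-cis edits).
#' @export
parse_mave_hgvs <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  if (s %in% c("_wt", "_sy")) {
    out <- variant_row(NA_character_, NA_character_, "no_change", NA, NA, "", "", TRUE)
    out$cis <- FALSE
    return(out)
  }
  tokens <- NULL
  if (grepl("^\\[.*\\]$", s)) {
    tokens <- strsplit(substr(s, 2L, nchar(s) - 1L), ";", fixed = TRUE)[[1]]
  } else {
    m <- regmatches(s, regexec("^([cngp])\\.\\[(.*)\\]$", s))[[1]]
    if (length(m)) {
      tokens <- paste0(m[2], ".", strsplit(m[3], ";", fixed = TRUE)[[1]])
    } else {
      tokens <- s
    }
  }
  tokens <- trimws(tokens)
  rows <- purrr::map(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([cngp])\\.(.*)$", tok))[[1]]
    if (!length(m)) {
      abort(sprintf("cannot parse MAVE-HGVS token '%s'", tok),
        class = "mavemap_parse_error"
      )
    }
    if (m[2] == "p") parse_one_pro(m[3], tok) else parse_one_nt(m[3], m[2], tok)
  })
  out <- dplyr::bind_rows(rows)
  out$cis <- length(tokens) > 1L
  out
}

format_pos_pair_nt <- function(kind, start, end) {
  if (kind == "substitution") {
    as.character(start)
  } else if (start == end && kind != "insertion") {
    as.character(start)
  } else {
    paste0(start, "_", end)
  }
}

#' Format a parsed variant back to MAVE-HGVS
#'
#' Inverse of [parse_mave_hgvs()] for single edits; protein output uses
#' 3-letter amino-acid codes (stop written `Ter`).
#'
#' @param v A one-row tibble (or list) with the columns produced by
#'   [parse_mave_hgvs()].
#' @return A MAVE-HGVS string.
#' @export
format_mave_hgvs <- function(v) {
  if (isTRUE(v$no_change)) {
    return(paste0(v$prefix %||% "p", ".="))
  }
  if (v$level == "nucleotide") {
    body <- switch(v$kind,
      substitution = paste0(v$start, v$ref, ">", v$alt),
      deletion = paste0(format_pos_pair_nt("deletion", v$start, v$end), "del"),
      insertion = paste0(v$start, "_", v$end, "ins", v$alt),
      delins = paste0(format_pos_pair_nt("delins", v$start, v$end), "delins", v$alt)
    )
    return(paste0(v$prefix, ".", body))
  }
  ref3 <- function(i) aa_to3(substr(v$ref, i, i))
  first3 <- aa_to3(substr(v$ref, 1L, 1L))
  last3 <- aa_to3(substr(v$ref, nchar(v$ref), nchar(v$ref)))
  body <- switch(v$kind,
    substitution = paste0(first3, v$start, aa_to3(v$alt)),
    deletion = if (v$start == v$end) {
      paste0(first3, v$start, "del")
    } else {
      paste0(first3, v$start, "_", last3, v$end, "del")
    },
    insertion = paste0(
      aa_to3(substr(v$flank, 1L, 1L)), v$start, "_",
      aa_to3(substr(v$flank, 2L, 2L)), v$end, "ins", aa_to3(v$alt)
    ),
    delins = if (v$start == v$end) {
      paste0(first3, v$start, "delins", aa_to3(v$alt))
    } else {
      paste0(first3, v$start, "_", last3, v$end, "delins", aa_to3(v$alt))
    }
  )
  paste0("p.", body)
}
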