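# Shared fixtures and independent oracles used across the suite. Oracles
# are deliberately naive (apply-and-compare, per-base enumeration,
# closed-form interpolation) and never call the code paths they check.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply a single edit to a sequence (independent of the allele machinery)
apply_edit <- function(seq, start0, end0, alt) {
  paste0(substr(seq, 1, start0), alt, substr(seq, end0 + 1, nchar(seq)))
}

# enumerate every single-edit representation (interval + state) equivalent
# to the given edit, by deriving candidate states from the edited string
equivalent_representations <- function(seq, start0, end0, alt) {
  edited <- apply_edit(seq, start0, end0, alt)
  n <- nchar(seq)
  d <- end0 - start0 # deleted length
  m <- nchar(alt)
  reps <- list()
  for (p in 0:(n - d)) {
    cand_alt <- substr(edited, p + 1, p + m)
    if (apply_edit(seq, p, p + d, cand_alt) == edited) {
      reps[[length(reps) + 1L]] <- list(start0 = p, end0 = p + d, alt = cand_alt)
    }
  }
  reps
}

# naive per-base liftover map: named integer vector, query base -> ref base
naive_base_map <- function(hit) {
  out <- integer(0)
  for (i in seq_len(nrow(hit$blocks))) {
    b <- hit$blocks[i, ]
    qs <- b$q_start:(b$q_end - 1L)
    rs <- if (hit$strand == "+") {
      b$r_start + (qs - b$q_start)
    } else {
      b$r_start + (b$q_end - qs - 1L)
    }
    out[as.character(qs)] <- rs
  }
  out
}

# flatten a lift result into a per-base map for comparison with the oracle
lift_to_base_map <- function(lift) {
  out <- integer(0)
  for (i in seq_len(nrow(lift$segments))) {
    s <- lift$segments[i, ]
    if (s$q_end0 == s$q_start0) next
    qs <- s$q_start0:(s$q_end0 - 1L)
    rs <- if (lift$strand == "+") {
      s$r_start0 + (qs - s$q_start0)
    } else {
      s$r_start0 + (s$q_end0 - qs - 1L)
    }
    out[as.character(qs)] <- rs
  }
  out
}

# random block alignment generator: 1-5 non-overlapping collinear blocks
random_hit <- function(n_blocks = sample(1:5, 1), strand = sample(c("+", "-"), 1)) {
  q_len <- 0L
  blocks <- list()
  q_cursor <- sample(0:3, 1)
  r_cursor <- sample(50:100, 1)
  for (i in seq_len(n_blocks)) {
    len <- sample(5:30, 1)
    blocks[[i]] <- tibble::tibble(
      q_start = q_cursor, q_end = q_cursor + len,
      r_start = r_cursor, r_end = r_cursor + len,
      matches = len
    )
    q_cursor <- q_cursor + len + sample(0:10, 1)
    r_cursor <- r_cursor + len + sample(1:200, 1)
  }
  b <- dplyr::bind_rows(blocks)
  q_size <- max(b$q_end) + sample(0:5, 1)
  if (strand == "-") {
    # mirror query coordinates so they descend as reference ascends
    b <- dplyr::mutate(b,
      tmp_start = q_size - q_end, tmp_end = q_size - q_start,
      q_start = tmp_start, q_end = tmp_end,
      tmp_start = NULL, tmp_end = NULL
    )
  }
  structure(
    list(
      ref_accession = "NC_ORACLE.1", strand = strand, blocks = b,
      matches = sum(b$matches), mismatches = 0L, identity = 1,
      coverage = sum(b$q_end - b$q_start) / q_size, q_size = q_size,
      score = sum(b$matches)
    ),
    class = "alignment_hit"
  )
}

# type-7 quantile by the closed-form interpolation formula
quantile_type7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

variant_id_for_test <- function(x) {
  if (inherits(x, "allele")) x$allele_id else x$block_id
}

# small shared genome fixture (built once per test run)
shared_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- mavemap::make_genome(101L)
    fx
  }
})
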