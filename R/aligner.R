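# Minimal BLAT-like local aligner: exact k-mer seeding on both strands,
# greedy x-drop extension into maximal ungapped blocks, and collinear
# chaining in which reference-only gaps model introns and query-only gaps
# model unaligned target content (e.g. minigene inserts). Adequate for
# desk-scale genomes; a PSL reader offers drop-in replacement by an
# external aligner.

#' Alignment parameters
#'
#' @param k Exact seed length (>= 4).
#' @param max_intron Maximum reference-only gap bridged when chaining
#'   collinear blocks (models introns).
#' @param min_identity,min_coverage Hit-level filters applied by
#'   [select_hit()]; fractions in `[0, 1]`. Deliberately permissive by
#'   default because heavily mutagenized targets may still partially align.
#' @param x_drop Ungapped extension stops when the running score (+1 match,
#'   -1 mismatch) falls more than `x_drop` below its maximum; the block end
#'   is the maximum-scoring position.
#' @param gap_open,gap_ext Chain scoring penalties (see [score_hit()]).
#' @return An `align_params` list.
#' @export
align_params <- function(k = 11L, max_intron = 500000L, min_identity = 0.5,
                         min_coverage = 0.3, x_drop = 20L,
                         gap_open = 2, gap_ext = 0.05) {
  stopifnot(
    k >= 4L, max_intron >= 0,
    min_identity >= 0, min_identity <= 1,
    min_coverage >= 0, min_coverage <= 1
  )
  structure(
    list(
      k = as.integer(k), max_intron = as.integer(max_intron),
      min_identity = min_identity, min_coverage = min_coverage,
      x_drop = as.integer(x_drop), gap_open = gap_open, gap_ext = gap_ext
    ),
    class = "align_params"
  )
}

#' Build an exact k-mer seed index over reference sequences
#'
#' @param genome Named character vector of reference sequences, or a
#'   [seq_store()] (all DNA records with accessions are indexed).
#' @param k Seed length.
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(genome, k = 11L) {
  k <- as.integer(k)
  seqs <- genome_as_vector(genome)
  if (length(seqs) == 0) {
    abort("empty genome: nothing to index", class = "mavemap_index_error")
  }
  if (all(nchar(seqs) < k)) {
    abort(sprintf("k = %d exceeds every reference sequence length", k),
      class = "mavemap_index_error"
    )
  }
  h <- new.env(parent = emptyenv())
  for (acc in names(seqs)) {
    s <- seqs[[acc]]
    n <- nchar(s)
    if (n < k) next
    pos0 <- 0:(n - k)
    kmers <- substring(s, pos0 + 1L, pos0 + k)
    by_kmer <- split(pos0, kmers)
    for (km in names(by_kmer)) {
      h[[km]] <- c(h[[km]], list(list(acc = acc, pos0 = by_kmer[[km]])))
    }
  }
  structure(list(h = h, k = k, seqs = seqs), class = "seed_index")
}

genome_as_vector <- function(genome) {
  if (inherits(genome, "seq_store")) {
    accs <- ls(genome$acc)
    out <- character(0)
    for (a in accs) {
      id <- genome$acc[[a]]
      if (genome$seqs[[id]]$kind == "dna") out[[a]] <- genome$seqs[[id]]$residues
    }
    out
  } else {
    stopifnot(is.character(genome))
    if (length(genome) == 0) {
      return(stats::setNames(character(0), character(0)))
    }
    stopifnot(!is.null(names(genome)))
    toupper(genome)
  }
}

# x-drop ungapped extension along one diagonal; returns extended (qs, qe)
extend_segment <- function(qc, rc, qs, qe, diag, x_drop) {
  lq <- length(qc)
  lr <- length(rc)
  # right
  score <- 0L
  best <- 0L
  best_i <- qe
  i <- qe
  while (i < lq && i + diag < lr) {
    score <- score + (if (qc[i + 1L] == rc[i + diag + 1L]) 1L else -1L)
    i <- i + 1L
    if (score > best) {
      best <- score
      best_i <- i
    }
    if (score < best - x_drop) break
  }
  qe <- best_i
  # left
  score <- 0L
  best <- 0L
  best_i <- qs
  i <- qs
  while (i > 0L && i + diag > 0L) {
    score <- score + (if (qc[i] == rc[i + diag]) 1L else -1L)
    i <- i - 1L
    if (score > best) {
      best <- score
      best_i <- i
    }
    if (score < best - x_drop) break
  }
  c(best_i, qe)
}

count_matches <- function(qc, rc, qs, qe, diag) {
  if (qe <= qs) {
    return(0L)
  }
  sum(qc[(qs + 1L):qe] == rc[(qs + diag + 1L):(qe + diag)])
}

# Align one query orientation against one reference sequence.
# Returns a tibble of chained blocks (q_start, q_end, r_start, r_end, matches)
# or NULL when nothing chains.
chain_one <- function(qc, rc, seed_hits, params) {
  if (nrow(seed_hits) == 0) {
    return(NULL)
  }
  by_diag <- split(seed_hits$qpos0, seed_hits$rpos0 - seed_hits$qpos0)
  seg_diag <- integer(0)
  seg_qs <- integer(0)
  seg_qe <- integer(0)
  for (d in names(by_diag)) {
    runs <- merge_runs(sort(unique(by_diag[[d]])), params$k)
    seg_diag <- c(seg_diag, rep(as.integer(d), length(runs[[1]])))
    seg_qs <- c(seg_qs, runs[[1]])
    seg_qe <- c(seg_qe, runs[[2]])
  }

  # extend each run, then merge overlapping extensions per diagonal
  for (i in seq_along(seg_qs)) {
    e <- extend_segment(qc, rc, seg_qs[i], seg_qe[i], seg_diag[i], params$x_drop)
    seg_qs[i] <- e[1]
    seg_qe[i] <- e[2]
  }
  segs_m <- NULL
  for (d in unique(seg_diag)) {
    sel <- seg_diag == d
    o <- order(seg_qs[sel])
    merged <- merge_intervals(seg_qs[sel][o], seg_qe[sel][o])
    segs_m <- rbind(segs_m, cbind(
      diag = rep(d, length(merged[[1]])),
      qs = merged[[1]], qe = merged[[2]]
    ))
  }
  segs <- tibble(
    diag = as.integer(segs_m[, "diag"]),
    qs = as.integer(segs_m[, "qs"]),
    qe = as.integer(segs_m[, "qe"])
  )
  segs <- segs[segs$qe > segs$qs, , drop = FALSE]
  if (nrow(segs) == 0) {
    return(NULL)
  }
  segs$matches <- purrr::pmap_int(segs, function(diag, qs, qe, ...) {
    count_matches(qc, rc, qs, qe, diag)
  })
  segs <- segs[order(segs$qs, segs$qe), , drop = FALSE]

  n <- nrow(segs)
  dp <- segs$matches
  prev <- rep(NA_integer_, n)
  if (n > 1) {
    for (j in 2:n) {
      for (i in 1:(j - 1)) {
        # query overlap between extended segments is allowed (resolved at an
        # optimal split during traceback) as long as both retain length
        o <- segs$qe[i] - segs$qs[j]
        if (o >= segs$qe[j] - segs$qs[j]) next
        if (o >= segs$qe[i] - segs$qs[i]) next
        trim <- max(0L, o)
        rj <- segs$qs[j] + segs$diag[j] + trim
        ri_end <- segs$qe[i] + segs$diag[i]
        rgap <- rj - ri_end
        if (rgap < 0 || rgap > params$max_intron) next
        cand <- dp[i] + segs$matches[j] - trim
        if (cand > dp[j]) {
          dp[j] <- cand
          prev[j] <- i
        }
      }
    }
  }
  j <- which.max(dp)
  path <- integer(0)
  while (!is.na(j)) {
    path <- c(j, path)
    j <- prev[j]
  }
  ch <- segs[path, , drop = FALSE]
  # resolve query overlaps between chained blocks at the split point that
  # maximizes total matches (extension overshoot past a junction carries
  # chance matches; the junction itself is where match counts are optimal)
  if (nrow(ch) > 1) {
    for (j in 2:nrow(ch)) {
      o <- ch$qe[j - 1] - ch$qs[j]
      if (o > 0) {
        lo <- ch$qs[j]
        hi <- ch$qe[j - 1]
        xs <- lo:hi
        pos <- lo:(hi - 1L)
        a_match <- qc[pos + 1L] == rc[pos + ch$diag[j - 1] + 1L]
        b_match <- qc[pos + 1L] == rc[pos + ch$diag[j] + 1L]
        # total(x) = matches of a over [lo, x) + matches of b over [x, hi)
        totals <- c(0L, cumsum(a_match)) + rev(c(0L, cumsum(rev(b_match))))
        x <- xs[which.max(totals)]
        ch$qe[j - 1] <- x
        ch$qs[j] <- x
      }
    }
  }
  ch <- ch[ch$qe > ch$qs, , drop = FALSE]
  if (nrow(ch) == 0) {
    return(NULL)
  }
  tibble(
    q_start = ch$qs, q_end = ch$qe,
    r_start = ch$qs + ch$diag, r_end = ch$qe + ch$diag,
    matches = purrr::pmap_int(
      list(ch$diag, ch$qs, ch$qe),
      function(diag, qs, qe) count_matches(qc, rc, qs, qe, diag)
    )
  )
}

# merge sorted seed start positions (same diagonal) into covered runs
merge_runs <- function(qpos0, k) {
  starts <- integer(0)
  ends <- integer(0)
  cur_s <- qpos0[1]
  cur_e <- qpos0[1] + k
  if (length(qpos0) > 1) {
    for (p in qpos0[-1]) {
      if (p <= cur_e) {
        cur_e <- max(cur_e, p + k)
      } else {
        starts <- c(starts, cur_s)
        ends <- c(ends, cur_e)
        cur_s <- p
        cur_e <- p + k
      }
    }
  }
  list(c(starts, cur_s), c(ends, cur_e))
}

merge_intervals <- function(qs, qe) {
  starts <- integer(0)
  ends <- integer(0)
  cur_s <- qs[1]
  cur_e <- qe[1]
  if (length(qs) > 1) {
    for (i in 2:length(qs)) {
      if (qs[i] <= cur_e) {
        cur_e <- max(cur_e, qe[i])
      } else {
        starts <- c(starts, cur_s)
        ends <- c(ends, cur_e)
        cur_s <- qs[i]
        cur_e <- qe[i]
      }
    }
  }
  list(c(starts, cur_s), c(ends, cur_e))
}

#' Align a DNA target against a seed index
#'
#' Seeds are matched on both strands (the minus strand by aligning the
#' reverse-complemented target; the hit is reported with `strand = "-"`).
#' Collinear seeds are chained when the query gap is non-negative and the
#' reference gap lies in `[0, max_intron]`, then greedily extended into
#' maximal ungapped blocks. Blocks are stored in plus-strand reference
#' coordinates with query coordinates on the original (uncomplemented)
#' target; for minus-strand hits the query coordinates therefore decrease
#' as reference coordinates increase.
#'
#' @param target DNA target sequence (length >= `k`).
#' @param index A [build_seed_index()] result.
#' @param params [align_params()].
#' @return A list of `alignment_hit` objects sorted by descending score;
#'   empty list when nothing seeds.
#' @export
align_target <- function(target, index, params = align_params()) {
  target <- toupper(target)
  stopifnot(nchar(target) >= index$k)
  lq <- nchar(target)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") target else reverse_complement(target)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    qpos0 <- 0:(lq - index$k)
    kmers <- substring(q, qpos0 + 1L, qpos0 + index$k)
    seed_list <- list()
    for (i in seq_along(kmers)) {
      entries <- index$h[[kmers[i]]]
      if (is.null(entries)) next
      for (e in entries) {
        seed_list[[length(seed_list) + 1L]] <- tibble(
          acc = e$acc, qpos0 = qpos0[i], rpos0 = e$pos0
        )
      }
    }
    if (length(seed_list) == 0) next
    seeds <- dplyr::bind_rows(seed_list)
    for (acc in unique(seeds$acc)) {
      rc_chars <- strsplit(index$seqs[[acc]], "", fixed = TRUE)[[1]]
      blocks <- chain_one(qc, rc_chars, seeds[seeds$acc == acc, ], params)
      if (is.null(blocks)) next
      if (strand == "-") {
        blocks <- blocks |>
          dplyr::mutate(
            q_start_new = lq - .data$q_end,
            q_end_new = lq - .data$q_start
          ) |>
          dplyr::mutate(q_start = .data$q_start_new, q_end = .data$q_end_new) |>
          dplyr::select(-"q_start_new", -"q_end_new")
      }
      aligned <- sum(blocks$q_end - blocks$q_start)
      matches <- sum(blocks$matches)
      hit <- structure(
        list(
          ref_accession = acc, strand = strand, blocks = blocks,
          matches = matches, mismatches = aligned - matches,
          identity = matches / aligned, coverage = aligned / lq,
          q_size = lq, score = NA_real_
        ),
        class = "alignment_hit"
      )
      hit$score <- score_hit(hit, params$gap_open, params$gap_ext)
      hits[[length(hits) + 1L]] <- hit
    }
  }
  hits[order(-purrr::map_dbl(hits, "score"))]
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat("<alignment_hit ", x$ref_accession, " (", x$strand, "): ",
    nrow(x$blocks), " block(s), identity ", round(x$identity, 3),
    ", coverage ", round(x$coverage, 3), ", score ", round(x$score, 2), ">\n",
    sep = ""
  )
  invisible(x)
}

block_gaps <- function(hit) {
  b <- hit$blocks
  if (nrow(b) < 2) {
    return(list(n_gaps = 0L, ref_gap_total = 0L))
  }
  rgap <- b$r_start[-1] - b$r_end[-nrow(b)]
  qgap <- if (hit$strand == "+") {
    b$q_start[-1] - b$q_end[-nrow(b)]
  } else {
    b$q_start[-nrow(b)] - b$q_end[-1]
  }
  list(n_gaps = sum(rgap > 0 | qgap > 0), ref_gap_total = sum(rgap[rgap > 0]))
}

#' Score an alignment hit
#'
#' `score = matches - mismatches - gap_open * n_internal_gaps -
#'  gap_ext * log2(total reference gap length + 1)`.
#'
#' @param hit An `alignment_hit`.
#' @param gap_open,gap_ext Penalties.
#' @return Numeric score.
#' @export
score_hit <- function(hit, gap_open = 2, gap_ext = 0.05) {
  g <- block_gaps(hit)
  hit$matches - hit$mismatches - gap_open * g$n_gaps -
    gap_ext * log2(g$ref_gap_total + 1)
}

#' Select one representative hit
#'
#' Hits failing the identity or coverage thresholds are discarded. Among
#' survivors the hit with the highest score wins; score ties prefer a hit
#' overlapping the genomic locus of `gene_hint` (resolved through the
#' transcript registry), then the smallest `(ref_accession, r_start)`.
#'
#' @param hits List of `alignment_hit` (from [align_target()]).
#' @param gene_hint Optional gene symbol.
#' @param registry Optional transcript registry tibble (see
#'   [read_registry()]); used only to resolve `gene_hint`.
#' @param params [align_params()] supplying the thresholds.
#' @return The selected `alignment_hit`, or `mapping_failure("no_alignment")`.
#' @export
select_hit <- function(hits, gene_hint = NULL, registry = NULL,
                       params = align_params()) {
  keep <- purrr::keep(hits, function(h) {
    h$identity >= params$min_identity && h$coverage >= params$min_coverage
  })
  if (length(keep) == 0) {
    return(mapping_failure("no_alignment"))
  }
  scores <- purrr::map_dbl(keep, "score")
  in_locus <- rep(FALSE, length(keep))
  if (!is.null(gene_hint) && !is.null(registry)) {
    loci <- registry[registry$gene == gene_hint, , drop = FALSE]
    if (nrow(loci) > 0) {
      in_locus <- purrr::map_lgl(keep, function(h) {
        any(purrr::pmap_lgl(loci, function(chrom, exons, ...) {
          if (!identical(chrom, h$ref_accession)) {
            return(FALSE)
          }
          lo <- min(exons$start0)
          hi <- max(exons$end0)
          any(h$blocks$r_start < hi & h$blocks$r_end > lo)
        }))
      })
    }
  }
  ord <- order(
    -scores, -in_locus,
    purrr::map_chr(keep, "ref_accession"),
    purrr::map_dbl(keep, function(h) min(h$blocks$r_start))
  )
  keep[[ord[1]]]
}

#' Read BLAT PSL alignments
#'
#' Standard 21-column PSL (header lines are skipped). Minus-strand rows use
#' BLAT's reverse-complemented query coordinates and are converted to this
#' package's contract (query coordinates on the original target, reference
#' coordinates plus-strand).
#'
#' @param path PSL file.
#' @param params [align_params()] for scoring.
#' @return List of `alignment_hit` sorted by descending score.
#' @export
read_psl <- function(path, params = align_params()) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\d", lines)]
  hits <- purrr::map(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 21) {
      abort("malformed PSL row (need 21 columns)", class = "mavemap_psl_error")
    }
    strand <- f[9]
    q_size <- as.integer(f[11])
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    q_starts <- as.integer(strsplit(f[20], ",")[[1]])
    t_starts <- as.integer(strsplit(f[21], ",")[[1]])
    if (strand == "+") {
      blocks <- tibble(
        q_start = q_starts, q_end = q_starts + sizes,
        r_start = t_starts, r_end = t_starts + sizes,
        matches = NA_integer_
      )
    } else {
      blocks <- tibble(
        q_start = q_size - (q_starts + sizes), q_end = q_size - q_starts,
        r_start = t_starts, r_end = t_starts + sizes,
        matches = NA_integer_
      )
    }
    matches <- as.integer(f[1])
    mismatches <- as.integer(f[2])
    aligned <- sum(sizes)
    hit <- structure(
      list(
        ref_accession = f[14], strand = strand, blocks = blocks,
        matches = matches, mismatches = mismatches,
        identity = matches / aligned, coverage = aligned / q_size,
        q_size = q_size, score = NA_real_
      ),
      class = "alignment_hit"
    )
    hit$score <- score_hit(hit, params$gap_open, params$gap_ext)
    hit
  })
  hits[order(-purrr::map_dbl(hits, "score"))]
}
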