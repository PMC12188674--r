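# Pre-/post-mapped variant pairing: variants validated on the target are
# pre-mapped as alleles on the target's computed sequence digest, lifted
# through alignment blocks (nucleotide) or residue offsets (protein) onto
# the selected reference, re-normalized and re-digested there, and each
# pair is classified for concordance by comparing the reference residues
# under the pre- and post-mapped locations.

#' Pre-map validated variants onto the target sequence
#'
#' One normalized, digested allele per variant, on the target's computed
#' sequence id; two or more in-cis variants become a cis-phased block.
#' Out-of-bounds variants cannot be represented on the target and yield no
#' pre-mapped object (the status is carried as the pair reason); variants
#' whose stated reference residues mismatch the target are still pre-mapped
#' (the assay measured them) with the mismatch recorded.
#'
#' @param variants Tibble from [validate_variants()] (interbase + status).
#' @param target_record A `sequence_record` for the registered target.
#' @param store [seq_store()].
#' @return List with `obj` (allele / cis-phased block / `NULL`), `members`
#'   (list of alleles in record order), and `reason`
#'   (`"none"`, `"ref_mismatch"`, `"out_of_bounds"`).
#' @export
premap <- function(variants, target_record, store) {
  if (any(variants$status == "out_of_bounds")) {
    return(list(obj = NULL, members = NULL, reason = "out_of_bounds"))
  }
  members <- purrr::pmap(
    variants[c("start0", "end0", "alt")],
    function(start0, end0, alt) {
      a <- make_allele(store, target_record$seq_id, start0, end0, alt)
      digest_allele(normalize_allele(a, store))
    }
  )
  obj <- if (length(members) == 1) members[[1]] else make_cpb(members)
  reason <- if (any(variants$status == "ref_mismatch")) "ref_mismatch" else "none"
  list(obj = obj, members = members, reason = reason)
}

#' Lift a query interval through an alignment hit
#'
#' A plus-strand interval within one block maps by offset arithmetic; on
#' the minus strand the interval is mirrored within the block. Intervals
#' crossing a reference gap (intron) split into one segment per block.
#' Intervals touching query positions not covered by any block are
#' `unmapped(non_homologous)`; intervals extending past the target are
#' `unmapped(out_of_bounds)`. A zero-length insertion interval at a block
#' boundary is assigned to the 5'-side block on the reference strand.
#'
#' @param hit Selected `alignment_hit`.
#' @param q_start0,q_end0 Interbase query interval (`q_start0 <= q_end0`).
#' @return List with `status` (`single`/`split`/`unmapped`), `segments`
#'   (tibble `r_start0`, `r_end0`, `q_start0`, `q_end0`, query-ascending),
#'   `strand`, and `reason` when unmapped.
#' @export
lift_interval <- function(hit, q_start0, q_end0) {
  stopifnot(q_start0 >= 0, q_end0 >= q_start0)
  if (q_end0 > hit$q_size) {
    return(list(
      status = "unmapped", segments = NULL, strand = hit$strand,
      reason = "out_of_bounds"
    ))
  }
  b <- hit$blocks[order(hit$blocks$q_start), , drop = FALSE]
  minus <- hit$strand == "-"
  map_point <- function(blk, q) {
    if (minus) blk$r_start + (blk$q_end - q) else blk$r_start + (q - blk$q_start)
  }
  if (q_start0 == q_end0) {
    cand <- which(b$q_start <= q_start0 & q_start0 <= b$q_end)
    if (length(cand) == 0) {
      return(list(
        status = "unmapped", segments = NULL, strand = hit$strand,
        reason = "non_homologous"
      ))
    }
    i <- cand[which.min(b$r_start[cand])]
    r <- map_point(b[i, ], q_start0)
    return(list(
      status = "single",
      segments = tibble(
        r_start0 = r, r_end0 = r, q_start0 = q_start0, q_end0 = q_end0
      ),
      strand = hit$strand, reason = NULL
    ))
  }
  s <- pmax(q_start0, b$q_start)
  e <- pmin(q_end0, b$q_end)
  keep <- which(e > s)
  covered <- sum(pmax(0L, e - s))
  if (covered < q_end0 - q_start0) {
    return(list(
      status = "unmapped", segments = NULL, strand = hit$strand,
      reason = "non_homologous"
    ))
  }
  segs <- purrr::map(keep, function(i) {
    blk <- b[i, ]
    if (minus) {
      tibble(
        r_start0 = blk$r_start + (blk$q_end - e[i]),
        r_end0 = blk$r_start + (blk$q_end - s[i]),
        q_start0 = s[i], q_end0 = e[i]
      )
    } else {
      tibble(
        r_start0 = blk$r_start + (s[i] - blk$q_start),
        r_end0 = blk$r_start + (e[i] - blk$q_start),
        q_start0 = s[i], q_end0 = e[i]
      )
    }
  }) |> dplyr::bind_rows()
  segs <- segs[order(segs$q_start0), , drop = FALSE]
  list(
    status = if (nrow(segs) > 1) "split" else "single",
    segments = segs, strand = hit$strand, reason = NULL
  )
}

#' Post-map a nucleotide variant through an alignment hit
#'
#' The variant's interbase interval is lifted through the blocks; the
#' alternate sequence replaces the reference at the lifted location
#' (reverse-complemented on minus-strand hits). Lifts that split across
#' blocks become cis-phased blocks of per-block alleles, with the
#' informational reason `exon_spanning`; unliftable intervals return no
#' object with the lift reason. Results are normalized and re-digested on
#' the reference sequence, so the mapped variant has a distinct identifier.
#'
#' @param v One parsed/validated variant row (with `start0`, `end0`, `alt`).
#' @param hit Selected `alignment_hit` whose `ref_accession` is registered
#'   in `store`.
#' @param store [seq_store()].
#' @return List with `obj`, `members` (query-ascending alleles), `reason`.
#' @export
postmap_nucleotide <- function(v, hit, store) {
  lift <- lift_interval(hit, v$start0, v$end0)
  if (lift$status == "unmapped") {
    return(list(obj = NULL, members = NULL, reason = lift$reason))
  }
  minus <- lift$strand == "-"
  segs <- lift$segments
  n_seg <- nrow(segs)
  qlen <- v$end0 - v$start0
  alts <- if (n_seg == 1) {
    v$alt
  } else if (nzchar(v$alt) && nchar(v$alt) == qlen) {
    substr(
      rep(v$alt, n_seg),
      segs$q_start0 - v$start0 + 1L, segs$q_end0 - v$start0
    )
  } else if (!nzchar(v$alt)) {
    rep("", n_seg)
  } else {
    # length-changing edit across a block boundary: the full alternate is
    # carried on the first query segment
    c(v$alt, rep("", n_seg - 1L))
  }
  members <- purrr::map(seq_len(n_seg), function(i) {
    alt_i <- if (minus && nzchar(alts[i])) reverse_complement(alts[i]) else alts[i]
    a <- make_allele(store, hit$ref_accession, segs$r_start0[i], segs$r_end0[i], alt_i)
    digest_allele(normalize_allele(a, store))
  })
  obj <- if (n_seg == 1) members[[1]] else make_cpb(members)
  list(
    obj = obj, members = members,
    reason = if (lift$status == "split") "exon_spanning" else "none"
  )
}

#' Post-map a protein variant through a transcript selection
#'
#' The residue offset locating the MAVE protein within the reference
#' protein is added to the variant's start and end.
#'
#' @param v One parsed/validated variant row.
#' @param sel One-row registry tibble from [rank_and_select()], with an
#'   `offset_aa` column.
#' @param store [seq_store()] with `sel$protein_accession` registered.
#' @return List with `obj`, `members`, `reason`.
#' @export
postmap_protein <- function(v, sel, store) {
  ref_len <- seq_length(store, sel$protein_accession)
  s0 <- v$start0 + sel$offset_aa
  e0 <- v$end0 + sel$offset_aa
  if (e0 > ref_len || s0 < 0) {
    return(list(obj = NULL, members = NULL, reason = "out_of_bounds"))
  }
  a <- make_allele(store, sel$protein_accession, s0, e0, v$alt)
  a <- digest_allele(normalize_allele(a, store))
  list(obj = a, members = list(a), reason = "none")
}

fetch_allele_ref <- function(allele, store) {
  fetch_subseq(store, allele$seq_id, allele$start0, allele$end0)
}

#' Annotate a pre-/post-mapped pair with reference residues and concordance
#'
#' `pre_ref` is the target residue string under the pre-mapped location(s);
#' `post_ref` the reference residues under the post-mapped location(s),
#' with minus-strand genomic segments reverse-complemented into target
#' orientation and concatenated in query order. The pair is concordant iff
#' a post-mapped object exists, no discordance reason was recorded, and
#' `pre_ref == post_ref`; an unexplained difference is classified
#' `ref_mismatch`.
#'
#' @param pair A pair list (internal structure produced by
#'   [map_score_set()]).
#' @param store [seq_store()].
#' @return The pair with `pre_ref`, `post_ref`, `concordant`, `reason`.
#' @export
annotate_concordance <- function(pair, store) {
  pre_ref <- if (is.null(pair$pre_members)) {
    NA_character_
  } else {
    paste(purrr::map_chr(pair$pre_members, fetch_allele_ref, store = store),
      collapse = ""
    )
  }
  post_ref <- NA_character_
  if (!is.null(pair$post_members)) {
    minus <- identical(pair$strand, "-")
    # members are kept in query-ascending order, so per-member reverse
    # complementation alone restores target orientation on the minus strand
    refs <- purrr::map_chr(pair$post_members, function(a) {
      r <- fetch_allele_ref(a, store)
      if (minus && nzchar(r)) reverse_complement(r) else r
    })
    post_ref <- paste(refs, collapse = "")
  }
  pair$pre_ref <- pre_ref
  pair$post_ref <- post_ref
  if (pair$reason == "none" && !is.null(pair$post_members) &&
    !identical(pre_ref, post_ref)) {
    pair$reason <- "ref_mismatch"
  }
  pair$concordant <- !is.null(pair$post_members) && pair$reason == "none" &&
    identical(pre_ref, post_ref)
  pair
}

REASON_LEVELS <- c(
  "none", "exon_spanning", "non_homologous", "out_of_bounds",
  "ref_mismatch", "offset_failure", "no_alignment", "no_transcript"
)

combine_reasons <- function(reasons) {
  # blocking > informational > validation mismatch > none
  priority <- c(
    non_homologous = 1, out_of_bounds = 2, offset_failure = 3,
    exon_spanning = 4, ref_mismatch = 5, none = 9
  )
  reasons[order(priority[reasons])][1]
}

#' Map a whole score set to the reference
#'
#' The three-step procedure: (1) DNA targets are aligned to the reference
#' genome and one representative hit is selected (protein targets skip
#' alignment); (2) a representative transcript/protein is selected --
#' MANE-tiered -- and, for protein targets, the residue offset of the MAVE
#' sequence within the reference protein is computed; (3) every variant
#' record is pre-mapped on the target, post-mapped on the reference, and
#' the pair is classified for concordance. Whole-set failures
#' (`no_alignment`, `no_transcript`) are returned as failure values.
#'
#' @param ss A [load_score_set()] result.
#' @param genome Named character vector of reference sequences, a
#'   [seq_store()], or a prebuilt [build_seed_index()].
#' @param registry Optional transcript registry tibble (required for
#'   protein targets; used for gene-hint tie-breaks on DNA targets).
#' @param params [align_params()].
#' @param store Optional [seq_store()] to reuse; a fresh one by default.
#' @return A `mapping_result`, or a `mave_failure`.
#' @export
map_score_set <- function(ss, genome, registry = NULL,
                          params = align_params(), store = seq_store()) {
  stopifnot(inherits(ss, "score_set"))
  meta <- ss$meta
  target_kind <- meta$target_sequence_type
  target_rec <- register_sequence(store, meta$target_sequence, target_kind)
  computed_ref <- list(
    sequence = target_rec$residues,
    sequence_type = target_kind,
    sequence_id = target_rec$seq_id
  )

  hit <- NULL
  sel <- NULL
  if (target_kind == "dna") {
    index <- if (inherits(genome, "seed_index")) {
      genome
    } else {
      build_seed_index(genome, params$k)
    }
    hits <- align_target(meta$target_sequence, index, params)
    hit <- select_hit(hits, gene_hint = meta$gene_hint, registry = registry, params = params)
    if (is_failure(hit)) {
      return(hit)
    }
    register_sequence(store, index$seqs[[hit$ref_accession]], "dna",
      accession = hit$ref_accession
    )
    mapped_ref <- list(
      accession = hit$ref_accession,
      sequence_type = "dna",
      sequence_id = store$acc[[hit$ref_accession]]
    )
    driving <- "hgvs_nt"
  } else {
    if (is.null(registry) || nrow(registry) == 0) {
      return(mapping_failure("no_transcript"))
    }
    cands <- if (!is.null(meta$gene_hint)) {
      tx_candidates(registry, gene_hint = meta$gene_hint)
    } else {
      registry
    }
    if (nrow(cands) == 0) {
      return(mapping_failure("no_transcript"))
    }
    offsets <- purrr::map(cands$protein_seq, function(p) {
      compute_offset(meta$target_sequence, p, min_identity = 0.5)
    })
    viable <- !purrr::map_lgl(offsets, is_failure)
    if (!any(viable)) {
      return(mapping_failure("no_transcript"))
    }
    sel <- rank_and_select(cands[viable, , drop = FALSE])
    off <- offsets[viable][[match(sel$tx_accession, cands$tx_accession[viable])]]
    sel$offset_aa <- off$offset_aa
    sel$offset_identity <- off$identity
    register_sequence(store, sel$protein_seq, "protein",
      accession = sel$protein_accession
    )
    mapped_ref <- list(
      accession = sel$protein_accession,
      sequence_type = "protein",
      sequence_id = store$acc[[sel$protein_accession]]
    )
    driving <- "hgvs_pro"
  }

  n_no_change <- 0L
  n_undriven <- 0L
  pairs <- vector("list", nrow(ss$records))
  for (i in seq_len(nrow(ss$records))) {
    rec <- ss$records[i, ]
    expr <- rec[[driving]]
    if (is.na(expr)) {
      n_undriven <- n_undriven + 1L
      pairs[[i]] <- NULL
      next
    }
    v <- parse_mave_hgvs(expr)
    if (all(v$no_change)) {
      n_no_change <- n_no_change + 1L
      pairs[[i]] <- NULL
      next
    }
    v <- v[!v$no_change, , drop = FALSE]
    v <- validate_variants(v, meta$target_sequence)
    pre <- premap(v, target_rec, store)

    post_obj <- NULL
    post_members <- NULL
    reason <- pre$reason
    if (reason != "out_of_bounds") {
      post_groups <- purrr::map(seq_len(nrow(v)), function(j) {
        if (target_kind == "dna") {
          postmap_nucleotide(v[j, ], hit, store)
        } else {
          postmap_protein(v[j, ], sel, store)
        }
      })
      post_reasons <- purrr::map_chr(post_groups, "reason")
      reason <- combine_reasons(c(reason, post_reasons))
      if (!any(post_reasons %in% c("non_homologous", "out_of_bounds"))) {
        post_members <- unlist(purrr::map(post_groups, "members"),
          recursive = FALSE
        )
        post_obj <- if (length(post_members) == 1) {
          post_members[[1]]
        } else {
          make_cpb(post_members)
        }
      }
    }

    pair <- list(
      accession = rec$accession,
      score = rec$score,
      pre_obj = pre$obj, pre_members = pre$members,
      post_obj = post_obj, post_members = post_members,
      strand = if (!is.null(hit)) hit$strand else "+",
      reason = reason
    )
    pair <- annotate_concordance(pair, store)
    pair$post_hgvs <- NA_character_
    if (!is.null(pair$post_members)) {
      level <- if (target_kind == "dna") "g" else "p"
      acc <- mapped_ref$accession
      pair$post_hgvs <- paste(
        purrr::map_chr(pair$post_members, allele_hgvs,
          accession = acc, level = level, store = store
        ),
        collapse = ";"
      )
    }
    pairs[[i]] <- pair
  }
  pairs <- purrr::compact(pairs)

  pairs_tbl <- tibble(
    accession = purrr::map_chr(pairs, "accession"),
    pre_mapped = purrr::map(pairs, "pre_obj"),
    post_mapped = purrr::map(pairs, "post_obj"),
    pre_ref = purrr::map_chr(pairs, "pre_ref"),
    post_ref = purrr::map_chr(pairs, "post_ref"),
    concordant = purrr::map_lgl(pairs, "concordant"),
    reason = purrr::map_chr(pairs, "reason"),
    post_hgvs = purrr::map_chr(pairs, "post_hgvs"),
    score = purrr::map_dbl(pairs, "score"),
    strand = purrr::map_chr(pairs, "strand")
  )

  by_reason <- table(factor(pairs_tbl$reason, levels = REASON_LEVELS))
  summary <- list(
    n_records = nrow(ss$records),
    n_pairs = nrow(pairs_tbl),
    n_no_change = n_no_change,
    n_undriven = n_undriven,
    n_concordant = sum(pairs_tbl$concordant),
    fraction_concordant = if (nrow(pairs_tbl) > 0) {
      sum(pairs_tbl$concordant) / nrow(pairs_tbl)
    } else {
      0
    },
    by_reason = stats::setNames(as.integer(by_reason), names(by_reason))
  )

  structure(
    list(
      urn = meta$urn,
      meta = meta,
      computed_reference_sequence = computed_ref,
      mapped_reference_sequence = mapped_ref,
      selection = list(hit = hit, transcript = sel),
      pairs = pairs_tbl,
      summary = summary,
      store = store
    ),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result ", x$urn, ": ", x$summary$n_pairs, " pairs, ",
    sprintf("%.1f%%", 100 * x$summary$fraction_concordant), " concordant, ",
    "mapped to ", x$mapped_reference_sequence$accession, ">\n",
    sep = ""
  )
  invisible(x)
}
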