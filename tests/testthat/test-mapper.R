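# Mapper: pre-mapping, interval liftover (with a per-base oracle),
# nucleotide and protein post-mapping, concordance annotation, and
# whole-score-set mapping including failure values.

two_block_hit <- function() {
  structure(list(
    ref_accession = "NC_M.1", strand = "+",
    blocks = tibble::tibble(
      q_start = c(0L, 10L), q_end = c(10L, 20L),
      r_start = c(100L, 200L), r_end = c(110L, 210L), matches = c(10L, 10L)
    ),
    matches = 20L, mismatches = 0L, identity = 1, coverage = 1,
    q_size = 20L, score = 20
  ), class = "alignment_hit")
}

test_that("lift arithmetic matches the worked examples", {
  h <- two_block_hit()
  single <- lift_interval(h, 12L, 13L)
  expect_identical(single$status, "single")
  expect_equal(unlist(single$segments[1, c("r_start0", "r_end0")], use.names = FALSE), c(202L, 203L))

  split <- lift_interval(h, 8L, 12L)
  expect_identical(split$status, "split")
  expect_equal(split$segments$r_start0, c(108L, 200L))
  expect_equal(split$segments$r_end0, c(110L, 202L))

  minus <- structure(list(
    ref_accession = "NC_M.1", strand = "-",
    blocks = tibble::tibble(
      q_start = 0L, q_end = 10L, r_start = 100L, r_end = 110L, matches = 10L
    ),
    matches = 10L, mismatches = 0L, identity = 1, coverage = 1,
    q_size = 10L, score = 10
  ), class = "alignment_hit")
  res <- lift_interval(minus, 2L, 3L)
  expect_equal(unlist(res$segments[1, c("r_start0", "r_end0")], use.names = FALSE), c(107L, 108L))
})

test_that("minus-strand lifts agree with a reverse-complement re-derivation", {
  # lifting (qs,qe) on a minus hit must equal lifting the mirrored interval
  # on the equivalent plus hit over the reverse-complemented reference
  set.seed(41)
  for (trial in 1:50) {
    h <- random_hit(strand = "-")
    L <- h$q_size
    plus <- h
    plus$strand <- "+"
    plus$blocks <- tibble::tibble(
      q_start = L - h$blocks$q_end, q_end = L - h$blocks$q_start,
      r_start = h$blocks$r_start, r_end = h$blocks$r_end,
      matches = h$blocks$matches
    )
    qs <- sample(0:(L - 1), 1)
    qe <- min(L, qs + sample(1:6, 1))
    res <- lift_interval(h, qs, qe)
    mirror <- lift_interval(plus, L - qe, L - qs)
    expect_identical(res$status, mirror$status)
    if (res$status != "unmapped") {
      expect_setequal(
        paste(res$segments$r_start0, res$segments$r_end0),
        paste(mirror$segments$r_start0, mirror$segments$r_end0)
      )
    }
  }
})

test_that("liftover agrees with a naive per-base map on random block alignments", {
  set.seed(42)
  for (trial in 1:120) {
    h <- random_hit()
    base_map <- naive_base_map(h)
    qs <- sample(0:(h$q_size - 1), 1)
    qe <- min(h$q_size, qs + sample(1:8, 1))
    res <- lift_interval(h, qs, qe)
    covered <- as.character(qs:(qe - 1))
    if (all(covered %in% names(base_map))) {
      expect_false(res$status == "unmapped", info = paste("trial", trial))
      expect_identical(lift_to_base_map(res)[covered], base_map[covered],
        info = paste("trial", trial)
      )
    } else {
      expect_identical(res$status, "unmapped")
      expect_identical(res$reason, "non_homologous")
    }
  }
})

test_that("out-of-range and uncovered intervals are classified", {
  h <- two_block_hit()
  oob <- lift_interval(h, 18L, 25L)
  expect_identical(oob$reason, "out_of_bounds")
  # zero-length insertion point at the junction goes to the 5' reference block
  j <- lift_interval(h, 10L, 10L)
  expect_identical(j$status, "single")
  expect_equal(j$segments$r_start0, 110L)
})

test_that("pre-mapping builds alleles on the target digest, CPBs for in-cis", {
  st <- seq_store()
  tr <- register_sequence(st, "AAAGAAAAACGT", "dna")
  v <- validate_variants(parse_mave_hgvs("c.4G>T"), tr$residues)
  pre <- premap(v, tr, st)
  expect_s3_class(pre$obj, "allele")
  expect_identical(c(pre$obj$start0, pre$obj$end0, pre$obj$state), c("3", "4", "T"))
  expect_identical(pre$reason, "none")

  v2 <- validate_variants(parse_mave_hgvs("[c.1A>T;c.9_10del]"), tr$residues)
  pre2 <- premap(v2, tr, st)
  expect_s3_class(pre2$obj, "cis_phased_block")
  expect_length(pre2$members, 2L)

  v3 <- validate_variants(parse_mave_hgvs("c.20A>T"), tr$residues)
  pre3 <- premap(v3, tr, st)
  expect_null(pre3$obj)
  expect_identical(pre3$reason, "out_of_bounds")
})

test_that("nucleotide post-mapping lifts, splits and reverse-complements state", {
  st <- seq_store()
  set.seed(43)
  refseq <- random_dna_str(400)
  register_sequence(st, refseq, "dna", accession = "NC_M.1")
  h <- two_block_hit()
  # a real substitution at the lifted position (202, 203)
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(refseq, 203, 203))[1]
  v <- tibble::tibble(start0 = 12L, end0 = 13L, alt = alt_base, kind = "substitution")
  res <- postmap_nucleotide(v, h, st)
  expect_identical(res$reason, "none")
  expect_equal(res$obj$start0, 202L)

  vdel <- tibble::tibble(start0 = 8L, end0 = 12L, alt = "", kind = "deletion")
  res2 <- postmap_nucleotide(vdel, h, st)
  expect_identical(res2$reason, "exon_spanning")
  expect_s3_class(res2$obj, "cis_phased_block")
  expect_length(res2$members, 2L)

  minus <- h
  minus$strand <- "-"
  # minus-strand lift of (12,13) lands at (207,208); pick a real change there
  alt2 <- setdiff(c("A", "C", "G", "T"), substr(refseq, 208, 208))[1]
  v2 <- tibble::tibble(start0 = 12L, end0 = 13L, alt = reverse_complement(alt2))
  res3 <- postmap_nucleotide(v2, minus, st)
  expect_identical(res3$members[[1]]$state, alt2)
  expect_equal(res3$obj$start0, 207L)
})

test_that("protein post-mapping applies the residue offset and bounds-checks", {
  st <- seq_store()
  prot <- paste(rep("A", 120), collapse = "")
  register_sequence(st, prot, "protein", accession = "NP_M.1")
  sel <- tibble::tibble(protein_accession = "NP_M.1", offset_aa = 90L)
  v <- tibble::tibble(start0 = 23L, end0 = 24L, alt = "C")
  res <- postmap_protein(v, sel, st)
  expect_equal(c(res$obj$start0, res$obj$end0), c(113L, 114L))
  v0 <- tibble::tibble(start0 = 0L, end0 = 1L, alt = "G")
  sel0 <- tibble::tibble(protein_accession = "NP_M.1", offset_aa = 0L)
  expect_equal(postmap_protein(v0, sel0, st)$obj$start0, 0L)
  far <- tibble::tibble(start0 = 499L, end0 = 500L, alt = "")
  expect_identical(postmap_protein(far, sel, st)$reason, "out_of_bounds")
})

test_that("concordance compares reference strings in target orientation", {
  st <- seq_store()
  tseq <- "ACGTACGTAC"
  tr <- register_sequence(st, tseq, "dna")
  register_sequence(st, paste0("TTTT", tseq, "TTTT"), "dna", accession = "NC_C.1")
  pre <- digest_allele(normalize_allele(make_allele(st, tr$seq_id, 2, 3, "T"), st))
  post <- digest_allele(normalize_allele(make_allele(st, "NC_C.1", 6, 7, "T"), st))
  pair <- list(
    pre_members = list(pre), post_members = list(post),
    strand = "+", reason = "none"
  )
  out <- annotate_concordance(pair, st)
  expect_true(out$concordant)
  expect_identical(out$pre_ref, out$post_ref)

  # mismatching reference under the post-mapped location
  post_bad <- digest_allele(normalize_allele(make_allele(st, "NC_C.1", 0, 1, "T"), st))
  pair_bad <- list(
    pre_members = list(pre), post_members = list(post_bad),
    strand = "+", reason = "none"
  )
  out_bad <- annotate_concordance(pair_bad, st)
  expect_false(out_bad$concordant)
  expect_identical(out_bad$reason, "ref_mismatch")

  # absent post-mapped object preserves the earlier reason
  pair_abs <- list(
    pre_members = list(pre), post_members = NULL,
    strand = "+", reason = "non_homologous"
  )
  out_abs <- annotate_concordance(pair_abs, st)
  expect_false(out_abs$concordant)
  expect_identical(out_abs$reason, "non_homologous")
})

test_that("whole-set mapping fails cleanly without alignment or transcript", {
  fx <- shared_fixture()
  set.seed(44)
  meta <- list(
    urn = "urn:test:junk", target_name = "JUNK",
    target_sequence = random_dna_str(120), target_sequence_type = "dna",
    target_type = "protein_coding"
  )
  tab <- tibble::tibble(
    accession = "urn:test:junk#1", hgvs_nt = "c.5A>T",
    hgvs_pro = NA_character_, score = 1
  )
  ss <- load_score_set(meta, tab)
  res <- map_score_set(ss, fx$sequences, registry = fx$registry)
  expect_s3_class(res, "mave_failure")
  expect_identical(res$reason, "no_alignment")

  pmeta <- list(
    urn = "urn:test:prot", target_name = "PROT",
    target_sequence = "WWWWWWWWWWWWWWWWWWWW", target_sequence_type = "protein",
    target_type = "protein_coding"
  )
  ptab <- tibble::tibble(
    accession = "urn:test:prot#1", hgvs_nt = NA_character_,
    hgvs_pro = "p.Trp5Cys", score = 1
  )
  pss <- load_score_set(pmeta, ptab)
  pres <- map_score_set(pss, fx$sequences, registry = fx$registry)
  expect_s3_class(pres, "mave_failure")
  expect_identical(pres$reason, "no_transcript")
})

test_that("identical-target mapping keeps states equal while ids differ", {
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG1", target_design("exact"), seed = 6)
  b <- make_score_set(tgt, "saturation_nt", seed = 6)
  mr <- map_score_set(b$score_set, fx$sequences, registry = fx$registry)
  expect_equal(mr$summary$fraction_concordant, 1.0)
  pre <- mr$pairs$pre_mapped[[1]]
  post <- mr$pairs$post_mapped[[1]]
  expect_identical(pre$state, post$state)
  expect_false(identical(pre$allele_id, post$allele_id)) # provenance preserved
  expect_false(identical(pre$seq_id, post$seq_id))
  # reason counts partition the records
  s <- mr$summary
  expect_equal(sum(s$by_reason) + s$n_no_change + s$n_undriven, s$n_records)
  # every pre-mapped location lies on the computed reference sequence
  expect_true(all(purrr::map_lgl(mr$pairs$pre_mapped, function(x) {
    members <- if (inherits(x, "allele")) list(x) else x$members
    all(purrr::map_chr(members, "seq_id") == mr$computed_reference_sequence$sequence_id)
  })))
})

test_that("wild-type rows are counted but not mapped", {
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG1", target_design("exact"), seed = 6)
  meta <- tgt$meta
  tab <- tibble::tibble(
    accession = paste0(meta$urn, "#", 1:3),
    hgvs_nt = c("c.5A>T", "_wt", "c.="),
    hgvs_pro = NA_character_,
    score = c(0.1, 0, 0)
  )
  tab$hgvs_nt[1] <- sprintf(
    "c.5%s>%s", substr(meta$target_sequence, 5, 5),
    setdiff(c("A", "C", "G", "T"), substr(meta$target_sequence, 5, 5))[1]
  )
  ss <- load_score_set(meta, tab)
  mr <- map_score_set(ss, fx$sequences, registry = fx$registry)
  expect_equal(mr$summary$n_no_change, 2L)
  expect_equal(mr$summary$n_pairs, 1L)
})

test_that("post-mapped HGVS re-resolves to the post-mapped identifier", {
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG2", target_design("exact"), seed = 7)
  b <- make_score_set(tgt, "saturation_nt", seed = 7)
  mr <- map_score_set(b$score_set, fx$sequences, registry = fx$registry)
  idx <- which(purrr::map_lgl(mr$pairs$post_mapped, function(x) inherits(x, "allele")))
  idx <- idx[seq(1, length(idx), by = 7)]
  for (i in idx) {
    back <- resolve_hgvs(mr$pairs$post_hgvs[i], mr$store)
    expect_identical(back$allele_id, mr$pairs$post_mapped[[i]]$allele_id)
  }
})
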