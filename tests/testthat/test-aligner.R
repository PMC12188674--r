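# Seed-chain-extend aligner: index construction, exact and structured
# alignments, strand handling, scoring, hit selection, PSL ingestion.

test_that("the seed index enumerates k-mer positions", {
  idx <- build_seed_index(c(chr1 = "ACGTACGT"), k = 4)
  hit <- idx$h[["ACGT"]]
  expect_identical(sort(unlist(purrr::map(hit, "pos0"))), c(0L, 4L))
  expect_error(build_seed_index(character(0), 4), class = "mavemap_index_error")
  expect_error(
    build_seed_index(c(chr1 = "ACGTACGT"), k = 9),
    class = "mavemap_index_error"
  )
})

test_that("an exact substring aligns as one full-coverage block", {
  set.seed(21)
  ref <- random_dna_str(400)
  target <- substr(ref, 101, 150)
  idx <- build_seed_index(c(chrT = ref), k = 11)
  hits <- align_target(target, idx)
  expect_gte(length(hits), 1L)
  h <- hits[[1]]
  expect_identical(h$strand, "+")
  expect_equal(nrow(h$blocks), 1L)
  expect_equal(unlist(h$blocks[1, c("q_start", "q_end", "r_start", "r_end")],
    use.names = FALSE
  ), c(0L, 50L, 100L, 150L))
  expect_equal(h$identity, 1.0)
  expect_equal(h$coverage, 1.0)
})

test_that("a two-segment target chains into two blocks over a reference gap", {
  set.seed(22)
  ref <- random_dna_str(600)
  target <- paste0(substr(ref, 101, 130), substr(ref, 201, 230))
  idx <- build_seed_index(c(chrT = ref), k = 11)
  h <- align_target(target, idx)[[1]]
  expect_equal(nrow(h$blocks), 2L)
  expect_equal(h$blocks$q_start, c(0L, 30L))
  expect_equal(h$blocks$q_end, c(30L, 60L))
  expect_equal(h$blocks$r_start, c(100L, 200L))
  expect_equal(h$blocks$r_end, c(130L, 230L))
})

test_that("reverse-complemented targets report minus-strand hits with original query coords", {
  set.seed(23)
  ref <- random_dna_str(400)
  target <- reverse_complement(substr(ref, 101, 150))
  idx <- build_seed_index(c(chrT = ref), k = 11)
  h <- align_target(target, idx)[[1]]
  expect_identical(h$strand, "-")
  expect_equal(unlist(h$blocks[1, c("q_start", "q_end", "r_start", "r_end")],
    use.names = FALSE
  ), c(0L, 50L, 100L, 150L))
})

test_that("strand symmetry: aligning rc(target) flips strand, same reference span", {
  set.seed(24)
  for (i in 1:5) {
    ref <- random_dna_str(500)
    target <- substr(ref, 151, 250)
    idx <- build_seed_index(c(chrT = ref), k = 11)
    fwd <- align_target(target, idx)[[1]]
    rev <- align_target(reverse_complement(target), idx)[[1]]
    expect_identical(fwd$strand, "+")
    expect_identical(rev$strand, "-")
    expect_equal(rev$blocks[, c("r_start", "r_end")], fwd$blocks[, c("r_start", "r_end")])
  }
})

test_that("hit scoring follows the stated formula", {
  one_block <- structure(list(
    ref_accession = "x", strand = "+",
    blocks = tibble::tibble(
      q_start = 0L, q_end = 50L, r_start = 0L, r_end = 50L, matches = 50L
    ),
    matches = 50L, mismatches = 0L, identity = 1, coverage = 1, q_size = 50L
  ), class = "alignment_hit")
  expect_equal(score_hit(one_block), 50)
  gapped <- structure(list(
    ref_accession = "x", strand = "+",
    blocks = tibble::tibble(
      q_start = c(0L, 30L), q_end = c(30L, 60L),
      r_start = c(0L, 100L), r_end = c(30L, 130L), matches = c(30L, 30L)
    ),
    matches = 60L, mismatches = 0L, identity = 1, coverage = 1, q_size = 60L
  ), class = "alignment_hit")
  expect_equal(score_hit(gapped), 60 - 2 - 0.05 * log2(71))
  worse <- one_block
  worse$matches <- 48L
  worse$mismatches <- 2L
  expect_lt(score_hit(worse), score_hit(one_block))
})

test_that("hit selection filters on identity/coverage and breaks ties by locus then position", {
  perfect <- structure(list(
    ref_accession = "chrA", strand = "+",
    blocks = tibble::tibble(q_start = 0L, q_end = 50L, r_start = 100L, r_end = 150L, matches = 50L),
    matches = 50L, mismatches = 0L, identity = 1, coverage = 1, q_size = 50L, score = 50
  ), class = "alignment_hit")
  expect_identical(select_hit(list(perfect))$ref_accession, "chrA")

  weak <- perfect
  weak$identity <- 0.2
  weak$matches <- 10L
  expect_s3_class(select_hit(list(weak)), "mave_failure")
  expect_identical(select_hit(list(weak))$reason, "no_alignment")

  other <- perfect
  other$blocks$r_start <- 5000L
  other$blocks$r_end <- 5050L
  registry <- tibble::tibble(
    tx_accession = "NM_X.1", gene = "GENEB", chrom = "chrA", strand = "+",
    exons = list(tibble::tibble(start0 = 4900L, end0 = 5100L)),
    cds_start0 = 4900L, cds_end0 = 5100L,
    protein_accession = "NP_X.1", protein_seq = "M", tags = list(character(0)),
    cds_len = 200L
  )
  picked <- select_hit(list(perfect, other), gene_hint = "GENEB", registry = registry)
  expect_equal(picked$blocks$r_start, 5000L)
  # without a hint, equal scores break to the smallest reference start
  picked2 <- select_hit(list(other, perfect))
  expect_equal(picked2$blocks$r_start, 100L)
})

test_that("aligner recovers exact embeddings block-perfectly (local-alignment oracle)", {
  set.seed(25)
  for (i in 1:12) {
    ref <- random_dna_str(3000)
    len <- sample(30:200, 1)
    at <- sample(1:(3000 - len), 1)
    target <- substr(ref, at, at + len - 1)
    idx <- build_seed_index(c(chrO = ref), k = 11)
    h <- align_target(target, idx)[[1]]
    # independent Smith-Waterman oracle for the embedding location
    aln <- Biostrings::pairwiseAlignment(
      pattern = target, subject = ref, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 5, gapExtension = 2
    )
    oracle_start <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
    expect_equal(nrow(h$blocks), 1L)
    expect_equal(h$blocks$r_start, oracle_start)
    expect_equal(h$blocks$r_end, oracle_start + len)
    expect_equal(h$blocks$q_start, 0L)
    expect_equal(h$blocks$q_end, as.integer(len))
  }
})

test_that("emitted hits satisfy the block and bound invariants", {
  set.seed(26)
  fx <- shared_fixture()
  idx <- build_seed_index(fx$sequences, 11)
  for (gene in c("SYNG1", "SYNG2")) {
    tgt <- derive_target(fx, gene, target_design("mutagenized"), seed = 9)
    hits <- align_target(tgt$meta$target_sequence, idx)
    for (h in hits) {
      expect_true(h$identity >= 0 && h$identity <= 1)
      expect_true(h$coverage >= 0 && h$coverage <= 1)
      b <- h$blocks[order(h$blocks$r_start), ]
      expect_true(all(b$r_end > b$r_start))
      if (nrow(b) > 1) {
        expect_true(all(b$r_start[-1] >= b$r_end[-nrow(b)]))
        qb <- b[order(b$q_start), ]
        expect_true(all(qb$q_start[-1] >= qb$q_end[-nrow(qb)]))
      }
    }
  }
})

test_that("PSL rows convert to hits bit-exactly, including minus strand", {
  psl <- withr::local_tempfile(fileext = ".psl")
  # 60-bp query: plus-strand two blocks; minus-strand single block
  writeLines(c(
    paste(c(
      58, 2, 0, 0, 0, 0, 1, 70, "+", "q1", 60, 0, 60, "chrZ", 1000,
      100, 230, 2, "30,30,", "0,30,", "100,200,"
    ), collapse = "\t"),
    paste(c(
      50, 0, 0, 0, 0, 0, 0, 0, "-", "q2", 50, 0, 50, "chrZ", 1000,
      300, 350, 1, "50,", "0,", "300,"
    ), collapse = "\t")
  ), psl)
  hits <- read_psl(psl)
  plus <- purrr::keep(hits, function(h) h$strand == "+")[[1]]
  expect_equal(plus$blocks$q_start, c(0L, 30L))
  expect_equal(plus$blocks$r_start, c(100L, 200L))
  expect_equal(plus$matches, 58L)
  minus <- purrr::keep(hits, function(h) h$strand == "-")[[1]]
  expect_equal(minus$blocks$q_start, 0L)
  expect_equal(minus$blocks$q_end, 50L)
  expect_equal(minus$blocks$r_start, 300L)
})
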