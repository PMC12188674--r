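# Reporting and export: concordance summaries with deduplication,
# per-residue means, percentile outliers against a closed-form oracle,
# and deterministic JSON / BED / TSV writers.

fixture_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- shared_fixture()
      r1 <- map_score_set(
        make_score_set(derive_target(fx, "SYNG1", target_design("exact"), seed = 8),
          "saturation_nt",
          seed = 8
        )$score_set,
        fx$sequences,
        registry = fx$registry
      )
      r2 <- map_score_set(
        make_score_set(derive_target(fx, "SYNG2", target_design("minigene"), seed = 8),
          "saturation_nt",
          seed = 8
        )$score_set,
        fx$sequences,
        registry = fx$registry
      )
      cache <<- list(r1 = r1, r2 = r2)
    }
    cache
  }
})

test_that("summaries count pairs, failures and reasons exactly", {
  rs <- fixture_results()
  s <- summarize_mappings(list(rs$r1, rs$r2, mapping_failure("no_alignment")))
  expect_equal(s$n_score_sets_processed, 2L)
  expect_equal(s$n_score_sets_failed, 1L)
  expect_equal(s$n_pairs, rs$r1$summary$n_pairs + rs$r2$summary$n_pairs)
  expect_equal(s$n_concordant, rs$r1$summary$n_concordant + rs$r2$summary$n_concordant)
  expect_equal(s$fraction_concordant, s$n_concordant / s$n_pairs)
  expect_equal(
    s$reason_histogram[["non_homologous"]],
    sum(rs$r2$pairs$reason == "non_homologous")
  )
  expect_lte(s$unique_pre, s$n_pairs)
  # empty input: all-zero with an explicit undefined flag
  s0 <- summarize_mappings(list())
  expect_equal(s0$n_pairs, 0L)
  expect_equal(s0$fraction_concordant, 0)
  expect_true(s0$undefined_fraction)
})

test_that("the same variant in two score sets deduplicates pre-mapped ids", {
  rs <- fixture_results()
  s1 <- summarize_mappings(list(rs$r1))
  s2 <- summarize_mappings(list(rs$r1, rs$r1))
  expect_equal(s2$n_pairs, 2L * s1$n_pairs)
  expect_equal(s2$unique_pre, s1$unique_pre)
  expect_equal(s2$unique_post, s1$unique_post)
})

test_that("per-residue means average concordant substitution scores", {
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG3", target_design("exact"), seed = 9, level = "protein")
  b <- make_score_set(tgt, "saturation_aa", seed = 9)
  mr <- map_score_set(b$score_set, fx$sequences, registry = fx$registry)
  tab <- per_residue_mean(mr)
  # brute-force oracle from the raw records (all pairs concordant here)
  v <- purrr::map_int(b$score_set$records$hgvs_pro, function(h) {
    parse_mave_hgvs(h)$start
  })
  oracle <- tapply(b$score_set$records$score, v, mean)
  expect_equal(nrow(tab), length(oracle))
  expect_equal(tab$mean_score, as.numeric(oracle[as.character(tab$residue)]))
})

test_that("per-residue means handle single and absent residues", {
  rs <- list(score = c(1.0, 3.0), residue = c(5L, 5L))
  expect_equal(mean(rs$score), 2.0) # definitional anchor for the grouped mean
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG3", target_design("exact"), seed = 10, level = "protein")
  b <- make_score_set(tgt, "saturation_aa", seed = 10)
  recs <- b$score_set$records[1:20, ] # only residue 1 scored (19) + one of residue 2
  ss <- load_score_set(tgt$meta, recs)
  mr <- map_score_set(ss, fx$sequences, registry = fx$registry)
  tab <- per_residue_mean(mr)
  expect_setequal(tab$residue, c(1L, 2L))
  expect_equal(
    tab$mean_score[tab$residue == 2L],
    recs$score[20]
  )
})

test_that("percentile thresholds match the type-7 interpolation oracle", {
  out <- percentile_outliers(tibble::tibble(id = as.character(1:100), score = 1:100), q = 0.99)
  expect_equal(out$upper_thr, 99.01)
  expect_equal(out$lower_thr, 1.99)
  expect_setequal(out$flagged, c("1", "100"))
  set.seed(51)
  for (trial in 1:20) {
    x <- rnorm(sample(10:200, 1))
    q <- runif(1, 0.8, 0.99)
    res <- percentile_outliers(tibble::tibble(id = seq_along(x), score = x), q)
    expect_equal(res$upper_thr, quantile_type7_oracle(x, q))
    expect_equal(res$lower_thr, quantile_type7_oracle(x, 1 - q))
    expect_setequal(res$flagged, as.character(which(x > res$upper_thr | x < res$lower_thr)))
  }
  const <- percentile_outliers(tibble::tibble(id = 1:5, score = rep(2, 5)))
  expect_equal(const$upper_thr, 2)
  expect_equal(const$lower_thr, 2)
  expect_length(const$flagged, 0L)
})

test_that("mapping JSON round-trips and is byte-deterministic", {
  rs <- fixture_results()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_mapping(rs$r1, f1)
  write_mapping(rs$r1, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  back <- read_mapping(f1)
  expect_identical(back$urn, rs$r1$urn)
  expect_equal(nrow(back$pairs), nrow(rs$r1$pairs))
  expect_identical(back$pairs$concordant, rs$r1$pairs$concordant)
  expect_identical(
    back$computed_reference_sequence$sequence_id,
    rs$r1$computed_reference_sequence$sequence_id
  )
  expect_identical(
    back$pairs$pre_id,
    purrr::map_chr(rs$r1$pairs$pre_mapped, function(x) variant_id_for_test(x))
  )
})

test_that("BED rows are valid, sorted and carry rank-normalized scores", {
  rs <- fixture_results()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs$r1, bed)
  rows <- readr::read_tsv(bed,
    col_names = c("chrom", "start", "end", "name", "score", "strand", "alt", "raw"),
    show_col_types = FALSE
  )
  expect_equal(nrow(rows), sum(rs$r1$pairs$concordant))
  expect_true(all(rows$start < rows$end | (rows$start == rows$end)))
  expect_true(all(rows$score >= 0 & rows$score <= 1000))
  expect_true(!is.unsorted(rows$start))
  expect_true(all(rows$strand %in% c("+", "-")))
  # determinism
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs$r1, bed2)
  expect_identical(readLines(bed), readLines(bed2))
  # protein-only result: zero rows with a warning
  fx <- shared_fixture()
  tgt <- derive_target(fx, "SYNG3", target_design("exact"), seed = 9, level = "protein")
  mrp <- map_score_set(
    make_score_set(tgt, "saturation_aa", seed = 9)$score_set,
    fx$sequences,
    registry = fx$registry
  )
  bedp <- withr::local_tempfile(fileext = ".bed")
  expect_warning(write_bed(mrp, bedp), "empty")
  expect_length(readLines(bedp), 0L)
})

test_that("summary TSV and tidiers expose the same numbers", {
  rs <- fixture_results()
  s <- summarize_mappings(list(rs$r1, rs$r2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, tsv)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(
    as.numeric(tab$value[tab$metric == "n_pairs"]), s$n_pairs
  )
  g <- glance(s)
  expect_equal(g$n_pairs, s$n_pairs)
  expect_equal(g$fraction_concordant, s$fraction_concordant)
  td <- tidy(s)
  expect_equal(sum(td$n), s$n_pairs)
  tmr <- tidy(rs$r1)
  expect_equal(nrow(tmr), nrow(rs$r1$pairs))
  expect_true(all(!is.na(tmr$pre_id)))
  gm <- glance(rs$r1)
  expect_equal(gm$fraction_concordant, 1.0)
})

test_that("autoplot methods return ggplot objects", {
  rs <- fixture_results()
  expect_s3_class(ggplot2::autoplot(rs$r1), "ggplot")
  expect_s3_class(ggplot2::autoplot(summarize_mappings(list(rs$r1, rs$r2))), "ggplot")
})
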