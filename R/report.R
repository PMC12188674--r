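# Aggregation and export: concordance summaries across score sets,
# per-residue score averages, percentile outlier calling, and JSON / BED /
# TSV writers. Writers are deterministic (sorted keys, fixed column order)
# so identical inputs produce byte-identical files.

#' Summarize concordance across mapping results
#'
#' Counts pairs and concordant pairs, deduplicates pre-mapped ids across
#' score sets and post-mapped ids among concordant pairs, and histograms
#' the discordance reasons. Whole-set failures count as failed score sets
#' with zero pairs.
#'
#' @param results A list of `mapping_result` and/or `mave_failure` objects
#'   (a single result is accepted).
#' @return A `concordance_summary` list.
#' @export
summarize_mappings <- function(results) {
  if (inherits(results, "mapping_result") || is_failure(results)) {
    results <- list(results)
  }
  failed <- purrr::map_lgl(results, is_failure)
  ok <- results[!failed]
  pairs <- purrr::map(ok, "pairs")
  all_pairs <- if (length(pairs) > 0) dplyr::bind_rows(pairs) else tibble()
  n_pairs <- nrow(all_pairs)
  n_concordant <- if (n_pairs > 0) sum(all_pairs$concordant) else 0L
  pre_ids <- if (n_pairs > 0) {
    purrr::map_chr(all_pairs$pre_mapped, function(x) {
      if (is.null(x)) NA_character_ else variant_id(x)
    })
  } else {
    character(0)
  }
  post_ids <- if (n_pairs > 0) {
    purrr::map2_chr(all_pairs$post_mapped, all_pairs$concordant, function(x, conc) {
      if (is.null(x) || !conc) NA_character_ else variant_id(x)
    })
  } else {
    character(0)
  }
  reasons <- if (n_pairs > 0) all_pairs$reason else character(0)
  structure(
    list(
      n_score_sets_processed = sum(!failed),
      n_score_sets_failed = sum(failed),
      failure_reasons = table(purrr::map_chr(results[failed], "reason")),
      n_pairs = n_pairs,
      n_concordant = n_concordant,
      fraction_concordant = if (n_pairs > 0) n_concordant / n_pairs else 0,
      undefined_fraction = n_pairs == 0,
      unique_pre = dplyr::n_distinct(stats::na.omit(pre_ids)),
      unique_post = dplyr::n_distinct(stats::na.omit(post_ids)),
      reason_histogram = stats::setNames(
        as.integer(table(factor(reasons, levels = REASON_LEVELS))),
        REASON_LEVELS
      )
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary: ", x$n_pairs, " pairs across ",
    x$n_score_sets_processed, " score set(s) (",
    x$n_score_sets_failed, " failed); ",
    sprintf("%.2f%%", 100 * x$fraction_concordant), " concordant; ",
    x$unique_pre, " unique pre-mapped / ", x$unique_post,
    " unique post-mapped>\n",
    sep = ""
  )
  invisible(x)
}

#' Per-residue mean scores
#'
#' Arithmetic mean of scores of concordant single-residue protein
#' substitutions, grouped by post-mapped residue position (1-based on the
#' reference protein). Rows without scores are excluded; residues with no
#' scored variants are absent from the table.
#'
#' @param mr A `mapping_result` for a protein target.
#' @return Tibble with `residue` and `mean_score`.
#' @export
per_residue_mean <- function(mr) {
  stopifnot(inherits(mr, "mapping_result"))
  p <- mr$pairs
  keep <- p$concordant & !is.na(p$score) &
    purrr::map_lgl(p$post_mapped, function(x) {
      inherits(x, "allele") && x$end0 - x$start0 == 1L
    })
  if (!any(keep)) {
    return(tibble(residue = integer(0), mean_score = numeric(0)))
  }
  tibble(
    residue = purrr::map_int(p$post_mapped[keep], function(a) a$start0 + 1L),
    score = p$score[keep]
  ) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$residue)
}

#' Percentile outliers of a score distribution
#'
#' Thresholds are linear-interpolation (type-7) quantiles at `q` and
#' `1 - q`; flagged ids have scores strictly above the upper or strictly
#' below the lower threshold.
#'
#' @param scores Tibble / data frame with columns `id` and `score` (missing
#'   scores dropped).
#' @param q Upper quantile, default 0.99.
#' @return List with `lower_thr`, `upper_thr`, `flagged` (character ids).
#' @export
percentile_outliers <- function(scores, q = 0.99) {
  scores <- as_tibble(scores)
  stopifnot(all(c("id", "score") %in% names(scores)), q > 0, q < 1)
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  upper <- unname(stats::quantile(scores$score, q, type = 7))
  lower <- unname(stats::quantile(scores$score, 1 - q, type = 7))
  flagged <- scores$id[scores$score > upper | scores$score < lower]
  list(lower_thr = lower, upper_thr = upper, flagged = as.character(flagged))
}

allele_to_list <- function(a) {
  list(
    end = a$end0,
    id = a$allele_id,
    location_id = a$location_id,
    sequence_id = a$seq_id,
    start = a$start0,
    state = a$state,
    type = "Allele"
  )
}

variant_to_list <- function(x) {
  if (is.null(x)) {
    return(NULL)
  }
  if (inherits(x, "allele")) {
    return(allele_to_list(x))
  }
  list(
    id = x$block_id,
    members = purrr::map(x$members, allele_to_list),
    type = "CisPhasedBlock"
  )
}

#' Write a mapping result to JSON
#'
#' Per-score-set JSON with keys `urn`, `computed_reference_sequence`,
#' `mapped_reference_sequence` and `mapped_scores`; keys sorted,
#' newline-terminated, deterministic (byte-identical across runs on the
#' same input).
#'
#' @param mr A `mapping_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mr, path) {
  stopifnot(inherits(mr, "mapping_result"))
  doc <- list(
    computed_reference_sequence = mr$computed_reference_sequence[order(names(mr$computed_reference_sequence))],
    mapped_reference_sequence = mr$mapped_reference_sequence[order(names(mr$mapped_reference_sequence))],
    mapped_scores = purrr::pmap(mr$pairs, function(accession, pre_mapped, post_mapped,
                                                  pre_ref, post_ref, concordant, reason,
                                                  post_hgvs, score, strand) {
      list(
        accession = accession,
        concordant = concordant,
        post_hgvs = if (is.na(post_hgvs)) NULL else post_hgvs,
        post_mapped = variant_to_list(post_mapped),
        post_ref = if (is.na(post_ref)) NULL else post_ref,
        pre_mapped = variant_to_list(pre_mapped),
        pre_ref = if (is.na(pre_ref)) NULL else pre_ref,
        reason = reason,
        score = if (is.na(score)) NULL else score,
        strand = strand
      )
    }),
    urn = mr$urn
  )
  json <- jsonlite::toJSON(doc,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = FALSE
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a mapping JSON back into a pairs table
#'
#' Round-trips the file written by [write_mapping()] into a tibble of
#' pair-level fields (allele objects come back as plain lists).
#'
#' @param path Mapping JSON file.
#' @return List with `urn`, `computed_reference_sequence`,
#'   `mapped_reference_sequence`, `pairs` tibble.
#' @export
read_mapping <- function(path) {
  doc <- jsonlite::read_json(path)
  pairs <- dplyr::bind_rows(purrr::map(doc$mapped_scores, function(m) {
    tibble(
      accession = m$accession,
      concordant = m$concordant,
      reason = m$reason,
      pre_id = m$pre_mapped$id %||% NA_character_,
      post_id = m$post_mapped$id %||% NA_character_,
      pre_ref = m$pre_ref %||% NA_character_,
      post_ref = m$post_ref %||% NA_character_,
      post_hgvs = m$post_hgvs %||% NA_character_,
      score = m$score %||% NA_real_,
      strand = m$strand
    )
  }))
  list(
    urn = doc$urn,
    computed_reference_sequence = doc$computed_reference_sequence,
    mapped_reference_sequence = doc$mapped_reference_sequence,
    pairs = pairs
  )
}

#' Write concordant genomic alleles as BED6+2
#'
#' One row per concordant genomic allele: `chrom`, `start0`, `end0`,
#' `name` (variant accession), `score` (assay score rank-normalized to
#' 0-1000), `strand`, then two extra columns (alternate sequence, raw
#' score). Rows sorted by `(chrom, start)`. Protein-only results produce
#' an empty file with a warning.
#'
#' @param mr A `mapping_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mr, path) {
  stopifnot(inherits(mr, "mapping_result"))
  p <- mr$pairs
  genomic <- mr$mapped_reference_sequence$sequence_type == "dna"
  keep <- genomic & p$concordant &
    purrr::map_lgl(p$post_mapped, function(x) inherits(x, "allele"))
  if (!any(keep)) {
    warn("no concordant genomic alleles; writing an empty BED")
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- tibble(
    chrom = mr$mapped_reference_sequence$accession,
    start0 = purrr::map_int(p$post_mapped[keep], "start0"),
    end0 = purrr::map_int(p$post_mapped[keep], "end0"),
    name = p$accession[keep],
    raw = p$score[keep],
    strand = p$strand[keep],
    alt = purrr::map_chr(p$post_mapped[keep], "state")
  )
  # rank-normalized display score in [0, 1000]
  scored <- !is.na(rows$raw)
  bed_score <- rep(0L, nrow(rows))
  n_sc <- sum(scored)
  if (n_sc == 1) {
    bed_score[scored] <- 500L
  } else if (n_sc > 1) {
    r <- rank(rows$raw[scored], ties.method = "average")
    bed_score[scored] <- as.integer(round(1000 * (r - 1) / (n_sc - 1)))
  }
  rows$score <- bed_score
  rows <- rows[order(rows$chrom, rows$start0, rows$end0, rows$name), , drop = FALSE]
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s",
    rows$chrom, rows$start0, rows$end0, rows$name, rows$score, rows$strand,
    ifelse(nzchar(rows$alt), rows$alt, "-"),
    ifelse(is.na(rows$raw), ".", format(rows$raw, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a concordance summary as TSV
#'
#' @param summary A `concordance_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "concordance_summary"))
  fields <- c(
    "n_score_sets_processed", "n_score_sets_failed", "n_pairs",
    "n_concordant", "fraction_concordant", "unique_pre", "unique_post"
  )
  vals <- purrr::map_chr(fields, function(f) {
    format(summary[[f]], trim = TRUE, scientific = FALSE)
  })
  hist <- summary$reason_histogram
  lines <- c(
    "metric\tvalue",
    paste(fields, vals, sep = "\t"),
    paste(paste0("reason_", names(hist)), hist, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
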