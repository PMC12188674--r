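# broom-style tidiers and ggplot2 methods for mapping results and
# concordance summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mapping result into one row per variant pair
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return A tibble with `accession`, `pre_id`, `post_id`, `pre_ref`,
#'   `post_ref`, `concordant`, `reason`, `post_hgvs`, `score`, `strand`.
#' @export
tidy.mapping_result <- function(x, ...) {
  p <- x$pairs
  tibble(
    accession = p$accession,
    pre_id = purrr::map_chr(p$pre_mapped, function(v) {
      if (is.null(v)) NA_character_ else variant_id(v)
    }),
    post_id = purrr::map_chr(p$post_mapped, function(v) {
      if (is.null(v)) NA_character_ else variant_id(v)
    }),
    pre_ref = p$pre_ref,
    post_ref = p$post_ref,
    concordant = p$concordant,
    reason = p$reason,
    post_hgvs = p$post_hgvs,
    score = p$score,
    strand = p$strand
  )
}

#' One-row summary of a mapping result
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return A one-row tibble of counts and the concordant fraction.
#' @export
glance.mapping_result <- function(x, ...) {
  s <- x$summary
  tibble(
    urn = x$urn,
    mapped_accession = x$mapped_reference_sequence$accession,
    n_records = s$n_records,
    n_pairs = s$n_pairs,
    n_no_change = s$n_no_change,
    n_concordant = s$n_concordant,
    fraction_concordant = s$fraction_concordant
  )
}

#' Tidy a concordance summary into a reason histogram
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return A tibble with `reason` and `n`.
#' @export
tidy.concordance_summary <- function(x, ...) {
  tibble(
    reason = names(x$reason_histogram),
    n = as.integer(x$reason_histogram)
  )
}

#' One-row view of a concordance summary
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(
    n_score_sets_processed = x$n_score_sets_processed,
    n_score_sets_failed = x$n_score_sets_failed,
    n_pairs = x$n_pairs,
    n_concordant = x$n_concordant,
    fraction_concordant = x$fraction_concordant,
    unique_pre = x$unique_pre,
    unique_post = x$unique_post
  )
}

#' Plot the discordance-reason histogram of a mapping result
#'
#' @param object A `mapping_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mapping_result <- function(object, ...) {
  d <- tidy.concordance_summary(summarize_mappings(object))
  d <- d[d$n > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reason, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "variant pairs",
      title = object$urn,
      subtitle = sprintf(
        "%.1f%% concordant", 100 * object$summary$fraction_concordant
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mapping_result
#' @export
autoplot.concordance_summary <- function(object, ...) {
  d <- tidy.concordance_summary(object)
  d <- d[d$n > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reason, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "variant pairs",
      subtitle = sprintf("%.1f%% concordant", 100 * object$fraction_concordant)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-residue mean scores of a protein mapping result
#'
#' @param mr A `mapping_result` for a protein target.
#' @return A ggplot of residue position against mean assay score.
#' @export
plot_residue_scores <- function(mr) {
  d <- per_residue_mean(mr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$mean_score)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "reference residue", y = "mean assay score", title = mr$urn
    ) +
    ggplot2::theme_minimal()
}
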