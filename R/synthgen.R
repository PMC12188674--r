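# Deterministic generator of toy genomes, transcript registries and score
# sets exhibiting the mapping pathologies seen in real MAVE data: targets
# identical to the reference, codon-optimized targets, minigene inserts,
# heavily mutagenized targets, targets truncated relative to their variant
# lists, and exon-spanning multi-nucleotide edits. Every fixture carries a
# machine-checkable truth table of expected per-variant reasons.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  codons <- names(Biostrings::GENETIC_CODE)
  ok <- codons[Biostrings::GENETIC_CODE != "*" ]
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

#' Generate a toy genome fixture with a transcript registry
#'
#' Genes are laid out on one chromosome on alternating strands, each with
#' `exons_per_gene` coding exons of `exon_len` bp separated by
#' `intron_len` bp introns; the CDS starts with ATG and ends with a stop.
#' Every gene gets one MANE Select transcript; the first gene additionally
#' gets a longer untagged transcript using an alternative (longer) final
#' exon, exercising the tier-over-length selection rule. Deterministic
#' under `seed`.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param exons_per_gene Coding exons per transcript.
#' @param exon_len Exon length (bp); `exons_per_gene * exon_len` must be a
#'   multiple of 3.
#' @param intron_len Intron length (bp).
#' @return A `genome_fixture`: list with `sequences` (named character),
#'   `registry` (tibble), `seed`.
#' @export
make_genome <- function(seed = 1L, n_genes = 4L, exons_per_gene = 3L,
                        exon_len = 60L, intron_len = 200L) {
  stopifnot((exons_per_gene * exon_len) %% 3L == 0L, exon_len >= 30L)
  withr::with_seed(seed, {
    chrom_name <- "NC_SYN1.1"
    spacer_len <- 100L
    pieces <- character(0)
    cursor <- 0L
    reg_rows <- list()

    push <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      start <- cursor
      cursor <<- cursor + nchar(s)
      c(start, cursor)
    }

    for (g in seq_len(n_genes)) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      gene <- sprintf("SYNG%d", g)
      n_codons <- (exons_per_gene * exon_len) %/% 3L
      cds <- paste0("ATG", random_codons(n_codons - 2L), "TAA")
      exon_seqs <- substring(
        cds,
        seq(1L, by = exon_len, length.out = exons_per_gene),
        seq(exon_len, by = exon_len, length.out = exons_per_gene)
      )
      push(random_dna(spacer_len))
      if (strand == "+") {
        ivs <- list()
        for (i in seq_len(exons_per_gene)) {
          if (i > 1) push(random_dna(intron_len))
          ivs[[i]] <- push(exon_seqs[i])
        }
      } else {
        # transcript 5'->3' runs right to left on the chromosome
        ivs <- list()
        for (i in seq(exons_per_gene, 1L)) {
          if (i < exons_per_gene) push(random_dna(intron_len))
          ivs[[i]] <- push(reverse_complement(exon_seqs[i]))
        }
      }
      ex_tbl <- dplyr::arrange(
        tibble(
          start0 = purrr::map_int(ivs, function(x) as.integer(x[1])),
          end0 = purrr::map_int(ivs, function(x) as.integer(x[2]))
        ),
        .data$start0
      )
      protein <- sub("\\*$", "", translate_dna(cds))
      reg_rows[[length(reg_rows) + 1L]] <- tibble(
        tx_accession = sprintf("NM_SYN%04d.1", g),
        gene = gene, chrom = chrom_name, strand = strand,
        exons = list(ex_tbl),
        cds_start0 = min(ex_tbl$start0), cds_end0 = max(ex_tbl$end0),
        protein_accession = sprintf("NP_SYN%04d.1", g),
        protein_seq = protein,
        tags = list("MANE_Select")
      )

      if (g == 1L) {
        # longer untagged transcript: alternative final exon, twice as long
        alt_len <- 2L * exon_len
        n_alt_codons <- alt_len %/% 3L
        alt_exon <- paste0(random_codons(n_alt_codons - 1L), "TAA")
        stopifnot(strand == "+")
        push(random_dna(spacer_len))
        alt_iv <- push(alt_exon)
        ex_b <- dplyr::bind_rows(
          ex_tbl[seq_len(exons_per_gene - 1L), ],
          tibble(start0 = as.integer(alt_iv[1]), end0 = as.integer(alt_iv[2]))
        )
        cds_b <- paste0(
          paste(exon_seqs[seq_len(exons_per_gene - 1L)], collapse = ""),
          alt_exon
        )
        reg_rows[[length(reg_rows) + 1L]] <- tibble(
          tx_accession = "NM_SYN0001B.1",
          gene = gene, chrom = chrom_name, strand = strand,
          exons = list(ex_b),
          cds_start0 = min(ex_b$start0), cds_end0 = max(ex_b$end0),
          protein_accession = "NP_SYN0001B.1",
          protein_seq = sub("\\*$", "", translate_dna(cds_b)),
          tags = list(character(0))
        )
      }
    }
    push(random_dna(spacer_len))
    fx <- structure(
      list(
        sequences = stats::setNames(paste(pieces, collapse = ""), chrom_name),
        registry = registry_tibble(reg_rows),
        seed = seed
      ),
      class = "genome_fixture"
    )
    # construction invariant: spliced CDS of every transcript translates to
    # its registered protein plus terminal stop
    for (i in seq_len(nrow(fx$registry))) {
      tx <- fx$registry[i, ]
      stopifnot(identical(
        translate_dna(spliced_cds(tx, fx$sequences)),
        paste0(tx$protein_seq, "*")
      ))
    }
    fx
  })
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat("<genome_fixture: ", length(x$sequences), " chromosome(s), ",
    nrow(x$registry), " transcripts, seed ", x$seed, ">\n",
    sep = ""
  )
  invisible(x)
}

#' Target design specification
#'
#' @param mode One of `exact` (target identical to the reference),
#'   `codon_optimized` (synonymous third-position differences),
#'   `minigene` (an assay-specific insert between two exons that does not
#'   align to the genome), `mutagenized` (random point differences),
#'   `overrun` (target truncated so later variants exceed its length),
#'   `exon_span` (exact target with a listed multi-nucleotide delins
#'   crossing an exon boundary).
#' @param synonymous_rate Per-codon probability of a synonymous swap
#'   (codon_optimized).
#' @param insert_len Minigene insert length (bp).
#' @param missense_rate Per-eligible-base substitution probability
#'   (mutagenized).
#' @param truncate_frac Retained fraction of the target (overrun).
#' @return A `target_design` list.
#' @export
target_design <- function(mode = c(
                            "exact", "codon_optimized", "minigene",
                            "mutagenized", "overrun", "exon_span"
                          ),
                          synonymous_rate = 0.05, insert_len = 30L,
                          missense_rate = 0.2, truncate_frac = 0.8) {
  mode <- match.arg(mode)
  stopifnot(
    synonymous_rate >= 0, synonymous_rate <= 1,
    missense_rate >= 0, missense_rate <= 1
  )
  structure(
    list(
      mode = mode, synonymous_rate = synonymous_rate,
      insert_len = as.integer(insert_len), missense_rate = missense_rate,
      truncate_frac = truncate_frac
    ),
    class = "target_design"
  )
}

# positions (1-based, target coords) of exon boundaries for a spliced CDS
exon_spans_in_target <- function(tx) {
  ex <- if (is.data.frame(tx$exons)) tx$exons else tx$exons[[1]]
  lens <- ex$end0 - ex$start0
  if (identical(tx$strand, "-")) lens <- rev(lens)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)]) + 1L
  tibble(start = starts, end = ends)
}

synonymous_swap <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  sames <- names(gc)[gc == aa & names(gc) != codon]
  # restrict to third-position-only differences
  sames <- sames[substr(sames, 1, 2) == substr(codon, 1, 2)]
  if (length(sames) == 0) {
    return(NULL)
  }
  sample(sames, 1)
}

# intron following/preceding the spliced junction, in transcript orientation
intron_in_tx_orientation <- function(tx, chrom_seq, junction_index) {
  ex <- if (is.data.frame(tx$exons)) tx$exons else tx$exons[[1]]
  if (identical(tx$strand, "+")) {
    s <- ex$end0[junction_index]
    e <- ex$start0[junction_index + 1L]
    substr(chrom_seq, s + 1L, e)
  } else {
    n <- nrow(ex)
    s <- ex$end0[n - junction_index]
    e <- ex$start0[n - junction_index + 1L]
    reverse_complement(substr(chrom_seq, s + 1L, e))
  }
}

#' Derive a target sequence (and truth bookkeeping) from a fixture gene
#'
#' Applies a [target_design()] to the MANE transcript of `gene`:
#' * `exact`: the target is the spliced CDS (`level = "dna"`) or the
#'   reference protein (`level = "protein"`).
#' * `codon_optimized`: synonymous third-position codon swaps at
#'   `synonymous_rate` (at least one), positions recorded.
#' * `minigene`: an `insert_len`-bp insert spliced between the first two
#'   exons, constructed base-wise non-homologous to the flanking intron so
#'   it cannot align; insert coordinates recorded.
#' * `mutagenized`: random substitutions at `missense_rate`, positions
#'   recorded.
#' * `overrun`: the target is truncated to `truncate_frac` of the CDS, but
#'   the variant list is generated over the full CDS.
#' * `exon_span`: exact target plus a listed same-length delins whose
#'   interval crosses the first exon junction.
#'
#' Edited positions are kept >= 13 bp from exon boundaries so every exon
#' end remains exactly alignable; this is what makes the expected per-variant
#' classification exact rather than approximate.
#'
#' @param fx A [make_genome()] fixture.
#' @param gene Gene symbol in the fixture registry.
#' @param design A [target_design()].
#' @param seed Integer seed for the design's randomness.
#' @param level `"dna"` or `"protein"` (protein only for `exact`).
#' @return A `target_fixture`: list with `meta` (six-field metadata list)
#'   and `truth` bookkeeping.
#' @export
derive_target <- function(fx, gene, design = target_design("exact"),
                          seed = 1L, level = c("dna", "protein")) {
  level <- match.arg(level)
  stopifnot(inherits(fx, "genome_fixture"), inherits(design, "target_design"))
  tx <- fx$registry[fx$registry$gene == gene &
    purrr::map_lgl(fx$registry$tags, function(t) "MANE_Select" %in% t), ]
  if (nrow(tx) != 1) {
    abort(sprintf("gene '%s' not in fixture registry", gene))
  }
  chrom_seq <- fx$sequences[[tx$chrom]]
  spliced <- spliced_cds(tx, fx$sequences)
  spans <- exon_spans_in_target(tx)
  margin <- 12L
  eligible <- unlist(purrr::map2(
    spans$start, spans$end,
    function(a, b) if (a + margin <= b - margin) (a + margin):(b - margin) else integer(0)
  ))

  withr::with_seed(seed, {
    truth <- list(
      mode = design$mode, gene = gene, level = level,
      changed_positions = integer(0), insert_range = NULL,
      full_sequence = NULL, listed = NULL
    )
    target <- spliced

    if (level == "protein") {
      stopifnot(design$mode == "exact")
      target <- tx$protein_seq
    } else if (design$mode == "codon_optimized") {
      codon_third <- seq(3L, nchar(spliced), by = 3L)
      cand <- codon_third[codon_third %in% eligible]
      pick <- cand[stats::runif(length(cand)) < design$synonymous_rate]
      if (length(pick) == 0) pick <- sample(cand, 1L)
      tchars <- strsplit(spliced, "", fixed = TRUE)[[1]]
      changed <- integer(0)
      for (p in pick) {
        codon <- paste(tchars[(p - 2L):p], collapse = "")
        swap <- synonymous_swap(codon)
        if (is.null(swap)) next
        tchars[(p - 2L):p] <- strsplit(swap, "", fixed = TRUE)[[1]]
        changed <- c(changed, p) # swaps differ only at the third position
      }
      target <- paste(tchars, collapse = "")
      truth$changed_positions <- sort(changed)
    } else if (design$mode == "minigene") {
      j <- spans$end[1]
      intron_tx <- intron_in_tx_orientation(tx, chrom_seq, 1L)
      li <- nchar(intron_tx)
      m <- design$insert_len
      stopifnot(li >= m)
      bases <- c("A", "C", "G", "T")
      insert <- character(m)
      for (i in seq_len(m)) {
        forb <- c(
          substr(intron_tx, i, i),
          substr(intron_tx, li - (m - i), li - (m - i))
        )
        insert[i] <- sample(setdiff(bases, forb), 1L)
      }
      insert <- paste(insert, collapse = "")
      target <- paste0(
        substr(spliced, 1L, j), insert,
        substr(spliced, j + 1L, nchar(spliced))
      )
      # construction check: no seed-length window overlapping the insert may
      # occur anywhere in the genome (either strand) -- the insert must be
      # genuinely non-homologous
      k <- 11L
      win_lo <- max(1L, j - k + 2L)
      win_hi <- min(nchar(target) - k + 1L, j + m)
      wins <- substring(target, win_lo:win_hi, (win_lo:win_hi) + k - 1L)
      genome_both <- paste(
        c(fx$sequences, purrr::map_chr(fx$sequences, reverse_complement)),
        collapse = "N"
      )
      stopifnot(!any(purrr::map_lgl(wins, function(w) grepl(w, genome_both, fixed = TRUE))))
      truth$insert_range <- c(j, j + m) # interbase on the target
    } else if (design$mode == "mutagenized") {
      pick <- eligible[stats::runif(length(eligible)) < design$missense_rate]
      tchars <- strsplit(spliced, "", fixed = TRUE)[[1]]
      for (p in pick) {
        tchars[p] <- sample(setdiff(c("A", "C", "G", "T"), tchars[p]), 1L)
      }
      target <- paste(tchars, collapse = "")
      truth$changed_positions <- sort(pick)
    } else if (design$mode == "overrun") {
      keep <- floor(design$truncate_frac * nchar(spliced))
      truth$full_sequence <- spliced
      target <- substr(spliced, 1L, keep)
    } else if (design$mode == "exon_span") {
      j <- spans$end[1]
      half <- 6L
      s <- j - half + 1L
      e <- j + half
      ref_run <- substr(spliced, s, e)
      alt_run <- chartr("ACGT", "TGCA", ref_run) # differs at every base
      listed <- tibble(
        hgvs = c(
          sprintf("c.%d_%ddelins%s", s, e, alt_run),
          sprintf(
            "c.%d%s>%s", 5L,
            substr(spliced, 5L, 5L),
            setdiff(c("A", "C", "G", "T"), substr(spliced, 5L, 5L))[1]
          )
        ),
        expected_reason = c("exon_spanning", "none")
      )
      truth$listed <- listed
    }

    urn <- sprintf("urn:synth:%s-%s-%s", tolower(gene), design$mode, level)
    meta <- list(
      urn = urn,
      target_name = gene,
      target_sequence = target,
      target_sequence_type = level,
      target_type = "protein_coding",
      gene_hint = gene
    )
    truth$target_len <- nchar(target)
    structure(list(meta = meta, truth = truth, design = design),
      class = "target_fixture"
    )
  })
}

expected_reason_nt <- function(start, end, truth) {
  if (end > truth$target_len) {
    return("out_of_bounds")
  }
  if (!is.null(truth$insert_range) &&
    start <= truth$insert_range[2] && end > truth$insert_range[1]) {
    return("non_homologous")
  }
  if (any(truth$changed_positions >= start & truth$changed_positions <= end)) {
    return("ref_mismatch")
  }
  "none"
}

#' Generate a score set (and truth table) for a target fixture
#'
#' `saturation_nt` writes all three substitutions at every target base
#' (over the *full* pre-truncation sequence for `overrun` designs);
#' `saturation_aa` writes all 19 substitutions at every residue of a
#' protein target; `listed` uses the design's listed variants (e.g. the
#' exon-spanning delins). Scores are standard-normal draws under `seed`.
#' The truth table records the expected mapping reason and concordance for
#' every record, together with the expected aggregate counts.
#'
#' @param tgt A [derive_target()] fixture.
#' @param design_kind `"saturation_nt"`, `"saturation_aa"` or `"listed"`.
#' @param seed Integer seed for the scores.
#' @return List with `score_set` (a [load_score_set()] object) and `truth`
#'   (tibble `accession`, `hgvs`, `expected_reason`, `expected_concordant`,
#'   plus an `aggregate` attribute).
#' @export
make_score_set <- function(tgt, design_kind = c(
                             "saturation_nt", "saturation_aa", "listed"
                           ), seed = 1L) {
  design_kind <- match.arg(design_kind)
  stopifnot(inherits(tgt, "target_fixture"))
  meta <- read_score_meta(tgt$meta)
  truth <- tgt$truth
  urn <- meta$urn

  if (design_kind == "saturation_nt") {
    seq_full <- truth$full_sequence %||% meta$target_sequence
    chars <- strsplit(seq_full, "", fixed = TRUE)[[1]]
    rows <- purrr::map(seq_along(chars), function(i) {
      alts <- setdiff(c("A", "C", "G", "T"), chars[i])
      tibble(
        hgvs_nt = sprintf("c.%d%s>%s", i, chars[i], alts),
        hgvs_pro = NA_character_,
        start = i, end = i
      )
    }) |> dplyr::bind_rows()
    rows$expected_reason <- purrr::map2_chr(
      rows$start, rows$end,
      function(s, e) expected_reason_nt(s, e, truth)
    )
  } else if (design_kind == "saturation_aa") {
    stopifnot(truth$level == "protein")
    chars <- strsplit(meta$target_sequence, "", fixed = TRUE)[[1]]
    aas <- setdiff(unname(AA3), "*")
    rows <- purrr::map(seq_along(chars), function(i) {
      alts <- setdiff(aas, chars[i])
      tibble(
        hgvs_nt = NA_character_,
        hgvs_pro = sprintf(
          "p.%s%d%s", aa_to3(chars[i]), i,
          purrr::map_chr(alts, aa_to3)
        ),
        start = i, end = i
      )
    }) |> dplyr::bind_rows()
    rows$expected_reason <- "none"
  } else {
    stopifnot(!is.null(truth$listed))
    rows <- tibble(
      hgvs_nt = truth$listed$hgvs,
      hgvs_pro = NA_character_,
      start = NA_integer_, end = NA_integer_,
      expected_reason = truth$listed$expected_reason
    )
  }

  n <- nrow(rows)
  scores <- withr::with_seed(seed, stats::rnorm(n))
  records <- tibble(
    accession = paste0(urn, "#", seq_len(n)),
    hgvs_nt = rows$hgvs_nt,
    hgvs_pro = rows$hgvs_pro,
    score = scores
  )
  ss <- load_score_set(meta, records)
  truth_tbl <- tibble(
    accession = records$accession,
    hgvs = dplyr::coalesce(rows$hgvs_nt, rows$hgvs_pro),
    expected_reason = rows$expected_reason,
    expected_concordant = rows$expected_reason == "none"
  )
  attr(truth_tbl, "aggregate") <- list(
    n_pairs = n,
    n_concordant = sum(truth_tbl$expected_concordant),
    fraction_concordant = mean(truth_tbl$expected_concordant),
    by_reason = stats::setNames(
      as.integer(table(factor(truth_tbl$expected_reason, levels = REASON_LEVELS))),
      REASON_LEVELS
    )
  )
  list(score_set = ss, truth = truth_tbl)
}

#' Write a genome fixture to FASTA / GFF3 / JSON files
#'
#' Emits `genome.fa`, `proteins.fa`, `registry.gff3` and `registry.json`
#' (the same formats the pipeline consumes).
#'
#' @param fx A [make_genome()] fixture.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_genome_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fa")
  dna <- Biostrings::DNAStringSet(fx$sequences)
  Biostrings::writeXStringSet(dna, genome_fa)
  prot_fa <- file.path(dir, "proteins.fa")
  prot <- Biostrings::AAStringSet(stats::setNames(
    fx$registry$protein_seq, fx$registry$protein_accession
  ))
  Biostrings::writeXStringSet(prot, prot_fa)
  gff <- file.path(dir, "registry.gff3")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(fx$registry))) {
    tx <- fx$registry[i, ]
    ex <- tx$exons[[1]]
    tag <- paste(tx$tags[[1]], collapse = ",")
    lines <- c(lines, sprintf(
      "%s\tmavemap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s;protein_id=%s%s",
      tx$chrom, min(ex$start0) + 1L, max(ex$end0), tx$strand,
      tx$tx_accession, tx$gene, tx$protein_accession,
      if (nzchar(tag)) paste0(";tag=", tag) else ""
    ))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tmavemap\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        tx$chrom, ex$start0[j] + 1L, ex$end0[j], tx$strand,
        tx$tx_accession, j, tx$tx_accession
      ), sprintf(
        "%s\tmavemap\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        tx$chrom, ex$start0[j] + 1L, ex$end0[j], tx$strand,
        tx$tx_accession, j, tx$tx_accession
      ))
    }
  }
  writeLines(lines, gff)
  reg_json <- file.path(dir, "registry.json")
  write_registry_json(fx$registry, reg_json)
  invisible(c(
    genome = genome_fa, proteins = prot_fa, gff3 = gff, registry = reg_json
  ))
}

#' Write a score set fixture (metadata JSON + scores CSV + truth TSV)
#'
#' @param bundle A [make_score_set()] result.
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_score_set <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- bundle$score_set$meta
  meta_path <- file.path(dir, "meta.json")
  jsonlite::write_json(
    unclass(meta)[!purrr::map_lgl(unclass(meta), is.null)],
    meta_path,
    auto_unbox = TRUE, pretty = TRUE
  )
  scores_path <- file.path(dir, "scores.csv")
  readr::write_csv(bundle$score_set$records, scores_path, progress = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(bundle$truth, truth_path, progress = FALSE)
  invisible(c(meta = meta_path, scores = scores_path, truth = truth_path))
}
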