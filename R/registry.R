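# Local transcript registry: a tibble standing in for an external
# transcript database, carrying per-transcript exon structure, CDS, protein
# sequence and MANE/RefSeq tags. Selection logic (MANE-tiered ranking and
# protein offset computation) operates on this table so the whole pipeline
# runs offline.

registry_tibble <- function(rows) {
  out <- dplyr::bind_rows(rows)
  stopifnot(all(c(
    "tx_accession", "gene", "chrom", "strand", "exons",
    "cds_start0", "cds_end0", "protein_accession", "protein_seq", "tags"
  ) %in% names(out)))
  out$cds_len <- purrr::map2_int(out$exons, seq_len(nrow(out)), function(ex, i) {
    s <- pmax(ex$start0, out$cds_start0[i])
    e <- pmin(ex$end0, out$cds_end0[i])
    sum(pmax(0L, e - s))
  })
  out
}

#' Read a transcript registry from a JSON file
#'
#' Schema: a JSON array of transcript objects with fields `tx_accession`,
#' `gene`, `chrom`, `strand` (`"+"`/`"-"`), `exons` (array of `[start0, end0]`
#' interbase genomic intervals, ascending), `cds` (`[start0, end0]`),
#' `protein_accession`, `protein_seq`, `tags` (array; subset of
#' `MANE_Select`, `MANE_Plus_Clinical`, `RefSeq_Select`).
#'
#' @param path JSON file.
#' @return A registry tibble (one row per transcript; `exons` and `tags`
#'   are list columns).
#' @export
read_registry_json <- function(path) {
  docs <- jsonlite::read_json(path)
  rows <- purrr::map(docs, function(d) {
    ex <- dplyr::bind_rows(purrr::map(d$exons, function(e) {
      tibble(start0 = as.integer(e[[1]]), end0 = as.integer(e[[2]]))
    }))
    tibble(
      tx_accession = d$tx_accession, gene = d$gene, chrom = d$chrom,
      strand = d$strand, exons = list(ex),
      cds_start0 = as.integer(d$cds[[1]]), cds_end0 = as.integer(d$cds[[2]]),
      protein_accession = d$protein_accession,
      protein_seq = toupper(d$protein_seq),
      tags = list(as.character(unlist(d$tags)))
    )
  })
  registry_tibble(rows)
}

#' Write a transcript registry to JSON
#' @param registry Registry tibble.
#' @param path Output file.
#' @export
write_registry_json <- function(registry, path) {
  docs <- purrr::pmap(registry, function(tx_accession, gene, chrom, strand, exons,
                                         cds_start0, cds_end0, protein_accession,
                                         protein_seq, tags, ...) {
    list(
      tx_accession = tx_accession, gene = gene, chrom = chrom, strand = strand,
      exons = purrr::map2(exons$start0, exons$end0, c),
      cds = c(cds_start0, cds_end0),
      protein_accession = protein_accession, protein_seq = protein_seq,
      tags = as.list(tags)
    )
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a transcript registry from GFF3 plus a protein FASTA
#'
#' The GFF3 subset carries `gene`, `mRNA`, `exon` and `CDS` features linked
#' by `ID`/`Parent`; mRNA features carry `gene`, `protein_id` and an
#' optional `tag` attribute (comma-separated MANE/RefSeq tags). Protein
#' sequences come from `protein_fasta`, keyed by protein accession.
#'
#' @param gff3 GFF3 file path.
#' @param protein_fasta Protein FASTA path.
#' @return A registry tibble.
#' @export
read_registry <- function(gff3, protein_fasta) {
  gr <- rtracklayer::import(gff3)
  md <- S4Vectors::mcols(gr)
  prot <- Biostrings::readAAStringSet(protein_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  is_mrna <- as.character(md$type) == "mRNA"
  mrna_ids <- as.character(md$ID[is_mrna])
  rows <- purrr::map(which(is_mrna), function(i) {
    id <- as.character(md$ID[i])
    parent_of <- vapply(md$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    child <- which(parent_of == id)
    types <- as.character(md$type)[child]
    ex_i <- child[types == "exon"]
    cds_i <- child[types == "CDS"]
    ex <- tibble(
      start0 = GenomicRanges::start(gr)[ex_i] - 1L,
      end0 = GenomicRanges::end(gr)[ex_i]
    ) |> dplyr::arrange(.data$start0)
    cds_s <- min(GenomicRanges::start(gr)[cds_i]) - 1L
    cds_e <- max(GenomicRanges::end(gr)[cds_i])
    pacc <- as.character(md$protein_id[i])
    tags <- md$tag[i]
    tags <- if (is.null(tags) || is.na(tags)) character(0) else strsplit(as.character(tags), ",")[[1]]
    tibble(
      tx_accession = id,
      gene = as.character(md$gene[i]),
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = list(ex),
      cds_start0 = cds_s, cds_end0 = cds_e,
      protein_accession = pacc,
      protein_seq = as.character(prot[[pacc]]),
      tags = list(tags)
    )
  })
  registry_tibble(rows)
}

#' Spliced CDS sequence of a registry transcript
#'
#' Concatenates the CDS portions of the exons in transcript orientation
#' (reverse-complemented for minus-strand transcripts). Used for fixture
#' validation: translating the result must reproduce `protein_seq` plus a
#' terminal stop.
#'
#' @param tx One registry row (one-row tibble or list).
#' @param genome Named character vector of chromosome sequences, or a
#'   [seq_store()].
#' @return DNA string of the spliced CDS, 5' to 3' in transcript orientation.
#' @export
spliced_cds <- function(tx, genome) {
  seqs <- genome_as_vector(genome)
  chrom_seq <- seqs[[tx$chrom]]
  ex <- if (is.data.frame(tx$exons)) tx$exons else tx$exons[[1]]
  s <- pmax(ex$start0, tx$cds_start0)
  e <- pmin(ex$end0, tx$cds_end0)
  keep <- e > s
  pieces <- substring(chrom_seq, s[keep] + 1L, e[keep])
  joined <- paste(pieces, collapse = "")
  if (identical(tx$strand, "-")) reverse_complement(joined) else joined
}

#' Find candidate transcripts for a genomic footprint or gene hint
#'
#' @param registry Registry tibble.
#' @param chrom,start0,end0 Genomic footprint (interbase); transcripts whose
#'   exon union overlaps it by at least 1 bp are returned.
#' @param gene_hint Optional gene symbol; matching transcripts are included
#'   regardless of footprint.
#' @return A registry tibble subset (possibly empty).
#' @export
tx_candidates <- function(registry, chrom = NULL, start0 = NULL, end0 = NULL,
                          gene_hint = NULL) {
  hit <- rep(FALSE, nrow(registry))
  if (!is.null(chrom)) {
    hit <- hit | (registry$chrom == chrom &
      purrr::map_lgl(registry$exons, function(ex) {
        any(ex$start0 < end0 & ex$end0 > start0)
      }))
  }
  if (!is.null(gene_hint)) {
    hit <- hit | registry$gene == gene_hint
  }
  registry[hit, , drop = FALSE]
}

TIER_ORDER <- c(
  MANE_Select = 1L, MANE_Plus_Clinical = 2L, RefSeq_Select = 3L
)

#' Rank candidate transcripts and select one
#'
#' Tier order: MANE Select > MANE Plus Clinical > RefSeq Select > longest
#' CDS among untiered; final ties break to the lexicographically smallest
#' transcript accession.
#'
#' @param cands Registry tibble of candidates.
#' @return One-row registry tibble with a `tier` column
#'   (`mane_select`, `mane_plus_clinical`, `refseq_select`,
#'   `longest_compatible`), or `mapping_failure("no_transcript")`.
#' @export
rank_and_select <- function(cands) {
  if (is.null(cands) || nrow(cands) == 0) {
    return(mapping_failure("no_transcript"))
  }
  tier_rank <- purrr::map_int(cands$tags, function(tg) {
    r <- TIER_ORDER[intersect(names(TIER_ORDER), tg)]
    if (length(r) == 0) 4L else min(r)
  })
  ord <- order(tier_rank, -cands$cds_len, cands$tx_accession)
  sel <- cands[ord[1], , drop = FALSE]
  sel$tier <- c(
    "mane_select", "mane_plus_clinical", "refseq_select",
    "longest_compatible"
  )[tier_rank[ord[1]]]
  sel
}

#' Locate a target protein within a reference protein
#'
#' Exact substring match returns the leftmost index with identity 1 (a
#' warning is recorded when the target occurs more than once). Otherwise an
#' ungapped sliding comparison over all offsets is tried, and finally a
#' local alignment (match +1, mismatch -1, gap -2) as fallback. Failure is
#' returned when the best identity falls below `min_identity`.
#'
#' @param target_protein,ref_protein Protein strings.
#' @param min_identity Minimum acceptable identity over aligned columns.
#' @return List with `offset_aa` (0-based residue offset of the target
#'   start in the reference) and `identity`, or
#'   `mapping_failure("offset_failure")`.
#' @export
compute_offset <- function(target_protein, ref_protein, min_identity = 0.5) {
  stopifnot(nzchar(target_protein), nzchar(ref_protein))
  target_protein <- toupper(target_protein)
  ref_protein <- toupper(ref_protein)
  idx <- regexpr(target_protein, ref_protein, fixed = TRUE)[[1]]
  if (idx > 0) {
    second <- regexpr(target_protein,
      substr(ref_protein, idx + 1L, nchar(ref_protein)),
      fixed = TRUE
    )[[1]]
    if (second > 0) {
      warn(sprintf(
        "target protein occurs more than once in reference; using leftmost offset %d",
        idx - 1L
      ))
    }
    return(list(offset_aa = idx - 1L, identity = 1.0))
  }
  tc <- strsplit(target_protein, "", fixed = TRUE)[[1]]
  rc <- strsplit(ref_protein, "", fixed = TRUE)[[1]]
  nt <- length(tc)
  nr <- length(rc)
  best <- list(offset_aa = NA_integer_, identity = -1)
  if (nr >= nt) {
    for (o in 0:(nr - nt)) {
      ident <- sum(tc == rc[(o + 1L):(o + nt)]) / nt
      if (ident > best$identity) best <- list(offset_aa = o, identity = ident)
    }
  }
  if (best$identity >= min_identity) {
    return(best)
  }
  # local-alignment fallback for partial overlaps / indel-containing targets
  mat <- matrix(-1, 27, 27, dimnames = list(c(LETTERS, "*"), c(LETTERS, "*")))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = target_protein, subject = ref_protein,
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  width <- nchar(as.character(Biostrings::pattern(aln)))
  # a local alignment must cover at least half the target to count; tiny
  # high-identity fragments say nothing about where the MAVE sequence sits
  if (width >= ceiling(nt / 2)) {
    ident <- Biostrings::nmatch(aln) / width
    off <- (BiocGenerics::start(Biostrings::subject(aln)) - 1L) -
      (BiocGenerics::start(Biostrings::pattern(aln)) - 1L)
    if (ident > best$identity) {
      best <- list(offset_aa = as.integer(off), identity = ident)
    }
  }
  if (best$identity < min_identity || best$offset_aa < 0) {
    return(mapping_failure("offset_failure", best_identity = max(0, best$identity)))
  }
  best
}
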