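---
title: "Mapping MAVE score sets to reference sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping MAVE score sets to reference sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemap)
```

# Overview

`mavemap` lifts variants described on assay-specific MAVE target sequences
onto reference genome and protein sequences, producing *pairs* of variant
objects — one on the target, one on the reference — so that the assay
context is never lost. This vignette documents the model, the tunable
parameters, the synthetic data the tests rely on, and the design decisions
taken where more than one reasonable choice existed.

# The mapping model

## Variant representation

Variants are represented as alleles: an interbase (0-based, half-open)
location on a content-addressed sequence, plus a literal alternate
sequence. Interbase coordinates make insertions zero-length intervals and
remove the off-by-one ambiguities of 1-based closed intervals. Sequences
are identified by `SQ.<digest>` where the digest is `sha512t24u` — the
URL-safe base64 encoding of the first 24 bytes of the SHA-512 hash of the
uppercased residue string's UTF-8 bytes. Identical sequences therefore
receive identical identifiers in any session, with no registry lookups.

Allele identifiers are digests over a pinned canonical serialization:
key-sorted, whitespace-free JSON with embedded digests as bare
32-character strings. The location serializes as
`{"end":E,"sequence":"<seq digest>","start":S,"type":"SequenceLocation"}`
and the allele as
`{"location":"<location digest>","state":{"sequence":"<alt>","type":"LiteralSequenceExpression"},"type":"Allele"}`.
Cis-phased blocks digest the sorted member ids, making block identity
independent of member order. The serialization is pinned so identifiers
are reproducible within the package; byte-exact conformance with external
registries is explicitly *not* claimed and would require conformance
fixtures from those systems.

## Normalization to full justification

Indels in repeat context are ambiguous: deleting any single `G` from
`ACGGGGT` yields the same molecule. Normalization proceeds in two steps.
First the longest common prefix, then the longest common suffix, of the
(reference, alternate) pair are trimmed. If both trimmed strings remain
non-empty the edit is a substitution or delins and is already unambiguous.
Otherwise the remaining inserted/deleted sequence is rolled left and right
over the flanking sequence as far as it can shift, and the allele is
expanded to cover the entire ambiguity region — for `ACGGGGT`, every
single-`G` deletion becomes the allele spanning the whole run, reference
`GGGG`, alternate `GGG`. The operation is idempotent and collapses entire
equivalence classes onto a single identifier; the test suite verifies this
against a brute-force enumerator that derives every equivalent
representation directly from the edited string.

HGVS output is the opposite convention: minimal and 3'-shifted. Emission
therefore re-trims the stored (fully justified) allele, removing the
common prefix first, which lands deletions and insertions at their
3'-most minimal representation. Both representations are recorded: the
stored allele is fully justified, the `post_hgvs` string is minimal.

## Alignment

DNA targets are aligned with a deliberately small seed–chain–extend local
aligner:

* exact `k`-mer seeds (default `k = 11`) against both strands (the minus
  strand by reverse-complementing the query);
* seeds on a diagonal merge and are extended ungapped with an x-drop rule
  (+1 match, −1 mismatch, stop when the running score falls `x_drop = 20`
  below its maximum; the block ends at the maximum);
* extended segments are chained by dynamic programming; a link requires a
  non-negative query gap and a reference gap in `[0, max_intron]`
  (default 500 kb). Reference-only gaps model introns; query-only gaps
  model assay content absent from the genome, such as minigene inserts.

Extension can overshoot a true junction when bases past it match by
chance. Chained segments are therefore allowed to overlap in query, and
the traceback resolves each overlap at the split point that maximizes
total matches across the junction (ties go to the 5'-most split). This is
the same trimming idea block-based aligners use and is what makes exon
boundaries land exactly.

Hits are scored `matches − mismatches − gap_open·(#gaps) −
gap_ext·log2(total reference gap + 1)` (defaults 2 and 0.05): the
logarithmic term prefers compact arrangements without punishing genuine
introns. Selection keeps hits with identity ≥ `min_identity` (0.5) and
coverage ≥ `min_coverage` (0.3) — permissive on purpose, because heavily
mutagenized targets still partially align and should map rather than fail
— then takes the best score, breaking ties toward a hit overlapping the
locus of the metadata gene hint, then the smallest `(accession, start)`.
All thresholds are `align_params()` arguments.

A 21-column PSL reader converts externally produced alignments to the
same hit structure, so a production aligner can replace the built-in one
without touching anything downstream.

## Transcript selection and protein offsets

Protein targets skip alignment. Candidate transcripts come from a local
registry (GFF3 subset + protein FASTA, or one JSON file) by genomic
footprint overlap or gene hint; ranking is MANE Select > MANE Plus
Clinical > RefSeq Select > longest CDS, with a lexicographic accession
tie-break, so selection is permutation-invariant. The residue offset of
the MAVE protein within the reference protein is computed by exact
substring search first (leftmost occurrence on repeats, with a warning),
then an ungapped sliding comparison over all offsets, then a local
alignment (match +1, mismatch −1, gap −2) as a last resort. A local
alignment must cover at least half the target to count — a short
high-identity fragment says nothing about where the MAVE sequence sits —
and any result below `min_identity` (0.5) is an `offset_failure`. When no
registry protein yields a viable offset the whole score set fails with
`no_transcript`, mirroring how real pipelines surface unselectable
protein identifiers.

## Lifting and concordance

Each variant's original target interval is lifted through the selected
hit's blocks. Intervals inside one block map by offset arithmetic (mirrored
on the minus strand); intervals crossing a reference gap split into one
segment per block and are represented as a cis-phased block of per-segment
alleles with the informational reason `exon_spanning`. We chose per-exon
alleles over one intron-spanning allele because the latter would assert a
multi-kilobase reference deletion that the assay never measured; the
per-exon form keeps each allele biologically interpretable. Exon-spanning
pairs are counted discordant — the genomic representation is not the
contiguous change the assay made. Intervals touching unaligned query
positions are `non_homologous`; intervals past the target end are
`out_of_bounds`. A zero-length insertion point on a block boundary is
assigned to the block that is 5' on the reference strand (a convention;
either neighbour is defensible, but one must be fixed for determinism).

Post-mapped alleles are re-normalized and re-digested on the reference
sequence, so pre- and post-mapped identifiers always differ through their
sequence digests even when the residues agree — this is what preserves
provenance. Concordance then compares the reference residues under the
two locations, with minus-strand segments reverse-complemented into
target orientation and concatenated in query order. Any unexplained
difference is `ref_mismatch`. For in-cis records, concordance requires
every member concordant.

Validation statuses are values, not errors: a variant whose stated
reference residue disagrees with the target is still pre-mapped (the
assay measured it) and still lifted, with `ref_mismatch` recorded.
Wild-type/synonymous placeholder rows (`_wt`, `_sy`, `p.=`, `p.Trp24=`)
are counted (`n_no_change`) but excluded from mapping. Rows lacking the
expression that drives their target type (e.g. protein-only rows on a DNA
target) are counted as `n_undriven` and skipped; resolving them would
require projecting protein coordinates through the codon structure, which
this package does not attempt. Summaries count one pair per score-set
record; members of a cis-phased block are not counted individually, which
keeps the invariant that reason counts partition the record list (the
member-level view remains available from the pairs table).

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k` | 11 | bp | Seed specificity ~4^-11; standard for DNA word matching at genome scale |
| `max_intron` | 500 000 | bp | Upper bound on bridged reference gaps; generous for human introns |
| `min_identity` | 0.5 | fraction | Permissive so mutagenized targets still map; configurable |
| `min_coverage` | 0.3 | fraction | Tolerates minigene/partial targets |
| `x_drop` | 20 | score | Extension stop; large enough to cross scattered mismatches, small enough to stop at introns |
| `gap_open`, `gap_ext` | 2, 0.05 | score | Mild, log-scaled intron cost |
| offset `min_identity` | 0.5 | fraction | Below this an offset is meaningless |
| `q` (outliers) | 0.99 | quantile | Conventional display threshold; type-7 interpolation |

# The synthetic data generator

`make_genome()` builds a single chromosome carrying four 3-exon genes on
alternating strands (60-bp exons, 200-bp introns, ATG…stop CDS), one MANE
Select transcript per gene and one longer untagged transcript for the
first gene (so tier-over-length selection is exercised), with the
construction invariant that every spliced CDS translates to its
registered protein plus stop. `derive_target()` then produces targets
that emulate what real MAVE metadata exhibits:

* **exact** — target identical to the reference (spliced CDS or protein);
* **codon_optimized** — synonymous third-position codon swaps at rate
  0.05 (at least one), positions recorded;
* **minigene** — a 30-bp insert spliced between the first two exons;
* **mutagenized** — point substitutions at rate 0.2, positions recorded;
* **overrun** — the target truncated to 80% of the CDS while the variant
  list covers the full CDS, so later variants exceed the target length;
* **exon_span** — an exact target plus a listed 12-bp same-length delins
  centred on the first exon junction.

Two generator properties are deliberate and documented rather than
incidental. First, edited positions (codon swaps, mutagenized bases) are
kept at least 13 bp from exon boundaries so every exon end remains exactly
alignable; this is what makes the expected per-variant classification
exact rather than approximate. Second, minigene inserts are constructed
base-by-base to differ from the flanking intron continuation on both
sides (and checked to share no 11-mer with either genome strand), so that
x-drop extension cannot creep into the insert on chance matches — the
insert is non-homologous *by construction*, which the design requires,
not merely with high probability. Scores are standard-normal draws; no
assay noise model is attempted. What passing tests show is therefore that
the *mapping machinery* is correct under each pathology — not that the
pipeline is robust to sequencing artefacts, metadata inconsistencies, or
the metadata-shape variety of real submissions, which are out of scope.

All randomness is confined to one seeded generator per fixture
(`withr::with_seed`), making every artifact byte-identical across runs.

# Numerical and degenerate-input choices

* Digest input is always the uppercased residue string; lowercase input
  is uppercased before hashing.
* A substitution whose alternate equals the reference collapses under
  trimming to an empty edit at a point interval; it maps, compares equal
  by construction, and emits `"="` HGVS.
* `percentile_outliers()` uses type-7 (linear interpolation) quantiles;
  constant score vectors give equal thresholds and no flags. Flagging is
  strict (`>` / `<`).
* Empty summaries report `fraction_concordant = 0` with an explicit
  `undefined_fraction` flag rather than NaN.
* BED display scores are rank-normalized to 0–1000 (the field is bounded
  and raw MAVE scales are arbitrary); a single scored row maps to 500.
  The raw score is carried in an extra column. The single-BED-item
  heatmap encoding used by genome-browser track hubs is not reproduced.
* Mapping JSON is written with sorted keys and a trailing newline, so
  identical inputs give byte-identical files.
* CLI exit codes: 0 success, 1 usage/IO error, 2 whole-set mapping
  failure.
* Problem sizes in the acceptance checks (e.g. 1000-class normalization
  sweeps, 500 lift oracles, 10^4 digest distinctness, 200-bp embeddings
  in 5-kb references) are the package's own desk-scale choices: large
  enough to exercise every branch, small enough to run interactively.

# Known limitations

* The aligner is adequate for desk-scale references (kilobases to a few
  megabases); genome-scale work should feed BLAT/minimap2 PSL output
  through `read_psl()`.
* MAVE-HGVS coverage is the four edit kinds (substitution, deletion,
  insertion, delins) plus in-cis brackets and wild-type markers; no
  duplications, frameshifts, or UTR/intronic offsets (`c.4+1G>T`).
* Protein variants are never projected to genomic coordinates; protein
  targets map to reference proteins only.
* One canonical metadata shape is accepted; the heterogeneous metadata
  layouts of real submissions must be normalized upstream.
* Identifier conformance with external variant registries is pinned to
  this package's serialization schema, not independently verified.
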