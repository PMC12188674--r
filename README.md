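# mavemap

Map variants from multiplexed assays of variant effect (MAVEs) onto
reference genome and protein sequences, preserving the provenance of the
assay-specific target sequence.

## The problem

MAVE experiments (deep mutational scans, massively parallel reporter
assays) report functional scores for thousands of variants at once — but
the variants are described on a *target sequence* chosen by the assay
designer, not on a reference sequence. Targets may be codon-optimized,
carry minigene inserts that exist nowhere in the genome, be heavily
mutagenized, or describe protein changes whose coding sequence spans exon
boundaries. Before MAVE scores can be used alongside clinical variant
databases, each variant needs a reference-coordinate representation — and
because the target and reference genuinely differ, the mapping has to keep
both representations side by side rather than silently replacing one with
the other.

`mavemap` implements that mapping as a three-step pipeline:

1. **Align** the DNA target to the reference genome with a seed–chain–extend
   local aligner (exact *k*-mer seeds, x-drop ungapped extension, collinear
   chaining in which reference-only gaps model introns and query-only gaps
   model unaligned assay content). Block structure mirrors PSL semantics,
   and a PSL reader allows an external aligner to stand in.
2. **Select** a representative transcript/protein, preferring MANE Select,
   then MANE Plus Clinical, then RefSeq Select, then the longest CDS; for
   protein targets, compute the residue offset of the MAVE sequence within
   the reference protein.
3. **Represent** every variant twice, as a *pre-mapped* allele on the target
   and a *post-mapped* allele on the reference. Alleles use interbase
   coordinates and literal alternate sequences, are normalized to **full
   justification** (an ambiguous indel is expanded to cover its whole
   repeat region), and receive content-derived identifiers
   `ga4gh:VA.<sha512t24u(serialization)>`, where `sha512t24u` is the
   URL-safe base64 of the first 24 bytes of SHA-512. In-cis multi-variants
   become cis-phased blocks. A pair is **concordant** when the reference
   residues under its two locations agree; discordance reasons
   (`ref_mismatch`, `non_homologous`, `out_of_bounds`, `exon_spanning`, …)
   are recorded per pair.

Downstream helpers aggregate concordance across score sets, compute
per-residue mean scores, flag 99th-percentile outliers (type-7 quantiles),
and export mapping JSON, summary TSV and BED6+2 tracks.

The package ships a deterministic synthetic-fixture generator
(`make_genome()`, `derive_target()`, `make_score_set()`) that reproduces
each of the pathologies above *with a machine-checkable truth table*, so
the whole pipeline is testable end to end without any external data.

## Worked example

```r
library(mavemap)
library(dplyr)

fx     <- make_genome(seed = 1)                 # toy genome + registry
tgt    <- derive_target(fx, "SYNG1", target_design("minigene"), seed = 1)
bundle <- make_score_set(tgt, "saturation_nt", seed = 1)
mr     <- map_score_set(bundle$score_set, fx$sequences, registry = fx$registry)
mr
#> <mapping_result urn:synth:syng1-minigene-dna: 630 pairs, 85.7% concordant, mapped to NC_SYN1.1>

tidy(mr) |> count(reason)
#> # A tibble: 2 × 2
#>   reason             n
#> 1 non_homologous    90
#> 2 none             540
```

The target is the spliced CDS of a fixture gene with a 30-bp minigene
insert spliced between its first two exons. Saturation mutagenesis writes
3 substitutions per target base (630 records on the 210-bp target). The 90
variants inside the insert (3 × 30) cannot be lifted — the insert does not
exist in the genome — and are classified `non_homologous`; the remaining
540 map concordantly. Each concordant pair carries both identifiers and an
HGVS description of the post-mapped allele, e.g.:

```r
tidy(mr) |> filter(concordant) |> slice(1) |> select(pre_id, post_id, post_hgvs)
#> pre_id    ga4gh:VA.2kKe0P1RarC3ItO_Nwie2lownYX1jBNP   (on the target digest)
#> post_id   ga4gh:VA.UF9X41S7Y6rHyE-7GBuALvaC5DF8_dFo   (on NC_SYN1.1)
#> post_hgvs NC_SYN1.1:g.101A>C
```

The two identifiers differ even though the assayed change is the same —
that difference *is* the provenance record: one id is bound to the assay
target's sequence digest, the other to the reference.

`summarize_mappings()` aggregates many results (with deduplicated unique
pre-/post-mapped ids), `per_residue_mean()` and `percentile_outliers()`
post-process protein scores, and `write_mapping()` / `write_bed()` emit
deterministic files. A thin command-line wrapper lives at
`inst/cli/mavemap.R`:

```sh
Rscript inst/cli/mavemap.R simulate --seed 5 --design exact --out fix
Rscript inst/cli/mavemap.R map --genome fix/genome.fa --registry fix/registry.json \
    --meta fix/meta.json --scores fix/scores.csv --out out --bed
Rscript inst/cli/mavemap.R report --out summary.tsv out/*.mapping.json
```

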