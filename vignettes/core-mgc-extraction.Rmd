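---
title: "Core metabolic gene cluster extraction: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core metabolic gene cluster extraction: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremgc)
```

## The problem

Metabolic gene clusters (MGCs) — sets of physically co-located genes that
together encode a biosynthetic or degradative pathway — are detected in
microbial genomes by HMM-based annotators (antiSMASH for secondary
metabolites, gutSMASH for gut primary metabolism). Those annotators output
one GenBank file and one HTML overview per genome, designed for
interactive inspection. `coremgc` turns that per-genome output into batch
results: for a user-named MGC type it extracts the cluster's core genes
from every genome, decides which keyword matches are genuine cluster
members, attaches taxonomy, and summarises prevalence across the batch.

A motivating case is the six-gene *caiTABCDE* operon of the
l-carnitine → γ-butyrobetaine pathway, a gut-bacterial precursor route to
trimethylamine (TMA) and TMAO, metabolites implicated in cardiovascular
disease. Screening thousands of genomes for *intact* copies of this
operon — not isolated *cai*-like genes — is exactly the kind of question
the package answers.

## The model: keyword matching plus gene proximity

The central assumption is biological: genes of a genuine MGC sit close
together on the chromosome, while homonymous genes scattered around the
genome are false positives. The procedure per genome and cluster
definition is:

1. **Match.** A CDS matches a definition label when its `/gene` qualifier
   equals the label case-insensitively; if the CDS has no gene name and
   the product fallback is enabled, a case-insensitive word-boundary token
   match against `/product` is accepted (`caiB` matches
   "carnitine CoA-transferase CaiB" but not "caiBase"). A CDS yields at
   most one match, taking the first applicable label in definition order.
2. **Chain.** With CDS sorted by coordinate, the gap between consecutive
   matches is the count of intervening non-matching coding genes
   (`ordinal` difference minus one). Matches partition into maximal runs
   whose every consecutive gap is at most the budget `g`.
3. **Classify.** A chain is *intact* when its matched label set equals the
   full definition set (set semantics, so duplicated paralog copies inside
   a chain do not hurt), *candidate* when it has at least `min_genes`
   members, otherwise *rejected*.
4. **Extract.** For intact and candidate chains the genome slice spanning
   the chain plus per-gene nucleotide (strand-oriented) and protein
   sequences are written as FASTA with taxonomy in every header.

### Why gaps are counted in genes, not locus-tag numbers

The field describes synteny thresholds "based on locus tag", and RefSeq
tags do step regularly (by 5). But tag numbering is not reliable
arithmetic: annotators renumber around insertions, merge tags, and draft
genomes restart numbering per contig. The only robust reading of "at most
10 genes between members" is a count of intervening CDS after coordinate
sorting, which is what the implementation uses. The fixture generator
nevertheless assigns tags stepped by 5, so tests can confirm the familiar
consequence: an uninterrupted operon's member tags form an arithmetic run.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `g` | 10 | max. unrelated coding genes between consecutive members (genes) |
| `strict` | off | preset `g = 4`: a gap of five breaks a chain |
| `min_genes` | 2 | minimum chain size for candidacy |
| `allow_product_fallback` | on | match `/product` tokens when `/gene` is absent |
| `require_region` | auto | restrict matching to annotated region spans when a region table exists |
| `tax_level` | Species | rank for summary aggregation |
| `min_coverage` | 0.8 | fraction of the reference protein length below which a sequence is filtered |

The default `g = 10` follows the published candidacy rule for two or more
genes in synteny; the strict preset encodes the stringent case-study
setting of gene intervals below five. Both are exposed because the
literature uses both; users screening for operons with known tight
packing should prefer `strict`. `min_coverage` uses a **strict** `<`
comparison: a protein at exactly 80% of its reference length (324 of
405 aa for K08298) is kept. Coverage is a pure length ratio against the
KEGG-ortholog reference length — no alignment is performed, which keeps
the filter deterministic and annotator-independent but means internal
deletions compensated by terminal extensions are not detected.

### Chains never cross contigs; mixed strands allowed

A definition split across contigs yields at best two candidate chains —
draft-genome fragmentation should surface as incompleteness, not be
papered over. Mixed strands within one chain are permitted (inversions
and mis-stranded draft annotations are common); each hit records a
strand-homogeneity flag so users can audit.

## Region resolution

The extraction contract is a canonical per-genome `regions.tsv`
(`genome_name, record_id, region_label, mgc_type, start, end`, 1-based
inclusive). Annotator HTML index pages vary across versions, so the HTML
scraper is a best-effort convenience: it reads overview tables under two
column dialects (From/To and Start/End), attributes each table to the
nearest preceding heading, skips malformed rows with warnings and never
crashes on unrecognized pages. Scraped annotations can be written back to
the canonical TSV, which round-trips exactly. MGC-type matching is exact
after normalizing case and separator characters — never substring — so a
query for `NRPS` cannot accidentally select `NRPS-like` regions. When a
genome has a region table, matching is restricted to CDS overlapping the
selected regions; without one, the whole record is scanned.

## Taxonomy

Two `species/` dialects are auto-detected per file: NCBI assembly-summary
tables (Species = first two words of `organism_name`, Genus = first word;
ranks above Genus are genuinely unavailable in this dialect and are
reported as such, not inferred) and two-column seven-rank lineage strings
(`d__...;p__...;...;s__...`). Hits are keyed by genome name, then record
id, then the longest taxonomy key embedded in the genome name (resolving
`results_GCF_013813205.1`-style directories to their accession).
Unmatched genomes aggregate under `Unclassified` rather than being
dropped, so hit totals are conserved at every rank — an invariant the
tests check.

## Dereplication

100%-identity dereplication is implemented natively in two modes: `exact`
(identical strings collapse to the first-seen representative) and
`containment` (a sequence that is a substring of a longer kept sequence is
absorbed, greedy longest-first — the behaviour of conventional
100%-identity clustering tools; their word-size/memory/thread knobs only
affect speed, not the resulting set, and are not modelled). Both modes
are idempotent and preserve first-seen representative order.

## What the synthetic generator emulates — and what it does not

`make_suite()` builds the entire on-disk layout the extractor consumes:
annotator-style GenBank files with ordered CDS (locus tags stepped by 5,
gene/product/translation qualifiers), canonical region tables covering
each planting, both taxonomy dialects, definition files, and a
ground-truth manifest. Plantings come in three kinds:

* **intact** — all definition genes, internal gaps drawn from 0–3 decoy
  genes (inside both the default and strict budgets, mirroring genuine
  operons which are contiguous or nearly so);
* **scattered** — members separated by 12–18 decoys, beyond the default
  candidacy bound, emulating scattered false-positive homologs;
* **partial** — a subset of members at chainable gaps, yielding
  candidates.

Flanking decoys (default 10 per genome) carry random unrelated gene
symbols and "hypothetical protein" products. Intergenic spacers are
50–200 nt; member protein lengths use the definition's reference length
where one is given (caiB = 405 aa) and 150–350 aa otherwise. All
randomness flows from a single integer seed and output is byte-identical
across runs.

The generator emulates annotator *output structure*, not genome realism:
no codon-usage or GC-content modelling, no pseudogenes, no split or
frameshifted CDS, no multi-contig fragmentation of a cluster, no
disagreement between region tables and gene content. Passing the
planted-recovery tests therefore demonstrates that the decision logic is
implemented correctly under the stated proximity model; it does not
demonstrate robustness to mis-annotation in real genomes, which is bounded
by the upstream annotator's quality.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; every user-facing output is
  1-based inclusive. The conversion is an involution (tested).
* Compound `join(...)` CDS locations collapse to their outer span with a
  warning — bacterial CDS essentially never splice, and extraction is
  span-based.
* A CDS without a locus tag gets a synthesized `<record>_cds<ordinal>`
  tag (with a warning) rather than being dropped, so gap counting stays
  correct.
* Feature ordering ties (identical starts) break by end, then locus tag,
  making ordinals — and therefore chaining — deterministic.
* Translation uses the annotator's `/translation` qualifier verbatim when
  present, otherwise re-translates with bacterial genetic code table 11;
  a minus-strand span is reverse-complemented first, a trailing stop is
  trimmed, and a span not divisible by three with no qualifier is a
  per-gene error (the gene is skipped in protein FASTA with a warning,
  never silently mistranslated).
* Empty inputs are valid everywhere: a genome with no region of the
  queried type, a header-only region table, an empty suite, zero hits in
  aggregation — all produce empty results, not errors.

## Test problem sizes

The suite's property tests run the chaining oracle comparison on 1,000
random records of up to 12 CDS across gap budgets 0–6, planted-cluster
recovery on a 50-genome mixed suite with monotonicity checked across
budgets 0–20, and filter/dereplication properties on 1,000 random
sequences; the end-to-end demonstration uses five genomes with
uninterrupted plantings. These sizes exercise every code path and
boundary while keeping the default test run fast.

## Known limitations

* Coverage filtering is length-based, not alignment-based (see above).
* HTML scraping is best-effort by design; the canonical TSV is the
  interface of record.
* The assembly-summary taxonomy dialect cannot populate ranks above
  Genus; aggregation at those ranks reports `Unclassified` with a
  warning rather than guessing.
* One chain is classified against one definition; overlapping definitions
  sharing gene labels produce independent hits per definition, which is
  intended (a region can legitimately satisfy two definitions) but means
  the per-hit counts are not disjoint across definitions.
* EMBL/GFF3 input, GenBank writing, and eukaryotic (intron-containing)
  genes are out of scope.
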