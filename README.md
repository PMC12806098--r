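# coremgc

Batch extraction of **core metabolic gene clusters (MGCs)** from microbial
genomes that have already been annotated by a cluster detector such as
antiSMASH (secondary metabolites) or gutSMASH (gut primary metabolites).

Cluster annotators are excellent at finding candidate regions, but their
results are geared to interactive, per-genome inspection in a browser. When
the question is *"which of my 1,500 genomes carry an intact carnitine
degradation operon, and in which species?"*, what is needed is a batch tool
that pulls the core genes out of every annotated genome, decides which
keyword matches are genuine cluster members, and stratifies the results by
taxonomy. That is what this package does.

## The decision rule

For a cluster definition with member genes \(L = \{l_1, \ldots, l_k\}\)
(e.g. *caiTABCDE* = {caiT, caiA, caiB, caiC, caiD, caiE}), each coding
sequence of a genome is tested by **keyword matching**: a CDS matches
\(l_i\) when its `/gene` qualifier equals \(l_i\) (case-insensitive), or —
when no gene name is annotated — when its `/product` contains \(l_i\) as a
word-boundary token.

Matches are then chained by **gene proximity (synteny)**. With CDS sorted
by coordinate and indexed by ordinal \(o_1 < o_2 < \ldots\), the *gap*
between consecutive matches is the number of intervening unrelated coding
genes, \(g_i = o_{i+1} - o_i - 1\). Matches form one chain as long as every
consecutive gap satisfies \(g_i \le g\); the default budget is \(g = 10\),
and a `strict` preset uses \(g = 4\) (a gap of five breaks the chain). A
chain is

* **intact** — its matched label set equals the full definition set;
* **candidate** — at least `min_genes` (default 2) members but not all;
* **rejected** — otherwise (scattered keyword matches, i.e. false
  positives whose gene names fit but whose genomic context does not).

Downstream, hits gain seven-rank taxonomy (Domain … Species), protein
sequences can be filtered by reference-length coverage
(\(\mathrm{cov} = |s| / L_\mathrm{ref}\), removed when
\(\mathrm{cov} < 0.8\); e.g. the 405-aa l-carnitine CoA-transferase
reference, K08298), and dereplicated at 100% identity.

## Worked example

Generate a five-genome synthetic suite (three genomes with a contiguous
*caiTABCDE* planting, one scattered decoy genome) and extract with the
strict gap budget:

```r
library(coremgc)
suite <- tempfile("suite")
make_suite(suite, 5, mix = c("intact", "intact", "scattered"), seed = 11)
res <- run_extraction(suite, "caiTABCDE", extraction_config(strict = TRUE),
                      out_dir = file.path(suite, "out"))
hits_table(res$hits)[, c("genome_name", "status", "n_genes", "max_gap")]
#>     genome_name  status   n_genes max_gap
#> 1  GCF_900001.1 intact    6       3
#> 2  GCF_900002.1 intact    6       3
#> 3  GCF_900003.1 rejected  1       0      (x6: scattered singletons)
#> 9  GCF_900004.1 intact    6       3
#> 10 GCF_900005.1 intact    6       3
```

Four genomes carry all six *cai* genes within the gap budget and are
reported intact; the scattered genome's six isolated keyword matches are
each rejected as false positives. Batch statistics:

```r
mgc_prevalence(res$hits, n_genomes = 5)
#>    mgc_type n_genomes_with_intact n_hits pct_of_genomes pct_of_all_intact_hits
#> 1 caiTABCDE                     4      4             80                    100
```

Extracted FASTA (nucleotide and protein per hit) lands in
`<suite>/out/`, with pipe-separated headers carrying genome, contig,
locus tag, gene label, cluster, 1-based coordinates, strand and species:

```
>GCF_900001.1|CTG_GCF9000011|RSD29_RS00030|caiT|caiTABCDE|3025..3684|+|Escherichia fergusonii
```

The same pipeline is available from a shell via the bundled script
(`system.file("scripts", "coremgc", package = "coremgc")`) with
subcommands `extract`, `simulate`, `stats`, `filter` and `derep`, e.g.
`coremgc extract -i <dir> -n caiTABCDE -g 4 -o out/`.

## Expected input layout

```
input_dir/
  results_<genome_name>/   one per genome: *.gbk (annotator GenBank output)
                           plus regions.tsv (canonical region table) or the
                           annotator's index.html (scraped best-effort)
  gene_label2/             one definition file per MGC: first line the
                           cluster name, then one gene label per line,
                           optionally TAB KO:length (e.g. caiB  K08298:405)
  species/                 taxonomy: NCBI assembly-summary TSV and/or
                           two-column key TAB d__...;p__...;...;s__... lineages
```

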