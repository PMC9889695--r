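# crescan

Promoter cis-regulatory element (CRE) scanning and representation analysis.

Gene sets that respond to a stimulus — e.g. the up- and down-regulated genes
of a transcriptomic contrast — are commonly characterized by the
transcription-factor binding sites their promoters carry. `crescan`
implements that analysis end to end for degenerate-consensus motif catalogs:

1. **Promoter extraction** — strand-aware 3-kb windows upstream of each
   gene's TSS from a genome FASTA plus GFF3/BED6 annotation
   (`read_fasta()`, `read_gene_annotations()`, `extract_promoters()`).
2. **Motif scanning** — every IUPAC consensus variant of every CRE group,
   both strands, reduced to a gene × CRE presence matrix
   (`scan_promoters()`, `build_presence_matrix()`).
3. **Representation statistic** — for CRE *c* and gene set *S* with
   presence indicator `present(g, c)`:

   `percent(c, S) = 100 · |{g ∈ S : present(g, c)}| / |S|`

   classified on the exact fraction into three tiers:
   **over-represented** (≥ 75%), **moderately over-represented** (50–74%),
   **under-represented** (≤ 49%) (`analyze_representation()`,
   `classify_representation()`), with gene-set comparison per tier
   (`compare_gene_sets()`) and TF/functional-category roll-ups
   (`annotate_results()`, `summarize_categories()`).
4. **Classification-only mode** — reanalyze a published per-CRE percent
   table without sequences (`classify_percent_table()`).
5. **Synthetic data** — promoter sets and whole toy genomes with motifs
   planted at known per-gene probabilities, for ground-truth recovery
   testing (`simulate_promoter_set()`, `generate_dataset()`).

Results are tibbles throughout; fitted results support `tidy()`,
`glance()` and `autoplot()`. `run_pipeline()` orchestrates either mode from
a config list or key=value file, and `inst/scripts/crescan` wraps it for
shell use (`scan` / `classify` / `simulate` subcommands).

## Worked example

Classify a bundled percent table (the over-represented tier listing of an
isoprene-response study, 61 up- / 54 down-regulated genes) and compare the
gene sets:

```r
library(crescan)

t1 <- classify_percent_table(
  system.file("extdata", "table1_percents.tsv", package = "crescan")
)
count_tiers(t1)
#> # A tibble: 6 × 3
#>   gene_set tier                           n
#>   <chr>    <ord>                      <int>
#> 1 down     underrepresented               0
#> 2 down     moderately_overrepresented     1
#> 3 down     overrepresented               10
#> 4 up       underrepresented               0
#> 5 up       moderately_overrepresented     3
#> 6 up       overrepresented               22

compare_gene_sets(t1, tier = "overrepresented")
#> CRE gene-set comparison at tier: overrepresented
#>   common: 7 | up only: 15 | down only: 3
#>   common CREs: DRE_like_motif, GATA_box, I_box, MYB_binding_site,
#>   RAV1_binding_site, SORLIP, W_box
```

22 CREs are over-represented among up-regulated genes, 10 among
down-regulated genes, and 7 CREs sit in the over-represented tier of both
sets — the published headline counts.

Sequence mode on a simulated dataset:

```r
ds <- generate_dataset(tempfile(), example_catalog(),
  n_up = 20, n_down = 20, promoter_length = 1000, seed = 20230131
)
res <- run_pipeline(list(
  genome = ds$paths$genome, annotation = ds$paths$annotation,
  gene_sets = ds$paths$gene_sets,
  catalog = system.file("extdata", "example_catalog.tsv", package = "crescan"),
  promoter_length = 1000, out_dir = tempfile()
))
res$representation
#> CRE representation analysis (sequence mode): 13 CREs x 2 gene set(s)
#> thresholds: over >= 0.75, moderate >= 0.50
#> # A tibble: 2 × 4
#>   gene_set underrepresented moderately_overrepresented overrepresented
#>   <chr>               <int>                      <int>           <int>
#> 1 down                    0                          2              11
#> 2 up                      0                          1              12
```

(Short consensi hit uniform background sequence often, so most example CREs
saturate both sets at 1-kb promoters — exactly why the bundled catalog is a
demonstration fixture, not a curated database.) The output directory holds
`promoters.fasta`, `occurrences.tsv`/`.bed`, `presence_matrix.tsv`,
`representation.tsv`, `comparison.tsv`, `annotated.tsv`,
`category_summary.tsv`, `tier_counts.json` and a `run_log.txt`.

See the vignette (`vignettes/cre-representation.Rmd`) for the window,
scanning and tier-boundary conventions and the design rationale.

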