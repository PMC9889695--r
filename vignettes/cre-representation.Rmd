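---
title: "Promoter CRE representation analysis: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter CRE representation analysis: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescan)
```

## The question the package answers

Gene sets that respond to a stimulus — here, sets of up- and down-regulated
genes — are often interrogated for the transcription-factor binding sites
(cis-regulatory elements, CREs) their promoters carry. The statistic at the
core of this package is deliberately simple: for each CRE group and each
gene set, the *percent of genes in the set whose promoter contains at least
one occurrence of the CRE*. CREs are then binned into three representation
tiers:

* **over-represented** — carried by at least 75% of the set's promoters,
* **moderately over-represented** — 50–74%,
* **under-represented** — at most 49%.

There is no significance test attached, by design: the method is a
threshold scheme on raw presence percentages, and adding a background-model
p-value would change the method, not implement it. Users who need
calibrated enrichment should use a dedicated enrichment tool downstream.

## Promoter windows

Promoters are fixed-length windows upstream of each gene's transcription
start site (TSS), 3 kb by default (`extract_promoters(length = 3000)`).
Conventions, each of which was a genuinely open choice:

* **Anchor.** The annotated gene start (TSS), not the translation start.
  Annotation sources differ here; gene-level features are the anchor this
  package uses, and the 5'-most coordinate of the `gene` feature on the
  annotated strand defines the TSS.
* **TSS base excluded.** The window is `[tss - L, tss)` on the forward
  strand for `+` genes: "upstream" is read exclusively. Either choice only
  shifts the window by one base; it is fixed and documented so results are
  reproducible.
* **Minus-strand genes** get the forward window `[tss + 1, tss + 1 + L)`
  reverse-complemented, so every returned promoter reads 5'→3' toward its
  TSS.
* **No trimming at neighboring genes.** Fixed windows are used even where
  an upstream gene overlaps them, matching the fixed-window convention of
  promoter databases.
* **Truncation.** Windows are clipped at chromosome bounds, flagged
  `truncated = TRUE`, and *retained*. The denominator of the percent
  statistic is the full gene set; `drop_truncated` in the pipeline excludes
  clipped promoters from both numerator and denominator for users who
  prefer a scannable-only denominator.

Internally all coordinates are 0-based half-open; GFF3 input (1-based
inclusive) is converted on read and human-facing FASTA headers print
1-based inclusive coordinates again.

## Motif model and scanning semantics

CRE groups are degenerate consensus strings in the 15-letter IUPAC
alphabet — not position weight matrices, because the motif catalogs this
method consumes publish consensi. A group may have several variants
(`TTGACC,TTGACT`); a promoter carries the group if **any** variant matches
(OR-over-variants). That is the only reading under which one percent per
CRE row is well defined when a row lists several binding-motif variants.

Scanning tests every window of each variant's length:

* **Both strands** by default (`strands = "both"`); CRE function is
  generally orientation-independent. A minus-strand hit at `[s, e)` means
  the reverse complement of that forward window matches the variant, and is
  found by scanning the reverse-complemented pattern forward.
* **Ambiguous genome bases are conservative.** A promoter `N` satisfies a
  pattern position only if that position allows all four bases (pattern
  `N`). The scanner never claims a match the sequence cannot guarantee.
* **Palindromes.** A self-reverse-complementary variant (e.g. `CANNTG`)
  reports both a `+` and a `-` occurrence at the same window; these count
  as one distinct occurrence window for presence purposes.
* **All overlapping occurrences are reported** — presence semantics make
  greedy consumption pointless, and the occurrence table is useful for
  reporting.
* **Presence threshold.** "Carries" means ≥ 1 distinct occurrence window by
  default; `min_occurrences` raises the bar for users who read "enriched"
  as "more than one hit".

## Tier classification

The published tier phrasing is in integer percent ("≥75%", "50–74%",
"≤49%"), which leaves non-integer fractions unassigned. The package uses
half-open intervals on the **exact rational fraction**:
`[0.75, 1]` over, `[0.50, 0.75)` moderate, `[0, 0.50)` under. So 74.9% is
moderate and 49.5% is under — the only partition consistent with both
printed phrasings. Classification never uses the rounded display percent:
a set where 74.5% of promoters carry a CRE is *not* promoted to
over-represented by display rounding.

`classify_percent_table()` applies the identical classifier to a published
percent table (classification-only mode), so tier counts and gene-set
comparisons can be reanalyzed without sequences. Blank cells mean "absent
from that set's listing" and are excluded from that set's rows.

## Annotation roll-up

Classified CREs are joined back to their catalog entry's interacting TFs
and functional tags. The tag vocabulary is `growth`, `stress`, `light`
plus free-form hormone tags (`ABA`, `JA`, `SA`, `CK`, `GA`, `BR`,
`auxin`, ...). Counting is multi-membership: a CRE tagged both `stress`
and `light` contributes to both counts, so tag counts sum to at least the
number of distinct CREs at a tier.

## The synthetic generator

`simulate_promoter_set()` / `generate_dataset()` emulate the study design
the pipeline targets: two labeled gene sets (defaults 61 up, 54 down),
3-kb promoters, i.i.d. background composition (uniform by default), and
per-gene, per-CRE Bernoulli planting of one concrete variant instance at a
uniform random offset. Defaults that the paper-scale conditions do not pin
down were chosen once: planting probabilities 0.85 (up) / 0.55 (down),
landing the two sets in the over- and moderately-over-represented tiers
the way published tables typically split. `generate_dataset()` writes one
chromosome per gene — padding, promoter, gene body, padding, with strands
alternating so both extraction branches are exercised — in exactly the
FASTA/GFF3/TSV dialects the readers consume, byte-identically for a fixed
seed (default 20230131).

Two details make ground-truth recovery exact rather than approximate:

* **Post-hoc truth.** Later plants may overwrite earlier ones at
  overlapping offsets; each intended site is re-checked against its pattern
  after all planting, and only surviving sites are recorded as truth.
* **Zero-background constructions.** With a pure-A background and a motif
  containing a non-A position, background hits are impossible, so observed
  presence must equal planted truth exactly — the sharpest possible test
  of the scanner and statistic. With any background, observed presence is
  ≥ planted truth (background hits only add).

What the generator does **not** emulate: real promoter grammar
(nucleosome positioning, CpG structure, motif clustering), overlapping
genes, alternative TSSs, repeat masking. Passing recovery tests therefore
demonstrates correctness of the machinery, not biological realism of any
particular catalog or threshold on real genomes.

## Numerical and testing choices

* Matching uses per-position base bitmasks; a pattern of length `L` against
  a promoter of length `n` costs `O(L (n - L + 1))` vector operations.
* Tests check the scanner against a naive per-window set-membership oracle
  (independently implemented, down to its own IUPAC tables) on hundreds of
  random sequence/pattern pairs, and check strand symmetry and occurrence
  monotonicity as properties.
* Tier-recovery simulations run at 100 genes × 300-bp promoters × 50
  seeds per planting probability (0.9 / 0.6 / 0.2). With a zero-background
  construction the promoter length does not enter the statistic, so 300 bp
  is simply an economical choice; recovery is asserted in ≥ 95% of seeds
  and observed fractions are checked against exact binomial 99% intervals
  with the same ≥ 95% coverage bar.
* All stochastic tests iterate over explicit seed lists; packaged example
  datasets use the single documented default seed.

## Known limitations

* Consensus matching is exact (no mismatches); degenerate positions are the
  only tolerance mechanism. PWM scoring is out of scope.
* The percent statistic ignores occurrence counts beyond the presence
  threshold and ignores positional biases within the promoter.
* The bundled example catalog contains widely used literature consensi as a
  convenience fixture; it is not a transcription of any specific motif
  database release, and analyses of real genomes should supply a curated
  catalog.
* Gene-level TSS anchors ignore isoform-specific alternative TSSs.
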