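# ribotraffic

Codon-level translation-efficiency analysis for synonymous expression
libraries and genomes: tAI-based per-codon speeds, translation **bottleneck**
scanning, ribosome traffic-jam prediction, library correlation statistics,
and genome-wide bottleneck placement surveys — plus a seeded synthetic
library generator that makes the whole pipeline testable offline.

## The science in brief

Gene-level codon-adaptation measures (CAI, tAI) average over a whole coding
sequence and ignore *where* slow codons sit. `ribotraffic` works at codon
resolution. Per-codon relative adaptiveness is derived from the tRNA pool,

    W_i = sum_j (1 - s_ij) * tGCN_j,      w_i = W_i / max_k W_k,

where `tGCN_j` is the gene copy number of anticodon `j` and `s_ij` the
codon:anticodon wobble constraint; `1/w_i` is the codon's translation time.
The **bottleneck** of a gene is the `n`-codon window (default `n = 21`, the
measured ribosome-to-ribosome spacing of 21.6 nm at 0.34 nm/base) whose
codons have the minimal harmonic mean of `w` — the window that takes longest
to translate. Each gene gets a bottleneck `relative_location = k/(l - n + 1)`
and `relative_strength` (window mean of `1/w` over the gene mean of `1/w`).
A trailing ribosome jams behind a leader iff
`max_k Tw(k, H) > Tw(1, H) + B` (strict), with `Tw` the window translation
time and `B` the initiation assembly time.

In synonymous expression libraries the package correlates bottleneck
geometry with per-cell protein abundance (bulk signal / optical density),
optionally controlling for mRNA folding energy by first-order partial
correlation; screens all 61 sense codons for usage-vs-fitness effects at a
Bonferroni-corrected 0.05/61; and ranks fitness-reducing codons by the
minimum absolute partial correlation against every other candidate codon.
At genome scale it surveys bottleneck placement (genes > 100 codons) and
tests quadrant enrichment of strong bottlenecks with one-sided
hypergeometric tails.

## Worked example

Simulate the default library (150 synonymous variants of a bundled
synthetic GFP-like protein, with planted effects: proximal + strong
bottlenecks raise abundance, TCA/CAT copies depress OD) and analyze it:

```r
library(ribotraffic)
library(dplyr)

w   <- codon_weights()                      # E. coli-style default pool
lib <- default_library(seed = 7, weights = w)

ana <- analyze_bottleneck_vs_expression(lib, w)
tidy(ana) |>
  filter(method == "spearman", parameter != "tai") |>
  select(parameter, scope, r, p_value, n_obs)
#> # A tibble: 4 × 5
#>   parameter         scope      r  p_value n_obs
#>   <chr>             <chr>  <dbl>    <dbl> <int>
#> 1 relative_location all   -0.760 1.57e-29   150
#> 2 relative_strength all   -0.150 6.72e- 2   150
#> 3 relative_location band   0.526 1.42e- 2    21
#> 4 relative_strength band   0.558 8.51e- 3    21
```

Proximal bottlenecks predict high per-cell abundance (negative location
correlation over all 150 variants), and within the proximal band
(relative location 0.16–0.28, 21 variants) stronger bottlenecks predict
higher abundance — the planted structure, recovered. Ranking the codons
whose usage depresses OD:

```r
rank_fitness_codons(lib) |>
  select(rank, codon, raw_r, min_abs_partial_r, controlling_codon) |>
  head(3)
#> # A tibble: 3 × 5
#>    rank codon  raw_r min_abs_partial_r controlling_codon
#>   <int> <chr>  <dbl>             <dbl> <chr>
#> 1     1 CAT   -0.804             0.797 GAA
#> 2     2 TCA   -0.498             0.486 TTG
#> 3     3 TTG   -0.204             0.163 TCA
```

The two planted penalty codons occupy ranks 1–2: no other codon's counts
explain their OD association away (large `min_abs_partial_r`), while the
rank-3 passenger collapses once controlled. Per-codon times are equally
direct:

```r
time_profile("ATGCGAAAA", w)
#> # A tibble: 3 × 4
#>   position codon weight  time
#>      <int> <chr>  <dbl> <dbl>
#> 1        1 ATG    0.5    2
#> 2        2 CGA    0.133  7.50
#> 3        3 AAA    1      1
```

Real data enter through `read_orf_fasta()`, `read_library_table()` (variant
measurements + variant FASTA), `read_trna_pool()`/`read_s_values()` and
`read_expression_levels()`; `survey_genome()`, `quadrant_enrichment()` and
`expression_classes()` cover the genome-scale stage, and
`run_pipeline(step, pipeline_config(...))` writes TSV artifacts with run
manifests for each stage. `autoplot()` methods draw the location-vs-abundance
scatter and the per-codon fitness bar chart.

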