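# giscreen

Quantitative analysis of arrayed genetic-interaction screens in budding
yeast — from colony-size time courses and binary selection-plate growth to
fitness scores, epistasis scores, consensus calls and synthetic-lethality
(SL) classification, with a full synthetic screen generator for testing
every stage against a known ground truth.

## Who it is for

Groups running SGA/E-MAP-style screens: a panel of *n* nonessential
deletions crossed pairwise (all *n(n−1)/2* unordered pairs), double-mutant
haploids selected, survivors pinned in quadruplicate onto phenotyping
plates imaged over 12–60 h on multiple media. The package takes the
plate-imager export (plate, media, row, col, time, size) plus a plate
layout, and returns replicate-level and consensus interaction scores and SL
calls with quality control.

## The model

Colony area grows approximately linearly over the imaging window, so each
colony is summarized by the ordinary-least-squares slope of

    s_t = r · t + s0

Fitness is the same-plate ratio to wild-type controls,

    W = r_mutant / r_WT

and the genetic-interaction score is the deviation from the multiplicative
expectation,

    ε = W_AB − W_A · W_B

(negative = aggravating, positive = alleviating; an SL pair of healthy
genes sits near ε = −1). Per plate, sizes are normalized to in-plate
wild-type controls, edge-adjacent colonies are rescaled so ring and
interior mean rates match, and each technical quadruplicate is
jackknife-filtered before averaging. Across biological replicates (up to
16 in the default design: 4 cross sets × 2 mating types × 2 marker
orientations) the consensus ε is a histogram mode: the midpoint of the
most populated 0.05-wide bin. SL is called from the binary stage: ≥ 4
no-growth replicates, after excluding parent strains with < 1/3 viable
progeny. Monogenic self-cross sentinels (which cannot yield double-marker
progeny) estimate the false-negative rate; single-parent and empty
positions estimate contamination. See the vignette
(`vignettes/scoring-genetic-interactions.Rmd`) for the full method account.

## Worked example

Simulate a 10-gene screen with 4 truly SL pairs on two media, analyze it,
and look at the calls:

```r
library(giscreen)

cfg    <- sim_config(panel = default_gene_panel()[1:10], n_sl_pairs = 4,
                     n_epistatic_pairs = 8, media = default_media()[1:2, ])
truth  <- make_truth(cfg, seed = 42)
screen <- simulate_screen(truth, seed = 43)
res    <- analyze_screen(screen)

subset(res$sl, likely_sl)
#> # A tibble: 4 × 6
#>   gene_a gene_b pair_id   n_replicates_scored support likely_sl
#>   <chr>  <chr>  <chr>                   <int>   <int> <lgl>
#> 1 BCK2   CLB3   BCK2:CLB3                  16       9 TRUE
#> 2 BUB1   CLB2   BUB1:CLB2                  16      14 TRUE
#> 3 BUB2   CLB2   BUB2:CLB2                  16       9 TRUE
#> 4 CLB2   CLB3   CLB2:CLB3                  16      12 TRUE

res$qc$fn$percent
#> [1] 38

head(subset(res$consensus, media == "YPD"), 4)
#> # A tibble: 4 × 10
#>   media gene_a gene_b pair_id    n_replicates consensus bottom2_5 bottom5 top5
#>   <chr> <chr>  <chr>  <chr>             <int>     <dbl> <lgl>     <lgl>   <lgl>
#> 1 YPD   BCK2   BUB1   BCK2:BUB1            16     0.025 FALSE     FALSE   FALSE
#> 2 YPD   BCK2   BUB2   BCK2:BUB2            16     0.025 FALSE     FALSE   FALSE
#> 3 YPD   BCK2   BUB3   BCK2:BUB3            16     0.025 FALSE     FALSE   FALSE
#> 4 YPD   BCK2   CDC55  BCK2:CDC55           16     0.075 FALSE     FALSE   TRUE
```

The four likely-SL calls are exactly the four pairs the truth table made
inviable: each shows 9–14 no-growth replicates of 16 (the shortfall from 16
is the simulated 38% false-negative escape process), and the sentinel
estimate recovers 38%. Consensus ε values for non-SL pairs sit within a
bin width of their generating values; `bottom5`/`top5` flag the empirical
5% tails per media. `write_results(res, "out/run1")` writes the replicate,
consensus and SL tables plus symmetric gene-by-gene matrices, all of which
re-read bit-exactly with `read_results()` / `read_pair_matrix()`.

Real data enter through `read_colony_sizes()` (CSV/TSV imager export) and
`read_layout()`; curated evidence (documented SL status, tetrad outcomes,
model predictions) through `read_evidence()`, reconciled into confidence
classes with `reconcile_evidence()` and compared with `venn_partition()`.

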