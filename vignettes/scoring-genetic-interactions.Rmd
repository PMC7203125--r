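---
title: "Scoring genetic interactions from arrayed double-mutant colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions from arrayed double-mutant colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giscreen)
```

## The screen and its model

`giscreen` analyzes arrayed genetic-interaction screens in budding yeast:
a panel of *n* nonessential gene deletions is crossed pairwise (all
*n(n−1)/2* unordered pairs), double-mutant haploids are selected, and the
survivors are pinned in quadruplicate onto phenotyping plates that are imaged
repeatedly. Two kinds of evidence come out of such a screen:

* **binary viability** on the double-mutant selection plates — the raw
  material for synthetic-lethality (SL) calls; and
* **colony-size time courses** on phenotyping plates — the raw material for
  quantitative fitness and epistasis scores.

Colony area grows approximately linearly over the 12–60 h imaging window
used here, so each colony is summarized by the ordinary-least-squares slope
of

$$s_t = r \cdot t + s_0,$$

its growth rate $r$ in area units per hour. Fitness is the same-plate ratio
to the wild-type controls, $W = r_\mathrm{mutant} / r_\mathrm{WT}$, and the
genetic-interaction score is the deviation from the multiplicative
expectation,

$$\varepsilon = W_{AB} - W_A W_B,$$

negative for aggravating and positive for alleviating interactions. A
synthetic-lethal pair of two individually healthy deletions sits near
$\varepsilon = -1$.

Biological replication is built into the crossing design
([`cross_design()`]): independent cross sets, both mating types, and the two
reciprocal marker orientations give up to
$4 \times 2 \times 2 = 16$ biological replicates per pair in the default
design — the screen's answer to the notorious irreproducibility of
single-pass SL screens.

## Pipeline order and the wild-type normalization

`compute_fitness()` processes each (plate, media) unit as: **normalize →
fit rates → edge-correct → jackknife quadruplicates → average → fitness**.
Plate-level corrections are applied before replicate aggregation so that
technical structure never leaks into biological averages.

Normalization deserves a note, because two reasonable conventions exist and
they are *not* interchangeable:

* dividing every size by the mean wild-type size **at the same time point**
  (`normalize_sizes(per_time = TRUE)`) makes the sizes themselves
  plate-comparable (the mean WT size is exactly 1 at every time point), but
  it also divides out the common time trend — rates fitted to such series
  are near zero and carry no growth information;
* dividing by a **single plate-level scalar**, the mean WT size over all
  control colonies and times (`per_time = FALSE`), removes the same
  multiplicative plate effect while preserving the linear time structure.

The rate pipeline therefore uses the scalar variant. Because $W$ is a
same-plate ratio of rates, any multiplicative plate effect cancels in $W$
either way; the per-time variant remains available for size-level QC and
display. This choice is the package's own; both variants satisfy the same
scale-invariance contract (multiplying all raw sizes on a plate by any
$c > 0$ leaves every $W$ unchanged, tested to $10^{-12}$).

## Edge correction

Colonies on the outermost occupied ring of the mutant array grow faster
(more nutrients, less competition). `correct_edge_effects()` multiplies the
edge-adjacent rates by (mean internal rate / mean edge rate) per plate, the
minimal adjustment that makes the two group means equal. Two conventions are
explicit here:

* *edge-adjacent* means lying on the outermost occupied ring (minimum or
  maximum occupied row or column) of the mutant array — the simplest
  testable predicate;
* the group means are computed over **growing** colonies only (fitted rate
  above `live_fraction` = 0.25 of the plate's median mutant rate). Dead
  positions carry near-zero slopes, and whichever group happens to hold more
  of them would otherwise be dragged toward zero, biasing the factor. The
  factor is then applied to all edge rates (scaling a near-zero slope is
  harmless).

The correction estimates its factor from group means, so when fitness
composition differs between ring and interior it transfers a little of that
difference into the rates. It is on by default
(`screen_config(edge_correct = TRUE)`); the noiseless-identity test disables
it, because with no injected edge effect the correction itself is the only
remaining error source.

## Quadruplicate filtering

Technical quadruplicates occasionally contain one failed pinning.
`jackknife_filter()` removes at most one value from a quad, and only when
both of these hold:

* removing it collapses the leave-one-out standard deviation below
  `tau_sd` = 0.5 times the full sd, and
* its absolute deviation from the quad median exceeds `mad_multiplier` = 3
  times the (raw) median absolute deviation.

With fewer than three values nothing is removed. The thresholds are
configuration (`screen_config()`), not biology: a quad like
{1.0, 1.01, 0.99, 0.0} loses its dead pin, while {1, 0, 1, 0} — no single
outlier — is left alone. The vectorized pipeline implementation is tested
for exact agreement with this reference function.

## Consensus interaction scores

Replicate $\varepsilon$ values for one genotype scatter widely, and their
mean is dominated by false-negative escapes. The consensus is a **histogram
mode**: scores are binned into left-closed, right-open bins of width 0.05
anchored at zero, and the consensus is the midpoint of the bin holding the
most replicates. Ties break toward the bin whose midpoint is smallest in
absolute value, then toward the lower bin — a deterministic, conservative
rule. Bin width and anchoring are configuration; 0.05 resolves fitness
differences comfortably above the replicate noise floor while keeping
single-replicate bins rare at 16 replicates. Pairs with fewer than
`min_replicates` = 4 biological replicates are reported as missing rather
than scored.

Per media, consensus scores in the empirical bottom/top 5% (and 2.5%) are
flagged (`flag_extreme_gi()`, type-7 quantiles, boundary values included);
with fewer than 20 values or a degenerate distribution no flags are set.

## Synthetic-lethality calling and QC

The binary stage scores each replicate lineage present/absent
(`call_growth()`: final size at least 3x the background level). Calls are
pooled per unordered pair across cross sets, mating types and orientations;
`support` is the number of no-growth replicates, and a pair is `likely_sl`
at support ≥ 4 (`screen_config(sl_threshold = 4)`). Parents whose crosses
mostly fail would flood this count with false support, so parent lines with
viable/attempted < 1/3 are excluded first (the boundary 12/36 is kept);
attempted/viable are counted over each parent's double-mutant crosses.

Sentinel positions provide the error accounting: *monogenic* crosses (both
parents deleted for the same gene) cannot yield double-marker progeny, so
their growth frequency estimates the false-negative rate —
`estimate_false_negative_rate(77, 202)` reproduces the 38% headline
arithmetic — and *single-parent*/*empty* positions estimate contamination.
Both are reported pooled and per mating type.

Tetrad analysis, where available, is the gold standard:
`classify_confidence()` applies an ordered, overridable rule table — any
viable tetrad ⇒ `high_confidence_viable`; an SL tetrad with no conflicting
(V or RV) tetrad ⇒ `high_confidence_SL`; everything else (ambiguous, MD,
RV-only, untested) ⇒ `uncertain`. `venn_partition()` compares documented,
observed and predicted SL sets region by region.

## What the simulator emulates — and what it does not

`make_truth()` + `simulate_screen()` generate a screen with the statistical
structure the analysis assumes, so that every stage runs and can be checked
against a known ground truth with no external data:

* the default conditions are the study design: 36 genes, 4 cross sets x 2
  mating types (10,368 lineages, 16 replicates per pair), quadruplicate
  384-density plates with WT rows A/B/I/J, six media with wild-type rates
  scaled inversely to doubling times of ~100/150/200 min (YPD/YPG/YPR, drug
  media at 0.8x YPD), imaging at 12–60 h, 29 truly SL pairs, a 38%
  false-negative and 2% false-positive process;
* viability is drawn **once per lineage** at the haploid-selection stage and
  shared by all media and technical quadruplicates — the master plate is
  pinned once, and a per-media draw would make the binary cross-set grids
  ill-defined;
* single-mutant fitness per gene: most genes near wild type
  (N(1, 0.03) truncated to [0.85, 1.1]), a 15% slow-growth tail
  (U(0.5, 0.85)) — a simulator convention, since no distribution is implied
  by the design itself; single-mutant reference values are measured from a
  parent-strain reference plate cycled over all blocks, per media;
* noise: additive measurement noise per imaging point, per-colony intercept
  jitter, one log-normal multiplier per (plate, media), and a 1.2x rate
  multiplier on the outermost mutant ring; dead positions produce
  background-level sizes below the growth-call threshold;
* escapes: a false-negative SL colony grows like its fitter single parent;
  a contaminant at a sentinel position grows like wild type.

Not emulated: mechanistic meiosis (suppressors, disomy, gene conversion are
collapsed into the phenomenological rates), logistic saturation of colony
growth, spatial noise beyond the two-group edge structure, media-specific
epistasis shifts, and agar or pinning artifacts that are not multiplicative.
Passing the recovery tests therefore shows the pipeline inverts its own
generative assumptions correctly — not that real plates satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Bin indices use `floor(x / w + 1e-9)`: values an IEEE rounding error below
  a bin boundary land in the bin they mathematically belong to.
* Quantiles are type-7 (linear interpolation); OLS is the closed form,
  exact on collinear input and cross-checked against `stats::lm`.
* Negative fitted slopes are clamped to zero at fitness computation only;
  the raw fit is kept for QC.
* Typed conditions (`giscreen_parse_error`, `giscreen_qc_error`,
  `giscreen_capacity_error`, ...) cover every documented failure: plates
  without WT controls, non-positive WT means, degenerate time designs,
  over-capacity layouts, malformed or duplicated table rows, unknown
  tetrad vocabulary, zero-sentinel rate requests.
* All randomness flows through explicit integer seeds; a (config, seed)
  pair reproduces a truth table or screen identically.

## Problem sizes used in the checks

The test suite exercises most properties on an 8-gene, 1–2 media screen
(seconds each) and runs the full default screen — 36 genes, all media for
the end-to-end check, with 288 monogenic sentinels — once. Calibration
properties use 200 sentinels x 50 seeds for the false-negative estimator
and >10,000 replicate-set draws against an exact binomial summation for the
support distribution. The acceptance script analyzes the full default
screen on the reference media.

## Known limitations

* The linear growth model is a deliberate simplification; late-saturating
  colonies bias rates downward on slow media.
* Single-mutant fitness is estimated from one reference plate per media;
  a systematic error there propagates into every $\varepsilon$ involving
  that gene.
* The edge correction is a two-group mean equalization, not a spatial
  model; plates with strong gradients need more than one factor.
* Consensus quality degrades below ~6 replicates; with 4 (the minimum) the
  mode is close to a majority vote.
* SL calling is a count threshold by design — no significance testing is
  attempted, matching the screen's decision rule.
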