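---
title: "Modeling cancer breakpoint hotspots from genomic and epigenomic tracks"
author: "BreakpointHotspots authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cancer breakpoint hotspots from genomic and epigenomic tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Somatic structural variants in cancer genomes break the DNA at loci that are
far from uniformly distributed: a small fraction of the genome accumulates
recurrent breakpoints ("hotspots"). The question this package addresses is
whether the location of those hotspots can be predicted from properties of
the *normal* genome — alternative DNA secondary structures (G-quadruplexes,
Z-DNA, repeats), transcription-factor binding, histone modifications,
methylation, chromatin accessibility, TAD organization and genic
architecture — and which of those feature classes carry the signal.

The analysis unit is a fixed-width genome window (100 kb by default). The
pipeline is:

1. **Windowing.** Tile each chromosome from its start into non-overlapping
   100 kb windows; drop the first and last window of every chromosome,
   windows intersecting centromere/telomere or blacklist intervals by at
   least one base, and entire excluded chromosomes (chrY, chrM in the real
   analysis). Window ids are stable: filtering flips a mask, never
   renumbers.
2. **Breakpoint reduction.** Breakpoint records carry a positional
   uncertainty interval; records wider than 10 bp are removed (strict: a
   width-10 record survives). Optionally, records overlapping a
   low-mappability track (Duke 35-mer uniqueness below 0.5) are removed for
   sensitivity analysis. Per window and cancer type, the density is the
   overlap count divided by the chromosome's record total for that cancer
   type — counted before window filtering, so the denominator is not
   affected by which windows are retained.
3. **Labeling.** A window is a hotspot at labeling type $q$ if its density
   strictly exceeds the $q$-th percentile of the density distribution over
   all retained windows genome-wide for that cancer type (zeros included).
   Labels nest by construction across
   $q \in \{75, 90, 95, 99, 99.5, 99.9\}$. A presence flag marks windows
   with any breakpoint.
4. **Feature engineering.** Per track: local coverage (covered fraction of
   the 100 kb window, overlapping intervals merged first), distant coverage
   (the covered fraction of the window's 1 Mb block, exported with the
   `upper_` prefix), a binary presence flag, and seven local-maximum
   indicators (strict exceedance of the feature's own 90/95/99th
   percentiles; strict dominance over all 1/5/10 neighbors per side; and
   the relative difference to the 10-per-side neighborhood maximum).
5. **Modeling and evaluation.** A Random Forest scores windows; quality is
   measured over 30 stratified 70/30 train/test splits with ROC AUC, PR
   AUC, and lift of recall/precision at the 0.03/0.05/0.1 probability
   percentiles. Feature and group importance use Boruta shadow-feature
   selection, forward selection, and lift-based group ranking.

# Evaluation metrics under class imbalance

Hotspots are ~1% of windows, so accuracy and even ROC AUC understate the
practical question: *of the windows the model is most confident about, how
many are real?* The lift metrics answer it directly. With
$n$ windows and selection fraction $p$, the top set is the
$\lceil pn \rceil$ highest-scoring windows (ties broken by window id, so
the selection is deterministic — a deliberate divergence from a literal
quantile cut, which is ambiguous under ties). Then

$$\mathrm{lift_{recall}}(p) = \frac{\mathrm{recall\ in\ top\ set}}{p},
\qquad
\mathrm{lift_{precision}}(p) = \frac{\mathrm{precision\ in\ top\ set}}{\pi},$$

where $\pi$ is the prevalence. A random ranking has expected lift 1; a
perfect ranking attains $\min(1/p, 1/\pi)$. ROC AUC uses the
pair-probability convention (ties count one half); PR AUC is step-wise
average precision. McFadden's pseudo-$R^2$, $1 - \ell_{model}/\ell_{null}$,
is computed from logistic fits and their intercept-only nulls.
Aggregates over splits report mean, median and the normal-approximation
95% CI of the mean ($\pm 1.96\,s/\sqrt{30}$).

# The synthetic data generator

Real inputs (ICGC breakpoint exports, ENCODE/UCSC tracks) are large and
external; the generator produces a desk-scale bundle in exactly the file
formats the real-mode readers consume, so synthetic and real pipelines
share one code path, plus a planted ground truth for recovery tests.

**Tracks.** Each feature's intervals follow a renewal process
(exponential gaps and lengths) whose gap mean is modulated block-wise
(1 Mb) by a mean-one lognormal field with scale set by a clustering
factor. Expected coverage is $\ell/(\ell+g)$ for mean length $\ell$ and
mean gap $g$; the clustering factor induces the spatial autocorrelation
that real annotation and peak tracks show. The defaults (three "non-B
DNA" features at ~20% coverage, three "TF" features at ~10%, two "genomic
regions" features at ~25%, clustering 0.5–0.8) were chosen once as
plausible desk-scale analogues.

**Breakpoints.** Window intensities follow a log-linear model
$$\lambda_w = \exp\!\big(\beta_0 + \beta^\top z_w + \gamma^\top u_w\big)\,
\varepsilon_w,$$
with $z_w$ standardized local coverages, $u_w$ standardized 1 Mb
aggregates, and $\varepsilon_w \sim \Gamma(1/d,\, d)$ (mean 1) an
overdispersion term (default $d = 0.5$) that produces the heavy-tailed
recurrent-hotspot structure that 99%+ labeling presumes. Standardizing
$z, u$ against the generated windows' own mean and SD makes the
coefficients scale-free. $N(1-\rho)$ breakpoints are allocated to windows
multinomially with weights $\lambda_w$; $N\rho$ noise breakpoints are
uniform over retained windows. Positions are uniform within the window;
uncertainty widths come from a mixture that emits ~8% of widths above the
10 bp cutoff, so the record filter is exercised on every bundle. The
planted truth marks the top 1% of windows by **expected density** —
$\lambda_w$ normalized by its chromosome's $\lambda$ total, the same
per-chromosome normalization the density labeler applies. (Ranking raw
$\lambda$ genome-wide would make the truth unrecoverable whenever one
chromosome carries a hot cluster, because that chromosome's denominators
deflate all its windows' densities.)

**Presets.**

| preset | genome | N | $\rho$ | effect | role |
|---|---|---|---|---|---|
| `local-signal` | 3 × 20 Mb (~588 windows) | 5000 | 0.1 | $\beta = 1.5$ on one local feature | signal recovery |
| `distant-signal` | 3 × 20 Mb | 5000 | 0.1 | $\gamma = 2$ on the 1 Mb aggregate of a locally noisy feature | distant-feature ablation |
| `mixed` | 3 × 20 Mb | 1200 | 0.5 | $\beta = 3$ on a sparse clustered feature | hotspot-vs-breakpoint discrimination |
| `null` | 3 × 80 Mb (~2388 windows) | 6000 | 1 | none | negative control |

The `mixed` preset uses fewer breakpoints so that a substantial share of
windows stays empty and the presence flag has two well-populated classes;
its carrier feature is sparse and strongly clustered so the signal half of
the breakpoints concentrates in a few dozen windows — hotspots are then
feature-driven while presence elsewhere is noise-dominated, the regime the
hotspot-vs-breakpoint comparison asks about. In `distant-signal` the
carrier's intervals are sparse enough that its 100 kb coverage is mostly
sampling noise (~25–30% relative) while the block-level signal is of the
same order; averaging ten windows into the 1 Mb aggregate recovers the
signal, so the effect is learnable at the distant scale but heavily
attenuated locally.

**Null-control sizing.** Because feature tracks are autocorrelated at the
1 Mb block scale, the effective sample size of a smooth feature field is
roughly the number of blocks, not the number of windows. A fixed random
label draw therefore correlates with the best of $K$ such fields at
magnitude $\approx \sqrt{2\log K / n_\mathrm{eff}}$, and the forest
exploits that spurious association consistently because all 30 splits
share the label vector. The null preset's genome is sized (240 blocks)
so this bias keeps the 30-split median ROC AUC within a few hundredths
of 0.5. This is worth knowing outside the simulation too: on small or
strongly autocorrelated genomes, repeated splits of a single labeling do
not average away label-field coincidences.

# What passing tests do and do not show

The generator emulates interval length/gap structure, spatial
autocorrelation, overdispersed recurrence, positional uncertainty and a
tunable random fraction. It does **not** emulate SV classes or breakend
pairing, donor-level clonal structure, sequence content, chromosome-scale
covariate gradients (e.g. replication timing), or inter-feature
correlation structure of real epigenomes. Recovery of planted effects
therefore validates the machinery — windowing, labeling, features,
models, metrics, selection — not the biological conclusions one would
draw on real data.

# Numerical and design choices

- **Coordinates.** Internally everything is a `GRanges` (1-based closed),
  the Bioconductor convention; BED I/O converts through `rtracklayer`, and
  ICGC-style 1-based inclusive tables map directly. Interval widths and
  overlap semantics are unaffected by this choice.
- **Percentiles** everywhere (hotspot thresholds, feature percentile
  flags) are `stats::quantile` type 7 — linear interpolation between order
  statistics — with strict exceedance. All-equal inputs yield zero
  hotspots.
- **Merging.** Canonical interval sets are sorted, disjoint, and merge
  touching intervals (coverage is unaffected; the canonical form is
  simpler).
- **Distant aggregation** uses fixed 1 Mb tiling aligned to the chromosome
  start (not a window-centered rolling mean): deterministic, one value per
  block matching the `upper_` naming, and the trailing partial block uses
  its actual length as denominator.
- **Maxima neighborhoods** run over retained windows in coordinate order
  (masked windows are skipped, not treated as gaps), never cross
  chromosome boundaries, compare against however many neighbors exist near
  edges, and a window with no neighbors gets flag 0. The relative
  difference uses $(x - m)/(m + 10^{-9})$ to stay finite on empty
  neighborhoods.
- **Splits.** "Stratified by chromosome and position" is operationalized
  as chromosome × positional tercile × class; strata under 4 rows collapse
  to chromosome × class; singletons always train. Within each stratum the
  test share is within one row of the plan's fraction. Base seed + repeat
  index makes every split reproducible.
- **Random Forest.** `randomForest` with 500 trees, max 512 terminal
  nodes, min node size 30, `mtry` = ⌈√p⌉ by default (regression: p/3).
  These are conventionally tuned by averaging test ROC AUC across cancer
  types; `tuneRF()` does exactly that on any config grid, breaking ties
  toward smaller models. Every fit is seeded, so
  (data, config, seed) determine scores bit-identically.
- **Imbalance** is handled purely through metrics; no resampling or class
  weights.
- **Boruta** scores features with out-of-bag permutation importance scaled
  by its SD over trees — the original method's statistic. Impurity (Gini)
  importance is available behind a flag but makes a poor decision
  statistic here: the feature most spuriously correlated with a fixed
  label vector beats every *fresh* shadow draw on Gini importance almost
  every iteration (its in-sample association is real while the shadows'
  is redrawn), which in our null simulations confirmed noise features in
  about half the runs; with the scaled permutation statistic the null
  confirms almost nothing. Each iteration adds one fresh shadow per
  remaining real feature, padded to at least five shadows when few remain
  (with one or two shadows the max-shadow reference collapses and null
  features hit at rate ~1/2). A hit requires *strictly* beating the best
  shadow; a two-sided binomial test at level $\alpha = 0.05$,
  Bonferroni-corrected across currently undecided features, confirms or
  rejects. Rejected features leave the design matrix; confirmed ones stay
  (they keep competing with shadows but their status is settled).
  Undecided features at `maxIter` are reported tentative and excluded
  from confirmed sets.
- **Degenerate inputs.** Zero-record chromosomes give zero densities (no
  division error); empty exclusion lists are allowed; single-class labels
  error with the missing class named; perfect logistic separation is
  flagged but likelihoods are still returned; an all-zero regression
  target errors.

# Problem sizes used in the test suite

Unit tests run on toy layouts (≤ a few Mb) against per-base and pair-counting
oracles. End-to-end checks use the presets above: 30-split Random-Forest
tasks on ~600-window bundles, a ~2,400-window null, ten-seed Boruta runs at
n = 400 with 25 features, and a 500 kb-window bundle on a 3 × 40 Mb genome
(~228 windows) for the 10-fold CV regression protocol — at 500 kb the
default genome would leave too few rows for cross-validation to be
meaningful. These sizes were chosen so the whole suite completes on
one CPU in well under half an hour while keeping every statistical check
comfortably powered.

# Known limitations

- The paper-scale numbers (real ICGC/ENCODE data: 29,288 windows, published
  ROC AUC/lift tables, McFadden values) require the external downloads and
  are out of scope; the package validates properties, not those values.
- `hotspot_vs_breakpoint` restricts rows to presence windows, so its
  splits stratify on a subset and small strata collapse more often.
- The multinomial allocation fixes the total breakpoint count (exactly N
  records); per-window counts are therefore slightly negatively correlated,
  unlike an idealized independent-Poisson field.
- Distant coverage assigns each window its containing block's value, so
  windows near block edges ignore the neighboring block entirely; a
  centered window would trade determinism and simplicity for smoothness.
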