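# BreakpointHotspots

Genome-window modeling of cancer structural-variant breakpoint hotspots in R
(Bioconductor-style: `GRanges`, `SummarizedExperiment`, S4 + camelCase).

## The problem

Somatic structural variants break cancer genomes at recurrent loci. Given a
table of breakpoints (with positional uncertainty intervals, donor and cancer
type, as in ICGC structural-mutation exports) and a collection of genomic /
epigenomic interval tracks (non-B DNA structures, TF binding sites, histone
marks, methylation, DNase accessibility, TADs, gene architecture), the
package asks: **can a model of the normal genome predict where breakpoint
hotspots form, and which feature classes carry that signal?**

The pipeline tiles the genome into non-overlapping 100 kb windows (first/last
window per chromosome, centromere/telomere/blacklist overlaps and excluded
chromosomes masked), computes per-window breakpoint densities

> density(w) = #breakpoints overlapping w / #breakpoints on w's chromosome,
> per cancer type,

labels a window a *hotspot* at labeling type *q* when its density strictly
exceeds the *q*-th percentile of the genome-wide density distribution
(q ∈ {75, 90, 95, 99, 99.5, 99.9}), and engineers per-track features at two
scales: local 100 kb coverage and distant 1 Mb block coverage (`upper_`
prefix), plus binary flags and local-maximum indicators. A Random Forest is
evaluated over 30 stratified 70/30 splits with imbalance-aware metrics:

> lift of recall(p) = recall among the top ⌈p·n⌉ windows by score ÷ p
> lift of precision(p) = precision among that top set ÷ prevalence

(a random ranking has lift 1; a perfect one reaches min(1/p, 1/π)), alongside
ROC AUC, PR AUC and McFadden's pseudo-R² = 1 − ℓ_model/ℓ_null. Feature
selection uses Boruta shadow features, forward selection, and scaled
lift-based group ranking. A synthetic-bundle generator plants a log-linear
intensity model λ_w = exp(β₀ + βᵀz_w + γᵀu_w)·ε_w (gamma overdispersion ε,
tunable pure-noise fraction ρ) and writes exactly the file formats the
real-mode readers consume, so every stage is testable with known ground
truth. See `vignettes/breakpoint-hotspot-modeling.Rmd` for the full model
account.

## Worked example

```r
library(BreakpointHotspots)

# a synthetic bundle: 3 x 20 Mb genome, 8 feature tracks in 3 groups,
# 5000 breakpoints with one strong planted local effect
bundle <- simulateBundle(simConfig("local-signal", seed = 1))
length(retainedWindows(bundle$grid))
#> [1] 588

# hotspot labels at the 99% labeling type, model on all engineered features
res <- runTask(taskSpec("hotspot_vs_all", q = 99), bundle,
               plan = splitPlan(nRepeats = 30, seed = 11),
               config = rfConfig())
subset(res$aggregate, metric %in% c("roc_auc", "pr_auc", "lift_recall_p03"))
#>            metric       mean     median     ciLow     ciHigh
#> 1         roc_auc  0.8764678  0.9311080  0.832208  0.9207276
#> 2          pr_auc  0.3777172  0.3172619  0.312227  0.4432075
#> 5 lift_recall_p03 18.8888889 16.6666667 16.826829 20.9509486
```

The model separates planted hotspots from the rest of the genome (median
test ROC AUC 0.93) and concentrates them ~17-fold over chance in its top 3%
of windows; the same machinery on a pure-noise bundle
(`simConfig("null")`) stays at chance (median ROC AUC ≈ 0.5).

```r
# which feature group carries the signal?
gc <- runGroupComparison(bundle, qPair = c(99, 99.5),
                         plan = splitPlan(6, seed = 21),
                         config = rfConfig(nTrees = 150, minNodeSize = 5))
gc$ranking
#>             group  score rank
#> 1       non-B DNA 1.0000    1
#> 2              TF 0.8125    2
#> 3 genomic regions 0.1250    3
```

The planted effect sits on a "non-B DNA" track, and the group ranking
recovers it with scaled score 1. (The "TF" group scores well here too:
with a clustered genome and only six hotspot windows at the 99% labeling
type, other smooth feature fields partially proxy the carrier — see the
vignette's effective-sample-size discussion.)

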