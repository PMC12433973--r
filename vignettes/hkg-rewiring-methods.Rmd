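---
title: "Methods: housekeeping-gene stability, co-expression rewiring, and diagnostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: housekeeping-gene stability, co-expression rewiring, and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkgrewire)
```

# Scope and model

`hkgrewire` implements a pipeline for studying housekeeping genes (HKGs) in
case/control transcriptomic cohorts such as psoriasis skin biopsies. HKGs
are genes expressed ubiquitously and stably across tissues; the package
asks two questions about them: *which genes qualify as housekeeping* (an
exon-level stability filter), and *how their co-expression with the rest of
the transcriptome is rewired in disease* (a binned differential
co-expression statistic). Around these sit the standard supporting stages:
two-group differential expression intersected across platforms, a weighted
co-expression network core for module and hub discovery, and an
ensemble-averaged neural-network classifier. All stages run on log2-scale
expression values.

# The housekeeping stability filter

An exon passes when all three criteria hold over the tissue panel:

1. **ubiquitous detection** — RPKM at or above `detection_min_rpkm`
   (default 1) in every tissue;
2. **low variability** — sample standard deviation of log2 RPKM strictly
   below `sd_max_log2` (default 1);
3. **no outlier tissue** — every tissue's ratio to the gene's mean lies
   strictly inside `(1/fold_max, fold_max)` (default 4; a tissue at
   exactly 4-fold fails, reading "at least 4-fold" as exclusion).

A gene is called an HKG when at least `exon_fraction_min` (default 50%) of
the exons of *some* transcript pass — the any-transcript rule, with the
best-supported transcript reported and ties broken lexicographically.

Two conventions are deliberately parameterized rather than guessed,
because the upstream catalogue construction does not publish them: the
detection floor (we default to RPKM ≥ 1, a common presence call), and
sample versus population SD (we default to the sample `n - 1` estimator,
the usual convention for expression variability; `population_sd = TRUE`
switches). A `log2_pseudocount` (default 0) is available for permissive
detection settings in which zeros can reach the log step.

# Differential expression and multi-platform intersection

Per gene, `logFC` is the case-minus-control mean difference of log2
values, with a two-sided Welch *t*-test and Benjamini–Hochberg adjustment
across genes. A gene is *up* when `adj_p < 0.05` and `logFC > 0.5`, *down*
symmetrically, both strict. We use a per-gene Welch *t* rather than a
moderated (empirical-Bayes) *t*: at the cohort sizes this pipeline
targets (dozens to hundreds of samples per group) variance moderation
changes little, and the plain *t* keeps the stage free of tuning
constants; a pooled-variance Student *t* is available via
`pooled_variance = TRUE`. Batch structure is handled by `batch_center()`,
the additive per-(gene, batch) offset model: subtract the batch mean, add
back the global gene mean.

`intersect_platforms()` keeps a gene only if it is significant on *every*
platform; by default its direction must also agree everywhere. Whether a
published multi-cohort consensus enforced direction consistency explicitly
or it held empirically is usually unstated; we default to enforcing it
(`require_consistent_direction = FALSE` switches) since a gene flipping
sign across platforms is not a reproducible marker.

# The co-expression network core

The network is built from scratch in a few dozen lines so that every step
is inspectable:

* **similarity** `S = |r|` (unsigned Pearson). Signedness is a genuine
  design fork; unsigned is the historical default of the method and is
  ours too, with `signed = TRUE` giving `(1 + r)/2`.
* **soft threshold**: for each candidate power, `A = S^beta`, node
  connectivity `k_i = sum_j a_ij`, and a scale-free fit index: square of
  the Pearson correlation between `log10(mean k)` and `log10(frequency)`
  over at most 10 equal-width connectivity bins, negated when the slope is
  positive. The smallest power with fit at or above `r2_target` (default
  0.8) is selected, falling back to the best-fitting power with a message.
  Bins with fewer than 3 distinct occupied cells yield a missing fit.
* **topological overlap**: `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 -
  a_ij)` with `l_ij = sum_u a_iu a_uj`; diagonal 1. Tested to 1e-12
  against a naive triple loop.
* **modules**: average-linkage clustering of `1 - TOM`, cut at a fixed
  height (default 0.99), clusters under `min_module_size` (default 30)
  unassigned. A static height cut replaces hybrid dynamic tree cutting:
  for planted-module recovery, which is what this package's tests and
  simulations measure, the static cut with a size filter is sufficient and
  has one fewer tuning surface. Modules are labelled M1, M2, ... by
  decreasing size (ties by smallest member id), so labels are
  deterministic.
* **eigengene**: first right singular vector of the gene-standardized
  module submatrix, unit norm, oriented so its mean correlation with
  member genes is positive.
* **MM / GS / hubs**: module membership is the signed correlation of a
  gene with its own module's eigengene; gene significance is the
  correlation with the 0/1 trait, reported as a magnitude by default
  (the conventional `GS > 0.8` hub filter implies a magnitude scale;
  `signed_gs = TRUE` exposes the sign). Hubs are module genes with
  `MM > 0.8` and `GS > 0.8`, strictly.

`wgcna_modules()` chains these; `power =` bypasses the scan when the
connectivity distribution is degenerate (a single clean module against
pure noise is bimodal and has no scale-free regime to fit).

# The rewiring statistic

Correlation values are binned into eight fixed intervals covering
[-1, 1], from "strongest negative" [-1, -0.75] to "strongest positive"
(0.75, 1]. The boundary convention is first-interval-closed, all others
left-open `(a, b]`, which makes the partition exact; note r = 0 therefore
falls in "weakest negative" (-0.25, 0]. The prose definitions of such
intervals ("-0.25 to 0", "0 to 0.25") never disambiguate 0; we chose the
left-open convention once and expose `convention = "right_open"` as the
alternative.

For a set of anchor genes (e.g. disease-linked HKGs),
`pairwise_group_correlations()` computes each (anchor, partner) Pearson
correlation separately within controls and cases; pairs with zero variance
in either group are excluded and counted, not imputed.
`transition_matrix()` tallies the 8x8 control-bin by case-bin table.
`select_rewired()` applies the selection rule: positive shifts of at least
`min_shift = 4` intervals, plus the explicitly listed extra transition
(5, 8) — weakest positive to strongest positive — kept as an explicit
extra rather than a lowered shift threshold, since it is a deliberate
inclusion, not a consequence of the distance rule. Downward shifts are
excluded by default (`direction = "both"` exposes them). By symmetry of
the construction, swapping the group labels transposes the matrix.

The packaged fixture `inst/extdata/table2.tsv` carries a published 8x8
worked example (34 anchor HKGs against the transcriptome, 569,646 pairs);
the default rule selects 139 pairs from it, the package's reference
output.

# The diagnostic stage

`train_ensemble_net()` implements averaged neural networks: `n_members`
(default 5) single-hidden-layer networks (logistic activations,
cross-entropy loss, L2 weight decay 0.01, `nnet` optimizer capped at 500
iterations) are trained on identical standardized features from different
seeded initializations, and the model score is the mean member class-1
probability. Averaging over initializations reduces score variance — the
property the tests assert directly. Ensemble size and architecture are
exposed defaults, not values inherited from any published analysis, which
reports none. Splitting is stratified 80/20 by class with per-class
rounding. `evaluate_scores()` reports the confusion matrix at a 0.5
threshold, accuracy, precision, recall, F1, and AUC as the Mann–Whitney
rank statistic with ties counted one half; the evaluation accepts scores
from *any* model, so other learner families can be dropped in.

# The synthetic-data generator

`simulate_two_group_study()` plants, on log2 scale with Gaussian noise:

* **baselines** — per-gene means N(8, 1.5), a realistic array-intensity
  scale;
* **modules** — gene `x_g = baseline + beta_g * f_m + noise`, with the
  module factor `f_m = alpha * trait + eta` and `alpha` solved so the
  population correlation between factor and 0/1 trait equals
  `module_trait_effect`. Loadings `beta_g` are uniform on `beta_range`
  (default 0.5–1.5): heterogeneous loadings give modules the connectivity
  spread of real co-expression networks (hubs load high, peripheral genes
  low), without which the degree distribution of a planted block is
  two-valued and the scale-free fit is meaningless;
* **DE genes** — a `de_shift` mean offset in cases with random sign,
  sampled outside modules and rewired pairs so the planted ground truth
  stays unconfounded;
* **rewired pairs** — partners generated conditionally on their anchor's
  standardized noise, per group: `z_partner = rho * z_anchor +
  sqrt(1 - rho^2) * z_new`, giving the exact target correlation structure
  and supporting several pairs sharing an anchor;
* **platforms** — `simulate_multi_platform()` re-simulates each platform
  independently from the same ground truth plus an additive
  per-(platform, gene) offset, the additive model that `batch_center()`
  removes.

Defaults mirror a large two-group skin cohort loosely (90 cases / 80
controls, 3 platforms). Note that module genes are *genuinely*
differentially expressed whenever `module_trait_effect > 0`, since their
factor contains `alpha * trait`; recovery experiments that score DE
sensitivity/FDR against the planted DE list therefore use module-free
configurations. Likewise, all modules share the single
`module_trait_effect`, so at high values the module factors become
mutually correlated (about the square of the effect) and modules merge;
module-recovery experiments use a moderate effect (0.5).

`simulate_tissue_exon_matrix()` plants stable genes that pass all three
stability criteria by construction (log2 profiles with truncated SD-0.2
noise) and unstable genes violating at least one: a zero-expression
tissue, an alternating high-variance profile (log2 SD > 1 but within the
fold band), or a 16-fold-low outlier tissue. The outlier is placed on the
*low* side because a single high outlier cannot exceed 4 times the
including-itself mean when tissues are few, whereas the low-side ratio
falls below 1/4 for any panel of at least two tissues.

What the simulations do **not** emulate: count-level sampling noise
(negative binomial), probe effects, correlated noise between non-module
genes, missing values, and single-cell structure. Passing recovery tests
therefore demonstrates correctness of the statistics under their own
assumptions, not robustness to real-array artefacts.

# Numerical choices and degenerate inputs

* Welch *t* with zero variance in both groups: p = 1 when means agree,
  the smallest positive double (with a warning) when they differ.
* Correlations outside [-1, 1] by more than 1e-9 are an error; within
  tolerance they are clamped before binning.
* Matrix outputs (similarity, TOM) are symmetrized by averaging with
  their transpose and clamped into [0, 1]; diagonals are set exactly.
* Zero-variance genes are an error in the network core (named in the
  message) and a counted exclusion in the rewiring stage — the former is
  a user mistake, the latter an expected event when a gene is silent in
  one group.
* All randomness flows from one master seed through a fixed derivation,
  so every simulate/train entry point is bitwise reproducible.

# Problem sizes

The recovery experiments shipped with the package use desk-scale versions
of the study design, chosen once: differential expression on 3 platforms
of 1000 genes at 100 samples per group; module recovery on 400 genes
(five 30-gene modules) at 60 per group; rewiring on 3 anchors x 500 genes
at 500 per group; the classifier on 200 samples x 34 features; each
averaged over 5 seeds. At these sizes the full suite and the acceptance
script each run in seconds.

# A worked example

```{r example, eval = FALSE}
library(hkgrewire)

tm <- read_transition_table(
  system.file("extdata", "table2.tsv", package = "hkgrewire"))
select_rewired(tm, rewiring_rule())
#> rewiring_selection: 139 pairs over 11 cells (5 nonzero)
#>   strong negative -> weak positive: 13
#>   weak negative -> strong positive: 51
#>   weak negative -> strongest positive: 1
#>   weakest negative -> strongest positive: 15
#>   weakest positive -> strongest positive: 59
```

# Known limitations

* No module merging by eigengene correlation and no blockwise computation;
  the network core targets networks of up to a few thousand genes.
* The static height cut can split one planted module at aggressive
  heights; the default 0.99 is tuned for TOM dissimilarities near 1
  between unrelated genes.
* The rewiring statistic carries no per-pair significance test, matching
  its original use as a descriptive selection; treat the selected pairs as
  candidates, not inferences.
* The HKG filter reproduces criteria, not any specific published
  catalogue, which depends on an external tissue compendium.
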