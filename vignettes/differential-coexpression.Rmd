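---
title: "Weighted co-expression networks and differential correlation: methods and design"
author: "dccnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression networks and differential correlation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccnet)
```

# The problem

Case-control transcriptomes are usually mined for genes whose *level*
changes. But regulation can also rewire: two genes tightly co-expressed in
health may decouple — or flip to anti-correlation — in disease, without
either gene moving much on average. Such *sign-switching pairs* are
invisible to differential expression, yet they are strong candidates for
regulatory changes, and the genes participating in many switched pairs
("hubs") are candidate master regulators.

`dccnet` implements this two-stage screen:

1. **Network stage.** Build a weighted gene co-expression network over all
   samples, partition it into modules, and keep the modules whose summary
   profile (eigengene) is most positively and most negatively correlated
   with the binary trait.
2. **Differential-correlation stage.** Inside those modules, test every
   gene pair for a change in correlation between the two conditions with
   Fisher's z-test, control the pair-level error with an empirical-Bayes
   local false discovery rate (lfdr), flag pairs whose correlation changes
   sign, and rank hub genes by their degree in the switched-pair network.

# The model, stage by stage

## Co-expression network

With expression matrix $X$ (genes × samples), the unsigned similarity is
$S_{ij} = |\mathrm{cor}(X_i, X_j)|$ (Pearson). A soft threshold raises it
elementwise to $a_{ij} = S_{ij}^{\beta}$, $\beta \ge 1$, which suppresses
weak correlations smoothly instead of cutting at an arbitrary hard
threshold. Connectivity is $k_i = \sum_{j \ne i} a_{ij}$.

The topological overlap matrix replaces raw adjacency by agreement of
neighbourhoods:
$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
  \qquad l_{ij} = \sum_{u \ne i, j} a_{iu} a_{ju}.$$
Two boundary facts pin the convention down, and are tested exactly: a gene
with zero adjacency to every other gene has a zero TOM row (isolated), and
a clique with all $a_{ij} = 1$ has TOM 1 everywhere. Both the neighbour sum
$l_{ij}$ and the connectivities exclude self-terms; including them can push
TOM above 1. Genes are clustered by average linkage on
$1 - \mathrm{TOM}$.

**Choosing $\beta$.** For each candidate power the connectivities are
binned into 10 equal-count bins and $\log_{10}$ of the per-unit-$k$ density
is regressed on $\log_{10}$ of the bin mean; an approximately scale-free
network gives a straight line with negative slope. We report the plain
$R^2$ of that fit (not a signed variant) and select the smallest power with
$R^2 \ge 0.80$. Two numerical details matter. Equal-count bins are robust
to the heavy-tailed $k$ distribution, but the binned quantity must then be
a *density* (count divided by bin width), since raw counts are constant by
construction. And powers that empty the network are excluded from
selection: once mean connectivity falls below 1 almost all $k$ are
numerically 0 and the log-log fit of pure noise becomes spuriously linear
($R^2 > 0.9$ is easily reached on Gaussian noise at $\beta \approx 13$), so
a candidate is only eligible while mean $k \ge 1$. The package's documented
default when selection is skipped is $\beta = 5$, a typical value for
unsigned networks of this kind.

## Sample outlier screening

Samples are clustered by average linkage on the Euclidean distance of
per-gene standardised expression. A fixed-quantile cut of the merge heights
cannot express "no outliers" — any cut below the root splits the tree — so
the cut is placed a Tukey-style fence of 3 interquartile ranges *above* the
0.99 quantile of merge heights: an unbroken tree is left intact, while a
sample merging far above the bulk (for example a +10 SD intensity shift) is
severed and dropped. The largest cluster is retained; `quantile = 1`
disables screening.

## Module detection

The published dynamic tree cut algorithm is a recursive hybrid; `dccnet`
deliberately approximates it by a transparent three-step rule: a static cut
at 0.99 of the tallest merge, removal of clusters below the minimum size
(default 30 genes; they become "grey", the conventional label for
unassigned genes), and a single reassignment pass in which each grey gene
joins the module with the smallest mean dissimilarity to its members if
that mean is below 0.85. The claim this package makes — and tests, with
adjusted Rand index $\ge 0.9$ against planted modules across seeds — is
recovery of block-correlation structure, not label-equivalence with any
particular tree-cut implementation. Modules are labelled by colour in
descending size order; equal sizes are ordered by their lexicographically
smallest member id so labels are deterministic. Module merging by eigengene
similarity is intentionally not performed.

## Eigengenes and trait association

A module eigengene is the first right singular vector over samples of the
module's gene-standardised expression — the first principal component —
sign-fixed so it correlates non-negatively with the module's mean profile,
which makes its orientation reproducible. Its association with the 0/1
trait is the Pearson (point-biserial) correlation, with the usual
$t = r\sqrt{(n-2)/(1-r^2)}$ p-value. Gene significance (GS) and module
membership (MM) are the absolute correlations of a gene with the trait and
with its module eigengene; signed variants are available behind a flag
because the sign convention differs between studies. The most positively
and most negatively trait-correlated significant modules become the key
modules (ties: larger module, then label order).

## Differential correlation

Within each key module, the per-condition Pearson correlations of every
gene pair are compared via Fisher's transformation:
$$z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
           {\sqrt{1/(n_1-3) + 1/(n_2-3)}},$$
two-sided normal p-value. Correlations here are *signed*, although network
construction is unsigned: a sign switch is only observable on signed
correlations, and it is the switch — positively correlated in one
condition, negatively in the other — that the screen is after. This is the
single most important convention split in the package.

Error control uses the empirical-Bayes local FDR: the marginal density
$\hat f$ of the module's z-statistics is estimated from a 120-bin histogram
smoothed by a log-linear natural-spline Poisson fit (7 basis functions),
the theoretical null is the standard normal $\varphi$, the null proportion
is $\pi_0 = \min\!\big(1, \mathrm{median}\, \hat f(z)/\varphi(z)\big)$ over
the central half of the data, and
$\mathrm{lfdr}(z) = \pi_0\,\varphi(z)/\hat f(z)$, capped at 1, floored at
$10^{-300}$ (an lfdr of exactly 0 is never printed), and made monotone
non-increasing in $|z|$ by isotonic regression. lfdr is estimated per
module, not pooled, mirroring per-module runs of the analysis. With fewer
than 50 statistics, or a degenerate density, the function falls back to
Benjamini–Hochberg q-values and says so; below 200 it warns that the
density estimate is unstable. BH q-values are always reported alongside
lfdr in the scan output for cross-checking. Significant switched pairs are
those with `switched` and `lfdr < 0.05`.

The eigen-molecule view complements the pair-level scan: a module's genes
are clustered on $1 - r$ (signed), cut into a requested number of
submodules, each summarised by its eigengene, with edges drawn between
submodules whose eigengenes correlate above a threshold (default 0.3).

## Downstream

Differential expression is the pooled-variance two-sample t-test (the
literal reading of "Student's t-test"; Welch behind a flag, since
microarray group variances are rarely equal) with Benjamini–Hochberg
adjustment at 0.05. Gene-set enrichment is the upper-tail hypergeometric
test against user-supplied GMT files — deliberately database-free, since
term databases version-drift. Hub genes are ranked by degree in the
switched-pair network, with ties broken by the summed correlation reversal
$\sum |r_1 - r_2|$ over incident edges (rewarding stronger reversals), then
by gene id.

# The synthetic-data generator

`simulate_expression()` is first-class, tested code, not a fixture. Each
module $m$ has a latent factor $f_m \sim N(0,1)$ per sample; a member gene
is $\sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\varepsilon$, giving expected
within-module correlation exactly $\rho$ (the factor-model closed form
$\lambda^2/(\lambda^2 + \sigma^2)$). Trait-linked modules shift their
factor by $\delta$ (in factor-SD units) in case samples; background genes
are independent noise. The defaults — 300 genes, four 50-gene modules at
$\rho = 0.7$, 150 case and 80 control samples, two trait-linked modules
with $\delta = \pm 1$ — emulate a moderately sized case-control microarray
design at desk scale, with one positively and one negatively
trait-correlated module as real module-trait heatmaps typically show. At
$\delta = 1$ the implied eigengene-trait correlation is
$\delta\sqrt{p(1-p)}/\sqrt{1 + \delta^2 p(1-p)} \approx 0.43$ at this class
balance — a clearly detectable but not caricatured effect.

**Planted switch pairs** are built on pair-private factors: pair $(a, b)$
loads on its own factor $h$, with $b$'s loading sign flipped in control
samples, so the pair's expected correlation is $+\rho$ in cases and $-\rho$
in controls. The alternative — flipping $b$'s loading on the shared module
factor — would make $b$ switch sign against *every* module member, so the
planted-pair list would not delimit the truly switched pairs and no
sensible empirical FDR could be scored against it; the pair-private
construction keeps every non-planted pair null by design. The cost is that
switch-pair genes do not co-cluster with their host module's factor genes
(they carry the module label only in the ground truth); recovery of
switches is therefore assessed by scanning the module's gene list, which is
how the pipeline uses module membership anyway.

What the generator does *not* emulate: probe-level effects, batch
structure, heteroscedastic or non-Gaussian noise, correlated background,
and overlapping modules. Passing the planted-recovery tests therefore
demonstrates correctness of the machinery under the factor model, not
performance on real microarray data.

# Numerical and design choices

- **Problem sizes.** Validation runs use 300-gene networks, 230 samples,
  2000-pair null calibrations and 10 replicate seeds — sizes at which every
  matrix operation is exact enough to compare against brute-force oracles
  (TOM to 1e-12 on 10–15 gene matrices) while the whole suite stays quick.
- **GS–MM correlation.** Under the equal-loading factor model the
  population GS and MM are identical for all members of a trait-linked
  module, so the across-member GS–MM correlation reflects only sampling
  variation; it is positive but modest (mean ≈ 0.2 at the default design),
  not the strong trend seen when loadings are heterogeneous.
- **Discrete p-values.** The null mean of an upper-tail hypergeometric
  p-value exceeds 0.5 by the discreteness term $\sum_k P(k)^2 / 2$; tests
  compare Monte-Carlo means against the enumerated exact value rather than
  against 0.5.
- **Degenerate inputs.** Zero-variance genes are an error where silence
  would corrupt results (correlation matrix) and an exclusion-with-warning
  where the operation can proceed (scan, eigengenes). Correlations at
  exactly $\pm 1$ are clamped to $\pm(1 - 10^{-7})$ with a warning before
  `atanh`; $|r| > 1$ is an error.
- **Determinism.** Module labels, pair ordering (lfdr, then $|z|$
  descending, then gene pair) and all tie-breaks are deterministic, and the
  file pipeline writes byte-identical outputs on reruns with the same seed;
  the run manifest records configuration, seed and per-file checksums.

# Limitations

- The tree-cut approximation can split or absorb modules that the hybrid
  dynamic algorithm would handle differently; only planted-recovery
  behaviour is guaranteed.
- The lfdr recipe (bins, spline dimension, $\pi_0$ rule) is this package's
  own; other implementations will give numerically different lfdr values,
  and agreement is expected only at the level of which pairs clear a
  threshold.
- Two conditions only; no time courses, no covariate adjustment, and no
  probe-to-gene annotation — the input is taken as an already summarised
  gene-level matrix.
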