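---
title: "Composition-aware meta-analysis of case/control brain transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-aware meta-analysis of case/control brain transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytometa)
```

## The problem

Bulk expression profiles of a degenerating tissue mix two signals that a
per-gene test cannot distinguish: genuine transcriptional regulation within
cells, and changes in which cells are present. In Parkinsonian substantia
nigra the dopaminergic neurons die, so every gene that is highly expressed
in neurons appears "downregulated" in bulk case/control comparisons, and
every oligodendrocyte- or endothelial-enriched gene appears "upregulated",
regardless of any within-cell biology. `cytometa` implements the full
analysis chain for handling this in a multi-study (meta-analysis) setting:

1. estimate per-sample cell-type proportions from bulk data with
   marker-guided deconvolution (`estimate_proportions()`,
   `deconvolve_studies()`);
2. meta-analyse the proportion shifts across studies with standardized mean
   differences and DerSimonian–Laird random-effects pooling (`prop_meta()`);
3. fit, per gene, two linear mixed models across studies — with and without
   the neuron and oligodendrocyte proportion estimates as covariates — and
   call differentially expressed genes (DEGs) from each (`run_de()`);
4. interpret the results with preranked gene-set enrichment
   (`gsea_preranked()`), expression-weighted cell-type enrichment bootstraps
   (`ewce_test()`), and central-protein nomination on a merged
   protein–protein interaction network (`merge_networks()`,
   `ppi_centrality()`, `central_nodes()`, `fisher_enrichment()`).

Every stage is exercisable on synthetic cohorts with exported ground truth
(`sim_config()`, `simulate_reference()`, `simulate_bulk()`,
`simulate_ppi()`), so the package's claims about error control are tested,
not asserted.

## The models

### Differential expression

For each gene probed by at least two studies, the composition-unaware model
is the random-intercept mixed model

$$y_{ij} = \beta_0 + \beta_1\,\mathrm{Status}_{ij} +
\beta_2\,\mathrm{Gender}_{ij} + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \sigma^2_u),\ \varepsilon_{ij} \sim N(0, \sigma^2_e),$$

where $j$ indexes studies; the composition-aware model adds the estimated
neuron (NEU) and oligodendrocyte (ODC) proportions as fixed effects. Only
those two types enter: the six proportion estimates live on a simplex and
are strongly inter-correlated, so adding all of them would make the design
ill-conditioned (`proportion_correlations()` reports the correlation matrix
so this choice can be checked on any dataset). Models are estimated by REML
and the Status coefficient is tested with Satterthwaite-approximated
degrees of freedom. A DEG is called at Benjamini–Hochberg adjusted
$p < 0.05$ and $|\beta_1| > \log_2 1.2$, both strict; with log2 expression,
the coefficient threshold is the only coherent reading of a 1.2-fold-change
rule.

The default fitting engine exploits the single-grouping-factor structure:
with $\lambda = \sigma^2_u/\sigma^2_e$, the REML criterion profiles to a
one-dimensional function of $\lambda$ whose every term reduces to per-study
sufficient statistics, and the Satterthwaite degrees of freedom come from
blockwise trace algebra (every block matrix involved has the form
$a\,I + b\,\mathbf{1}\mathbf{1}^\top$, a family closed under
multiplication). `engine = "lmer"` delegates to `lmerTest::lmer()` instead;
the test suite checks the two agree to $10^{-6}$ on coefficients, which is
what makes genome-scale replicate studies of the pipeline feasible on one
CPU.

### Deconvolution

`estimate_proportions()` is marker-guided and reference-light: it needs a
ranked marker panel per cell type (`select_markers()` realizes the top 20
present on each study's platform), not a full signature matrix. Marker
expression is un-logged — mixing is linear in cell counts, so all mixing
arithmetic happens on the linear scale — and the algorithm alternates
non-negative least squares for per-sample proportions (projected to the
simplex by sum normalization) with non-negative least squares for per-marker
cell-type profiles, until the largest proportion change falls below `tol`.

Two numerical choices matter and are exposed as arguments:

* `row_scale` (default `TRUE`): markers span orders of magnitude of
  absolute expression, and unweighted least squares is dominated by the few
  brightest genes; each marker row is therefore divided by its mean.
* `profile_ridge` (default 2): per-study cohorts here have 10–25 samples
  while the profile step re-estimates one row per marker, and an
  unpenalized update drifts away from the marker structure that identifies
  the decomposition. The profile update is therefore shrunk toward its
  near-diagonal initialization (own-type entry at the marker's mean
  expression, cross-type entries at 20% of the global marker mean — the
  typical off-type background of a marker with at least four-fold
  separation) with an L2 weight of `profile_ridge` per sample.
  `profile_ridge = 0` gives the plain alternation.

Supplying a fixed `profiles` matrix skips the profile update entirely
(reference-based mode); in that mode, with `row_scale = FALSE`, rescaling
one sample's markers by any constant leaves that sample's estimated
proportions exactly unchanged, since sum normalization absorbs it.

### Proportion meta-analysis

Within each study, each cell type's proportion is regressed on Status plus
whichever of Gender, Age, and Braak stage are available (all-missing or
constant covariates are dropped and recorded), and the case/control
contrast is summarized as Hedges $g$ — the standardized mean difference
with the small-sample correction $J = 1 - 3/(4n - 9)$ — with variance
$(n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$. Study effects are pooled by
DerSimonian–Laird: $\tau^2$ from Cochran's $Q$ by method of moments,
weights $1/(v_i + \tau^2)$, normal test of the pooled effect. The
method-of-moments estimator was chosen over REML for $\tau^2$ because it is
closed-form, deterministic, and the convention for standardized mean
differences; the test suite cross-checks it against `metafor::rma.uni`
(method "DL") to $10^{-10}$. Benjamini–Hochberg correction is applied
across the cell types of one run.

### Enrichment machinery

`gsea_preranked()` ranks genes by $-\log_{10}(p_{\mathrm{adj}})\cdot
\mathrm{sign}(\beta_1)$ (adjusted p floored at $10^{-300}$) and computes
the classic weighted running-sum enrichment score (hit increments
proportional to $|$score$|$, miss decrement $1/(N-m)$). The null re-draws
random same-size gene-label sets; the one-sided $p$ compares against nulls
of the same sign and NES divides by the same-sign null mean magnitude.
With `exhaustive = TRUE` and a small universe the null enumerates all
$\binom{N}{m}$ label sets, which is how the test suite pins the
implementation to a brute-force oracle exactly. Magnitude ties between the
positive and negative excursion (common, because both are rational
multiples of the same miss step) resolve to the earliest position in the
list, compared with a relative tolerance of $10^{-9}$ so floating-point
noise cannot flip the sign.

`ewce_test()` scores a gene list's mean specificity per cell type against
`n_boot` same-size lists sampled uniformly *without replacement* from the
specificity matrix's genes; $p = (1 + \#\{\text{boot} \ge \text{obs}\}) /
(1 + n_\mathrm{boot})$ never returns zero, and the $z$ score ("standard
deviations from the random-list mean") is the effect size. Sampling is
uniform over the gene universe, not expression-matched; this matches the
bootstrap described for the original analysis era and is a documented
divergence from later conditional variants. A list equal to the whole
universe makes every draw identical; the degenerate bootstrap is flagged
rather than returning 0/0.

### Network analysis

`merge_networks()` uppercases symbols, applies an optional human-symbol
allow-list, removes self-loops, collapses duplicate undirected edges with
source tags unioned, and removes degree-1 nodes in a *single* pass — nodes
whose degree drops to 1 because a neighbor left are kept. Iterating the
pruning to a 2-core is a different operation with a different result; the
single pass matches a one-shot "remove nodes with just one edge" cleaning
rule. Betweenness is exact Brandes on the unweighted graph (via igraph),
tested against an all-pairs path-counting oracle. `central_nodes()` uses
nearest-rank percentiles with ties *included*: a node is central when both
degree and betweenness reach their 95th-percentile values, and top-central
when additionally not encoded by a seed DEG. `fisher_enrichment()` is the
one-sided hypergeometric upper tail with the conditional
maximum-likelihood odds ratio; the background universe is the number of
human protein-coding genes (configurable; no canonical value is assumed)
for whole-network tests, and the network size for tests on central
proteins.

## What the synthetic cohorts emulate

The generator mirrors a nine-study microarray meta-analysis: 70 control
and 88 case samples split across studies of 11–26 samples, six brain cell
types, per-study gene-wise batch offsets (SD 0.3 log2), measurement noise
(SD 0.5 log2), a male shift on Y-proxy genes, and 30 genuinely
condition-responsive genes at one log2 unit. Composition is the core of
the design:

* Per-sample proportions are Dirichlet draws, so composition varies within
  groups, not only between them.
* A latent per-sample **degeneration severity** (Beta-distributed; mild in
  controls, broad in cases) interpolates each sample's Dirichlet
  concentration between the control and case alpha vectors. All
  disease-driven shifts — neurons down, oligodendrocytes and endothelial
  cells up — therefore co-vary on one axis, the way degeneration actually
  moves a tissue's composition, and the neuron/oligodendrocyte estimates
  carry information about the shifts in the types the aware model omits.
  The centred scaling keeps each group's mean concentration exactly at its
  stated alphas, so the planted neuron standardized mean difference stays
  near $-1$.
* Non-marker genes vary across cell types with SD 1 log2 unit, which makes
  composition change a genome-wide confounder (a few percent of non-marker
  genes cross a 1.2-fold call from composition alone) while keeping that
  confounding along the corrected axis.

Defaults the literature does not pin down were set once and documented:
within-study variance components (batch 0.3, noise 0.5 log2 — ordinary
microarray scales), the male fraction 0.6 (the cohort the layout mirrors
is ~61% male), a 2-log2-unit male shift on Y-proxy genes, and the severity
Beta shapes (1.5, 8) / (4, 3).

What the generator does **not** model: probe-level artifacts of specific
array platforms, RNA degradation, and cell-size or RNA-content differences
between cell types (deconvolution returns cell fractions only up to that
systematic bias — a known limitation of marker-based deconvolution
generally). Passing tests therefore demonstrate correct behavior under
log-additive noise with honest marker panels, not robustness to marker
misspecification.

## What the tests and the acceptance script compute

The suite pins every analytic component to an independent oracle
(exhaustive GSEA permutations, all-pairs betweenness counting, hand-stepped
DerSimonian–Laird, hypergeometric subset enumeration, `lmerTest` and
`metafor` and `fgsea` as cross-checks) and verifies the pipeline-level
claims by replicate simulation: deconvolution recovers mixed proportions
to MAE $\le 0.05$ at noise SD 0.1; pooling keeps type-I error at the
nominal 5% and detects the planted neuronal decrease with the right sign;
and across twenty cohort replicates the unaware model calls several times
more DEGs than the aware model, whose empirical false discovery rate stays
at or below 10% with full recall of the planted genes.
`scripts/acceptance.R` recomputes these quantities from scratch at a
user-supplied seed; problem sizes there (20 cohort replicates at 2,000
genes, 200 null and 100 alternative meta-analysis replicates, 500
bootstrap calibration lists) are the package's chosen design points for a
single-CPU desk run.

## Known limitations

* The aware model corrects only the neuron/oligodendrocyte axis;
  composition variation orthogonal to it (rare under the severity model,
  common if cell types shift independently) leaks into the Status
  coefficient. This mirrors the method being modeled rather than a
  removable defect.
* Deconvolution assumes markers are not themselves condition-regulated
  within cells; a planted effect on a marker gene would bias its type's
  estimate.
* Preranked GSEA reports no leading-edge subsets and uses the plain
  permutation p, not a multilevel refinement; with $10^5$ permutations the
  smallest attainable p per set is $\approx 10^{-5}$.
* Gender imputation is a 2-means split on Y-proxy genes; cohorts with very
  few samples of one sex can flip the cluster labeling, which is why the
  low-confidence flag exists.
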