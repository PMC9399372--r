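---
title: "Discovering radiosensitivity gene signatures with radiosig"
author: "radiosig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering radiosensitivity gene signatures with radiosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiosig)
```

# The problem

Cellular radiosensitivity is commonly summarized by SF2, the surviving
fraction of a cell line after a single 2 Gy dose; lower SF2 means a more
radiosensitive line. Genes whose expression tracks SF2 across a panel of
cell lines, and which respond to irradiation over time, are candidate
radiosensitivity signatures. `radiosig` implements a multi-stage discovery
funnel for such signatures:

1. **Time-response filter.** One-way ANOVA of expression across
   post-irradiation timepoints (0, 2, 4, 8, 12, 24 h by default), with cell
   lines as replicates. Genes with unadjusted p < 0.05 are kept;
   multiplicity is deferred to the cluster-significance step, where the
   discovery claims are actually made.
2. **Temporal profile clustering.** Genes are matched against a library of
   short time-series model profiles — integer unit changes per interval,
   bounded by `c`, summarized as cumulative curves — and assigned to the
   profile with the highest Pearson correlation. Cluster significance is
   assessed by permuting each gene's timepoint labels and re-assigning,
   with Benjamini–Hochberg correction across profiles (q < 0.01).
3. **Cluster eigengene screen.** Each significant cluster is summarized by
   the first principal component of its (standardized) member-by-line
   baseline submatrix, and retained when the Spearman correlation between
   that eigengene and SF2 exceeds 0.1 in absolute value.
4. **Single-gene models.** Each surviving gene is scored by (a) permutation
   importance in one regression random forest predicting SF2 from all
   candidates jointly, and (b) the single-gene linear-quadratic (SGLQ)
   model, the radiobiology dose–survival law transplanted to expression:
   \(SF = e^{\alpha E - \beta E^2}\), fit as no-intercept least squares of
   \(\ln SF2\) on \((E, E^2)\). Genes failing **both** are excluded.
5. **Multi-omics hub screen.** Four network layers — insulated heat
   diffusion on mutation frequencies, the same on copy-number alteration
   magnitudes, topological-overlap co-expression modules, and a
   confidence-filtered protein-interaction edge list — are united on the
   candidate genes, and hubs are called where degree, betweenness and
   closeness all exceed their medians strictly.

Final candidates are the hub genes; over-representation against gene sets
uses the one-sided hypergeometric test with BH correction.

# Models and numerical conventions

## One-way ANOVA

Row-wise F statistics are computed vectorized from the between/within
group sums of squares and referred to the F distribution; the
implementation is cross-checked against `stats::oneway.test` in the test
suite. A constant gene has an undefined statistic and is reported with
p = 1 (filtered out); a gene with zero within-group variance but distinct
group means gets p = 0.

## Profile library and assignment

With T timepoints and maximum unit change `c` there are \((2c+1)^{T-1}\)
candidate profiles; the flat profile is dropped and `m` representatives
are selected greedily to maximize the minimum pairwise distance
(1 − Pearson correlation between cumulative curves). Selection starts from
the first candidate in enumeration order, ties break to the lowest index,
and the chosen set is kept in selection order, so the first k
representatives do not depend on `m`. Defaults follow the usual practice
for this family of methods: c = 2, m = 50, 1,000 permutations.

Gene series are per-timepoint means across cell lines expressed as change
from the first timepoint: profiles are time-shapes, so the level is
removed, and because inputs are z-scores (which can be negative) the
transform is a difference, not a log-ratio. Assignment is therefore
invariant to adding a constant to a gene's series. Zero-variance series
cannot be correlated and are reported unassigned.

Permutation p-values use the +1 smoothing, \(p = (b + 1)/(B + 1)\), so
they are bounded below by \(1/(B+1)\). One practical interplay deserves
note: with m = 50 profiles, B = 1,000 permutations and q < 0.01, a cluster
at the permutation floor is only significant when roughly five or more
clusters are discovered together (the BH factor m/rank must not push
\(50/(1001 \cdot \text{rank})\) over 0.01). Real irradiation time courses
produce on the order of ten significant clusters, and the synthetic
generator plants ten archetypes for the same reason.

## Cluster eigengenes

PC1 of the row-standardized member submatrix, computed by
`stats::prcomp`. The sign of a principal component is arbitrary, so scores
are oriented to correlate non-negatively with the members' mean
standardized profile; this removes backend-dependent sign flips. Constant
members are zeroed (they carry no information), and a constant eigengene
screens as correlation 0 rather than an error so batch screens never
abort. The 0.1 cutoff is applied to |cor| by default so protective
(negatively correlated) clusters are not silently discarded; a signed mode
is available in the configuration.

## SGLQ model

The fit is exactly linear in \((\alpha, \beta)\) on the log scale and has
no intercept, so the prediction at E = 0 is exactly SF = 1 and noise-free
data are recovered to machine precision. Coefficients are not constrained
non-negative because expression is z-scored. The default pass rule is the
overall no-intercept regression F-test at 0.05. Note a structural
consequence: because \(E^2\) partially absorbs a constant, this test
rejects whenever the panel's mean log-SF2 is far from 0 (i.e. mean SF2
far from 1), so with realistic SF2 levels most genes "pass" SGLQ and the
fail-both filter is driven mainly by the random-forest importance. The
pass threshold is exposed in the configuration.

## Random forest

One regression forest (500 trees, mtry = p/3) predicts SF2 from all
candidate genes jointly; importance is the unscaled permutation increase
in out-of-bag MSE, and a gene passes when it is strictly positive. The
seed is mandatory; a fixed seed gives identical importance vectors.

## Heat diffusion

Insulated diffusion with restart probability \(\beta\):
\(F = \beta (I - (1-\beta) W)^{-1}\) with W the column-degree-normalized
walk matrix, computed per connected component by dense inversion;
exchanged heat is \(E_{ij} = F_{ij} h_j\). Hot edges are the layer's edges
with strictly positive bidirectional exchange
\(\min(E_{ij}, E_{ji}) \ge \delta\); requiring strict positivity makes
\(\beta = 1\) (pure restart) yield no multi-node subnetwork at any
threshold, while \(\delta = 0\) recovers the layer's connected components.
The reference method selects \(\delta\) by permutation; here the default
is the 0.95 quantile of the positive edge min-exchange values ("keep the
hottest 5% of interactions"), and any fixed \(\delta\) or quantile can be
configured. Column sums of F are exactly 1 on components without isolated
nodes, so each source's heat is conserved — a property the tests check
against the closed form.

## Co-expression modules

Soft adjacency \(a = |\text{cor}|^{6}\), topological overlap
\(TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 -
a_{ij})\) with unit diagonal, average-linkage clustering of 1 − TOM cut at
height 0.99, modules below 30 genes dropped to the unassigned label, and
modules merged while their eigengenes correlate above 0.75. The emitted
layer connects within-module pairs whose TOM reaches the 0.9 quantile of
within-module TOM. Fewer than 20 samples triggers a warning (correlation
estimates are noisy); constant genes are dropped with a warning.

## Hub rule

Degree, shortest-path betweenness, and harmonic closeness (classic
closeness behind a flag); harmonic closeness is the default because union
graphs are routinely disconnected and 1/∞ = 0 needs no convention. A node
is a hub only if **all three** centralities are strictly greater than
their medians — ties at the median are not hubs, so a centrality-regular
graph (e.g. a complete graph) has none. By default centralities are
computed on the union graph induced on the surviving candidates; a flag
computes them on the full gene universe instead and intersects afterwards.

# The synthetic study

`simulationConfig()` defines the package's reference conditions: 2,000
genes, 24 cell lines, six timepoints after 2 Gy. Three gene classes are
planted:

* **Signature genes** (20): follow one shared temporal archetype, load
  (0.8) on a latent per-line radioresponse factor at baseline, generate
  SF2 through the SGLQ law (mean prediction over signature genes,
  log-scale noise 0.1, clipped to (0,1]), carry 10-fold elevated
  mutation/CNA heats, and are rewired into a dense (0.6) subgraph of the
  interaction network.
* **Time-responsive decoys** (300): follow the other nine planted
  archetypes but are marginally independent of SF2. They exist because the
  downstream stages need a realistic candidate pool: with only signature
  genes surviving to the hub stage, the strict median rule could never
  flag more than half of them, and the fail-both filter would have nothing
  to act on.
* **Null genes**: time-independent iid noise. Deliberately no per-line
  baseline effects — shared line effects inflate the within-group variance
  of the across-time ANOVA and would make its null distribution
  conservative, whereas the filter is specified (and tested) to hold its
  nominal type-I error on null genes.

Background co-expression blocks (4 × 60 genes, loading 0.8) give the
co-expression layer non-trivial structure, and the interaction network is
Erdős–Rényi with mean degree 4 plus the signature subgraph; a disconnected
planted subgraph is a generation error.

The generative SGLQ coefficients default to \(\alpha = 0.05,
\beta = 0.2\). Because expression is z-scored per gene across all samples
and the signature archetype is time-decreasing, signature baselines sit
around +1.5 z-units; these coefficients keep \(\alpha E - \beta E^2\)
negative and monotone over the realized baseline range, producing SF2
between roughly 0.5 and 0.95 — the range reported for real NSCLC panels —
without saturating the (0,1] clip.

Every generator operation derives its own child seed from the master
seed, so a fixed seed yields bit-identical bundles (checked on the
manifest checksums). With zero noise, signature series reproduce their
archetype exactly and SF2 satisfies the SGLQ law exactly.

What the generator does **not** emulate: probe-level microarray effects,
batch/platform effects, count noise, survival endpoints, or realistic
pathway topology. Passing the recovery tests therefore demonstrates that
the pipeline's stages compose correctly and are calibrated under the
stated noise model — not that the thresholds are optimal for any
particular real dataset.

# Design choices on open points

* **Absolute vs signed cluster–SF2 cutoff**: absolute by default (keeps
  protective clusters), signed available.
* **Hub scope**: candidate-induced union graph by default, full-graph mode
  behind a flag.
* **"Did not perform well"** in the single-gene stage is made precise as:
  RF permutation importance ≤ 0 and SGLQ F-test p ≥ 0.05; both thresholds
  are configuration entries.
* **Noise model**: Gaussian on the normalized expression scale and on
  log-SF2; both SDs are configuration entries.

# Degenerate inputs and numerical floors

Constant genes: p = 1 in the ANOVA, unassigned in profile matching,
dropped with warning in co-expression, rank-deficient (pass = FALSE) in
SGLQ, correlation 0 in screens. RSS below 1e-12 in the dose-linearity AIC
is clamped with a warning so the log stays finite while larger nested
models still pay their 2-per-parameter penalty. Permutation p-values never
report below 1/(B+1). Fewer than 100 permutations and fewer than 20
co-expression samples warn.

# Problem sizes used by the tests

The unit suite runs a reduced study (500 genes, 12 signature, 105 decoys,
8 archetypes, 16 lines) chosen so planted cluster sizes are several times
the permuted expectation; calibration checks use 10,000 null genes (ANOVA
type-I), 100 null studies at the full 2,000-gene scale (cluster false
discovery), 200 replicates for SGLQ bias, and 100 random small graphs for
the diffusion and centrality oracles. The end-to-end recovery check runs
the full reference conditions (2,000 genes, 20 planted, fixed seed).

# Known limitations

* The AIC dose-linearity check inherits AIC's classical ~16% per-extra-
  parameter overfitting probability; across degrees 1–3 the true linear
  model is selected in roughly 78–80% of noisy replicates, independent of
  sample size or noise level. Where near-certain selection of the linear
  model matters, BIC-style penalties would be needed; the implementation
  keeps the standard AIC form \(n\ln(RSS/n) + 2k\).
* The SGLQ pass rule (overall F-test, no intercept) conflates "related to
  SF2" with "SF2 differs from 1"; see above.
* The HotNet2-style δ selection by permuted-heat networks is simplified to
  a configured threshold/quantile.
* WGCNA-style module detection uses a fixed-height cut, not the full
  dynamic tree-cut heuristic.
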