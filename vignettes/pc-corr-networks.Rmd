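---
title: "PC-corr: inferring discriminative correlation networks from PCA loadings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PC-corr: inferring discriminative correlation networks from PCA loadings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccorrnet)
```

## The model

Given a samples-by-features matrix whose samples separate into groups
along some principal component, PC-corr asks which *interacting*
features carry that separation. The construction has three steps.

**1. A discriminative component.** PCA — centered or non-centered — is
fitted by singular value decomposition; loadings are the right singular
vectors, so each component's loadings have unit Euclidean norm. A
component is called discriminative when its sample scores differ
between the groups by a two-sided Mann-Whitney test (Kruskal-Wallis
when there are more than two groups). `select_discriminative_pc()`
scans both centerings over components 1..`max_pc` (default 3) and keeps
the candidate with the smallest p-value, preferring centered PCA and
lower component index on ties. Non-centered PCA is worth scanning
because when group structure lives in overall signal magnitude rather
than in deviations around the grand mean, the raw-matrix SVD can expose
a separation the centered one hides.

**2. Loading processing.** Raw loadings are not comparable with
correlation coefficients: their individual magnitudes shrink as
$1/\sqrt{p}$ with the feature count, and their distribution's skewness
varies wildly between datasets. Each loading is therefore passed
through a sign-preserving, lognormal-inspired map

$$v^{*}_i = \operatorname{sign}(V_i)\,
  \log_{10}\!\Big(1 + \frac{|V_i|}{\overline{|V|}}\Big),$$

whose scaling factor — the mean absolute loading $\overline{|V|}$ — is
tuned automatically by the data, and then scaled onto $[-1,1]$ by
dividing by $\max_j |v^{*}_j|$. The map is strictly increasing in
$|V_i|$, so ranks and signs are preserved; the log damps the heavy
right tail that a few dominant features otherwise contribute.

**3. The minimum-operator fusion.** For features $i, j$ with Pearson
correlation $c_{ij}$,

$$\mathrm{PCcorr}_{ij} = \operatorname{sign}(c_{ij})\,
  \min(|c_{ij}|, |v^{new}_i|, |v^{new}_j|).$$

The minimum behaves as an AND gate: both endpoints must discriminate
*and* co-vary for the edge to survive a cut-off. Thresholding keeps
edges with $|w| \ge$ cut-off, removes singleton nodes, and attributes
each node to the group whose samples have the higher median of that
feature (red-to-white colour gradient for the first group, black-to-
white for the second, linear in $|v^{new}|$).

## Assumptions and when the method cannot be used

The construction presumes (i) a roughly linear group separation that
PCA can capture, (ii) Pearson correlation as the association measure
(monotone-linear co-variation), and (iii) an actual discrimination:
when no component separates the groups significantly, there is nothing
for the loadings to explain, and `pc_corr(pc = "auto")` refuses to run
rather than normalize noise.

On significance: the scan evaluates up to `2 × max_pc` candidate
(centering, component) pairs. Declaring the winner significant at its
raw p-value would inflate the family-wise error of the whole scan to
roughly 20–25% on pure noise at the default settings, so the scan
Bonferroni-corrects the minimum p over the candidates actually
evaluated before comparing with `alpha`. With a genuine planted
separation the cost is negligible (p-values are orders of magnitude
below any threshold); on the pure-noise preset the false-alarm rate of
the corrected scan measures at 3–5%. A user who has fixed the component
in advance (e.g. read it off the PCA plot) can bypass the gate entirely
by passing `pc = <index>`, which applies a single uncorrected test —
that is also what the package's regime simulations do when the question
is whether a network *exists*, not whether the scan finds it.

## Cut-off choice and frustration

The cut-off is the one genuinely user-facing knob. The useful range
starts at 0.5 — below that, the Pearson factor admits weakly correlated
pairs — and every quoted cut-off in practice carries two decimals,
which fixes the raise-policy step at 0.01. In a clean network, positive
edges join nodes whose loadings share a sign and negative edges join
opposite-sign nodes; an edge violating this pattern is *frustrated*.
`resolve_frustration()` implements three policies: `report` (annotate
only), `drop` (delete frustrated edges, allowed only while they are
under 5% of all edges), and `raise` (increase the cut-off in 0.01 steps
until frustration vanishes or the network empties). Frustration of an
empty network is 0 by convention.

Two boundary conventions are deliberate: the threshold is non-strict
($\ge$) so results are deterministic at exact ties, and constant
features get correlation 0 (with a warning) rather than an error,
because real omic tables contain constant columns and a constant
feature simply cannot carry an edge — the min-operator then annihilates
its row regardless.

## The baselines

The **P-value network** screens features univariately (two-sided
Mann-Whitney per feature, Benjamini-Hochberg adjustment, keep adjusted
p ≤ 0.05) and draws Pearson edges at the same cut-off among survivors;
nodes carry the difference of group medians. With fewer than two
significant features the network *does not exist* — this is returned as
a result object, not an error, because it is a real outcome: in the
weak-distributed-shift regime the screen finds nothing while the
PC-corr network is well formed. For large baseline networks,
`match_node_count_cutoff()` finds the cut-off that matches the PC-corr
network's node count, so Venn comparisons are size-fair.

The **P-value MI network** replaces Pearson edges with a mutual-
information inference: Gaussian MI $-\tfrac12\ln(1-r^2)$ from the same
correlations, then the CLR transform (per-row z-scores of the MI
profile, $\sqrt{z_i^2+z_j^2}$ per pair). CLR scores have no natural
[0, 1] scale, so they are min-max rescaled before the shared cut-off is
applied; this is a package convention — the weight scale on which such
networks are usually cut is not standardized — and it is recorded in
the network metadata. MI at $|r|=1$ is capped at the value for
$r = 0.999999$ with a warning. Other MI inference variants (ARACNE,
MRNET) are out of scope; CLR is the one that matters for the
comparisons here.

## Leave-one-out robustness

`run_loocv()` removes each sample in turn, refits the PCA at the fixed
(component, centering), and rebuilds the PC-corr matrix on the reduced
sample set. Three conventions make the combination well defined:

- **Sign alignment.** An eigenvector's sign is arbitrary, and averaging
  flipped loading vectors is meaningless; each iteration's loadings are
  flipped to non-negative inner product with the full-data vector, and
  flips are logged.
- **min_abs sign.** The minimum-absolute-value combination (the
  intersection network) takes its magnitude as the exact per-edge
  minimum across iterations and its sign from the full-data matrix;
  edges whose sign varies across iterations are flagged sign-unstable
  so they can be excluded from robustness claims.
- **Speed filter.** Features whose maximum $|v^{new}|$ across all
  iterations is below the cut-off are excluded before any correlation
  is computed. By the min-operator bound
  $|w_{ij}| \le \min(|v_i|,|v_j|)$ this cannot change any thresholded
  network — a property the test suite verifies by building the networks
  both ways.

The headline robustness score is the fraction of the original network's
edges retained in the min_abs network at the original cut-off.

## The synthetic generator

`generate_planted()` draws equicorrelated Gaussian blocks (one-factor
construction, pairwise correlation $\rho$), shifts the second group's
means by $\delta$ standard deviations, and appends i.i.d. noise
features. Equicorrelated blocks are the simplest structure that
exhibits "discriminative correlation"; Cholesky machinery is
unnecessary because the one-factor form is exact for equicorrelation.
One arithmetical fact drives the preset design: a mean shift by itself
induces pooled correlation
$(\delta_1\delta_2/4)\big/\sqrt{(1+\delta_1^2/4)(1+\delta_2^2/4)}$
between any two shifted features, even when they are independent within
groups. "Discriminative-but-uncorrelated" features can therefore only
exist with moderate shifts, which is why the `and_gate` preset plants
its singletons at $\delta = 0.8$ (induced correlation ≈ 0.31, safely
under a 0.5 cut-off at $n = 40$) next to a strong block at
$\delta = 3$. The `metagenomics_like` preset spreads a weak shift
($\delta = 0.6$, undetectable univariately at $n = 8$ vs 8 after BH)
over six tight sub-blocks ($\rho = 0.75$), which keeps within-module
correlations high while the discrimination is only multivariate — the
regime in which the univariate baseline has nothing to show.

What the generator does **not** emulate: platform-specific noise
(count overdispersion, intensity heteroscedasticity, compositional
constraints of relative abundances, linkage structure of genotypes),
batch effects, or heavy-tailed outliers. Passing tests on these
Gaussian fixtures demonstrates the algorithmic contracts — the AND-gate
selectivity, the screen/fusion interplay, the LOOCV algebra — not
performance on any particular platform's data.

## Numerical choices and degenerate inputs

- PCA sign convention: each loading column is flipped so its
  largest-magnitude entry is positive (deterministic node colours).
- Mann-Whitney uses the exact distribution whenever R's implementation
  allows (both groups < 50, no ties), the normal approximation with tie
  correction otherwise; the suite checks exactness against a
  full-enumeration oracle for every split with total n ≤ 10.
- Mode imputation of genotype codes breaks frequency ties toward the
  smallest code (determinism; 0 = homozygous wild-type).
- Pearson correlations feed on the same preprocessed matrix as the PCA,
  so both factors of the fusion see identical data.
- All-zero loading vectors, matrices with fewer than 3 samples or 2
  features, empty groups after a LOOCV removal, and cut-offs outside
  (0, 1] are rejected with specific errors; empty networks are returned
  with warnings, never errors.

## Problem sizes in the test and acceptance runs

Simulation-backed checks use 20 seeds (AND-gate selectivity and LOOCV
retention at n = 20 vs 20), 50 seeds (metagenomics-like regime at
n = 8 vs 8), 30 seeds (MI containment at n = 15 vs 15), 100 seeds (null
control), and 200 seeds (screen-level false-discovery control at
n = 10 vs 10) — sizes at which the binomial noise on each reported rate
is a few percent, appropriate to the bounds being asserted.

## Known limitations

Linear separations only (no robust or nonlinear embedding); two-group
statistics throughout the baselines (the PC scan itself degrades
gracefully to Kruskal-Wallis); no automatic cut-off optimization — the
frustration policies are diagnostics, not an optimizer; and the Gaussian
MI estimator ties the MI network to the Pearson correlation, which is a
modelling convenience, not an estimator of general dependence.
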