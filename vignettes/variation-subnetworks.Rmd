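---
title: "Variation subnetworks of functional connectivity: model, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation subnetworks of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsubnets)
```

## The model

Each subject contributes one symmetric K×K matrix of Pearson correlations
between parcel time courses. Taking absolute values (connection *strength*,
regardless of sign) and vectorizing the strict lower triangle gives an
N×E cohort matrix `X`, E = K(K−1)/2. The working assumption is a linear
mixture over the *subject* dimension: after removing each edge's cohort
mean, a few latent edge-space components, shared by everyone but loaded
subject-specifically, generate the inter-individual variation:

\[ X' = A\,S \]

where `X'` is the PCA-reduced (C×E) cohort, `A` the C×C mixing matrix and
the rows of `S` the independent components. A disorder that reorganizes
connectivity is expected to show up as a group shift in the loadings of one
or a few components — the *variation subnetworks* — rather than as
scattered edge effects.

Assumptions worth stating explicitly:

* **Linearity and additivity** of component effects on edge weights.
* **Super-Gaussian sources.** Infomax with the logistic nonlinearity
  separates heavy-tailed/sparse sources; near-Gaussian directions (most of
  the post-PCA residual) are not identifiable, which is precisely why the
  reproducibility ranking exists: unidentifiable components do not
  replicate across restarts and fall to the bottom.
* **Group comparability.** Pooled-variance t-tests assume roughly equal
  group variances; the matched design (equal group sizes) makes the pooled
  test the default, with Welch available (`welch = TRUE`).

## Stage-by-stage conventions

### PCA (`pca_reduce`)

Columns (edges) are centered; the SVD keeps the smallest C with cumulative
explained variance ≥ `variance_target` (default 0.90, capped at N−1).
Two conventions make the result a pure function of the *set* of subjects,
so that reordering input subjects cannot change anything downstream even in
the last bit: the SVD is computed with rows sorted by `subject_id`, and
each reduced row's sign is fixed (largest-magnitude entry positive).
Without them, LAPACK returns permutation-dependent floating-point noise and
sign flips, and the advertised run-to-run stability of the ranked
components would hold only approximately.

### Infomax ICA (`infomax_ica`)

Natural-gradient Infomax, logistic nonlinearity, PCA-whitening inside;
update `ΔW = lr (I + (1−2g(Y))Yᵀ/E) W`, initial `lr = 0.1`, halved on
divergence and annealed by 0.9 when the update direction turns sharply;
stop at update norm < `tol` (1e−7) or `max_iter` (1000). The removed row
means are folded back into `S` as per-row constants so `A %*% S == X'`
*exactly*; this changes no correlation or variance. Output conventions —
under which all downstream thresholds are interpreted — are: rows of `S`
unit-variance (so ICA values are on a z-like scale and the discriminant
cut |ICA| > 3.5 means "3.5 SDs out in the tail"), largest-magnitude entry
positive.

On cohort-scale data the tolerance is usually *not* reached within
`max_iter`: after the identifiable sources converge (a few hundred
iterations), the gradient keeps crawling in the near-Gaussian residual
subspace where the objective is almost flat. This is flagged per run
(`converged`), summarized in one warning per ensemble, and is harmless by
construction: the affected components are exactly the non-reproducible
ones that RAICAR ranks last. Clean low-dimensional problems (e.g. two
Laplace sources) do converge below tolerance.

### Reproducibility ranking (`raicar_align`)

Classic RAICAR aligns components across R ICA restarts and *averages* the
matched rows, so the final edge values differ between executions. The
modification here selects one *reference run* — the run whose components
have the highest total best-match absolute correlation with all other runs,
i.e. the most central restart — and scores each of its components by both
how often it reappears and how faithfully:

\[ \text{score} = \frac{\#\{\text{runs with best } |r| \ge 0.8\}}{R-1}
   \times \overline{|r|}_{\text{matched}} . \]

Rows are ranked by descending score (ties: higher mean |r|, then component
index; scores are rounded to 12 digits for ordering so last-bit correlation
noise cannot flip ties), and the representative rows are the reference
run's own, never averaged. `match_threshold = 0.8` is deliberately strict:
a component must essentially reappear, not merely resemble. The first
`n_components = 8` ranked components are kept; connectedness of the
resulting subnetworks is a useful diagnostic but takes no part in
selection, keeping the procedure blind.

### Edge pruning (`prune_components`)

The contribution of edge e in component i is the exact increase in squared
reconstruction error of `X'` when the single entry `S[i,e]` is zeroed:
`‖A[,i]‖² S[i,e]²`. The default rule (`relative_max`) keeps edges whose
contribution reaches τ = 0.2 of the **global** maximum over all components
and edges. Global — not per-component — normalization is what allows
retained counts to differ between components: a weak component keeps few or
no edges, a dominant one keeps many. This replaces per-component z-score
thresholding, which necessarily retains similar counts everywhere. A
`cumulative` mode (smallest edge set covering 1−τ of a component's own
contribution mass) is provided because the exact published rule behind the
0.2 threshold is not fully specified; both are documented reconstructions,
and the accounting identity (added squared error = sum of dropped
contributions, exact) holds for either. Components that lose every edge
are dropped from the pipeline with a warning.

### Group statistics (`subnetwork_stats`, `discriminant_links`)

Method A uses only edge *locations*: subjects' restricted vectors are
projected on `Diff = |V_HC − V_SZ|`. Note the acknowledged circularity —
the group means come from the same subjects later projected — reproduced
as designed and relevant when interpreting method-A p-values. Method B
projects the full edge vector on the pruned ICA values and involves no
group averaging. Significance is fixed at α = 0.005 for both (the stated
multiple-comparison-adjusted level; no further division by test count).
Discriminant links: edges with |ICA| > 3.5 (unit-variance convention),
then per-edge pooled t-tests on the raw FC values at p < 0.01.

### RSN overlap (`permutation_overlap_test`)

Nodal strength = sum of incident |ICA| values; overlap with an RSN = the
percentage of total strength on that RSN's nodes, the denominator excluding
unlabeled ("None", subcortical) nodes so the seven percentages sum to 100.
The null relocates the retained weights to uniformly random edge positions
among all E (default), because shuffling weights *within* the retained mask
preserves nodal membership and cannot test anatomical specificity; the
within-mask variant is available for comparison. p = (#null ≥ observed)/n,
without the +1 correction, matching the count-divided-by-permutations
definition; `correct = TRUE` adds it. α = 0.005, n = 1000 by default.

### Graph metrics (`graph_metrics`)

Edge lengths for shortest paths are reciprocal weights 1/w: strong
correlations are short. The literal alternative — reading raw weights as
lengths — would reward *weak* edges and is kept only as
`length_mode = "raw"` for comparison. Characteristic path length averages
finite shortest-path lengths over ordered pairs (disconnected pairs are
excluded and counted in `n_disconnected_pairs`); global efficiency averages
1/L with disconnected pairs contributing 0; strength is `sum(W)/K`,
counting each edge from both endpoints as in its printed definition (halve
with `per_edge_once`); clustering is the Onnela cube-root form with
k<2 nodes contributing 0; local efficiency is the efficiency of each
node's neighbor subgraph with the node removed. Subnetwork graphs carry
the subject's *original* absolute FC at the retained edges. Group tests at
α = 0.05; subjects whose graph leaves a metric undefined are excluded from
that metric's test.

### Classifier (`fit_score_model`, `cross_validate`)

Per SZ-specific subnetwork (significant under method B), the training
groups' method-B projection moments (μ, σ) are the entire model. The
combination of the "two z-scores" into one score is not uniquely
determined by its verbal description; `s = |z_HC| − |z_SZ|` is used
because it is negative exactly when the subject is closer, in z units, to
the HC distribution, which matches the stated decision rule (HC iff total
< 0; the boundary 0 is labeled SZ because HC requires *strictly* less).
PPV/NPV are prevalence-adjusted post-test probabilities; the prevalence is
a required explicit input (0.5 for a matched case-control design) because
no single implied value reproduces both the printed predictive values and
the printed sensitivity/specificity. AUC is the Mann–Whitney probability
(ties ½), identical to the trapezoid area under the threshold-sweep ROC.
Cross-validation is stratified by group (unstratified by flag), fits on
training folds only — test subjects never touch the moments — while the
subnetworks themselves remain fixed from the full cohort, a residual
leakage inherent to the design and acknowledged as such.

## The synthetic world

`synthetic_config()` defaults describe the world used by every test:
K = 30 nodes, 20 + 20 subjects, 4 components, one effect component whose
loadings shift by 1.5 loading-SDs in the SZ group, noise SD 0.05,
sparsity 0.15, and a seed that fixes everything.

Choices that need justification:

* **Loadings are Laplace** (unit SD): super-Gaussian, satisfying Infomax's
  identifiability assumption — the decomposition is being tested, not the
  model mismatch.
* **Source values are one-signed** (half-normal magnitudes, SD 0.08) on
  `round(sparsity·E)` edges concentrated in a contiguous node block. A
  component models a coherent modulation of its member edges, as empirical
  hypo-/hyper-connectivity effects are one-directional. This matters
  statistically: with sign-symmetric sources the method-A group separation
  is `Σ |δ_e| δ_e ≈ 0` by symmetry, i.e. the location-only projection
  would be structurally blind in a world that real data do not inhabit.
* **Baseline 0.45** plus signal plus noise, clipped to [0, 1]: typical
  cortical |r| levels; at the stated amplitudes clipping is rare, so the
  distortion relative to the pure linear model is minimal.
* The planted node→RSN map assigns seven contiguous blocks plus ~12%
  "None" (subcortex stand-in), and component blocks overlap known RSNs, so
  overlap tests have a planted winner.

What the generator does **not** emulate — and therefore what a green test
does not establish: empirical FC covariance structure (spatial
autocorrelation, hub structure, distance effects), site/motion artifacts,
heavy-tailed subject outliers, and any nonlinearity in how components
combine. Passing tests establish that the pipeline recovers what its own
generative model plants, at realistic sizes and noise, with calibrated
false-positive behavior — not that a particular clinical dataset will
yield the same subnetworks.

## Numerical choices and degenerate inputs

* Edge order is frozen: lower triangle, row-major (i ascending, j < i
  ascending); all files and vectors use it.
* Matrix symmetry is enforced within 1e−8 then symmetrized exactly;
  entries outside [−1, 1] are errors, not clipped.
* Constant rows in the normality screen are flagged untestable, never
  fatal; the Shapiro–Wilk n ≤ 5000 cap is handled by a deterministic
  evenly spaced edge subsample (flagged).
* Empty subnetworks: direct projection calls error; the pipeline drops
  them with a warning. Empty graphs report strength/efficiency/clustering
  0 and undefined path length (flagged).
* All randomness (ICA restarts, permutations, CV splits) flows from one
  master seed through `derive_seeds()`; sub-seeds stay below 2³¹.
* Tests use R = 10 ICA runs and reduced permutation counts for speed; the
  reference configuration (R = 100, n_perm = 1000) is the default of
  `pipeline_config()`.

## Known limitations

* The Infomax implementation is the logistic (super-Gaussian) variant;
  extended Infomax for sub-Gaussian sources is out of scope (config stub
  only).
* The reproducibility score operationalizes "correlation values as well as
  the number of similar components" as their product; alternative
  weightings would reorder near-ties but leave the clearly reproducible
  components on top.
* Method-A circularity means its p-values are optimistic; method B is the
  selection rule for the classifier partly for this reason.
* With N ≈ 50 subjects, C ≈ 30 reduced dimensions and E ≈ 8000 edges,
  component estimates are noisy; the ranking mitigates but does not remove
  small-sample instability.
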