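---
title: "Dynamic high-order connectivity, spanning-tree pruning, and nested SVM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic high-order connectivity, spanning-tree pruning, and nested SVM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honmst)
```

## The model

Resting-state functional connectivity is usually summarized by one
correlation per region pair over the whole scan.  That summary discards
the fact that inter-regional coupling waxes and wanes over minutes, and
that the *co-fluctuation* of two couplings is itself informative: if the
connectivity of pair (i, j) rises and falls together with that of pair
(p, q), the four regions participate in a common dynamic process.  This
package implements a classification pipeline built on exactly that
statistic.

**1. Sliding windows.**  A regional mean BOLD series of length $M$ time
points (TR sampling) is cut into $K$ overlapping windows of length $N$
advanced by step $S$:
$$K = \lfloor (M-N)/S \rfloor + 1 .$$
With the default acquisition-style sizes $M = 238$, $N = 60$, $S = 1$
this gives $K = 179$ windows (`count_windows()`).

**2. Low-order dynamic networks.**  Within each window the $R \times R$
Pearson correlation matrix of the regional series is computed
(`windowed_correlations()`).  Collecting entry $(i,j)$ across windows
yields the *connectivity time series* $y_{ij} \in \mathbb{R}^K$, one per
region pair, $P = R(R-1)/2$ in total, ordered lexicographically
(`pair_map()`).

**3. High-order network.**  The high-order network has the $P$ region
pairs as nodes and edge weights
$$H_{ij,pq} = \mathrm{corr}\!\left(y_{ij},\, y_{pq}\right),$$
the correlation between connectivity time series
(`highorder_matrix()`).  An edge involves up to four distinct regions.
For the significance-filtered baseline (`fdr_threshold()`), two-sided
p-values from the $t$ transform $t = r\sqrt{K-2}/\sqrt{1-r^2}$ are
corrected with the Benjamini–Hochberg step-up over all upper-triangle
edges and non-surviving weights are zeroed.  Overlapping windows make
successive $y$ values autocorrelated, so these nominal degrees of
freedom overstate the effective sample size; we document rather than
correct this, since the thresholded network is only a comparison
baseline here (see *Limitations*).

**4. Spanning-tree pruning.**  The tree pathway consumes the
*unthresholded* $H$: pruning, not significance filtering, is its way of
discarding edges.  `kruskal_mst()` (default) and `prim_mst()` compute
the spanning tree minimizing the total transformed edge length.  Two
orientations are exposed because "minimum spanning tree" is ambiguous
for correlation weights:

* `retain_strongest` (default): length $d = 1 - |w|$, keeping the
  strongest-magnitude correlations — the standard convention in
  brain-network spanning-tree analysis;
* `literal_minimum`: length $d = w$, the literal minimum-weight tree.

Ties in $d$ are broken by (smaller node id, larger node id), making both
algorithms deterministic; with distinct lengths they return the same
tree, which the tests verify against brute-force enumeration of all
spanning trees.  Tree edges carry their original signed weight forward.

**5. Node features.**  Each node's feature is a weighted local
clustering coefficient
$$f_i \;=\; \frac{2\sum_{j \in \Delta_i} \mathrm{sgn}(w_{ij})\,|w_{ij}|^{1/3}}
        {3\,|\Delta_i|\,(|\Delta_i|-1)},$$
with $\Delta_i$ the neighbours of $i$ (`clustering_coefficients()`).
Unlike the triangle-based weighted clustering coefficient — identically
zero on any tree — this degree-normalized neighbour-sum form is
non-trivial on spanning trees, which is why it is the feature the tree
pathway needs.  Leaves ($|\Delta_i| \le 1$) get $f = 0$, the continuous
extension as the neighbour sum vanishes.  The cube root is
sign-preserving by default so anticorrelation is not discarded
(`weight_mode = "absolute"` is available).

**6. Feature selection.**  Relief weighting (`relief_weights()`) uses
the original deterministic two-class algorithm: every training sample
contributes the difference between its distance to the nearest miss and
the nearest hit, per feature, on range-scaled values.  Weights
*accumulate* over samples without dividing by the sample count, so their
scale grows with the training set and the threshold $\delta$ must always
be tuned to the data at hand — with thousands of features and tens of
subjects, useful thresholds live in the thousands; at the synthetic
study scale below, in single digits.  Features at or above $\delta$ are
kept (`select_by_threshold()`), then pairwise redundancy pruning
(`redundancy_prune()`) walks the survivors in descending-weight order
and drops the lower-weight member of any pair with $|r| > \lambda$.

**7. Nested classification.**  `outer_cv()` runs repeated stratified
10-fold cross-validation.  Within each outer training fold,
`inner_optimize()` makes one stratified 3:1 split into an inner training
set B and a tuning set, computes Relief weights on B, and scores every
$(\delta, \lambda, C, \gamma)$ grid combination by tuning-set accuracy
of an RBF-SVM fit on B; exact ties prefer higher $\delta$, then lower
$C$, $\gamma$, $\lambda$ (sparser, simpler models).  The winning
parameters are refit on the *entire* outer training fold — the standard
choice when a tuning split is only a means of model selection — and the
held-out fold is predicted.  Features are z-scored with training-fold
statistics before the SVM (RBF kernels need comparable scales).  The
patient group is the positive class for sensitivity/specificity;
decision scores are pooled across folds within a repetition for the ROC
curve and the trapezoid AUC is averaged over repetitions.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `window_N` | window length (TRs) | 60 | grid 40–90 is customary |
| `window_S` | window step (TRs) | 1 | 1–5 |
| `mst_algorithm` | tree construction | `kruskal` | `prim` identical for distinct lengths |
| `edge_transform` | edge-length orientation | `retain_strongest` | see step 4 |
| `fdr_alpha` | FDR level (thresholded baseline) | 0.05 | |
| `delta_grid` | Relief threshold grid | 1000–1600 | scale is data-dependent |
| `lambda_grid` | redundancy threshold grid | 0.75–0.95 | |
| `c_grid` | SVM penalty grid | 1–10 | |
| `gamma_grid` | RBF width grid | 0–0.45 | small values ≈ linear kernel |
| `n_folds`, `n_repeats` | CV design | 10, 10 | |

## The synthetic-data generator

No public cohort accompanies the method, so
`generate_synthetic_cohort()` is a first-class module that emulates the
*one* property the pipeline claims to detect: a group difference in the
temporal co-fluctuation of selected pair connectivities, with the static
connectivity structure matched between groups.

Each planted couple names two region pairs.  Its four regions share a
static latent factor $w(t)$ with loading $\sqrt{\bar\rho}$,
$\bar\rho = c/2$ where $c$ is `coupling_strength`; on top of it the two
regions of a pair are mixed so that their total instantaneous
correlation is
$$\rho(t) = c\,\bigl(1 + \sin(2\pi t/T + \phi)\bigr)/2,$$
oscillating through $[0, c]$ around its mean $\bar\rho$ while every
region keeps unit signal variance.  In patients (label 1) *all* planted
pairs of a subject follow one common modulator — one period and one
subject-random phase — so their connectivity series rise and fall
together, within couples and across them; in controls each pair draws an
independent modulator (independent phase, and period jittered by
±`period_jitter` so same-frequency sinusoids cannot stay accidentally
phase-locked over the short scan).  All regions receive a weak static
global signal (`background_coupling`) and white noise (`noise_sd`).
Setting `coupling_strength = 0` removes the planted structure entirely
and the two groups become distributionally identical — the null the
tests exercise.

Design notes, fixed before the test suite was frozen:

* The *mean* coupling is identical in both groups by construction
  (time-average $\bar\rho$ within pairs, $\bar\rho$ across the couple,
  background elsewhere), so static Pearson/partial baselines carry no
  planted signal; only the high-order statistic does.  This is verified
  by a test comparing full-series correlations between groups.
* Sharing one modulator per patient across all couples (rather than one
  per couple) gives the planted structure a connected footprint —
  at the default five couples, a 10-node clique of strong high-order
  edges — which a spanning tree can retain.  Isolated single edges are
  routinely displaced by spurious strong edges (see *Limitations*).
* Defaults (`R = 20`, `M = 238`, `n_per_group = 20`,
  `coupling_strength = 0.9`, `noise_sd = 0.2`, `modulator_period = 120`,
  `period_jitter = 0.3`, `background_coupling = 0.1`) are the study
  conditions used throughout the tests and the acceptance script.

What the generator does **not** emulate: hemodynamic response shapes and
1/f BOLD spectra (regional series are white between planted components),
head motion and physiological nuisance structure (`residualize_nuisance()`
exists for real data but synthetic series need no cleaning), spatial
autocorrelation between neighbouring parcels, scanner/site effects, and
any disease biology beyond the planted co-fluctuation.  Passing tests
therefore demonstrate that the pipeline recovers the statistic it
targets under controlled conditions — not that it diagnoses a disease.

## Numerical choices

* Zero-variance regional series in any window, and constant connectivity
  time series, are hard errors naming the offending window/pair — NaNs
  would otherwise silently poison every downstream correlation.
* Correlation values are clamped to $[-1, 1]$ to absorb floating-point
  overshoot before bounds-checked code consumes them.
* Window indexing is 0-based half-open $[kS, kS+N)$; pair ordering is
  lexicographic with $i < j$; both conventions are asserted by tests.
* Relief nearest-neighbour ties resolve to the smallest sample index;
  features with zero range on a training fold are an error in the
  exported `relief_weights()` (the contract says ranges must be
  positive), while the cross-validation wrapper marks them $-\infty$ so
  no threshold selects them — on tree features, a column can
  legitimately be all-zero within a fold because leaves have $f = 0$.
* Grid combinations that select zero features score chance (0.5) in the
  inner loop rather than erroring; a final fit with zero features falls
  back to a majority-class model with zero decision scores.
* One top-level seed drives everything: per-repetition fold shuffles and
  per-fold inner splits are derived sub-seeds, so a `cv_result` is
  exactly reproducible.

## Problem sizes used by the test suite

The packaged checks run the full study at reduced scale: cohorts of
40 subjects with $R = 20$ regions ($P = 190$ pair nodes) and $M = 238$
time points; nested CV with 10 folds and 2 repetitions over a grid of
$\delta \in \{1,2,3,4\}$, $\lambda = 0.9$, $C \in \{1,3,10\}$,
$\gamma \in \{0.005, 0.02, 0.05, 0.2\}$; 20 generator seeds for the
Relief-rank recovery check and 10 for the coupling-zero null;
spanning-tree optimality against brute-force enumeration over all
labelled trees for $P \le 7$.  `scripts/acceptance.R` re-runs the same
computations from an installed copy of the package.

## Known limitations

* **Effective degrees of freedom of windowed series.**  With step 1 and
  window $N$, neighbouring connectivity values share $N-1$ of their $N$
  samples; a length-$K$ series has only about $M/N \approx 4$
  effectively independent values at the default sizes.  Correlations
  between such smooth series are enormously variable, so the high-order
  matrix of *any* cohort — patient or control — contains thousands of
  spurious entries near $\pm 0.9$ at $P = 190$.  The significance
  p-values of `correlation_pvalues()` use nominal $K - 2$ degrees of
  freedom and are therefore anti-conservative; they are retained because
  the thresholded network is a baseline, not the endpoint.
* **What the spanning tree can carry.**  A retain-strongest tree picks
  the $P-1$ strongest of $P(P-1)/2$ edges.  Under the saturation just
  described, most chosen edges are spurious extremes in both groups, and
  the clustering-coefficient features — zero on leaves, quasi-discrete
  on low-degree internal nodes, sign-noisy where random edges attach —
  transmit only part of even a very large planted high-order effect.  At
  the reduced study scale the planted couple correlation separates
  groups by dozens of standard errors and planted features sit clearly
  above the median Relief rank, yet cross-validated accuracy sits well
  below what the separation of the underlying statistic would suggest;
  the acceptance script computes the actual numbers for any seed.  At
  the full parcellation scale ($P = 4005$) with larger cohorts the
  balance may differ, but that regime is outside desk-scale testing.
* **Inner tuning variance.**  The 3:1 inner split tunes four parameters
  on a handful of held-out subjects at cohort sizes like 40; the
  selected combination is noisy fold to fold.  This is a property of the
  framework, faithfully implemented.
* The AAL-90 lobe-module table shipped in `inst/extdata/` is a
  documented convention (5 modules covering 90 regions); other
  assignments exist, and the file can simply be replaced.
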