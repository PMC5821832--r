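---
title: "Methods: kernel PCA quadrant labeling, conditional importance, and association mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel PCA quadrant labeling, conditional importance, and association mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Metabolic profiling experiments (urine ^1^H NMR peak tables merged with
ICP-OES element concentrations, hundreds of samples from a handful of
volunteers) often carry *non-linear* structure: sample groupings driven by
physiology or diet that no linear projection separates. Linear PCA then
concentrates samples at particular positions of the score plot and the
grouping that follows is biased. This package implements an unsupervised
workflow for that situation:

1. normalize and merge the feature blocks (PQN, auto scaling);
2. embed the samples by kernel PCA with an ANOVA kernel;
3. pseudo-label each sample by the signs of its first two component scores
   (four quadrant classes);
4. rank variables against the pseudo-classes with a conditional permutation
   importance forest, validated by leave-one-out cross-validation;
5. confirm the top variables with Kruskal–Wallis rank tests;
6. link discretized metabolite levels to dietary/nutrient items by
   association-rule mining, exported as a Cytoscape network.

Every stage is also exercisable against a seeded synthetic study with known
ground truth (`generate_study()`), because data of this kind are rarely
shareable.

# Kernel PCA and the ANOVA kernel

For samples $x, y \in \mathbb{R}^p$ the ANOVA kernel is

$$K(x,y) = \Big(\sum_{k=1}^{p} \exp\big(-\sigma\,(x_k-y_k)^2\big)\Big)^{d}.$$

The sum runs over the $p$ coordinates (feature count), and the degree
defaults to $d = 1$, where the kernel is simply the sum of one-dimensional
Gaussian kernels. This additivity is why the kernel behaves well on wide,
partially informative omics tables: a coordinate on which two samples agree
contributes its full term regardless of how many other coordinates
disagree, whereas the multiplicative Gaussian kernel
$\exp(-\sigma\|x-y\|^2)$ lets uninformative coordinates crush the
similarity. Gaussian, Laplace and linear kernels are provided for
comparison.

KPCA itself is standard: the Gram matrix is double-centered
($\tilde K = K - \mathbf{1}_n K - K \mathbf{1}_n + \mathbf{1}_n K
\mathbf{1}_n$, $\mathbf{1}_n$ the matrix of $1/n$), eigendecomposed, dual
coefficients normalized so $\lambda_i\,\alpha_i^\top\alpha_i = 1$, and
scores computed as $\tilde K \alpha_i$. With the linear kernel on centered
data this reproduces classical PCA scores exactly, which is the main
correctness oracle in the test suite. Component signs are fixed
deterministically (largest-magnitude dual coefficient made positive) so
repeated fits are bit-identical.

## Bandwidth selection

$\sigma$ is the one tunable that matters. `scan_sigma()` fits one KPCA per
grid point (default 0.05–0.30, the range worth exploring for autoscaled
data) and reports the PC1 contribution rate together with a dispersion
score of the 2-D score plot: the **mean pairwise distance of the
min-max-normalized scores**. The auto-pick maximizes dispersion; the
preset used in practice for this workflow ($\sigma = 0.135$, $d = 1$)
ships as the `pipeline_config()` default for fixed-sigma runs.

Why mean *pairwise* distance rather than mean nearest-neighbor distance?
Both penalize the pathology the scan exists to avoid — samples concentrated
at particular positions, which makes the subsequent quadrant grouping
unbalanced. But nearest-neighbor distance also penalizes *cluster
formation* itself: as the embedding sharpens genuine group structure,
within-group neighbors get closer and the NN score falls, so maximizing it
systematically prefers the fuzziest (most linear-like) embedding. On the
package's radial synthetic design that choice collapses the quadrants back
to linear-PCA behavior, while the pairwise score — dominated by
between-group separation — selects bandwidths whose quadrants track the
true classes. The dispersion measure is a package design choice and is
reported alongside the full contribution-rate curve so users can pick
differently.

## Quadrant pseudo-labeling

Classes are the sign patterns of (PC1, PC2): $(+,+) \to 1$, $(-,+) \to 2$,
$(-,-) \to 3$, $(+,-) \to 4$ by default. A score of exactly zero counts as
positive — a measure-zero tie that must nevertheless be deterministic. The
quadrant-to-class-number mapping is configurable and every downstream stage
is mapping-agnostic; a hand-made label file can replace the rule entirely
(`pipeline_config(labels_file = ...)`), preserving the manual-classification
workflow some analysts prefer.

The number of components used for grouping is fixed at two. Automatic
selection of the component count or class count is explicitly out of scope;
the workflow is exploratory by design.

# The conditional permutation importance forest

KPCA cannot attribute structure to variables (scores live in the dual
space), so variables are ranked by how much they help a forest classifier
re-predict the quadrant classes.

**Base learner.** Trees are CART-style: Gini impurity, `mtry` random
candidate variables per node (default $\lceil\sqrt{p}\rceil$), grown on
subsamples drawn *without replacement* (fraction 0.632) — the sampling
scheme known to keep permutation importance unbiased under predictor
correlation. Full conditional-inference-tree induction (permutation-test
split selection) is deliberately **not** reproduced: the property this
workflow actually relies on is the *conditional permutation importance*,
which is implemented faithfully on top of the simpler trees. This is an
approximation and is documented as such; the preset used for wide spectral
tables (`ntree = 80`, `mtry = 900`) is available as
`forest_config_spectral()`.

**Conditional importance.** For variable $j$ and each tree: out-of-bag
samples are predicted before and after permuting $j$'s OOB values *within
strata* defined by the tree's own split points of the variables correlated
with $j$ (|Pearson r| > 0.2 by default). The importance is the mean OOB
accuracy drop over trees. Permuting within correlation strata removes the
inflation that plain permutation importance awards to variables merely
correlated with informative ones — the decoy-debiasing property checked in
the acceptance suite. Variables a tree never splits on contribute exactly
zero for that tree, so constant variables get importance exactly 0.

**Determinism.** One master seed; per-tree and per-fold seeds derive from
it by a counter scheme, so results do not depend on execution order.
Leave-one-out folds are seeded by the held-out sample's rank among sorted
sample ids and the training fold is put in canonical id order, making the
LOOCV report invariant to input row order. Majority-vote ties go to the
lowest class number.

**Open question resolved.** Whether importance should be computed on the
full data or within CV folds is ambiguous in this workflow's protocol
ordering; the package computes importance on the full-data forest and uses
LOOCV only for the accuracy/confusion report, matching the stage order
`forest importance -> validation`.

# Kruskal–Wallis validation

Each top-ranked variable is tested across the four classes with the
tie-corrected Kruskal–Wallis statistic,

$$H = \frac{\frac{12}{N(N+1)}\sum_j R_j^2/n_j - 3(N+1)}
          {1 - \sum_t (t^3 - t)/(N^3 - N)},$$

with $p$ from $\chi^2_{k-1}$ and star tiers at 0.05 / 0.01 / 0.001. Raw
thresholds are reported by default because that is how this workflow's
results are conventionally annotated; Benjamini–Hochberg adjustment is
available behind `adjust = "BH"`. When all values are identical the
correction denominator degenerates and $H$ is defined as 0 with $p = 1$.
Box-plot summaries (`group_summaries()`) use linear interpolation of the
empirical CDF (R quantile type 7) — stated once here because box-plot
conventions differ between tools. Post-hoc pairwise tests are out of scope.

# Association mining

Continuous variables become items by a per-variable **median split**:
strictly above the median emits `name=high`, strictly below `name=low`,
exactly at the median nothing. The scheme is configurable (k-quantile
bins); median split is the simplest rule that makes the preset support
cutoff meaningful at a few hundred samples. Frequent itemsets come from a
level-wise Apriori with the downward-closure prune (exact supports, maximum
itemset size 3 by default to bound combinatorics); rules are all
antecedent→consequent partitions of frequent itemsets, scored by
support (of $A \cup C$, the arules convention), confidence and lift, and
filtered at the workflow presets 0.0625 / 0.25 / 1.2. Independent item
pairs sit at lift 1 and fall to the 1.2 cutoff. Networks are exported as
SIF and GraphML (edge attributes: support, confidence, lift) for Cytoscape;
rendering is the user's concern.

# The synthetic study

`generate_study()` is first-class, tested code — the stated world against
which the pipeline's claims are checked. Defaults: $n = 400$ samples
(near the scale of the motivating study), 8 subjects with random
intercepts on every variable (sd 0.2), $p = 100$ profiling variables of
which 8 are informative, 12 nutrients with 6 planted metabolite–nutrient
pairs, class imbalance 73:94:96:123.

The default `"radial"` design places the four classes at (inner/outer
radius) × (upper/lower half-plane) positions of a 2-D latent space —
class membership depends on the *radius*, a non-linear function of the
coordinates — and the informative variables are noisy linear readouts of
the latent position. Any linear projection can separate at most the
upper/lower contrast by score signs, so linear-PCA quadrants merge the
inner and outer classes, while a kernel embedding can resolve them. Decoys
are correlated at $r \approx 0.9$ with one informative variable each but
are conditionally independent of the class given it; planted nutrient
pairs co-occur at $r \approx 0.85$, i.e. lift $\approx 1.6$ at a median
split — comfortably above the 1.2 cutoff but far from deterministic.
Latent spreads (radius sd 0.12, angle sd 0.4, class-center radii 0.6/1.8)
were chosen once so that the classes are recoverable but overlapping, and
are not tuned thereafter.

What the generator does *not* emulate: spectral realism (peak shapes,
baseline, alignment error — `spectralize()` offers only a thin Lorentzian
embedding for testing the raw-spectrum utilities), real urine composition,
dietary record structure, or subject-by-class confounding. A green
end-to-end test therefore establishes that the machinery does what it
claims on data with the *assumed statistical shape*, not that the
workflow's scientific conclusions transfer to any particular cohort.

# Numerical conventions

- PQN reference: point-wise median of total-area-normalized samples (the
  standard Dieterle variant), overridable; zero-reference points are
  excluded from the quotient median; all-zero samples are an error naming
  the sample.
- Zero-variance columns are dropped (with a warning) by `autoscale()`
  rather than erroring — merged omics tables routinely contain them.
- Missing values are rejected at load time; the pipeline does not impute.
- Retained KPCA eigenvalues must exceed $10^{-10}\lambda_{\max}$;
  requesting more components than the positive spectrum supports is an
  error reporting the usable count.
- Gram matrices are symmetrized after computation to remove rounding
  asymmetry; Gaussian/Laplace distances are accumulated per coordinate to
  avoid the cancellation of the $\|x\|^2 + \|y\|^2 - 2x^\top y$ expansion.
- Importance ties are broken by variable name; majority-vote ties by
  lowest class; score-sign ties by the positive half-plane.

# Limitations

- The forest is an approximation of conditional-inference forests (see
  above); absolute importance values are not comparable across
  implementations, only rankings and the conditional-vs-unconditional
  contrast are.
- Out-of-sample projection of new samples onto a fitted KPCA is not
  provided; the workflow is exploratory, not predictive.
- Apriori is exact but level-wise; at the default median split every item
  has support near 0.5, so mining hundreds of variables at itemset size 3
  is combinatorially heavy — restrict to the top-importance variables (the
  pipeline default) or lower `max_len`.
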