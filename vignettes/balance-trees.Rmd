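---
title: "Balance trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balance trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancetrees)
```

## The model

A sequenced community of `D` taxa is observed only up to a multiplicative
constant, so the sample space is the Aitchison simplex: vectors of positive
proportions summing to one, with perturbation (closed element-wise product)
and powering (closed element-wise power) as the vector-space operations.
Any rooted strictly binary tree over the taxa induces an orthonormal
coordinate system of this space. Internal node `i`, with `r` taxa in its
first (numerator) subtree `i_L` and `s` taxa in its second (denominator)
subtree `i_R`, contributes the balance

$$ b_i \;=\; \sqrt{\tfrac{rs}{r+s}}\;
   \ln \frac{g(x_{i_L})}{g(x_{i_R})}, $$

where `g()` is the geometric mean of the proportions in a subtree.
Equivalently, `b = clr(x) Ψ'` where `Ψ` is the (D−1) × D matrix whose row
for node `i` holds `sqrt(s/(r(r+s)))` on numerator taxa and
`−sqrt(r/(s(r+s)))` on denominator taxa — the square-root factors are
exactly what makes the rows unit-norm and pairwise orthogonal.
`buildIlrBasis()` constructs `Ψ`, `ilrTransform()` / `inverseIlr()` apply
the isomorphism in both directions, and the class validity checks enforce
orthonormality at tolerance 1e-8 on every constructed basis.

Three consequences carry the statistical weight, and are asserted at 1e-9 in
the test suite across random trees up to `D = 200`:

* **scale invariance** — multiplying a sample's abundances by any constant
  (sequencing depth) leaves every balance unchanged;
* **subcompositional coherence** — a change confined to taxa outside node
  `i`'s clade leaves `b_i` untouched, which is precisely what proportions
  lack;
* **isometry** — Euclidean geometry on balances is Aitchison geometry on
  compositions, so ordinary linear models on balances are well-posed and
  any valid tree gives the same total variance.

All logarithms are natural. Base only rescales balances by a constant and
would break none of the identities, but the inverse transform and the
round-trip contracts assume one fixed base, so none is exposed.

## Trees

Trees are `ape::phylo` objects; any user newick that parses to a strictly
binary tree with unique tips is accepted (`readNewickBinary()` rejects
polytomies by node name). Internal nodes are named `y0, y1, ...` in level
order from the root, so `y0` is always the root balance — the coarsest and,
with the most taxa on each side, the most trustworthy contrast. The first
child in newick order is the numerator; `buildIlrBasis(flip = TRUE)`
reverses every contrast globally.

When no meaningful phylogeny exists, `upgmaNiche()` builds the tree from the
data. Each feature's mean niche is the abundance-weighted mean of the sample
gradient (`meanNicheEstimator()`), and features are clustered by
average-linkage (UPGMA) agglomeration of the one-dimensional distances
`|niche_x − niche_y|` — the only natural metric on a scalar niche. Two
conventions are library choices, made deterministic because nothing in the
method fixes them:

* **tie-breaking**: among merge pairs at equal distance, the pair whose
  smallest member sorts first by feature identifier wins — reruns are
  byte-identical across platforms;
* **child order**: within each merge the higher-mean-niche cluster becomes
  the numerator, so every balance reads "high-gradient organisms over
  low-gradient organisms" and a positive slope against the gradient means
  the high-niche side takes over (`highFirst = FALSE` reverses this).

Cophenetic heights are kept as branch lengths but balances use topology
only. The implementation is a direct O(D³) agglomeration — trees here are
feature trees (hundreds of tips), not read trees — and is cross-checked in
the tests against `stats::hclust(method = "average")` clade sets.

Mean-niche weighting defaults to per-sample proportions (so a deeply
sequenced sample does not dominate a feature's niche estimate); raw-count
weighting (`proportions = FALSE`) is provided because the two readings
coincide only at equal depth. Either way the estimate is a convex
combination of observed gradient values, hence bounded by their range.

## Zeros and filtering

Log ratios need strictly positive entries. The pipeline follows the common
practice for count tables: add a pseudocount (default 1, `addPseudocount()`)
to *every* entry, then close to proportions (`prepareComposition()`).
Tables that already are proportions skip the pseudocount; if they contain
zeros this is an error with guidance rather than a silent fix, because no
meaningful pseudocount exists on the proportion scale. Rare features are
removed before any of this by `filterFeatures()`, which keeps features whose
study-wide total is *strictly greater* than the threshold (the case-study
values are 100 and 500 reads). Low-count taxa make tip-adjacent balances
volatile — a one-read change is a large log-ratio change — which is why
root-ward balances should be trusted over tip-ward ones.

## Regression on balances

`fitOls()` fits the shared design to every balance column independently
(one QR decomposition, all columns at once) and reports per-(node, term)
estimates, standard errors and t-test p-values. The global coefficient of
determination is computed in balance space,

$$ R^2 = 1 - \mathrm{SSE}/\mathrm{SST}, $$

summing squared residuals and squared centred balances over all nodes and
samples. Because the ILR is an isometry this quantity is invariant to the
tree (verified to 1e-9 across 20 random trees), which is the reason to
aggregate in balance space rather than per node. Degenerate cases: a
saturated design (as many columns as samples) fits exactly and reports no
standard errors or p-values; balances with zero variance give an undefined
(NA) `R²`.

`fitLme()` fits, per balance, a random-intercept model
`b ~ fixed + (1 | group)` by REML via lme4 — the structure that absorbs
baseline differences between groups (e.g. patients with idiosyncratic lung
communities) while testing a shared gradient effect. Random slopes are out
of scope. P-values are Wald normal approximations on the fixed-effect t
statistics (lme4 supplies no denominator degrees of freedom); with 100+
observations per fit the approximation is mild. A per-node fit that errors
or raises a convergence warning keeps whatever estimates exist, gets an NA
p-value and a `FALSE` entry in the `converged` vector, and never aborts the
other nodes.

Multiple testing uses Bonferroni across the `D − 1` internal nodes,
separately per model term; adjusted values are clipped at 1 and NA p-values
still count toward the family size. Family-wise error under label
permutation is checked empirically in the acceptance suite (500 permuted
refits).

`predictProportions()` evaluates the fixed-effect linear predictor at new
covariates and maps the predicted balances through `inverseIlr()`, giving
communities that sum to one — the "predict the whole community from pH
alone" use of the model.

## The simulators: what they emulate, and what they do not

`generateGradientCommunity()` draws unimodal niche responses: expected
proportions proportional to Gaussian bumps `exp(−(g − opt)²/(2w²))`, closed
per sample, with proportions below `zeroThreshold` (default 1e-4) rounded
down to zero and the sample re-closed — the zero-rounding rule keeps the
pseudocount pathway honestly exercised. Counts are multinomial at fixed
depth. Defaults are a soil-like world: a pH gradient 3–9 over 50 samples,
optima spread evenly, width 1 pH unit (taxa occupy a restricted slice of the
gradient, wide enough to overlap neighbours), depth 10 000 reads. These are
stated conditions, not tuning knobs.

`generatePatientGradient()` emulates the repeated-measures microcosm: 16
patients × pH 5–8.5 in steps of 0.5 (128 samples), a shared pool of 40
features whose optima span the pH range, and an idiosyncrasy level (default
0.5) giving each patient a random subset of the pool — the regime where
per-feature tests starve for power because no single feature is shared, yet
the root balance responds to pH in every patient.

`generateBloomDataset()` builds the false-discovery experiment: two groups
of 50 samples over a uniform 1000-taxon community, one taxon's absolute
abundance multiplied by `bloomFactor` in group 2, multinomial counts at
depth 100 000. The bloom default is 1000 — the bloomer grows to roughly
half the community — and this choice is analytic, not fitted: a bloom of
factor `f` shifts each unchanged taxon's expected proportion by
`(f−1)/(D(D−1+f))`, while the standard error of a group-mean difference at
depth `N` with `n` samples per group is `sqrt(2p(1−p)/(Nn))`. With
`D = 1000`, `N = 1e5`, `n = 50`, a factor of 8 gives a t statistic around
0.35 — indistinguishable from null — whereas the overwhelming-false-positive
regime needs `f` on the order of hundreds. Only a dominant bloom makes
proportion tests fail *en masse*; the coherent balances stay calibrated at
`α` either way, which is the point of the experiment
(`fdrExperiment()` reports both rejection rates, classifying a balance as
null when the bloomer lies outside its clade).

What the generators do **not** emulate: sequencing error, chimeras,
overdispersion beyond multinomial, taxon-taxon interactions, or the sparsity
profile of real 16S data. A green test therefore establishes the
compositional geometry and the statistical machinery on a stated world — it
does not validate the biology of any particular study, and the published
soil/sputum case studies (which require Qiita downloads) are not reproduced
here.

## Numerical conventions

* Geometry contracts (orthonormality, round trip, coherence, scale
  invariance, route equivalence) are tested at 1e-9; class validity uses
  1e-8 to leave headroom for accumulation at `D = 1000`.
* Closure refuses all-zero samples by name; `upgmaNiche()` refuses
  non-finite niche values by feature.
* All generator randomness flows from a single integer `seed`; the CLI
  threads one `--seed` through every stage, and reruns are byte-identical.
* Equal-mean-niche merge children are ordered by smallest member identifier;
  every tie-break in the package is lexicographic so results never depend on
  hash or platform order.

## Limitations

Balances answer questions about *groups* of taxa defined by the tree, not
about individual taxa; a pseudocount remains a crude answer to zeros; the
mixed model is random-intercept only; and the niche tree is built from the
same data it is later tested on — the per-balance p-values are conditional
on the chosen tree, as in the original workflow, and should be read as
descriptive strength-of-trend measures rather than confirmatory tests.
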