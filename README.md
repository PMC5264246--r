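# balancetrees

Balance-tree analysis of compositional microbiome data: isometric log-ratio
(ILR) balances over bifurcating trees, niche-driven tree construction from an
environmental gradient, and per-balance regression / mixed-effects modelling.

## The problem

16S rRNA count tables are compositional: sequencing reports *relative*
abundances, so when one taxon blooms, every other observed proportion drops
even though nothing else changed. Per-taxon statistics (t tests, Pearson or
Spearman correlations) applied to proportions therefore flag taxa that never
moved — in the simulation shipped with this package, a single blooming
species makes per-taxon t tests reject essentially 100 % of the unchanged
taxa.

Balances sidestep this. Given a bifurcating tree whose tips are the taxa,
each internal node `i` defines one coordinate

```
b_i = sqrt(r*s / (r + s)) * ln( g(i_L) / g(i_R) )
```

where `i_L`, `i_R` are the taxon sets of the node's two subtrees with `r` and
`s` members and `g()` is the geometric mean of their proportions. The `D − 1`
balances are an orthonormal (ILR) coordinate system of the Aitchison simplex:
scale-invariant (sequencing depth cancels), subcompositionally coherent
(changes outside a node's clade leave its balance untouched), and an isometry
(Euclidean distance between balance vectors is Aitchison distance). Standard
statistics — OLS, linear mixed-effects models — can then be applied to
balances directly, and fitted balances map back to predicted proportions.

When no phylogeny is appropriate, the tree is built from the data: each
feature's **mean niche** is its abundance-weighted mean position on a sample
gradient (e.g. pH), `niche_x = Σ_i g_i x_i / Σ_i x_i`, and features are
clustered by UPGMA on those values so that the root balance reads "high-pH
organisms over low-pH organisms".

## Worked example

Two count scenarios with identical proportions — Red doubling (200, 100) vs
Blue halving (100, 50) — give the same balance, and equal counts give zero:

```r
library(balancetrees)

counts <- CompositionTable(matrix(c(200, 100, 100, 50, 100, 100), 3,
    byrow = TRUE, dimnames = list(c("t1", "t2", "t3"), c("Red", "Blue"))))
tree <- readNewickBinary("(Red,Blue)y0;")
tableValues(ilrTransform(closure(counts), buildIlrBasis(tree)))
#>           y0
#> t1 0.4901291      # sqrt(1/2) * ln 2
#> t2 0.4901291      # same balance: depth is irrelevant
#> t3 0.0000000      # equal parts
```

A full gradient analysis on simulated unimodal communities (12 taxa with
niche optima spread over pH 3–9, multinomial counts at depth 5000):

```r
sim   <- generateGradientCommunity(nFeatures = 12,
                                   gradient = seq(3, 9, length.out = 60),
                                   depth = 5000, seed = 42)
ph    <- setNames(sim$metadata$gradient, sim$metadata$sample)
niche <- meanNicheEstimator(sim$counts, ph)   # per-taxon mean pH, 3.69 .. 8.32
tree  <- upgmaNiche(niche)                    # binary tree, root = y0
basis <- buildIlrBasis(tree)
bal   <- ilrTransform(prepareComposition(sim$counts), basis)
fit   <- fitOls(bal, data.frame(ph = ph, row.names = names(ph)), ~ ph)
fit
#> RegressionResult (ols): ~ph
#>   global R2 (balance space): 0.8878
#>   11 nodes x 2 terms; 7 significant non-intercept rows at alpha = 0.05 (Bonferroni)

head(subset(coefTable(fit), term == "ph"), 3)
#>   node term estimate stderr   pvalue     padj significant
#>     y0   ph    4.038 0.0799 1.16e-49 1.28e-48        TRUE
#>     y1   ph    1.084 0.0887 1.14e-17 1.26e-16        TRUE
#>     y2   ph    0.953 0.1145 1.79e-11 1.97e-10        TRUE
```

The root balance `y0` — all high-pH taxa over all low-pH taxa — rises
steeply with pH, and pH alone explains 89 % of the balance-space variation in
this synthetic community (`globalR2` is invariant to the choice of tree).
`predictProportions(fit, newdata, basis)` maps fitted balances back to
proportions summing to one. For repeated-measures designs (e.g. patients ×
pH), `fitLme()` adds a random intercept per group. `nicheSort()` orders a
table by sample gradient and taxon mean niche to expose the diagonal band
structure of niche-partitioned communities.

A command-line interface wrapping the same pipeline is installed at
`system.file("scripts", "balance-trees.R", package = "balancetrees")` with
subcommands `niche-tree`, `fit`, `simulate` and `basis-export`.

## Acceptance script

`scripts/acceptance.R` regenerates the blooming-species experiment from
scratch with the installed package — two groups of 50 samples over a uniform
1000-taxon community, one taxon blooming in group 2, multinomial counts at
depth 100 000 — runs a two-sample t test on every taxon's proportions at
α = 0.05, and reports the percentage of taxa flagged:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
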