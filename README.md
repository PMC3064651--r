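# spermcomp

Phylogenetic comparative analysis of sperm competition and ejaculate
quality.

## What this package is for

Across species, males facing stronger sperm competition — more rival
ejaculates per fertilization opportunity — evolve larger testes relative to
their body size. `spermcomp` is for comparative biologists asking how sperm
*quantity* (total epididymal sperm number) and ejaculate *quality* traits
(percentages of morphologically normal, acrosome-intact, live and motile
sperm) respond to sperm competition, using species-mean trait tables and a
phylogeny. It ships a fixture dataset of 18 muroid rodent species (voles
and mice) with a consensus topology.

The core machinery:

* **Relative testes mass (RTM)** via the rodent allometry
  `Y = 0.031 * X^0.77` (X = body mass in g): `RTM = testes_mass / Y`, the
  standard sperm competition proxy, plus coefficients of variation
  (`CV = 100 * SD / mean`).
* **λ-model phylogenetic GLS**: `y = Xβ + ε`, `ε ~ N(0, σ² V(λ))`, where
  `V` holds shared branch lengths and Pagel's λ rescales its off-diagonal.
  σ² is profiled by ML; λ is estimated by bounded profile-likelihood search
  with boundary-aware likelihood-ratio tests against λ = 0 and λ = 1.
* **Sequential (Type I) sums of squares** with predictors in the fixed
  order body mass, then testes mass, so the testes-mass F measures the
  sperm competition effect beyond body size (15 residual df on the
  fixture).
* **Effect sizes** `r = sqrt(F / (F + df))` with Fisher-z confidence
  limits (`atanh(r) ± z / sqrt(df − 3)`), phylogenetically corrected
  pairwise correlations, and single-linkage clustering of traits on
  `d = 1 − r`.
* **"Overall sperm quality"**: correlation-matrix PCA of the four quality
  traits, varimax-rotated top-two components, and a scalar composite score.
* **Simulators** (pure-birth trees, λ-structured Brownian traits, full
  synthetic studies) for parameter-recovery and type-I-error testing.

See `vignette("sperm-competition-pgls")` for the model, its assumptions
and the design decisions.

## Worked example

```r
library(spermcomp)

tab  <- muroid_traits()   # 18 species, Tables of species means
tree <- muroid_tree()     # consensus topology, Grafen branch lengths

describe_traits(tab)$traits[, c("trait", "cv")]
#>                  trait   cv
#>              body_mass 61.5
#>            testes_mass 87.5
#>            total_sperm 75.5
#>             pct_normal  8.2
#>           pct_acrosome 18.1
#>               pct_live 15.3
#>             pct_motile 25.9
#>   relative_testes_mass 78.4
```

Testes mass varies far more than body mass (CV 87.5% vs 61.5%): exactly
the signature of divergent sperm competition levels. Relative testes mass
runs from 0.134 (*Mus famulus*) to 2.235 (*Apodemus sylvaticus*), a
~17-fold range.

```r
pgls_regression(tab, tree, "total_sperm", c("body_mass", "testes_mass"))
#> Phylogenetic GLS (lambda model): total_sperm ~ body_mass + testes_mass
#> lambda = 0 (logLik -0.003; vs lambda=0 p=0.5, vs lambda=1 p=0.00297)
#>               slope       F      p
#> body_mass   -0.6521  0.5705 0.4617
#> testes_mass  0.9044 22.7038 0.0003
#> Residual df = 15, adjusted R^2 = 0.556
```

λ is estimated at 0 (Brownian motion rejected, independence not), and the
sequential testes-mass F is highly significant: species with relatively
larger testes keep far more sperm in reserve, at any body size. The same
call with each quality percentage as response finds significant positive
testes-mass effects for all quality traits *except* `pct_live`.

```r
pca_quality(tab)
#> Quality-trait PCA on the correlation matrix
#> eigenvalues: 2.062 1.348 0.312 0.278
#> top 2 components explain 85.3% of variance
#> varimax-rotated loadings:
#>              factor1 factor2
#> pct_normal     0.899   0.070
#> pct_acrosome   0.893  -0.191
#> pct_live      -0.169   0.938
#> pct_motile     0.625   0.681
```

Normal morphology and acrosome integrity load together, live sperm sits
alone on factor 2, motility splits — quality traits largely co-vary, with
viability the odd one out. `run_full_analysis()` chains every stage
(descriptives → correlations → clustering → PCA → six regressions with
effect sizes) into one report, and `reproduce_published()` prints a
side-by-side comparison of the recomputed fixture quantities against the
published reference values, including the blocks where the unpublished
branch lengths of the original tree prevent exact magnitude agreement
(see the vignette).

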