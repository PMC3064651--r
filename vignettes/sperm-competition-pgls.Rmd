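---
title: "Comparative analysis of sperm competition and ejaculate quality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of sperm competition and ejaculate quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermcomp)
```

## The scientific question

When females mate with several males in one receptive period, the males'
ejaculates compete to fertilize the ova. Species under stronger sperm
competition evolve larger testes relative to their body size, so *relative
testes mass* (RTM) — observed testes mass divided by the mass predicted
from body mass by the rodent allometry $Y = 0.031\,X^{0.77}$ — is the
standard proxy for sperm competition level. This package asks how sperm
*quantity* (total epididymal sperm number) and the traits that determine
ejaculate *quality* (percentages of morphologically normal, acrosome-intact,
live, and motile sperm) respond to sperm competition across species, and
whether quality traits co-evolve or trade off against one another.

The shipped fixture is a species-mean table for 18 muroid rodents (7 voles,
11 mice, 3–8 males per species) together with a consensus topology of those
species. Because closely related species are not independent data points,
every cross-species association is estimated in a phylogenetic generalized
least squares (PGLS) framework.

## The statistical model

### Phylogenetic covariance and Pagel's lambda

Under Brownian-motion trait evolution on a tree, the covariance between the
trait values of two species equals the branch length they share from the
root to their most recent common ancestor, $V_{ij} = t_{\mathrm{shared}}$,
and $V_{ii}$ is the root-to-tip distance. Pagel's $\lambda \in [0, 1]$
rescales only the off-diagonal entries,
$V(\lambda) = \lambda V + (1-\lambda)\,\mathrm{diag}(V)$: $\lambda = 1$ is
pure Brownian motion, $\lambda = 0$ means phylogenetic independence.

The regression model is
$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal N\!\big(0,\ \sigma^2 V(\lambda)\big). $$
$\beta$ is estimated by GLS through a Cholesky whitening of $V(\lambda)$
(no explicit matrix inversion on the analysis path; an explicit-inversion
implementation exists only as a test oracle). $\sigma^2$ is profiled out
analytically by maximum likelihood ($\hat\sigma^2 = \mathrm{RSS}/n$, ML
rather than REML, matching the likelihood-ratio framing of the lambda
tests). $\lambda$ is estimated by maximizing the profile log-likelihood
with a deterministic start grid $\{0, 0.25, 0.5, 0.75, 1\}$ followed by
bounded golden-section/parabolic search (tolerance $10^{-6}$); the grid
guards against local optima on multimodal profiles.

The fitted $\hat\lambda$ is compared against the fixed models $\lambda = 0$
and $\lambda = 1$ by likelihood-ratio tests on $\chi^2_1$. When
$\hat\lambda$ sits on a boundary of $[0,1]$ the null distribution of the
LRT statistic is the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$,
so the $\chi^2_1$ p-value is halved. On the fixture, $\hat\lambda$ is 0 for
every model: Brownian motion is rejected ($p < 0.05$ against
$\lambda = 1$) and phylogenetic independence is not ($p \geq 0.5$ against
$\lambda = 0$).

### Sequential (Type I) sums of squares

Body mass and testes mass are collinear (testes mass scales with body
mass), so the multiple regressions enter them in a fixed order — body mass
first, then testes mass — and use sequential sums of squares: predictor
$k$ is credited with the increment in explained (GLS-whitened) sum of
squares after predictors $1..k{-}1$, divided by the full-model residual
mean square, on $(1, n - p - 1)$ df. The testes-mass F therefore measures
the effect of sperm competition *beyond* body size, which is exactly the
RTM logic; RTM itself is never used as a regression variable because the
ratio does not properly remove the allometry. With 18 species and two
predictors every test has 15 residual df.

### Effect sizes and confidence limits

Each F converts to a correlation-scale effect size
$r = \sqrt{F/(F + \mathrm{df})}$, signed by the GLS slope where a
direction exists. The default confidence limits are Fisher-z intervals,
$\mathrm{atanh}(r) \pm z_{0.975}/\sqrt{\mathrm{df}-3}$, reported on the z
scale (bounds such as 2.29 exceed 1 and cannot be correlations; the output
labels the scale). This formula reproduces all twelve reference intervals
of the fixture regressions to within 0.011 — the residual discrepancy is
rounding of the printed F values — and is therefore the default even
though a noncentral-F inversion (mapping the noncentrality bounds through
partial $\eta^2 = \delta/(\delta + \mathrm{df} + 2)$, reported on the r
scale) is also available.

### Pairwise correlations, clustering, and the quality composite

Phylogenetically corrected pairwise correlations fit a single-predictor
PGLS per trait pair. The pair's $\lambda$ is estimated once by maximizing
the *pooled* profile log-likelihood (the sum over both regression
directions), which makes $r$, $p$ and $\hat\lambda$ exactly symmetric in
the two traits; with a per-direction $\lambda$ the two directions could
disagree, and nothing in the model privileges one. The trait association
structure is summarized by single-linkage agglomerative clustering on the
distance $d = 1 - r$.

"Overall sperm quality" reduces the four quality percentages to one
variable: they are standardized, the correlation matrix is
eigendecomposed, the top two components are retained and varimax-rotated
(raw criterion, no Kaiser normalization, so the optimum is directly
checkable against an exhaustive rotation-angle search). PCA uses the
correlation — not covariance — matrix: the fixture eigenvalues (2.06,
1.35) sum with the remaining two to 4, which is only consistent with
standardized traits. Each unrotated component is oriented so its
largest-magnitude loading is positive, fixing the sign indeterminacy of
eigen-solvers. The scalar composite defaults to the unrotated first
principal-component score; because the source analysis reports two
factors yet regresses a single "overall quality" variable without stating
the combination rule, the rotated-factor-1 and eigenvalue-weighted rules
are kept switchable, and the rule used is recorded in the output.

## Transformation policy

Body mass, testes mass and total sperm number are log10-transformed before
any fit; the percentage traits enter raw. The policy is recorded per trait
on the table and propagated to every downstream stage. Raw percentages
were adopted after checking slope scales: reference slopes of ~16–36 for
percentage responses on log10 testes mass are only consistent with
untransformed responses. An arcsine-square-root tag is available per trait
for users who prefer variance-stabilized percentages; on this dataset it
changes no qualitative conclusion. CVs are always computed on untransformed
species means with the $n-1$ standard deviation — the convention that
reproduces all eight reference CVs exactly.

The normality check is a Kolmogorov–Smirnov statistic against a normal
with estimated moments. Since estimating the moments invalidates the naive
KS null distribution, the default p-value uses the Lilliefors calibration;
the uncalibrated KS p-value is available as an option.

## The fixture tree and branch lengths

The study tree's branch lengths were never published; the packaged
phylogeny (`muroid_tree_synthetic.nwk`) is a consensus *topology* assembled
from standard muroid taxonomy and is documented as a synthetic stand-in.
Branch lengths are assigned by rule, Grafen's method by default (node
height = descendant tips − 1, rescaled to unit root-to-tip depth), with
all-unit lengths or user-supplied lengths as alternatives. Because
$\hat\lambda = 0$ on this dataset, the fitted models are insensitive to
this choice: at $\lambda = 0$ on an ultrametric tree, PGLS reduces exactly
to OLS (a tested invariant).

This is also where reproduction of the reference analysis finds its limit.
The descriptive arithmetic (all CVs, the RTM column up to the rounding of
the printed masses), the PCA eigenvalues/loadings, every significance
pattern (which regressions and correlations are significant, including
live sperm's isolation), and the LRT pattern for $\lambda$ all reproduce.
The *magnitudes* of the reference F statistics and correlations do not:
e.g. the total-sperm testes-mass F recomputes to 22.7 versus a reference
111.75, and no combination of transformation, predictor order, weighting
or fixed $\lambda$ recovers them from the printed species means. The
dataset contains one influential species (*Mus famulus*: near-smallest
testes, mid-range sperm count) whose down-weighting — as a long branch
would do under $\lambda = 0$ on a non-ultrametric molecular tree — moves
every statistic strongly in the reference direction. Without the original
branch lengths this cannot be settled; the package reports what the stated
inputs support, and `reproduce_published()` prints the side-by-side
comparison rather than hiding it.

## What the simulator emulates

`simulate_study()` generates data with exactly the structure the analysis
assumes: a unit-depth pure-birth (Yule) tree — the simplest ultrametric
null consistent with the lambda model, since tree shape is not a study
variable — log10 body mass as a Brownian trait, log10 testes mass as the
allometry plus a lambda-structured deviation (the "sperm competition"
axis), a response following the configured linear model with
lambda-structured residuals, and quality percentages as correlated latent
Gaussians mapped into (0, 100) by a logistic squashing. Defaults are the
study conditions: 18 species, $\lambda = 0$, slopes −0.60 (body) and 1.16
(testes) for log10 sperm number, residual SD 0.25 on log10 sperm number
(the residual scale of the fixture fit).

The logistic map keeps percentages bounded without truncation artifacts,
at the cost of a deliberate mismatch with the raw-percentage analysis
scale; at the default latent SD the distortion is negligible (tested).
The simulator draws species means only — within-species sampling error is
not modelled, because the analysis operates on species means — and real
data also differ in having measurement error, non-Yule tree shape, and
possibly non-lambda covariance (e.g. Ornstein–Uhlenbeck), none of which a
passing recovery test speaks to.

## Numerical and testing choices

* Covariance solves use Cholesky factorization throughout; the
  explicit-inversion GLS exists only as a test oracle (agreement to
  $10^{-10}$ on random 8-species instances).
* Parameter recovery: mean $\hat\lambda$ over 100 replicates at $n = 200$
  is required within 0.1 of the generating value for
  $\lambda \in \{0, 0.5, 1\}$; slope recovery is checked against its
  Monte-Carlo standard error. These sizes keep the default test run to a
  few minutes while leaving Monte-Carlo noise well below the asserted
  bounds.
* The type-I error of the sequential testes-mass F at $n = 18$ (500 null
  replicates) measures ~7%, slightly above the nominal 5%: estimating
  $\lambda$ by ML before the F test is known to inflate small-sample
  error rates mildly. The package reports this honestly rather than
  recalibrating the test.
* Degenerate inputs error early with the offending row/column named:
  percentages outside [0, 100], nonpositive masses, duplicate species or
  tip labels, negative branch lengths, collinear designs, constant traits.
* Ties in the lambda profile (flat likelihood) resolve to the grid point
  with the highest likelihood, preferring the optimizer's interior
  solution only when it strictly improves on the grid.

## Known limitations

* No measurement-error (within-species SEM) weighting; the reference
  analysis does not use it and sample sizes per species are small.
* No Ornstein–Uhlenbeck or other non-lambda covariance models.
* No multiple-testing correction across the 10 trait pairs or 6
  regressions ($\alpha = 0.05$ throughout, as in the reference analysis).
* The packaged topology is a stand-in; users with a calibrated molecular
  tree should supply it — `run_full_analysis()` accepts any tree whose
  tips match the trait table.
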