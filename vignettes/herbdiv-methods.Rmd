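---
title: "Methods: community diversity metrics and herbivory inference in herbdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community diversity metrics and herbivory inference in herbdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbdiv)
```

## The scientific problem

herbdiv analyses how the functional and phylogenetic diversity of a woody
plant community relates to the standing insect herbivory experienced by
individual saplings of a set of dominant focal species. The study design it
supports is an observational forest-plot survey: a network of plots spanning
a woody-species richness gradient, a species-by-trait table of leaf traits,
a plot-by-species abundance matrix, a dated (ultrametric) phylogeny of the
species pool, and a sapling survey in which every leaf of every surveyed
sapling is assigned to one of six visual damage classes.

The analysis has four stages, each exposed as ordinary functions that take
and return data frames:

1. **Damage calibration** — visual damage classes are converted to
   proportions using the mean scanned damage of leaves per class.
2. **Diversity metrics** — community-weighted mean traits (CWM), Rao's
   quadratic entropy for single traits, multivariate trait groups and the
   phylogeny, and focal-species dispersion measures.
3. **Predictor preparation** — a PCA of plot characteristics, a
   response-guided collinearity screen, and z-standardization.
4. **Inference** — binomial mixed models with crossed random intercepts
   fitted by Laplace approximation, simplified backwards by AICc, and
   compared across five nested predictor families by AICc weights.

## Metrics

All metrics are abundance-weighted with plot-level relative abundances
$p_i$ (individual counts normalized per plot).

* **CWM** of trait $t$: $\sum_i p'_i t_i$, where $p'$ renormalizes over the
  species with $t$ measured, in raw trait units.
* **Rao's Q**: $Q = \sum_i \sum_j p_i p_j d_{ij}$, the expected
  dissimilarity between two individuals drawn with replacement. Self-pairs
  contribute 0 and are included, so the convention is the full double sum,
  not $2\sum_{i<j}$. A monoculture has $Q = 0$.
* **Trait distances**: traits are z-scored over the measured species pool
  (sample SD, $n-1$; the pool, not per plot, so distances are comparable
  across plots). Single-trait dissimilarity is the absolute z-score
  difference. For multi-trait sets the z-scored block is rotated by a PCA
  with all axes retained and no rescaling before taking Euclidean
  distances; since a full-rank unscaled PCA is a rotation, this equals
  Euclidean distance on the z-scores, which the test suite checks as an
  invariance.
* **Phylogenetic distances** are cophenetic: the branch-length sum along
  the path between two tips of the ultrametric tree.
* **Focal dispersion** $Q^{spec}$: the abundance-weighted mean
  dissimilarity between an individual of a focal species and the other
  individuals of its plot, $\sum_{j \ne f} p''_j d_{fj}$ with weights
  renormalized over non-focal species. This is the abundance-weighted mean
  pairwise distance (MPD) of the focal species to its community.
  Conspecific pairs (distance 0) are excluded by default because the MPD
  analogy anchors that choice; `include_conspecifics = TRUE` switches to
  weighting over all individuals for sensitivity analyses.

Species with missing traits are dropped per metric with weight
renormalization. This is defensible when, as in the intended designs, trait
coverage concentrates on abundant species so that measured species represent
the bulk of individuals; with trait coverage biased against abundant species
the metrics would be correspondingly distorted.

## The damage-class calibration

Damage classes are 0%, <1%, 1–5%, >5–15%, >15–35% and >35% of leaf area
removed. Intervals are treated as left-open and right-closed (a measured
fraction of exactly 0.05 belongs to "1–5%"); the zero class is the
singleton {0}. Calibration is the per-class arithmetic mean of scanned
damage fractions, pooled over species, with the zero class fixed at 0.
A sapling's response is the mean calibrated value over its leaves, and the
sapling's leaf count is carried as the binomial trial weight.

## The mixed model

Per-sapling damage proportions $y_i$ with leaf counts $w_i$ are modelled on
the logit scale:

$$\mathrm{logit}(\pi_i) = \mathbf{x}_i^\top \beta + b_{species(i)} +
b_{plot(i)} + b_i,$$

with independent mean-zero Gaussian random intercepts for species, plot and
observation (OLRE). The likelihood is the proportional-binomial form
$w_i [y_i \log \mu_i + (1-y_i)\log(1-\mu_i)]$ plus a
gamma-function generalization of the binomial coefficient, so non-integer
success counts (calibrated class means are continuous) are handled
directly. The OLRE absorbs extra-binomial dispersion. A "saplings within
species" term is not offered separately: with one record per sapling it is
formally identical to the OLRE (two observation-level intercepts are one
intercept with summed variance), so adding it could only produce a boundary
fit.

**Fitting.** The marginal likelihood is approximated by a Laplace
(second-order) expansion of the joint log-likelihood around the conditional
mode of the random effects. The mode over fixed effects and random
intercepts jointly is found by penalized iteratively reweighted least
squares with step-halving. Because the OLRE design matrix is the identity,
its block is eliminated analytically: it enters the working normal
equations only through effective weights $W_i / (1 + \sigma^2_{obs} W_i)$,
leaving a small dense system in the fixed effects plus the species and plot
intercepts. The outer optimization runs over the log-SD parameters only
(Nelder–Mead for several components, golden-section for one), profiling
fixed effects inside the penalized step — the same fast profiling used as
lme4's `nAGQ = 0` path. We chose this over a joint outer optimization of
fixed effects and variance parameters because the Schur elimination makes
each profile evaluation a few dense solves, and the test suite cross-checks
the resulting coefficients and variance components against an independent
`glmer` implementation on simulated data.

Numerical choices: variance parameters live on the log scale with a floor
at $e^{-10}$; SDs below $10^{-3}$ are reported as 0 with a boundary flag;
the inner iteration stops at a relative penalized-deviance change of
$10^{-8}$ (at most 80 iterations); the outer relative tolerance is
$10^{-8}$ by default; initialization is deterministic (working response
from the data, all log-SDs at $\log 0.5$), so fits are reproducible and
row-order invariant. Wald standard errors come from the fixed-effect block
of the inverse joint observed information; P-values are two-sided normal.

**AICc.** $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the
number of saplings and $k$ the number of fixed effects (including the
intercept) plus the number of *estimated* variance components. The
convention for $k$ in mixed-model AICc is not unique; counting estimated
variance components matches common practice and is applied consistently,
which is what AICc comparisons require.

**Backward selection** deletes, at each step, the predictor whose removal
lowers AICc the most, stopping when no removal lowers it; interactions are
deleted before their main effects, and main effects are protected while
their interaction remains. For speed, candidate deletions are ranked with
variance parameters held at the current estimates (they move little between
adjacent nested models); shortlisted candidates are refitted with free
variance parameters and a deletion is applied only if the full refit
genuinely lowers AICc. When no shortlisted refit improves, all remaining
candidates are refitted before stopping, so the stopping rule is exact.
A known property of this (entirely standard) criterion is that a single
irrelevant predictor is retained whenever its Wald $\chi^2_1$ exceeds
roughly 2, which happens with probability about 0.16 under the null — AICc
is not a consistent selector, and the selection tests in this package
observe deletion rates near that theoretical ceiling of ~84%.

**Model sets.** Five families are compared after individual backward
simplification: (1) all predictors plus the richness-by-$Q_{phylo}$
interaction, (2) the abiotic PC1 plus all trait-based (functional) metrics,
(3) the abiotic PC1 plus the phylogenetic metrics, (4) the abiotic PC1 plus
species richness, (5) the abiotic PC1 alone. ΔAICc is relative to the best
minimal model, and Akaike weights are $\exp(-\Delta/2)$ normalized to 1.

## Predictor preparation choices

* The plot-characteristics PCA standardizes internally; PC1 is sign-fixed
  so stand age loads positively, making it a stand-age axis. Aspect enters
  untransformed; it is a circular variable, and users with strongly
  aspect-driven systems should pre-transform it themselves.
* The collinearity screen works on sapling rows (plot metrics joined to
  saplings), so plot-level correlations are implicitly weighted by sapling
  numbers. For each pair with |r| above the threshold (default 0.7) the
  member less correlated with damage is dropped, greedily from the worst
  pair, with a documented canonical ordering (plot covariates, CWM before
  Q before $Q^{spec}$, traits in table order) breaking exact ties so the
  result is deterministic.
* The abiotic PC1 is not a screening candidate in the full pipeline: it
  belongs to every model set by design (it absorbs plot-level confounding),
  so excluding it for collinearity with a diversity metric would leave the
  abiotic-only set empty.
* Standardization is z-scoring over sapling rows; the interaction column is
  the product of the two standardized mains, itself re-standardized.

## The synthetic-study generator

The generator produces complete studies with known truth, mirroring the
intended field design: 27 plots; a 147-species pool with lognormal base
abundances; per-plot richness uniform on 25–69; the 10 most abundant
species as focal species, forced present everywhere; at most 10 (by
default 3–10) saplings per focal species and plot; leaf counts lognormal
with mean 45.4 and SD 45.3, clipped at 1; 20% of species (rarity-biased,
never focal) with all traits missing. Traits evolve as correlated Brownian
motion on a pure-birth tree rescaled to depth 1, then map through fixed
monotone transforms into realistic ranges (leaf C into (35, 51) %); the
default trait correlation matrix includes chemical pairs above |r| = 0.7 so
the collinearity screen always has work to do. Plot characteristics follow
a latent stand-age axis so a dominant PC1 exists. True damage follows the
logit-linear model above with default standardized effects of ±0.08–0.19
(chemical trait diversity positive, CWM leaf C negative, richness positive,
and so on), intercept $\mathrm{logit}(0.08)$, and random-intercept SDs of
0.6 (species), 0.3 (plot) and 0.5 (observation) — magnitudes that put
species mean damage in the few-percent-to-one-fifth range typical of
subtropical forest saplings.

Each leaf is damaged with probability $\min(1, \pi/\bar{s})$ where
$\bar{s} = 0.25$ is the mean severity of damaged leaves; damaged leaves
draw a Beta-distributed severity (precision 4) whose mean is chosen so the
expected per-leaf damage equals $\pi$ exactly for every sapling. The
resulting fraction is discretized into the six classes, and calibration
scans are drawn from the same severity distribution conditioned on each
class, so calibrated class means estimate the correct conditional means.
Abundance distributions within plots (Poisson counts around lognormal base
weights) are a modelling convenience — the design states no empirical
distribution — and the generator makes no attempt at spatial structure,
succession, herbivore population dynamics, or intraspecific trait
variation. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *pipeline*, not the field realism of any
particular dataset.

One consequence of observing damage through visual classes deserves
emphasis: the per-leaf class-mean response is less variable than a binomial
leaf count, and the top class (">35%") truncates severe damage, so the
binomial-likelihood mixed model mildly attenuates the strongest positive
effects (on the order of ten percent of the true standardized effect in the
default design, as measured by the parameter-recovery test). This is a
property of the class-calibrated measurement process itself, shared by any
analysis of such data with binomial error, and should be kept in mind when
interpreting standardized effect sizes from visual damage surveys.

## Problem sizes in the test suite

The validation suite exercises: metric oracles on over a thousand random
small communities against individual-pair enumeration; rotation invariance
on 100 random trait tables; the fixed-effects-only limit against an
independent IRLS implementation on 20 datasets; parameter recovery over 100
replicate studies of the default 27-plot design; selection behaviour over
60 replicates at n = 500; and model-set ranking over 15 replicate studies
with 2–4 saplings per plot and species. These sizes are the package's
choices for a thorough-but-routine validation run; all thresholds are
stated in the tests themselves.

## Known limitations

* Phylogenetic uncertainty is ignored; the tree is taken as known.
* No spatial autocorrelation structure is available among plots.
* The Laplace approximation can bias variance components downward for
  small numbers of levels (10 species); fixed effects are the estimands of
  interest and are cross-checked by simulation.
* Wald confidence intervals for plot-level covariates are slightly
  anticonservative when the number of plots is small: the effective sample
  for such an effect is the number of plots (27 in the default design), and
  the recovery test measures coverage just below the nominal 95% for the
  species-richness coefficient. Inference on plot-level effects in designs
  of this size should be read with that in mind (a parametric bootstrap
  would tighten it, but is outside the scope of the Wald-based workflow).
* AICc-based backward selection retains noise predictors at the
  theoretical ~16% rate; it is a parsimony device, not an error-controlled
  test.
* The collinearity screen's outcome is data-dependent; which of a strongly
  correlated metric pair survives can differ between datasets.
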