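# herbdiv

Linking individual-level insect herbivory on woody-plant saplings to the
functional and phylogenetic diversity of the surrounding forest community.

`herbdiv` is aimed at community ecologists analysing forest-plot surveys in
which (i) leaf damage on saplings of a set of dominant focal species is
scored into visual percentage classes, and (ii) the surrounding community
is characterized by a species-by-trait table, a plot-by-species abundance
matrix, an ultrametric phylogeny and plot-level stand descriptors. The
package provides the full analysis chain as pipe-friendly functions on
tibbles, plus a synthetic-study generator with known ground truth so the
whole chain can be validated end to end.

## What it computes

**Community metrics** (all abundance-weighted by plot-level relative
abundances *p*):

- community-weighted mean traits: CWM<sub>t</sub> = Σ<sub>i</sub> p′<sub>i</sub> t<sub>i</sub>
- Rao's quadratic entropy: Q = Σ<sub>i</sub> Σ<sub>j</sub> p<sub>i</sub> p<sub>j</sub> d<sub>ij</sub>,
  for single traits (|Δz|), multivariate morphological and chemical trait
  groups (Euclidean distance over all axes of an unscaled PCA of the
  z-scored traits), and the phylogeny (cophenetic distances)
- focal-species dispersion Q<sup>spec</sup> = Σ<sub>j≠f</sub> p″<sub>j</sub> d<sub>fj</sub>,
  the abundance-weighted mean pairwise distance between a focal species and
  the rest of its community

**Damage calibration**: per-class mean scanned damage fractions turn the
six visual classes (0%, <1%, 1–5%, >5–15%, >15–35%, >35%) into per-sapling
mean damage proportions.

**Inference**: binomial (logit) mixed models of per-sapling damage with
crossed species and plot random intercepts plus an observation-level term,
fitted by a Laplace approximation implemented in the package; Wald z tests;
AICc-based backward simplification; and comparison of five nested predictor
families (all predictors / abiotic PC1 + functional metrics / + phylogenetic
metrics / + species richness / abiotic PC1 only) by ΔAICc and Akaike
weights. Per-species single regressions and partial residuals support
species-level and effect-display follow-ups.

## Worked example

Generate a synthetic study emulating the intended field design (27 plots,
147-species pool, 10 focal species), calibrate damage, compute metrics and
fit a model:

```r
library(herbdiv)

cfg    <- synthetic_config(seed = 42)
study  <- simulate_study(cfg)
#> Synthetic herbivory study (seed 42 )
#>   27 plots, 147 species pool, 10 focal species, 1706 saplings

cal    <- calibrate_classes(study$scans)
cal
#> # A tibble: 6 × 3
#>   class_label mean_fraction n_scans
#>   <chr>               <dbl>   <int>
#> 1 0%                0            25
#> 2 <1%               0.00553      25
#> 3 1-5%              0.0292       25
#> 4 >5-15%            0.104        25
#> 5 >15-35%           0.248        25
#> 6 >35%              0.544        25

survey  <- sapling_mean_damage(study$survey, cal)
metrics <- compute_all_metrics(study$communities, study$traits,
                               study$phylogeny, study$focal_species)
tab <- build_predictor_table(survey, metrics,
                             plot_pca(study$plot_characteristics)) |>
  standardize_predictors()

fit <- fit_binomial_glmm(tab, c("Q_chem", "CWM_C", "richness", "Qspec_phylo"))
fit
#> Binomial mixed model (Laplace approximation)
#>   n = 1706  logLik = -3378.34  AICc = 6772.77
#>   random-intercept SDs (logit scale):
#>      species = 0.5327
#>      plot = 0.3331
#>      obs = 0.2958
#> # A tibble: 5 × 5
#>   term        estimate std.error statistic  p.value
#>   <chr>          <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)  -2.27      0.181    -12.5   5.63e-36
#> 2 Q_chem        0.274     0.0679     4.03  5.48e- 5
#> 3 CWM_C        -0.158     0.0706    -2.24  2.53e- 2
#> 4 richness     -0.0676    0.0723    -0.935 3.50e- 1
#> 5 Qspec_phylo   0.199     0.0540     3.68  2.32e- 4
```

Reading the output: the intercept −2.27 is the logit of mean damage for an
average sapling (plogis(−2.27) ≈ 9% leaf area lost); the standardized
estimates say that one standard deviation more chemical trait diversity in
the community (`Q_chem`) raises damage by 0.27 logits, while higher
community-mean leaf carbon (`CWM_C`) lowers it — the generator's true
effects for this study were +0.19 and −0.19, with `Qspec_phylo` +0.14. The
random-intercept SDs partition the remaining variation among species, plots
and individual saplings.

The full five-model-set comparison, with screening and backward
simplification, is one call:

```r
run <- run_pipeline(run_config(synthetic = synthetic_config(seed = 42),
                               seed = 42, outdir = "herbdiv_run"))
tidy(run$comparison)          # Table-style results: model, term, Std. Est., SE, z, P, AICc, ΔAICc, weight
autoplot(run$comparison)      # ΔAICc / Akaike-weight plot
```

`run_pipeline()` writes `results_table.csv`, metric tables, the exclusion
log, partial residuals, a JSON fit dump and a manifest; rerunning with the
same seed reproduces the CSVs byte-identically. A thin command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

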