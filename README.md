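# beartroph

Bayesian hierarchical estimation of bear trophic position from diet
compositions and collagen δ¹⁵N, with full uncertainty propagation.

## The scientific problem

Bears span the whole herbivory–carnivory continuum, and individual
populations shift along it. This package implements two complementary
analyses of that flexibility, for macroecologists and paleoecologists
working with the corresponding data types:

**Macroecological model.** Annual diet compositions from scat and
stomach-content studies report, per food category *i*, the relative
frequency of occurrence *F<sub>i</sub>* and (in about half of published
records) the relative volume *V<sub>i</sub>*. Trophic position is the
dietary energy share of animal prey,

> *E<sub>i</sub>* = *c<sub>D<sub>i</sub></sub>c<sub>E<sub>i</sub></sub>V<sub>i</sub>* / Σ *c<sub>D<sub>i</sub></sub>c<sub>E<sub>i</sub></sub>V<sub>i</sub>*,  *P<sub>j</sub>* = Σ<sub>animal</sub> *E<sub>i</sub>*,

with digestibility (*c<sub>D</sub>*) and energy-content (*c<sub>E</sub>*)
corrections. Records lacking volumes have them imputed inside the model
through a hierarchy of per-record geometric-mean regressions of log *V* on
log *F*. The compressed, probit-transformed *P<sub>j</sub>* is regressed on
log₁₀ NPP, growing season length and co-occurrence with larger or smaller
bear species, with study and species random intercepts — all in one joint
posterior, so imputation uncertainty propagates into the effect estimates.

**Paleoecological model.** Collagen δ¹⁵N of brown bear (consumer) and red
deer (a strict herbivore, the isotopic baseline) over the last 55 ka is
corrected for material type (tooth vs bone) and elevation, and converted to
a per-period trophic position

> *TP<sub>j</sub>* = (consumer*<sub>j</sub>* − baseline*<sub>j</sub>*) / μ<sub>Δ</sub> + λ,  λ = 2,

where μ<sub>Δ</sub> is the trophic discrimination factor estimated from
predator–prey pairs. Period trophic positions are regressed on paleoclimate
NPP and growing season length within the same joint posterior.

Supporting machinery: collagen quality control (C/N 2.9–3.6, %C > 8,
%N > 3), a marine-resource screen, time-bin assignment over eight named
periods, equal-tailed intervals, probability of direction, posterior
predictive p-values, marginal/conditional R², variance inflation factors,
partial-residual plots, and seed-deterministic synthetic-data generators
with known ground truth for every stage. Models are fitted with JAGS via
rjags.

## Worked example

Simulate a small macroecological dataset with known effects (NPP −0.18,
GSL −0.41 on the probit scale), half the volumes missing, and fit it with
short chains:

```r
library(beartroph)

sim <- simulate_macro(macro_truth(n_obs = 80, n_studies = 60, n_species = 5,
                                  missingness = 0.5, seed = 42))
fit <- fit_macro(sim$data,
                 mcmc = mcmc_config(chains = 2, iterations = 4000,
                                    burn_in = 1000, thin = 2, seed = 42))
tidy(fit)
#> # A tibble: 5 × 9
#>   term        estimate eti50_lo eti50_hi eti90_lo eti90_hi    pd  rhat   ess
#>   <chr>          <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <dbl> <dbl> <dbl>
#> 1 (Intercept)  -0.534    -0.659  -0.422    -0.897 -0.210   0.994  1.10  49.6
#> 2 npp_s        -0.117    -0.161  -0.0721   -0.228 -0.00695 0.96   1.06 177.
#> 3 gsl_s        -0.460    -0.498  -0.420    -0.553 -0.364   1      1.05 233.
#> 4 subordinate  -0.539    -0.637  -0.440    -0.765 -0.305   0.999  1.01 146.
#> 5 dominant     -0.0246   -0.132   0.0833   -0.279  0.250   0.563  1.05 199.
```

Each row is a fixed effect on the probit scale for standardised predictors:
the posterior median, 50% and 90% equal-tailed intervals, the probability of
direction (`pd`, the fraction of draws sharing the median's sign), and
convergence diagnostics. Both environmental effects are negative — trophic
position falls as productivity and growing season length rise — and the 90%
intervals cover the generating truths. At these deliberately short chain
lengths the split-Rhat warning fires for the slow-mixing intercept;
`mcmc_config()` defaults (5 × 201,000, thinned by 100) resolve it.

```r
glance(fit)
#> # A tibble: 1 × 7
#>   n_datasets n_imputed   ppp r2_marginal r2_conditional max_rhat n_draws
#> 1         80        40 0.528       0.433          0.903     1.55    3000
```

A posterior predictive p-value near 0.5 indicates adequate global fit.
`plot_partial(fit, "gsl_s")` draws the component + residual plot.

The paleoecological side works the same way:

```r
paleo <- simulate_paleo(paleo_truth(seed = 7))   # 219 bears, 372 deer, 8 periods
pfit <- fit_paleo(paleo$samples, paleo$refs, paleo$period_env,
                  mcmc = mcmc_config(chains = 2, iterations = 3000,
                                     burn_in = 500, thin = 1, seed = 7))
pfit
#> Paleoecological trophic-position model
#>   identified periods: 8 of 8
#>   PPP (baseline, consumer): 0.5 0.5
#>
#>         period n_bear n_deer tp_median tp_eti90_lo tp_eti90_hi
#>           GI-1     27     46      2.77        2.65        2.92
#>   Greenlandian     28     47      2.19        2.08        2.29
#>           GS-1     27     47      2.85        2.72        3.00
#>   GS-2 to GI-2     27     46      2.20        2.09        2.32
#>   GS-3 to GI-8     27     46      2.78        2.66        2.94
#>  GS-9 to GI-14     27     46      2.20        2.08        2.30
#>     Meghalayan     28     47      2.23        2.11        2.35
#>  Northgrippian     28     47      2.72        2.59        2.86
```

A trophic position of 2 is a strict herbivore; values above 2 reflect
increasing animal-prey consumption. `tidy(pfit, "regression")` returns the
period-level NPP and GSL effects, `tidy(pfit, "corrections")` the tooth–bone
offset, elevation slope and trophic discrimination factor, and
`autoplot(pfit)` the trophic-position timeline.

End-to-end runs with artifact output (draw tables, summaries, QC reports,
diagnostics JSON, reproducibility metadata) are available through
`run_macro_pipeline()` / `run_paleo_pipeline()` with a YAML or list config.
Real data enter through `read_diet_table()` and `read_isotope_table()`;
supply calibrated digestibility/energy correction factors via the
categories table — the shipped defaults are documented placeholders.

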