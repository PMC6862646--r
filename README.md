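# geofgmc

Bayesian geo-additive modelling and mapping of female genital
mutilation/cutting (FGM/C) prevalence among girls in clustered
household-survey data.

## What problem this solves, and for whom

Survey programs such as the DHS record, per girl aged 0–14, whether
she has undergone FGM/C, alongside her mother's status and attitudes,
household covariates, and the sampling geography (region → cluster →
household). Epidemiologists and survey analysts who want to map where
risk is concentrated — and to separate *community normative influence*
(how many women around a girl are cut, support continuation, or see a
religious obligation) from residual *location* effects — need a model
that handles all of: binary outcomes, nonlinear covariate effects,
spatial autocorrelation between neighboring regions, region-level
heterogeneity, and change over survey waves.

`geofgmc` fits the structured additive logistic model

```
logit(p_i) = β0 + z_i'β + Σ_j f_j(x_ij) + f_y(t_i)
           + f_str(s_i) + f_unstr(s_i) + f_st(s_i, t_i)
```

where `z_i'β` are linear effects (reported as posterior odds ratios),
`f_j` are Bayesian P-splines (girl's/mother's age, ethnic
fractionalization index, community norm proportions), `f_str` is an
intrinsic Markov random field (ICAR) over the region adjacency graph,
`f_unstr` is iid region heterogeneity, `f_y` a smooth time trend, and
`f_st` a tensor-product region × time interaction. Estimation is exact
Gibbs sampling via Pólya–Gamma augmentation (no proposal tuning,
seed-reproducible draws). Model assessment uses DIC/pD and MCMC
effective sample size; outputs include posterior odds-ratio tables,
95%-credible significance classes per region (HIGH/LOW/NONSIG), and
predicted prevalence surfaces.

Because real FGM/C microdata are restricted, the package ships a
synthetic survey generator (`simulate_survey()`) that emulates
stratified two-stage cluster sampling, wave-specific outcome
definitions (eldest daughter / most recently cut daughter / all
daughters), missing attitude items in the 2003-style wave, and a known
ground-truth predictor — so the full pipeline is testable end to end.

## Worked example

```r
library(geofgmc)

sim   <- simulate_survey(generator_config(years = 2014L, seed = 1))
graph <- kenya_region_graph()
suite <- run_suite(sim$dataset, graph, c("A", "B"),
                   mcmc_config(3000, 500, 5, seed = 1))
suite$comparison
#>  model  dic    pd mean_ess
#>      B 1883 14.16    248.5
#>      A 2011 13.29    153.8
```

The dataset is 2,571 girl records in 80 clusters over 8 regions. Model
A uses the normative-influence variables only; model B adds the total
spatial effects and wins on DIC by ~128 points — the generator planted
a real spatial field, and DIC detects it. Model B's summaries:

```r
suite$fits$B$summary$por_table
#>         term      por    lower    upper
#> 1 mother_cut 6.022178 4.621184 7.777094
```

A girl whose mother is cut has about 6 times the odds of being cut
(95% CI 4.6–7.8); the generator's true odds ratio is exp(2) ≈ 7.4.

```r
suite$fits$B$summary$region_class
#>         region       mean      lower       upper  class
#> 1      Nairobi -0.8970218 -1.9849037  0.01371442 NONSIG
#> 2      Central  0.1973987 -0.3024160  0.69432563 NONSIG
#> 3      Eastern -0.6510742 -1.1306855 -0.09450352    LOW
#> 4   RiftValley  1.0234574  0.6862233  1.33073845   HIGH
#> ...
```

Regions classified HIGH have a 95% credible interval for their total
spatial effect entirely above zero (significantly elevated residual
risk); LOW entirely below; NONSIG otherwise. Against the generator's
ground truth:

```r
recovery_report(sim$truth, suite$fits$B$samples, suite$fits$B$frame)
#>        term truth posterior_mean   bias lower upper covered
#>  mother_cut     2           1.79 -0.213  1.53  2.05    TRUE
#> spatial field Pearson r: 0.931
#> prevalence RMSE: 0.0164
```

The posterior-mean spatial field correlates 0.93 with the planted one
and predicted reference-profile prevalence is within ~1.6 percentage
points RMSE of truth.

A thin command line mirrors this workflow
(`inst/cli/geofgmc.R`: subcommands `simulate`, `fit`, `suite`, `maps`,
`recover`, with `--seed`, `--iters`, `--burn-in`, `--thin`, `--level`,
`--out-dir`).

## Layout

- `R/` — data model and IO, community covariates (EFI, norm
  proportions), spatial graph (ICAR precision, Moran's I), smoothers
  (B-splines, RW penalties, tensor bases), design/MCMC, assessment,
  synthetic generator, suite runner.
- `src/` — exact PG(1, z) sampler (Rcpp).
- `inst/extdata/kenya_provinces.graph` — 8-province adjacency fixture.
- `vignettes/geoadditive-fgmc-modelling.Rmd` — model, priors,
  identifiability, generator design, validation rationale, limits.
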