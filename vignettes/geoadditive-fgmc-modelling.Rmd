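---
title: "Geo-additive Bayesian modelling of FGM/C prevalence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geo-additive Bayesian modelling of FGM/C prevalence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geofgmc)
```

## The problem

Female genital mutilation/cutting (FGM/C) is recorded in household
surveys such as the Demographic and Health Surveys as a binary status
per girl, with strong geographic clustering and powerful community-level
normative influences: the share of cut women around a girl, the share
who support continuation of the practice, and the share who believe it
is a religious obligation.  Mapping where the risk is concentrated — and
separating community norms from pure location effects — calls for a
regression that mixes linear covariate effects, smooth nonlinear
effects, and spatially structured random effects, estimated coherently.
`geofgmc` implements that model for clustered girl-level survey data,
together with everything needed to exercise it end to end without
restricted microdata: a survey generator with known ground truth.

## The model

For girl $i$ living in region $s$ at survey time $t$, the outcome
$y_i \in \{0,1\}$ (1 = cut) is Bernoulli with probability $p_i$, and

$$
\eta_i = \operatorname{logit}(p_i) = \beta_0 + z_i'\beta
 + \sum_j f_j(x_{ij}) + f_y(t_i)
 + f_{\mathrm{str}}(s_i) + f_{\mathrm{unstr}}(s_i)
 + f_{\mathrm{st}}(s_i, t_i).
$$

* **Linear block** $z_i'\beta$: dummy-coded categorical and binary
  covariates (mother's cut status, urban residence, religion,
  education, wealth quintile, ethnicity) under a diffuse Gaussian prior
  (variance $10^4$, configurable).  Effects are reported as posterior
  odds ratios: the posterior mean of $e^\beta$ with empirical 2.5% and
  97.5% quantiles.
* **Smooth terms** $f_j$: Bayesian P-splines.  Each covariate (girl's
  and mother's age, the ethnic fractionalization index, the three
  community norm proportions) gets a B-spline design on an equidistant
  knot grid and a random-walk prior on the coefficients.  Defaults are
  cubic splines with 20 inner knots and a second-order random walk —
  the convention of the structured-additive-regression software family
  this model descends from; knot count, degree, and penalty order are
  all configurable per term.
* **Structured spatial effect** $f_{\mathrm{str}}$: an intrinsic
  Markov random field (ICAR) over the region adjacency graph.  The
  full conditional of one region's effect given the rest is Gaussian
  with mean the neighbor average and variance $\tau_s^2 / N_s$ —
  neighboring regions borrow strength from each other.
* **Unstructured spatial effect** $f_{\mathrm{unstr}}$: iid Gaussian
  region heterogeneity, capturing non-spatial region-level variation.
* **Time and interaction**: a P-spline in survey year plus a
  tensor-product interaction whose first margin is the region
  indicator basis and whose second margin is the year spline.  Regions
  are areal units, so an indicator margin (rather than a spatial
  spline) is the natural construction for region-by-year prevalence
  surfaces.  The tensor penalty is the Kronecker sum of the ICAR
  precision (space margin) and the random-walk penalty (time margin).
* **Hyperpriors**: every variance parameter $\tau^2$ gets an
  inverse-gamma prior, IG$(a, b)$ with $a = 1$, $b = 5\cdot 10^{-4}$
  by default.

### The ethnic fractionalization index

For a community with ethnic-group shares $s_k$,
$\mathrm{EFI} = 1 - \sum_k s_k^2$ — one minus the Herfindahl
concentration.  It is 0 for a monoethnic community and $1 - 1/n$ for
$n$ equal groups.  "Community" is operationalized as the sampling
cluster (the survey's primary sampling unit), the closest available
analogue of a village or urban neighborhood.  Community norm
proportions are computed over the cluster's distinct mothers,
leave-self-in and unweighted by default; leave-one-out and
survey-weighted variants are available for sensitivity checks.

## Estimation

Posterior inference is by Gibbs sampling with Polya-Gamma data
augmentation: given latent $\omega_i \sim \mathrm{PG}(1, \eta_i)$, the
Bernoulli-logit likelihood becomes Gaussian in every coefficient
block, so each block (fixed, each smooth, spatial, tensor) has an
exact multivariate-normal full conditional, and each $\tau^2$ an exact
inverse-gamma one.  No proposal tuning is needed and a fixed seed
reproduces every stored draw bit for bit.  The PG(1, z) sampler is the
exact alternating-series method, implemented in C++ on R's RNG stream.

**Identifiability.**  The additive decomposition is only identified up
to level shifts, so the intercept absorbs the overall level and every
centered block — structured, unstructured, each smooth, the year
smooth, and the tensor block — is constrained to sum to zero.  The
constraint is enforced exactly on every draw by conditioning each
Gaussian full conditional on $A\beta = 0$ ("conditioning by kriging"),
where for the tensor block $A$ stacks both margin-sum constraints (one
redundant row dropped).  This also resolves the intrinsic prior's rank
deficiency: the ICAR precision has rank $S - 1$ on a connected graph,
and sampling under the sum-to-zero constraint works on exactly the
subspace where the prior is proper.

**Defaults.**  20 000 sweeps, 2 000 burn-in, thinning to every 50th
draw; initialization at zero coefficients and $\tau^2 = 0.1$.  Reduced
regimes (e.g. 5 000/500/5) are used for the package's replicate
simulations; the stored-draw count, not the raw sweep count, is what
matters for the summaries.

**Degenerate inputs.**  An all-0 or all-1 response is rejected; tied
or scarce distinct covariate values are allowed (the prior regularizes
the basis) but flagged; prediction points outside a training knot span
are clamped to the span with a warning; isolated regions are refused a
structured effect (their variation belongs to the unstructured term).

## Assessment

* **DIC**: $\bar D + p_D$ with $p_D = \bar D - D(\bar\eta)$, the
  plug-in evaluated at the posterior mean *linear predictor* — under
  sum-to-zero constraints this is well defined where a plug-in at raw
  coefficient means would not be.  A negative $p_D$ is reported with a
  warning, never clipped.
* **ESS**: $N / (1 + 2\sum_k \rho_k)$ with autocorrelations
  accumulated under Geyer's initial-positive-sequence rule.  Note that
  DIC's "effective number of parameters" and the MCMC "effective
  sample size" are different quantities; the package computes and
  labels both.
* **Significance maps**: a region is classified HIGH if the lower
  credible bound of its spatial effect exceeds zero, LOW if the upper
  bound is below zero, NONSIG otherwise — by default on the total
  (structured + unstructured) effect at the 95% level; a
  structured-only variant is a flag away.
* **Prevalence surfaces**: for a stated reference covariate profile
  (default: sample means for continuous covariates, modes for
  categorical ones) the per-draw $\eta$ is assembled for each region
  and year, inverted through the logit, and summarized.
* **Moran's I**: areal autocorrelation screening with binary
  (row-unstandardized) weights and a two-sided permutation test —
  permutation rather than the normal approximation because eight
  regions are far too few for asymptotics.

## The synthetic generator

`simulate_survey()` emulates the survey design the model assumes:
stratified two-stage cluster sampling over 8 regions (the shipped
adjacency encodes the standard contiguity of Kenya's eight former
provinces, an assumption since no authoritative adjacency table is
bundled with the survey data), clusters within regions allocated
round-robin to the survey waves, 25 mothers per cluster, daughters per
mother Poisson(1.3), ages uniform.  Region-varying ethnic mixtures
drive true EFI variation; mothers' cut status has region-varying rates
(0.15 to 0.8); attitude items correlate with cut status and are set
missing in the 2003-style wave, as in the real questionnaires.
Outcomes are drawn from the model's own predictor with known effects:
linear effects (mother cut $\beta = 2$, urban $-0.3$), centered smooth
shapes (increasing in girl's age, decreasing in mother's age, a
rise-then-fall EFI shape, a sharp rise of risk once the community cut
proportion passes roughly 55%), an ICAR-distributed structured field
($\tau_s = 1$), iid heterogeneity ($\tau_u = 0.3$), a declining time
trend, and a doubly centered space-time interaction.  Wave-specific
outcome definitions are applied afterwards: eldest daughter
(1998/2003-style), most recently cut daughter (2008-style — the eldest
daughter is emitted as uncut when no daughter is cut, a choice the
questionnaire descriptions leave open), or all daughters aged 0-14
(2014-style).  Log-normal(0, 0.3^2) survey weights exercise the
weighted descriptives.

These are documented simulation constants, not claims about Kenya.
What the generator does *not* emulate: real oversampling fractions,
household structure, non-response, reporting bias, or the
post-stratification behind real survey weights — so passing recovery
tests demonstrates correctness of the estimation machinery under the
model's assumptions, not robustness to the ways real data violate
them.

## Validation choices and what the checks mean

* **Sampler correctness** is established at desk scale against
  deterministic quadrature (intercept-only and two-parameter logistic
  models), with agreement required within three Monte-Carlo standard
  errors, and by exhaustive agreement of the ICAR conditional with
  precision-matrix conditioning over every connected labeled graph on
  up to five regions.
* **Field recovery** is measured by the Pearson correlation between
  posterior-mean and true total spatial effects, pooled over three
  full-size replicates: a single 8-region field provides too few
  points for a stable correlation, and weak field realizations make
  single-replicate correlations erratic at no fault of the sampler.
* **Interval calibration** is checked at null signal (vanishing field,
  zero smooth shapes), where the fitted model is exactly the
  data-generating process.  Under a strong field, the generator's
  regionally graded mother-cut rates are collinear with the region
  effects; shrinkage of the spatial block then tightens fixed-effect
  intervals below their frequentist spread (measured coverage around
  0.86 at default signal).  This is a known and documented trade-off
  of hierarchical spatial shrinkage in this design, not an estimation
  bug.
* **Model selection** is exercised where it should discriminate: with
  a structured field at twice the default scale plus covariate
  effects, the fully adjusted model must beat the normative-only model
  on DIC in at least 90% of replicates; at null spatial signal, DIC
  must not systematically favor the spatial model.  At the *default*
  field scale the comparison is genuinely ambiguous, because the
  community cut proportion is itself a regionally structured covariate
  that proxies much of the spatial signal — an instructive property of
  normative-influence covariates, not a test failure.
* **Problem sizes**: replicate fits use 8 regions x 4 clusters x
  10-12 mothers and 1 000-1 200 sweeps; full-size fits use the default
  8 x 10 x 25 design (~2 600 girls) and 5 000 sweeps.  These sizes
  were chosen so that a complete validation pass is a coffee-break
  affair while remaining large enough for the asserted properties.

## Missing data policy

The 2003-style wave lacks the two attitude items.  At the data layer
the values stay explicitly missing — nothing is imputed.  Model
fitting is complete-case on the covariates the specification uses,
with dropped-record counts reported; a suite comparison additionally
takes complete cases on the *union* of its members' covariates so that
every member is fitted to the same records and DIC values are
comparable.  The practical consequence: pooled suites that smooth the
attitude proportions exclude the 2003-style wave.  An analyst who
wants that wave in a pooled fit should drop the attitude smooths from
the specification.

## Known limitations

* Mothers with several eligible daughters contribute one record per
  daughter; no within-mother random effect is fitted (the observed
  mother-level covariates carry that correlation in the model).
* Alternative spatial priors (Gaussian random fields, Leroux,
  convolution) are out of scope; the ICAR + iid pair is the only
  spatial structure offered.
* The CLI and suite runner derive per-model seeds deterministically
  from one run seed; runs are bit-reproducible on a fixed platform,
  but floating-point reproducibility across BLAS builds is not
  guaranteed.
* Single-chain estimation with ESS reporting follows the design it
  implements; no multi-chain convergence diagnostics are included.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_survey(generator_config(years = 2014L, seed = 1))
graph <- kenya_region_graph()

suite <- run_suite(sim$dataset, graph, c("A", "B", "C"),
                   mcmc_config(5000, 500, 5, seed = 1))
suite$comparison

fitC <- suite$fits$C
fitC$summary$por_table       # posterior odds ratios
fitC$summary$region_class    # HIGH / LOW / NONSIG per region
recovery_report(sim$truth, fitC$samples, fitC$frame)
```
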