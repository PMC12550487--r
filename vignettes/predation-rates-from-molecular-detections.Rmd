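---
title: "Estimating predation rates from binary molecular gut-content data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating predation rates from binary molecular gut-content data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Molecular gut-content assays (multiplex PCR and kin) tell us whether a
predator carries detectable DNA of a given prey — a binary answer. The
quantity of ecological interest is the **predation rate** λ: how many prey
items of that type the predator consumes per unit time. The two are
separated by digestion: a meal stops being detectable after a while, so a
negative test may mean "did not eat" or "ate too long ago". `predrate`
bridges the gap by modelling both processes and fitting them jointly to
two data sources:

* a **feeding trial**, where predators are fed a known prey and tested at
  scheduled delays after the meal, which identifies how fast the molecular
  signal decays, and
* **field captures**, where each individual is tested once, with no
  knowledge of its feeding history, which identify the predation rate
  once the decay is known.

## The model

**Digestion.** The probability that a meal is still detectable `t` hours
after ingestion follows a logistic decay,

$$\operatorname{logit} \pi(t) = \beta_0 - \beta_1 t, \qquad \beta_1 > 0,$$

with `beta0` the log-odds of detection immediately after the meal and
`beta1` the decay slope per hour. Each feeding-trial test at delay `d` is
Bernoulli(π(d)).

**Predation.** Predation events are assumed independent, one prey item per
event, at constant intensity — a homogeneous Poisson process with rate λ
per hour. The rate is constant in time (steady-state assumption); the
package reports rates per day as 24λ.

**Field detection.** A meal taken `u` hours before capture is still
detectable with probability π(u). Thinning the Poisson process by π leaves
the number of *detectable* meals Poisson with mean λ·I, where

$$I = \int_0^\infty \pi(t)\,dt = \frac{\log(1 + e^{\beta_0})}{\beta_1}$$

is the **detectability integral** — the effective detection window of the
assay in hours, computed in closed form by `detectability_integral()`
(stable `log1p`-based formulation; the closed form is verified against
adaptive quadrature in the test suite to 1e-8 relative error). A binary
field test is positive as soon as one meal is detectable:

$$\Pr(\text{positive}) = p(I) = 1 - e^{-\lambda I}.$$

**Effects and hierarchy.** With several prey `p` and predator species `c`,
the pair-level parameters decompose additively:

$$\beta_0(p,c) = \alpha_{\beta_0}(p) + \delta_{\beta_0}(c) + \gamma_{\beta_0}(p,c),
\qquad
\ln \lambda(p,c) = \alpha_{\lambda}(p) + \delta_{\lambda}(c) + \gamma_{\lambda}(p,c),$$

and `beta1` is log-normal with a single shared family (one `log_beta1` per
pair, common location and scale). Predator effects, interaction effects
and `log_beta1` are **hierarchised**: drawn from Normal distributions
whose scale is estimated at the level of the whole species group, so
information flows from well-sampled species to species caught once or
never. Prey effects are few and heterogeneous, so they are *not*
hierarchised; they carry fixed Normal(0, 2) priors on the logit/log scales.

## Priors, identifiability and parameterisation

The additive decomposition is translation-invariant: adding a constant to
all predator effects and subtracting it from the prey effects leaves the
likelihood unchanged. Weak priors alone regulate this ridge poorly — in
early runs the location hyperparameter of the predator-λ family showed
potential scale reduction factors near 2 while every pair-level composite
had converged. The package therefore:

* pins the family-level **locations** of the predator and interaction
  effects at zero (the overall level is carried by the prey effects), and
* applies a **sum-to-zero constraint** to the predator effects inside the
  sampler, which removes the ridge completely, and
* uses a **non-centred parameterisation** for the interaction effects,
  whose per-family information is weakest and which otherwise sit in a
  funnel with their scale.

Family scales have half-Normal(1) hyperpriors; the `log_beta1` location
has a Normal(0, 1) hyperprior. All constants are overridable through
`default_hyperpriors()` or the YAML configuration
(`write_config_template()`). These are weakly-informative choices on
logit/log scales: e.g. the implied prior on a pair's daily rate spans
roughly four orders of magnitude around 1 event per hour. Because the
exact values any particular study would use are application-specific,
sensitivity of rare-species estimates to the scale hyperpriors should be
checked (refit with, say, half-Normal(0.5) and half-Normal(2)) rather than
assumed.

## Sampling and convergence

`fit_model()` aggregates Bernoulli rows into binomial cells per
(pair, delay) and per pair — an exact likelihood rewrite that keeps the
JAGS graph small — and runs 3 Markov chains (JAGS 4, Gibbs/slice updates).
Defaults are 4000 warmup plus 30000 kept iterations thinned by 5, and the
chains are **extended automatically** until the rank-normalised split
R-hat of every monitored parameter falls below 1.01 (or a cap is hit).
These are deliberately longer runs than a gradient sampler would need:
one-at-a-time updates mix slowly across hierarchical scale parameters.

The reported diagnostic is the rank-normalised split R-hat, which is
well-behaved for the heavy-tailed posteriors of scale parameters; the
classic Gelman–Rubin statistic is available for comparison
(`gelman_rubin(fit, method = "classic")`) and is the conventional < 1.01
acceptance gate. On identical-copy chains the classic statistic is
returned as 1 (zero between-chain variance).

Goodness of fit is assessed by `posterior_predictive_check()`: for every
(species, prey) pair the observed frequency of positive field tests is
compared with the posterior distribution of p(I), reporting the fractions
of pairs falling inside the central 95% and 50% intervals.

Summaries (`fit_report()`) use **lower-interpolation quantiles** (type 1)
so that reported medians and interval bounds are attained posterior draws
and exactly reproducible.

## The event-based simulator

`simulate_field_tests()` does not use the closed form: it draws actual
predation events over a look-back window before capture, tests each event
for detectability with probability π(elapsed), and reports whether any
survived. That makes it an *independent oracle*: with independent events
its positive frequency must converge to `1 - exp(-lam * I)`, and the test
suite holds it to within 3 Monte-Carlo standard errors at n = 20,000.

* **Look-back window.** Events are simulated on `[capture − W, capture]`
  with `W = (|beta0| + 10)/beta1`, beyond which π < 4.5e-5; doubling W
  changes frequencies by less than Monte-Carlo noise (tested).
* **Aggregation.** `cluster_mean = k` relaxes the one-item-per-event
  assumption: events become clusters of several items ingested together
  (mean size k, shifted-geometric interpretation), arriving at rate λ/k so
  the *consumption* rate is unchanged. A cluster's pooled molecular signal
  decays as one, so it offers a single detection opportunity. Fitting the
  independent-event model to aggregated data therefore estimates the
  cluster arrival rate; multiplying the posterior rate by the mean cluster
  size recovers the consumption rate (the acceptance suite holds this to
  within a factor 1.5 at k = 3).
* **Study-like scenario.** `make_study_like_scenario()` emulates a
  25-species, 5-prey ground-beetle community: field sample sizes declining
  geometrically from 657 to 1 (~1530 individuals in total), daily rates
  ~0.02–5 per day, prey digestibility spanning half-lives of ~6 h to
  ~60 h with pair-level spread. What the simulator does *not* emulate:
  temperature- or season-dependent rates, trap-capture timing, meal-size
  (voracity) variation, cross-prey dependence within an individual, and
  imperfect assay sensitivity/specificity. Passing tests on simulated data
  therefore validate the estimator under its own assumptions, not the
  assumptions themselves.

## The biocontrol indicator

`biocontrol_indicator()` aggregates to community scale:

$$\lambda_{com,p} = \sum_{c} \lambda_{c,p} A_c,$$

with `A_c` the abundance (activity-density) of species `c`. It is
evaluated on 100 joint posterior draws by default (configurable), so
cross-species correlation is preserved; predation rates are held constant
across communities and seasonality enters through the abundances only.
`rough_indicator()` is the frequency-based comparator — abundances
weighted by raw detection frequencies, read per day. Whenever the
detectability window I is shorter than 24 h the rough value is biased
down, and the shorter the window the larger the gap; the acceptance suite
reproduces this ordering on a study-like scenario with all I < 24 h.
Pooled (not per-session) frequencies are used, matching the
constant-rates convention.

## Numerical choices and degenerate inputs

* `log(1 + e^x)` and the logistic are computed with overflow-safe
  branches (exact to double precision for |x| up to ~700).
* A field dataset with all tests positive triggers a saturation warning:
  p(I) → 1 carries no upper information about λ.
* λ = 0 is valid in the simulator and the likelihood (an all-negative
  pair has log-likelihood 0 under λI = 0).
* A predator present in only one dataset is retained; the hierarchy
  supplies the missing arm. A predator with zero field rows gets a proper,
  hierarchy-informed posterior whose spread exceeds that of well-observed
  species (tested).
* Unknown species/prey labels, non-binary detections, negative times and
  duplicated (individual, prey) rows are validation errors that name the
  offending rows; rows are never silently dropped.

## Problem sizes used by the checks

The test suite refits the model on 20 simulated replicates of a
4-observed-predator × 2-prey community (300 field individuals per
predator, 30 feeding-trial tests per pair over delays 2–72 h) plus one
predator with no field data; `scripts/acceptance.R` runs 12 such
replicates and one 25 × 5 study-like indicator comparison (3 × 6000
draws, no gate extension — the underestimation contrast is large and
robust to a coarse posterior). These sizes are the package's choice of a
desk-scale experiment with tight-enough Monte-Carlo error for the bands
being checked.

## Known limitations

* Constant λ and digestion parameters (steady state); no covariates on
  either. Refit on data subsets to explore, e.g., seasonal variation.
* The assay is assumed perfectly specific and sensitive; a
  detection-floor/ceiling extension would change `p(I)` and Eq-level code
  in `model_core`.
* Gut samples only: a faecal assay with delayed peak detectability would
  need a right-skewed decay curve instead of the logistic.
* The indicator is a rate times an activity-density — a *relative*
  pressure index, not prey killed per unit area (that needs true predator
  density).
* With saturated detections (few negatives) the rate is only bounded
  below; quantitative assays are the way out in that regime.
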