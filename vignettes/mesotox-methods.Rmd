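---
title: "Models and methods for the diquat mesocosm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the diquat mesocosm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mesotox reimplements the statistical analysis of a replicated outdoor
mesocosm experiment on the aquatic herbicide diquat: 30 tanks (a control
and five treatments in geometric progression from 74 to 1153 µg/L nominal,
five replicates each) holding caged amphipods (*Hyalella azteca*, two
cages of 20 per tank, survival checked at 2/4/6 weeks), northern leopard
frog tadpoles (15 per tank), and naturally colonizing phytoplankton.
This vignette explains each model, its assumptions, the tunable parameters,
the numerical choices made where the design was open, and what the
synthetic-data generator does and does not emulate.

## The hormetic survival model for amphipods

Amphipod survival rises at low diquat concentrations and collapses at high
ones — a hormetic (biphasic) response. Rather than a dedicated hormesis
likelihood (e.g. Brain–Cousens), survival is modeled directly as a
binomial response with a quadratic polynomial on the logit scale:

$$ y_{ij} \sim \mathrm{Binomial}(n_{ij},\, p_{ij}), \qquad
   \mathrm{logit}(p_{ij}) = \beta_0 + \beta_1 x_i + \beta_2 x_i^2 + u_i $$

where $x_i = \log_2(c_i + 1)$ is the transformed diquat concentration of
tank $i$ (the +1 places the control exactly at the intercept), $j$ indexes
cages, and $u_i \sim \mathcal N(0, \sigma^2)$ is a tank-level random
intercept absorbing extra-binomial variation. Cages within a tank share
the tank effect. By default each exposure week is fitted separately
(`week_structure = "separate_fits"`); a joint model with week-specific
intercepts and shared slopes is also provided for the week-6-vs-week-2
intercept contrast.

The quadratic form makes every toxicity metric a closed-form function of
the coefficients, so each posterior draw yields a draw of the metric and
uncertainty propagates exactly:

* control survival $p_0 = \mathrm{logit}^{-1}(\beta_0)$ for an average
  tank ($u = 0$);
* LC$_x$: the descending-limb root of
  $\beta_2 x^2 + \beta_1 x + (\beta_0 - \mathrm{logit}((1-f)p_0)) = 0$,
  back-transformed by $c = 2^x - 1$. LC$_x$ is defined *relative to the
  control level* $(1-f)\,p_0$ (an absolute-probability definition is a
  switch), because the stimulation limit is also defined relative to
  control and the two should refer to the same baseline;
* peak of stimulation $x^\ast = -\beta_1 / (2\beta_2)$;
* limiting concentration of stimulation $x_{\lim} = -\beta_1/\beta_2 =
  2x^\ast$, the non-zero root of $\beta_1 x + \beta_2 x^2 = 0$, i.e. where
  survival returns to the control level. On the concentration scale this
  means $c_{\lim} = (c^\ast + 1)^2 - 1$, an identity the tests verify on
  every posterior draw.

Draws in which a metric does not exist (no real non-negative root, or the
wrong curvature sign) are excluded and the `fraction_defined` is reported;
summaries flag metrics defined in fewer than 90% of draws. All intervals
are 95% highest-density continuous intervals (the shortest contiguous
interval holding 95% of the draws, leftmost window on ties).

### Priors and sampler

Priors are weakly informative on the logit scale: $\mathcal N(0, 2.5)$ on
$\beta_0, \beta_1, \beta_2$ and half-$\mathcal N(0, 1)$ on $\sigma$. At
the observed effect sizes ($|\beta_1| \approx 3$) the $\beta$ prior exerts
mild shrinkage; the parameter-recovery suite verifies that 95% HDIs still
cover generating values at the nominal rate under the full design.

Sampling uses a purpose-built adaptive Metropolis-within-Gibbs sampler
(compiled C++), designed around this posterior's specific geometry:

* the regression block is updated jointly with a random-walk proposal
  whose covariance is adapted (Haario-style) during warmup, **in the
  QR-orthogonalized basis** of the design — the raw $x$ and $x^2$ columns
  induce a posterior correlation close to $-1$ that defeats random-walk
  proposals on the natural scale;
* tank effects use the non-centered parameterization $u = \sigma z$,
  removing the funnel between the effects and their scale, with
  conditionally independent per-tank updates;
* two likelihood-invariant "ridge" move families accelerate the slow
  directions: a $\sigma$/z rescaling that holds $u = \sigma z$ fixed, and
  translations $\beta \mathrel{+}= \delta d$, $z \mathrel{-}= \delta
  w/\sigma$ for each design direction $d$ (valid because every covariate
  is constant within tanks). These matter when a deliberately
  misspecified model (the linear form on hormetic data) inflates
  $\sigma$ to absorb lack of fit;
* all adaptation stops at the end of warmup, so retained draws come from
  a fixed-kernel chain.

Defaults are 4 chains × 3000 warmup + 8000 retained draws (about 2 s for
all three weeks), gated at split-$\widehat R < 1.01$ for every monitored
parameter with effective sample sizes reported; the fit fails loudly on a
gate violation unless overridden. Chain lengths are longer than an
HMC-based fit would need because a random-walk kernel has higher
autocorrelation; the gate, not the length, is the contract.

### Model comparison by exact leave-one-out

Candidate dose shapes (quadratic, linear, null) are compared by exact
LOO cross-validation: for every cage×week record the model is refit
without it and the record is scored by its log predictive density
$\log \frac1S \sum_s P(y_i \mid \theta^{(s)})$, with the tank effect taken
from the refit (the tank's other cage keeps it informed) or integrated
over $\mathcal N(0, \sigma^2)$ if the tank vanished from the training
set. Pairwise elpd differences carry standard errors from the pointwise
contributions. Refits use reduced settings (2 chains, 2000 + 3000) gated
at $\widehat R < 1.02$ with one doubled-length retry; a shared per-fold
seed stream makes identical specifications give an elpd difference of
exactly zero. The full 3-model comparison refits 540 models in about 80 s.

## Mixed models for the other endpoints

All remaining endpoint models are standard likelihood fits, delegated to
lme4 (Laplace GLMMs, REML/ML LMMs) behind thin wrappers that add the
observation-level random effect, AICc accounting, and conditional
($u = 0$, "average mesocosm") predictions:

* **tadpole survival** — binomial GLMM with a tank random intercept;
  null, linear and quadratic dose shapes compared by AICc with the
  ΔAICc < 2 equivalence convention. AICc comparisons always use ML;
  reported coefficients may use REML. AICc is
  $-2\ell + 2k + 2k(k{+}1)/(n{-}k{-}1)$;
* **development rate** — (final Gosner − initial)/days on the log2 scale;
  the initial stage is taken as 25 (release window 25–27, configurable).
  Because the observed acceleration is consistent across all treated
  groups, the stage compares a log-linear dose shape against an
  any-exposure step (and a null) by AICc and reports predictions from the
  winner — a linear-in-dose model fitted to step-structured data would
  bias both endpoint predictions toward each other;
* **mass and HSI** — log2 LMMs with dose plus linear and quadratic Gosner
  terms (mass rises then falls across late development). Coefficients on
  the log2 scale are percent-per-doubling effects: $100(2^b - 1)$. HSI is
  100 × liver mass / body mass (the standard convention);
* **sex ratio** — female vs not, restricted to Gosner ≥ 36 where
  morphological sexing is reliable; the tank random effect is dropped
  automatically when the mixed fit fails to converge;
* **amphipod growth** — one-way ANOVA of log2 wet weight with Tukey HSD
  (tank-level mixed fits did not converge in the original study design);
* **reproduction** — binomial GLMM with an observation-level random
  effect; successes are juvenile counts and trials juveniles + surviving
  adults (the proportion-of-juveniles definition is not fully pinned down
  and is configurable);
* **oxidative stress** — pooled-liver values compared by Kruskal–Wallis;
  means reported with BCa bootstrap intervals (bias term $z_0$ from the
  bootstrap distribution's position of the estimate, acceleration from
  jackknife skewness), deterministic under a fixed seed;
* **multiple comparisons** — Holm–Bonferroni step-down adjustment.

## Community analytics

Phytoplankton counts per tank and day form tank × taxon matrices.
Shannon diversity uses the natural log. Diversity is modeled by least
squares with a treatment × day interaction; treatment-vs-control
contrasts within each day are computed directly as linear combinations of
the coefficients with delta-method standard errors (checked against
emmeans in the tests) and Holm adjustment. Composition analyses use
Bray–Curtis dissimilarities on raw counts (a transform switch exists;
the counting effort of ≥ 300 cells per sample makes raw counts
defensible), NMDS (k = 2, 50 random starts plus a metric-scaling start,
stress < 0.1 read as a reliable ordination), one-way PERMANOVA with
freely permuted labels per day, and dispersion-homogeneity tests
(group centroids in principal-coordinates space) so that significant
PERMANOVA results can be read as location effects. All of these stand on
vegan, the same engine the original analysis used; the test suite checks
them against independent recomputations (stress-1 from its definition,
classical ANOVA F on Euclidean toy data).

## Exposure fate

Measured 1-h concentrations are summarized as percent of nominal over the
25 treated tanks. Dissipation is summarized per treatment by a
least-squares fit of log concentration on day over *uncensored* points
(DT50 = ln 2 / k). Below-detection values (reporting limit 5 µg/L) are
stored at the detection limit with a censoring flag — never as zero — and
excluded from kinetic fits rather than substituted at half the limit;
with at most two censored points per series the simple, transparent rule
was preferred.

## The synthetic experiment generator

`simulate_experiment()` generates the full dataset under the documented
study conditions, which are the package defaults: 84 ± 10% (per-tank SD)
of nominal at 1 h; dissipation half-lives of 2 d (three lowest
treatments) and 3.5 d (two highest), reproducing detection at day 21 only
in the two highest treatments; amphipod survival on per-week hormetic
curves solved exactly from (control survival, peak concentration, LC50) =
(0.82, 10, 170), (0.67, 10, 162), (0.60, 10, 155) for weeks 2/4/6 — the
week-4 LC50 interpolates the reported 2- and 6-week values — with tank
effects of SD 0.3 and cumulative (conditional-binomial) counts across
check weeks; tadpole survival logit-linear from 77.5% to 90.0%;
development at 0.092 stages/day jumping to 0.333 for any exposure (plus a
small configurable log-linear term); mass +2.29% per concentration
doubling on top of a quadratic Gosner profile; stress markers lognormal
and treatment-independent, centered on the reported means (HNE 323.8 µg/g
ww, protein carbonyl 1.19 nmol/mg). `solve_beta_from_metrics()` inverts
the quadratic so the generating coefficients reproduce the stated metrics
exactly through the closed forms; the implied peak survival is a
consequence of the quadratic family and is accepted as such. One
consequence worth noting: these curve parameters put week-6 survival at
the 474.6 µg/L treatment near zero, so synthetic growth data typically
span four diquat treatments rather than five.

Where the study conditions do not pin a parameter down, values were fixed
once at magnitudes a mesocosm ecologist would call realistic and then
left alone: the phytoplankton pool is 12 taxa with a Dirichlet-
multinomial tank-to-tank structure (concentration parameter 9) whose
tolerant-taxa share follows a logistic curve in transformed dose after
day 0 (over 40% in the lower treatments and over 90% in the two highest
at day 7), partially converging by day 41 while the control community
drifts toward dominance as well; the reproduction effect (log-linear
slope 0.10 per doubling with observation-level noise 0.4) was set so the
treatment-vs-null AICc margin matches the strength of evidence reported
for that endpoint; chlorophyll is proportional to total biomass with
lognormal noise chosen to give a biomass–chlorophyll R² near 0.55.

`simulate_null_experiment()` zeroes every treatment effect through the
same code path (flat survival curves via an infinite LC50, no development
step, no composition shift) and feeds the type-I-error suites.

What the generator does **not** emulate: dissolved-oxygen/pH dynamics,
nutrient pulses, macrophyte decay (out of scope), immigration of nuisance
species (*Daphnia*, dragonfly larvae, fish), time-varying exposure within
a week, or between-cage differences beyond binomial noise. Passing tests
therefore demonstrate that the *statistical machinery* recovers known
structure of the assumed forms at the study's design size — not that the
original field data satisfy those forms.

## Problem sizes and numerical choices

The test and acceptance suites fix their problem sizes as package policy:
parameter recovery uses 200 replicate experiments at the full 30-tank
design with reduced MCMC (2 chains, 1500 + 2500); type-I-error checks use
500 null experiments with 199-permutation PERMANOVA (resolution 0.005)
and pooled raw contrast p-values; the exact-LOO comparison runs the full
540 refits. Bisection oracles verify closed forms to 1e−8 in transformed
dose. NMDS convergence follows vegan's defaults with stress change
< 1e−6 between restarts; ties in the HDI window take the leftmost
interval; degenerate inputs (all-tied ANOVA/Kruskal data, constant
bootstrap samples, zero dissipation slopes) return the documented
boundary values rather than erroring.

## Known limitations

* The original Bayesian model's exact priors and week structure live in a
  supplement that is not part of the package's sources; the priors above
  are declared substitutes, and both week structures are exposed.
* LC50s estimated under the relative-to-control definition differ from
  absolute-probability LC50s when control survival is well below 1; the
  switch is provided, and comparisons with published point values should
  bear the ambiguity in mind.
* Data-dependent statistics of the original experiment (an exact ANOVA F,
  an exact ΔAICc) are not reproducible from synthetic data; the pipeline
  reports their computed analogues.
* The sampler is specialized to this model family; it is not a
  general-purpose MCMC engine.
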