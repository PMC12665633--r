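# mesotox

Statistical analysis of chronic diquat effects on non-target biota in
outdoor mesocosms.

Diquat is a fast-dissipating contact herbicide applied directly to water
bodies to control invasive aquatic plants. A replicated mesocosm
experiment — a control and five diquat treatments (74–1153 µg/L nominal,
a geometric series up to the full label rate), five tanks each — exposed
caged amphipods (*Hyalella azteca*), northern leopard frog tadpoles
(*Rana pipiens*) and naturally colonizing phytoplankton for six weeks.
This package implements the complete statistical pipeline for such an
experiment and a synthetic-data generator that reproduces its structure,
so every stage is testable end to end without the original raw data.

## What's inside

The scientific core is a Bayesian hormetic concentration–response model
for amphipod survival. Survival is binomial with a quadratic polynomial
on the logit scale in the transformed dose `x = log2(c + 1)`:

```
y ~ Binomial(n, p),   logit(p) = b0 + b1*x + b2*x^2 + u_tank,
u_tank ~ Normal(0, sigma^2)
```

Because the dose–response is a parabola on the logit scale, every
toxicity metric is a closed-form function of `(b0, b1, b2)` and becomes a
posterior quantity with exact uncertainty propagation: LC10/LC25/LC50
(descending-limb roots, defined relative to control survival), the peak
concentration of hormetic stimulation `x* = -b1/(2 b2)`, and the limiting
concentration of stimulation `x_lim = 2 x*` where survival returns to the
control level. Sampling uses a purpose-built adaptive
Metropolis-within-Gibbs sampler in compiled C++ (QR-orthogonalized
coefficient block, non-centered tank effects, likelihood-invariant ridge
moves), gated at split-Rhat < 1.01. Model variants (quadratic vs linear
vs no effect) are compared by *exact* leave-one-out cross-validation —
every one of the 540 fold-model refits is a genuine refit.

Around that core: lme4-backed GLMMs/LMMs for tadpole survival,
development rate, mass, hepatosomatic index and sex ratio (AICc model
selection, conditional "average mesocosm" predictions, BCa bootstrap
intervals, Kruskal–Wallis, Holm–Bonferroni); vegan-backed community
analytics (Shannon diversity contrasts, Bray–Curtis NMDS, PERMANOVA,
dispersion homogeneity); exposure-fate summaries with detection-limit
censoring; and `simulate_experiment()` / `simulate_null_experiment()`,
which generate complete synthetic experiments under the documented study
conditions.

## Worked example

```r
library(mesotox)

ds  <- simulate_experiment(sim_config(seed = 1))   # 30-tank experiment
obs <- survival_observations(ds)
set.seed(1)
fit <- fit_hormetic_model(obs)                     # ~2 s, 4 chains
fit
#> Hormetic survival model (quadratic, separate_fits)
#> Weeks: 2, 4, 6
#> Draws: 32000 ( 4 chains )
#> Max split-Rhat: 1.0025 ; min ESS: 1846

derived_metrics(fit, week = 6)[, 1:5]
#>              metric week      median     hdi_low    hdi_high
#> 1  control_survival    6   0.5822531   0.4986412   0.6620336
#> 2              LC10    6 117.7438745 107.0276220 128.4345896
#> 3              LC25    6 126.9287663 116.9863917 138.1113768
#> 4              LC50    6 144.5331238 133.7998353 156.9755535
#> 5 stimulation_limit    6 111.7966540 101.1511511 123.4682456
#> 6         peak_conc    6   9.6205769   9.1069853  10.1565338
#> 7     peak_survival    6   0.9967401   0.9928079   0.9991753
```

The week-6 posterior median LC50 of ~145 µg/L says that six weeks after a
single application, the diquat concentration halving amphipod survival
relative to control is roughly 13–14% of the label-rate concentration;
the peak near 10 µg/L and the stimulation limit near 112 µg/L bracket the
hormetic window in which survival sits *above* the control level. (Exact
numbers vary with the simulation seed.)

The full analysis is organised as numbered drivers:

```sh
Rscript analysis/01_simulate.R    # generate + validate the dataset
Rscript analysis/02_exposure.R    # percent-of-nominal, DT50, censoring
Rscript analysis/03_amphipods.R   # hormetic model, exact LOO, growth
Rscript analysis/04_tadpoles.R    # survival/development/mass/HSI models
Rscript analysis/05_algae.R       # diversity, NMDS, PERMANOVA
```

Each writes tab-delimited tables and a JSON run manifest under
`results/`.

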