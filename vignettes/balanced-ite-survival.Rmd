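---
title: "Counterfactual survival, restricted-survival-time ITEs, and weighted evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual survival, restricted-survival-time ITEs, and weighted evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(itesurv)
```

This vignette is the package's account of its statistical machinery: the
models, the assumptions they lean on, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## The estimand

For a binary treatment $A \in \{0, 1\}$ and covariates $x$, write
$S_a(t \mid x)$ for the survival function the patient would experience under
arm $a$. The individual treatment effect is taken on the
restricted-survival-time (RST) scale at a horizon $t^\ast$ (60 months by
default):

$$\mathrm{ITE}(x) = \int_0^{t^\ast} S_1(u \mid x)\,du -
  \int_0^{t^\ast} S_0(u \mid x)\,du,$$

the additional months a patient is expected to live within the horizon if
given arm 1. This scale has two virtues over the log hazard ratio that a
Cox-type model outputs directly: it is a patient-interpretable quantity
(months), and it folds in the arm-specific *baseline* hazards, which carry
real prognostic information whenever the two arms have different baseline
risk shapes. Arm 1 is recommended when $\mathrm{ITE}(x) > 0$; exact zeros
(measure-zero on continuous predictors) go to the reference arm, a
deliberately conservative tie-break since arm 1 is typically the more
intensive option. A configurable minimum-benefit threshold exists but
defaults to 0, i.e. any predicted benefit counts.

The per-patient ITE drives recommendations; cohort-level sums are reported
separately as aggregates (summing the two uses would conflate a decision
rule with a population summary).

## The balanced T-learner

A T-learner fits one outcome model per arm, $\mu_0$ and $\mu_1$, and
differences their predictions. Its survival-specific weakness in
observational data is twofold: the two models see systematically different
covariate distributions (confounded assignment), and each extrapolates into
the other arm's region. The balanced variant counters this with a shared
encoder $\Phi$ and a distributional penalty:

$$L = \mathrm{CoxLoss}_0(\eta_0 \circ \Phi) +
      \mathrm{CoxLoss}_1(\eta_1 \circ \Phi) +
      \alpha \cdot \mathrm{IPM}\big(\Phi(X_{A=0}), \Phi(X_{A=1})\big),$$

where each $\mathrm{CoxLoss}_a$ is the negative log Cox partial likelihood
(Breslow tie handling, averaged over events) of that arm's risk head on that
arm's patients, and the IPM term measures the distance between the two
arms' empirical representation distributions. At $\alpha = 0$ the loss is
exactly the sum of two Cox losses — an unbalanced neural T-learner, which
doubles as the DeepSurv-style benchmark. Larger $\alpha$ trades a little
arm-specific fit for representations in which treated and control patients
look alike, which is the property that makes differencing the two heads a
defensible counterfactual contrast.

One wording issue deserves a note: descriptions of this architecture
sometimes speak of *maximizing* the Wasserstein distance between arms. The
balancing objective as used across the representation-learning causal
inference literature minimizes that distance — a maximized distance would
make the two heads' domains maximally disjoint and the T-learner contrast
meaningless. The penalty here is therefore additive with $\alpha \ge 0$,
shrinking the distance.

### The IPM estimators

Two interchangeable estimators of representation imbalance:

* **Entropic 2-Wasserstein (default).** Squared-Euclidean cost, uniform
  marginals, entropic regularization $\varepsilon$ (default 0.1, intended
  for roughly standardized representations), solved by Sinkhorn scaling
  iterations — a fast kernel-scaling path with a log-domain fallback when
  the Gibbs kernel underflows. Because entropic optimal transport is biased
  away from zero at identical inputs, the package uses the *debiased*
  Sinkhorn divergence $W_\varepsilon(P,Q) - \tfrac12 W_\varepsilon(P,P) -
  \tfrac12 W_\varepsilon(Q,Q)$, clamped at zero, and reports its square
  root so the penalty is on the scale of a distance (two point masses a
  distance $d$ apart score $d$; the exponent $p = 2$ is the conventional
  choice and is fixed). Gradients flow through the cost matrix with the
  transport plan held fixed — the envelope-style approximation standard in
  balancing methods; tests verify it is directionally accurate.
* **RBF-kernel MMD.** Biased V-statistic estimator with the median
  heuristic bandwidth on pooled pairwise distances, square-rooted. Cheaper
  and gradient-exact (up to the bandwidth's own data dependence, which is
  treated as fixed).

During training the Sinkhorn solver is capped at `sinkhorn_iters` (default
100) iterations per batch with early exit on convergence; the exported
`ipm_penalty()` defaults to 500 so examples and tests evaluate at
convergence. A mini-batch in which one arm is absent contributes a zero
penalty with a warning.

### Networks and optimization

Encoder and heads are multilayer perceptrons (ReLU, Glorot-uniform
initialization) trained by mini-batch Adam with L2 weight decay and
inverted dropout; all written in plain R with hand-derived backpropagation,
which keeps the dependency surface at base R and makes every gradient
testable against finite differences (the test suite does exactly that for
the Cox loss and both IPM kinds). Empty layer lists are allowed: no encoder
layers means the identity representation, and no head layers means linear
risk heads — with both empty the model *is* a pair of linear Cox models fit
by gradient descent, which is the correctly specified estimator for the
synthetic generator and the configuration used when the tests compare
against `survival::coxph` partial-likelihood fits.

Early stopping monitors the full validation loss (Cox terms plus penalty,
no dropout) every `eval_every` steps and stops once it has not improved for
`patience_steps` gradient steps (default 1,000, configurable — "iteration"
is interpreted as a gradient step); the parameters at the best validation
loss are restored. Hyperparameters are tuned by exhaustive grid search with
five-fold cross-validation, deterministic folds from a seed, and failed
grid points recorded as infinite loss rather than aborting the search.

A diverging loss (non-finite, e.g. from an aggressive learning rate) aborts
with a diagnostic rather than returning garbage parameters.

### From log-risks to curves

After training, each arm's baseline cumulative hazard is estimated by the
Breslow estimator on that arm's own training patients at the final
parameters — arm-specific baselines are retained deliberately, because
they differ in shape whenever the arms differ in mechanism. Predictions are
$\hat S_a(t \mid x) = \exp\{-\hat H_{0,a}(t)\,e^{\eta_a(x)}\}$, which are
non-increasing step functions starting at 1 by construction; the
`survival_curves` container enforces those invariants on every prediction
path. Breslow tie handling is used throughout (losses, baselines, classical
benchmarks) because month-resolution registry data are heavily tied and
Breslow keeps the loss smooth.

RST integration uses the trapezoid rule with linear interpolation of the
final partial interval, on a grid defaulting to the union of observed event
times and a monthly grid; refining the grid tenfold moves smooth-curve
integrals by less than 0.01 months.

## Evaluating a recommender on observational data

A recommender cannot be evaluated by intervening, so the package uses the
consistency contrast: patients whose actual treatment equals the
recommendation (Consis) versus the rest (Inconsis), compared on overall
survival. Because consistency is itself a function of covariates, the
contrast is confounded, and every metric is therefore reported both raw and
under stabilized inverse probability weights $P(G=g)/P(G=g \mid x)$ from a
logistic propensity for *Consis membership* (that is the exposure being
weighted, not the clinical treatment), with fitted probabilities clipped to
[0.01, 0.99] and weights truncated at the 1st/99th percentiles — the
standard variance-controlling choices. Reported metrics:

* multivariate Cox HR (adjusted for the same covariate list) and weighted
  Cox HR with robust sandwich CIs;
* 5-year ARR, $100\,[S_C(60) - S_I(60)]$, and DRMST, the difference of the
  exact step-function integrals of the two weighted Kaplan–Meier curves,
  both with percentile bootstrap CIs (200 resamples; the bootstrap
  re-estimates the propensity in every resample);
* classical and weighted log-rank tests — weights are normalized to mean 1
  first, making the statistic exactly invariant to rescaling all weights;
* cause-specific HRs under competing risks: deaths from other causes are
  re-coded as censoring at their time (inputs untouched), then the weighted
  Cox model is applied — a marginal structural cause-specific model when
  IPTW weights are supplied;
* the integrated Brier score over $[0, t^\ast]$ with Kaplan–Meier
  inverse-probability-of-censoring weights ($G(T^-)$ for deaths, $G(t)$ for
  survivors); if the censoring estimator hits zero before the horizon the
  integral truncates with a warning.

Analytic robust CIs are used for Cox quantities and bootstrap CIs for
everything else; both routes exist because registry-style analyses report
CIs without stating their method, and the bootstrap is the safer default
for functionals of weighted KM curves.

## Interpretation layers

**Probability differences.** For a binary characteristic $c$, PD is the
(weighted) share of carriers recommended arm 1 minus the share of
non-carriers, in percentage points; the IPTW variant weights by a
propensity for the characteristic given the *other* covariates (columns
collinear with the characteristic are dropped automatically — adjusting a
characteristic for itself is perfect separation by construction).
Multi-level characteristics are handled one-vs-rest per level; age uses
bands [0, 30), [30, 60], (60, ∞) by default, configurable because the
boundary convention is not standardized. CIs are percentile bootstrap (500
resamples). No multiple-testing correction is applied across
characteristics; the tables say so.

**Mediation.** Whether following recommendations helps *directly* (better
matching of treatment to patient) or merely through shifting how many
patients get the more effective arm is answered with a
linear-probability-model decomposition, treating the actual treatment as
the mediator of the consistency effect on death within the horizon: NDE is
the exposure slope given the mediator, the mediator path is $a \times b$,
and NDE + NIE equals the reduced-model total slope *exactly* (the OLS
omitted-variable identity; asserted to $10^{-9}$ in tests). The outcome is
death within 60 months, matching the evaluation horizon. A counterfactual
(Pearl-type) decomposition with interactions is out of scope; the linear
version is what the reported slopes mean.

**Subgroup ATEs.** Within each subgroup (e.g. recommended-for-arm-1 versus
recommended-for-arm-0) the HR of actual treatment, raw and weighted by a
within-subgroup treatment propensity. Opposite-signed subgroup HRs with the
overall HR near 1 are the signature of a qualitative interaction — the
pattern that makes individualized recommendation worthwhile at all.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a data
compressor: it emulates the *structure* of a head-and-neck registry cohort
(covariates: age in years, tumor size in mm, sex, nodal stage, an
advanced-T indicator; overall survival in months; ~58% assigned to the
more intensive arm; ~78% event rate; exponential censoring at 0.004/month
plus an administrative cutoff at 192 months, matching a 5–16-year follow-up
window), with three structural choices made for verifiability:

* **Weibull proportional hazards** with linear log-hazard
  $\beta'x + a(\gamma + \delta'x)$ — the minimal outcome model under which
  the Cox-based estimators are correctly specifiable and the true ITE has a
  closed form (verified by adaptive quadrature against the package's own
  integrator);
* **logistic propensity** on the same design, so the true assignment
  mechanism is inside the class the IPTW layer fits;
* a **qualitative interaction**: the default scenario gives arm 1 a harmful
  main effect ($\gamma = 0.35$ on the log hazard) reversed in the
  advanced-T subgroup ($\delta_{T4} = -1.1$), so roughly half the cohort
  truly benefits from each arm and the true ITE changes sign across an
  identifiable subgroup.

Cause of death is a covariate-independent categorical draw at event time
(primary cancer 0.6, cardiovascular 0.2, adverse effect 0.1, other 0.1):
enough to exercise the competing-risk machinery, while cause-specific
confounding stays out of scope. Times are continuous by default; a
`round_months` switch coarsens to whole months to produce registry-like
ties for tie-handling tests. Time is months everywhere.

What passing tests on this generator shows: the estimators recover truth
when their assumptions hold, the weighting removes the confounding that was
injected, and every reduction identity (unit weights → classical
estimators, $\alpha = 0$ → per-arm Cox) is exact. What it does not show:
robustness to non-proportional hazards, unmeasured confounding, informative
censoring, measurement error, or covariate distributions unlike the
simulated ones — real-registry performance claims are outside what this
package's validation can establish.

## Problem sizes and numerical tolerances

The test suite and acceptance script run at sizes chosen to keep Monte
Carlo error well inside the asserted tolerances on a single CPU: n = 10,000
for coefficient-recovery checks (±0.1), n = 5,000 for ITE-recovery,
balance, subgroup and null checks, 100 simulation replicates × 200
bootstrap resamples at n = 1,000 for the NIE coverage property (accepting
90–99%), and n = 5,000 with a 70/30 split for the end-to-end acceptance
run. Closed-form identities are asserted at $10^{-9}$–$10^{-12}$;
quadrature and KM-limit comparisons at the grid error actually incurred
(0.01–0.4 months depending on n). Determinism is exact: one integer seed
fixes cohort generation, fold assignment, initialization, batching,
dropout, and every bootstrap.

## Known limitations

* Individual ITEs are reported without uncertainty intervals; only
  cohort-level contrasts carry CIs.
* The balanced learner's Sinkhorn gradient is the plan-fixed approximation;
  with tiny $\varepsilon$ and few iterations it can lag the exact gradient.
* Linear-probability mediation can predict outside [0, 1] in extreme
  covariate regions; its slopes remain the intended estimand but are not
  probabilities.
* The forest T-learner interpolates survival only at observed death times;
  very small leaves can produce coarse curves.
* Fine–Gray subdistribution hazards, time-varying weights, matching
  estimators, and latent-cluster effect models are intentionally not
  implemented.
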