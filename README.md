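# itesurv

Individualized treatment recommendations from counterfactual survival
models, for observational (registry-style) oncology cohorts with
right-censored overall survival.

## The problem

When two treatments (say, definitive chemoradiotherapy versus surgery plus
adjuvant radio/chemotherapy) are both defensible for a disease, the best
choice can differ patient by patient: a covariate-dependent, possibly
sign-reversing treatment effect. Registry data are large enough to learn
such heterogeneity but confounded — sicker or older patients are steered
toward particular arms — so naive arm comparisons mislead, both when fitting
models and when judging a recommender.

`itesurv` implements the full workflow:

1. **Counterfactual survival estimation** with a *balanced neural
   T-learner*: a shared encoder Φ maps covariates to a representation, and
   two arm-specific risk heads are trained by the negative log Cox partial
   likelihood (Breslow ties) on their own arm's patients. An integral
   probability metric between the arms' encoded distributions
   (entropic 2-Wasserstein via Sinkhorn, or RBF-kernel MMD) is added to the
   loss with weight α, shrinking the representation imbalance that
   confounded assignment induces:

   L = CoxLoss₀ + CoxLoss₁ + α · IPM(Φ(X₀), Φ(X₁)).

   Per-arm Breslow baseline hazards turn log-risks into survival curves
   Ŝₐ(t|x) = exp{−Ĥ₀,ₐ(t) e^{ηₐ(x)}}. Classical per-arm Cox and survival
   forest T-learners are provided behind the same prediction contract.
2. **ITE on the restricted-survival-time scale.** For horizon t* (default
   60 months), ITE(x) = ∫₀^{t*} Ŝ₁(u|x) du − ∫₀^{t*} Ŝ₀(u|x) du — the extra
   months a patient is expected to live within the horizon under arm 1.
   Arm 1 is recommended when the ITE is positive.
3. **Observational evaluation.** Patients whose actual treatment matches
   the recommendation (Consis) are contrasted with those whose treatment
   does not (Inconsis): multivariate Cox HR, stabilized-IPTW HR with robust
   CIs, 5-year absolute risk reduction, difference in restricted mean
   survival time, weighted log-rank tests, cause-specific competing-risk
   HRs, and the censoring-weighted integrated Brier score.
4. **Interpretation.** Probability differences per characteristic (raw and
   IPTW-adjusted), linear-probability-model mediation of the consistency
   effect through the actual treatment (NDE/NIE), and subgroup average
   treatment effects.
5. **Synthetic cohorts with ground truth.** A Weibull proportional-hazards
   generator with a logistic propensity, treatment-by-covariate
   interactions (including a qualitative sign flip in an advanced-T
   subgroup), exponential plus administrative censoring, and closed-form
   per-patient true ITEs, so every layer above can be validated against
   known truth.

## Worked example

```r
library(itesurv)

cfg <- default_scenario(n_patients = 2000, seed = 42)
result <- run_phase(list(generator = cfg, estimator = "balanced", seed = 42,
                         spec = balanced_tlearner_spec(
                           shared_layers = c(16L, 16L), head_layers = 8L,
                           balance_weight = 0.5, max_steps = 2000L,
                           patience_steps = 500L, seed = 42)))
head(result$ite[, c("patient_id", "rst_arm1", "rst_arm0", "ite", "recommended_arm")], 3)
#>   patient_id rst_arm1 rst_arm0       ite recommended_arm
#> 1        561 44.03437 32.11532 11.919049               1
#> 2        321 42.75332 38.47767  4.275651               1
#> 3       1177 39.40341 37.98922  1.414195               1
print(result$report)
#> Consis (n=346) vs Inconsis (n=254), horizon 60 months
#>   HR 0.62 (0.52-0.75)  IPTW HR 0.64 (0.54-0.76)
#>   DRMST 6.79 (3.10-10.13)  IPTW DRMST 7.59 (4.06-11.08) months
#>   ARR 15.5 (8.0-24.7)  IPTW ARR 17.5 (10.1-26.0) %
#>   log-rank p 6.94e-06  IPTW log-rank p 8.95e-07
```

Reading the output: for patient 561 the model predicts 44.0 expected months
alive within 5 years under arm 1 versus 32.1 under arm 0, an ITE of +11.9
months, so arm 1 is recommended. Across the test split, patients treated in
agreement with the recommendations had an IPTW-weighted hazard ratio of
0.64 (95% CI 0.54–0.76) relative to those treated against them — following
the model's advice is associated with a 7.6-month gain in 5-year restricted
mean survival and a 17.5-point higher 5-year survival probability after
weighting.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on the synthetic
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + ground truth
Rscript analysis/02_fit_models.R             # balanced, Cox and forest T-learners
Rscript analysis/03_evaluate_recommendations.R  # Consis/Inconsis performance table
Rscript analysis/04_interpret.R              # subgroup ATEs, PDs, mediation
```

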