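# mrsynth

Bayesian cross-species synthesis of restricted-mean survival time ratios,
applied to ketogenic therapy (ketogenic diets and calorie restriction, alone
or combined with other treatment) in high-grade glioma.

Direct randomized evidence for dietary interventions in glioma barely
exists: three small human cohorts and seventeen rodent experiments. This
package combines all of them. Each study is summarized by the ratio of
restricted mean survival times between its treatment and control arm,
MR = RMST_T / RMST_C with RMST(t\*) = ∫₀^t\* S(t) dt, analyzed on the log
scale. A two-way hierarchical model then links species and interventions:

    y_ij ~ N(theta_ij, c_ij^2)
    theta_ij ~ N(alpha_i + gamma_j, sigma^2)
    alpha ~ MVN(mu_alpha, Ralpha),  gamma ~ MVN(mu_gamma, Rgamma)
    sigma ~ N(0.5, 0.01) truncated at 0

for species i (humans, athymic / C57BL / SCID mice, Fisher rats) and
interventions j (KD, KD+, CR, CR+). The potency scale sigma quantifies the
*equal relative potency* assumption — the ratio between two interventions'
effects carries across species to within a factor exp(±sigma). Prior
covariance matrices Ralpha and Rgamma encode eleven named belief sets, from
skeptical (SP1, SP2, FSP) through relational (RP1–RP3) and mechanistic
(MP1, MP2) to enthusiastic (EP, EP_MP1, EP_MP2); see `?make_prior`. The
payoff of the hierarchy is a posterior for cells with *no data at all*, such
as calorie restriction as monotherapy in humans.

The package also provides the surrounding machinery: Kaplan–Meier / RMST
estimation with Greenwood-type standard errors from raw survival tables,
Bayesian random-effects pooling of multi-study cells, DIC / effective
parameters / entropy model comparison, sensitivity reruns, and simulators
with known ground truth for validating every stage.

## Worked example

```r
library(mrsynth)

fit <- mrsynth(load_table2(), prior = "EP_MP2", seed = 1)
summary(fit)
#> Hierarchical MR synthesis fit (prior 'EP_MP2')
#>   grid: 5 species x 4 interventions, 12 observed cells
#>   10000 retained draws (burn-in 100000, 200000 draws, thin 20)
#>   sigma acceptance rate: 0.40
#>
#> Posterior MR for Humans:
#>  intervention median_mr cri_low cri_high p_gt_1 observed
#>            KD     1.495   0.862    2.604  0.928     TRUE
#>           KD+     1.536   0.941    2.554  0.961     TRUE
#>            CR     1.540   0.888    2.725  0.938    FALSE
#>           CR+     1.570   0.928    2.660  0.954     TRUE
#>
#> sigma: median 0.370, 95% CrI (0.195, 0.567)
#> DIC: -3.987 (Dbar -13.867, pD 9.879)
```

Under this enthusiastic-plus-synergy prior, every ketogenic intervention is
estimated to prolong survival in humans by roughly 50% (posterior median MR
about 1.5), with better than 90% posterior probability of *some* benefit
(`p_gt_1`) — including the CR cell, for which no human study exists and the
estimate is borrowed across species. The posterior median of sigma (0.37)
sits below its prior mean of 0.5: the data support equal relative potency
somewhat more than the prior assumed. Under the most pessimistic catalogue
prior (FSP, which *expects* tumor promotion), the posterior still favors
benefit with more than 75% probability for every intervention — run
`predict(mrsynth(load_table2(), "FSP", seed = 1), "Humans")` to see.

Other entry points: `rmst_table()` for raw survival tables,
`pool_random_effects()` for multi-study cells, `compare_priors()` for the
DIC table across the catalogue, `reproduce_table3()` /
`reproduce_sensitivity()` for the full refits, and `simulate_table()` /
`recovery_experiment()` for calibration studies.

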