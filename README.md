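# mamsrb

Design and simulation of **multi-arm multi-stage (MAMS) clinical trials
with a risk–benefit treatment-selection rule** on a bivariate normal
(efficacy, safety) endpoint.

Seamless phase II/III MAMS trials compare K experimental arms with a
shared control, select one arm at the first analysis, and test it against
control at the end of the trial. Standard MAMS methodology bases both
steps on a single efficacy endpoint, but in practice safety shapes
selection just as much: good efficacy does not excuse poor safety. This
package treats safety as a co-primary endpoint throughout — in the
probability model, the selection rule, the hypothesis test, and the
error-rate calibration — for trials such as multi-dose comparisons where a
minimum safety requirement must hold and the carried-forward arm should
offer the best safety/efficacy trade-off among the safe ones.

## The method in brief

Patient responses on arm `k` are bivariate normal with means
`(mu_Ek, mu_Sk)`, known standard deviations `sigma_E, sigma_S` and
within-subject correlation `rho`. With `n` patients per arm, each
endpoint's score statistic is `Z_Tk = I_T (muhat_Tk - muhat_T0)` with
information `I_T = n / (2 sigma_T^2)`. At the first analysis:

* arms with `Z_Sk > c` (default `c = 0`) form the eligible set; if it is
  empty the trial stops for futility;
* among eligible arms, the one maximising the weighted objective
  `O_k = w_E Z_Ek / sqrt(I_E) + w_S Z_Sk / sqrt(I_S)` (with
  `w_E^2 + w_S^2 = 1`) is selected;
* the selected arm's null hypothesis `H_0k: theta_Ek <= 0 or
  theta_Sk <= 0` is rejected iff `Z_E,i* >= u_E` **and** `Z_S,i* >= u_S`.

The boundaries `(u_E, u_S)` are calibrated in the two worst-case limits of
the null space — all safety effects infinite with null efficacy, and vice
versa — so that the familywise error rate is controlled at `alpha` in the
strong sense; the safety criterion is conditioned on at least one arm
clearing the gate, whose probability under the equicorrelated (shared
control) null is `K/(K+1)` at `c = 0`. Sample size comes from a
one-dimensional information search attaining a target disjunctive power,
with boundaries re-solved at every candidate. Multi-stage versions monitor
the selected arm over J analyses with alpha-spending boundary schedules
and binding futility. All limiting probabilities are computed by
Gauss–Legendre quadrature of exact post-selection distributions and
cross-checked against a seeded Monte-Carlo oracle.

## Worked example

The default `rb_design()` mirrors a four-arm dose-selection trial
(TAILoR-style): `K = 4`, `alpha = 0.05`, power `0.9`, desirable efficacy
effect `delta = 0.545`, minimum clinically important effect
`delta0 = 0.178`, equal selection weights, `rho = 0.4`, unit variances,
safety gate `c = 0`.

```r
library(mamsrb)
des <- rb_design(K = 4, alpha = 0.05, power = 0.9,
                 delta = 0.545, delta0 = 0.178,
                 w_E = sqrt(0.5), rho = 0.4, c = 0)
sol <- solve_information(des)
sol
#> Single-stage risk-benefit MAMS design
#>   information per arm I1* = 47.1361  (n unrounded = 94.2722)
#>   boundaries at I1*: u_E = 14.4639, u_S = 14.4640
#>   rounded n* = 95 per arm -> u_E = 14.5197, u_S = 14.5197
#>   attained limiting power at n*: 0.9019
```

Reading: about 94.3 patients per arm are needed for 90% power to carry a
truly effective, safe arm through to rejection; rounding up to 95 patients
per arm lifts attained power slightly above target (the rounding is
conservative), and with equal weights and variances the efficacy and
safety boundaries coincide. A familywise error check over worst-case
mixed null patterns (each arm null on one endpoint, huge on the other):

```r
oc <- mixed_null_fwer(des, sol$boundaries_at_I_star, reps = 1e5, seed = 42)
head(oc[, 1:3], 4)
#>   pattern   fwer       se
#> 1    SSSS 0.0497 0.000687
#> 2    ESSS 0.0493 0.000685
#> 3    SESS 0.0499 0.000689
#> 4    EESS 0.0506 0.000693
```

Every pattern stays at or below `0.05` within Monte-Carlo error. A
two-look version of the same trial, with quadratic error spending and
binding futility:

```r
solve_max_information(rb_design(J = 2))
#> Multi-stage risk-benefit MAMS design (J = 2)
#>   maximum information I_EJ = 69.9976, recruitment ceiling n* = 140 per arm
#>   attained limiting power 0.9000
#>   stage   t info_E info_S      l_E    u_E     l_S    u_S
#> 1     1 0.5 34.999 34.999 -0.23759 15.723  2.2622 15.723
#> 2     2 1.0 69.998 69.998 17.23164 17.232 17.1984 17.198
```

The interim look raises the recruitment ceiling (140 vs 95 per arm) but
saves information in expectation through early stopping.

Other entry points: `solve_boundaries()` (boundaries at fixed
information), `limiting_power()` and `power_with_finite_safety()`,
`run_single_stage_trial()` / `run_multistage_trial()` (patient-level
executors), and the operating-characteristics sweeps `sweep_weights()`,
`fwer_power_grid()`, `mixed_null_fwer()`, `rho_misspecification()`,
`power_vs_safety()`. Designs round-trip to flat YAML configs via
`write_design_config()` / `read_design_config()`, and
`inst/cli/mamsrb` exposes the same functionality as shell subcommands
(`design single-stage`, `design multi-stage`, `oc grid|mixed-null|...`).

See `vignettes/risk-benefit-mams.Rmd` for the model, the limiting
post-selection distributions behind the boundary calibration, and every
numerical choice.

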