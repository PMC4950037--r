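---
title: "Designing risk-benefit MAMS trials: model, calibration, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing risk-benefit MAMS trials: model, calibration, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design problem

Seamless phase II/III multi-arm multi-stage (MAMS) trials compare $K$
experimental arms with a shared control, select a single arm at the first
analysis, and carry it forward for confirmatory testing. In most published
MAMS methodology both selection and testing rest on a single efficacy
endpoint, yet in practice safety drives selection at least as much as
efficacy: a treatment that is marginally more effective but clearly less
safe than its competitors should not be the one carried into phase III.

`mamsrb` implements a MAMS design in which a bivariate (efficacy, safety)
endpoint enters the trial at every level: the joint probability model, the
selection rule, the hypothesis test, and the error-rate calibration. The
motivating setting is a trial like TAILoR (telmisartan for insulin
resistance in HIV-positive patients), where change in HOMA-IR is the
efficacy endpoint and change in systolic blood pressure a natural safety
endpoint; the package's defaults (`rb_design()`) correspond to that
setting: $K = 4$, $\alpha = 0.05$, power $0.9$, $\delta = 0.545$,
$\delta_0 = 0.178$, $\rho = 0.4$, unit variances.

## Model and selection rule

Patient $i$ on arm $k \in \{0, 1, \dots, K\}$ (arm 0 = control) yields

$$\begin{pmatrix} Y_{Eik} \\ Y_{Sik} \end{pmatrix} \sim
N\!\left(\begin{pmatrix} \mu_{Ek} \\ \mu_{Sk} \end{pmatrix},
\begin{pmatrix} \sigma_E^2 & \rho\sigma_E\sigma_S \\
\rho\sigma_E\sigma_S & \sigma_S^2 \end{pmatrix}\right),$$

with the covariance treated as known. Treatment effects are differences
versus control, $\theta_{Tk} = \mu_{Tk} - \mu_{T0}$ for $T \in \{E, S\}$,
and higher responses are better on both endpoints. The null hypothesis for
arm $k$ is composite: $H_{0k}: \theta_{Ek} \le 0 \text{ or } \theta_{Sk}
\le 0$ — rejecting it declares arm $k$ both effective and safe.

With $n$ responses per arm (1:1 allocation), Fisher's information per
comparison is $I_T = n / (2\sigma_T^2)$ and the data are summarised by
score statistics $Z_{Tk} = I_T(\hat\mu_{Tk} - \hat\mu_{T0})$, which have
variance $I_T$, cross-arm correlation $1/2$ (shared control), and
within-arm cross-endpoint correlation $\rho$.

At the first analysis, arms with $Z_{Sk} > c$ form the eligible set
$\mathcal{S}_S$ (default $c = 0$: at least as safe as control; $c = -\infty$
recovers a co-primary-efficacy design with no gate). If the set is empty
the trial stops for futility. Otherwise the selected arm $i^\star$
maximises the risk-benefit objective

$$O_k = w_E \frac{Z_{Ek}}{\sqrt{I_E}} + w_S \frac{Z_{Sk}}{\sqrt{I_S}},
\qquad w_E^2 + w_S^2 = 1,$$

and the single-stage test rejects $H_{0i^\star}$ iff $Z_{Ei^\star} \ge u_E$
and $Z_{Si^\star} \ge u_S$. Equal weights ($w_E = w_S = \sqrt{0.5}$) keep
the selection criterion aligned with the final bivariate test. Ties in the
argmax have probability zero under the continuous model; the package breaks
them towards the lowest arm index so that reruns are bit-for-bit
reproducible.

## Calibrating the boundaries: worst-case limiting configurations

The familywise error rate (FWER) is the probability of rejecting the null
of the selected arm when that null is true. Strong control is obtained by
calibrating $(u_E, u_S)$ in the two least-favourable limits of the null
space:

* **Efficacy limit** — all safety effects $\to +\infty$, all efficacy
  effects $0$: every arm is eligible almost surely and the safety margin is
  cleared almost surely, so the test errs iff $Z_{Ei^\star} \ge u_E$. The
  boundary $u_E$ is chosen so this probability equals $\alpha$.
* **Safety limit** — all efficacy effects $\to +\infty$, all safety
  effects $0$: the error event reduces to the safety margin, and $u_S$ is
  chosen so that $P(Z_{Si^\star} \ge u_S \mid N_S \ge 1) =
  \alpha / P(N_S \ge 1;\, \theta_S = 0)$ — equivalently the joint
  probability equals $\alpha$.

The conditioning constant accounts for the free futility look the gate
provides. Because the safety statistics are equicorrelated at $1/2$ through
the shared control, $P(N_S \ge 1)$ is a $K$-variate orthant probability,
never a product of marginals; at $c = 0$ exchangeability gives it exactly as
$K/(K+1)$ (e.g. $0.8$ for $K = 4$). The two searches uncouple, and with
equal weights and equal variances the two solved boundaries coincide — a
property the test suite checks rather than assumes.

Control at these two limits is extended to the whole null space by the
design's monotonicity arguments plus simulation: the package's
`mixed_null_fwer()` enumerates all $2^K$ per-arm patterns with one endpoint
at zero and the other at the large surrogate, and the acceptance suite
verifies empirical FWER $\le \alpha$ within Monte-Carlo error on each.

### Limiting post-selection distributions

The supplementary derivations of the original methodology are not
reproduced here; instead the package derives the limiting distributions
from a shared-control decomposition and then requires agreement with an
independent Monte-Carlo oracle. Writing standardised statistics
$X_{Tk} = Z_{Tk}/\sqrt{I_T}$ as $(A_k - A_0)/\sqrt{2}$ plus drift, with
$(A_k, B_k)$ i.i.d. bivariate standard normal pairs per arm, the selection
objective ranks arms by $C_k = w_E A_k + w_S B_k$ (common terms cancel),
with $\mathrm{Var}(C_k) = 1 + 2 w_E w_S \rho$. Conditioning on the selected
arm's $(A, C)$ and on the control variable collapses:

* the efficacy-limit tail and the limiting power to **one-dimensional**
  Gauss-Legendre quadratures (the inner normal expectation has a closed
  form, $E\,\Phi(X - t) = \Phi((m - t)/\sqrt{1 + v})$ for
  $X \sim N(m, v)$);
* the safety-limit tail to a **two-dimensional** quadrature whose kernel
  contains a bivariate normal orthant probability (the chance that a
  competing arm neither beats the selected arm's objective nor fails the
  gate).

Differentiating the tails in the threshold yields the stage-1
post-selection densities used by the multi-stage recursion. Every
integrated quantity has a Monte-Carlo twin (`method = "monte_carlo"`)
drawn at the surrogate effect; the tests require the two routes to agree
within three Monte-Carlo standard errors on randomised parameter sets, and
the solved example design reproduces the published values to the third
decimal.

## Sample size

Power is disjunctive — the probability of rejecting at least one false
null — evaluated under the sizing configuration $\theta_E = (\delta_0,
\dots, \delta_0, \delta)$ with all arms arbitrarily safe (the limit is the
natural sizing assumption: a treatment suspected of being unsafe would not
be in the trial). `solve_information()` runs a one-dimensional search over
a common information level $I_1$, re-solving the efficacy boundary at every
candidate so FWER control holds throughout, until the limiting power equals
$1 - \beta$. The per-arm sample size is rounded up to a whole patient,
$n^\star = \lceil 2 \max(\sigma_E^2, \sigma_S^2)\, I_1^\star \rceil$, and
boundaries are recomputed at the attained information; since power
increases with information the rounding is conservative, which the tests
confirm empirically. When the safety effect is finite rather than infinite
the gate genuinely binds and power is lower; `power_with_finite_safety()`
estimates it by simulation.

```{r}
library(mamsrb)
des <- rb_design()          # K = 4, alpha = 0.05, power 0.9, rho = 0.4
sol <- solve_information(des)
sol
```

## Multi-stage designs

With $J$ analyses, selection still happens at analysis 1; afterwards the
selected arm's statistics are monitored against stagewise boundaries
$(l_{Tj}, u_{Tj})$: reject when both endpoints clear their upper bounds at
the same analysis, accept as soon as either crosses its lower bound
(futility is binding — the type-I error calculation relies on stopping),
continue otherwise. Increments of the selected arm's score statistics
across stages are independent Gaussians exactly as in a univariate
group-sequential test; only the stage-1 distribution carries the selection
effect. Boundaries therefore come from an error-spending construction:
monotone functions $f_U, f_L$ with $f_U(0) = f_L(0) = 0$, $f_U(1) =$ level
and $f_L(1) = 1 -$ level allocate stagewise crossing probabilities under
the endpoint's limiting configuration; stage 1 uses the exact
post-selection tail, later stages the standard sub-density recursion on a
Gauss-Legendre grid. Spending the full unit mass forces $u_{TJ} = l_{TJ}$,
so the test always terminates with a decision. The efficacy schedule spends
to $\alpha$; the safety schedule to $\alpha / P(N_S \ge 1)$, conditioned on
eligibility, and spends as a function of the *efficacy* information
fraction. Safety information runs at $I_{Sj} = \sigma_E^2 I_{Ej} /
\sigma_S^2$ — the same patients drive both endpoints.

`solve_max_information()` searches for the final-look information $I_{EJ}$
attaining the target power (recruitment ceiling $n^\star = \lceil 2
\sigma_E^2 I_{EJ} \rceil$ per arm); interim looks with binding futility
cost maximum information relative to the single-stage design but save
information in expectation, both of which the tests verify by simulation.

```{r}
sch <- solve_max_information(rb_design(J = 2))
sch
```

## Numerical choices

* **Quadrature.** Fixed-order tensor Gauss-Legendre rules (96 nodes per
  dimension, ranges $\pm 8$ standard deviations of each integrand
  variable). The integrands are analytic with Gaussian tails, so fixed
  rules converge far below the 1e-6 absolute target — values are stable to
  below 1e-8 between 64 and 192 nodes — and, unlike adaptive cubature,
  cost the same at every root-search iterate.
* **Bivariate orthant probabilities** are computed by Gauss-Legendre
  integration of the conditional normal tail, with exact handling of
  $\rho = \pm 1$; none of the installed packages provides this primitive.
  Accuracy is pinned in the tests against closed forms (independence,
  perfect correlation, the quadrant identity $1/4 + \arcsin r / 2\pi$).
* **Root-finding.** Bracketed scalar solvers (`uniroot`) with boundary
  tolerance 1e-6 on the score scale and geometric bracket expansion; the
  information searches use tolerance 1e-6 (single-stage) / 1e-5
  (multi-stage) on the power scale. The Monte-Carlo route solves boundaries
  on one fixed set of draws (common random numbers), which makes the
  empirical tail monotone in the boundary and the root well-defined.
* **Surrogate infinity.** Limiting configurations are simulated at
  `gamma_surrogate = 1e6`; on the score scale this shifts statistics by
  $\sim 10^6 \sqrt{I}$ while leaving doubles with ample precision for the
  $O(1)$ noise that decides selection.
* **The gate versus the safety boundary.** All designs of practical
  interest have $u_S \gg c$. The solver accepts $u_S \le c$ (the safety
  margin is then partially absorbed by the conditioning) but that regime
  sits outside the validated designs and should be treated accordingly.
* **Seeding.** Every stochastic function takes an explicit seed; sweep
  functions derive per-configuration substream seeds from one master seed,
  so any table reproduces bit-for-bit and replicates may be evaluated in
  any order.
* **Stage fractions** default to equal spacing; spending families shipped
  are the power family `pow:kappa` and an O'Brien-Fleming-type spend
  (`obf`), standard choices where the methodology does not prescribe one.

## What the simulator does and does not emulate

The Monte-Carlo engine draws from exactly the bivariate normal model above
— known variances and correlation, common correlation across arms, 1:1
allocation, immediate response observation, no dropout, no drift over
stages. Passing tests therefore certify the *design calculations* (error
rates, power, boundary recursions) under the stated model, not robustness
to non-normality, unknown nuisance parameters, or operational deviations.
One robustness axis is explored deliberately: `rho_misspecification()`
designs at one correlation and simulates at another. For the default
design the procedure is conservative for true correlations below the
design value; at perfect positive correlation all six probe
configurations collapse to the same selection event (with equal variances
the two endpoints' statistics coincide) and the FWER inflates to about
0.0565, i.e. roughly 13% of the nominal level — the price of assuming
$\rho = 0.4$ when the endpoints are really exchangeable copies.

Replication sizes used by the test and acceptance suites are $10^5$ for
error-rate and power verification and $10^4$ to $4 \times 10^4$ for
qualitative trend checks; sweeps default to $10^4$ per grid point. These
are the package's verification choices: binomial standard errors at
$10^5$ replicates ($\approx 7 \times 10^{-4}$ at $\alpha = 0.05$) resolve
the quantities the checks assert.

## Known limitations

* One arm is selected, at the first analysis only; dropped arms are not
  revisited and no selection happens later.
* 1:1 allocation across all arms; unequal allocation ratios are not
  implemented.
* Normal endpoints with known covariance; no plug-in variance estimation
  or quantile substitution.
* Binding futility only; non-binding monitoring would require different
  spending arithmetic.
* No confidence intervals on termination, and no conditional-error
  machinery for unplanned changes to the selection rule.
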