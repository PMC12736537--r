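---
title: "Methods: joint fluoxetine–norfluoxetine population PK, estimation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint fluoxetine-norfluoxetine population PK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, estimators and numerical choices behind
`fluoxpk`, in enough detail that a reader can judge what the package's tests
do and do not demonstrate.

## 1. Structural model and units

Fluoxetine is modelled as a one-compartment system with first-order oral
absorption; norfluoxetine as a catenary metabolite compartment fed by parent
elimination (depot → parent → metabolite, rate constants `ka`,
`kE = CL_P/V_P`, `km = CL_M/V_M`). Bioavailability is not separable from
trough-only oral data, so all clearances and volumes are apparent (CL/F,
V/F) and F ≡ 1; the fraction of parent converted to metabolite, F_M, is
likewise unidentifiable separately from CL_M/F and fixed at 1.

All concentrations are computed by closed-form superposition. For a dose D
(mg) every τ hours, each exponential term `e^(−λt)` carries the accumulation
weight `(1 − e^(−nλτ))/(1 − e^(−λτ))` for `n` doses, with the steady-state
limit at `n = ∞`. The metabolite profile is the tri-exponential
partial-fraction expansion over {ka, kE, km}. Amounts are propagated in mg
and volumes in L, giving mg/L internally; every user-facing value is
converted to ng/mL (×1000), matching the assay scale (LLOQ 1 ng/mL) and the
additive residual-error unit.

Numerical safeguards:

* **Eigenvalue collisions.** If two rate constants agree within a relative
  gap of 1e−6, the exported concentration functions switch to numerical
  integration (`deSolve::ode`, rtol/atol 1e−10) rather than evaluating a
  0/0 form. The vectorized internal path used inside estimation nudges the
  colliding constant by 2e−6 relative instead, bounding the error at O(1e−6)
  while staying vectorizable; collisions essentially never occur at the
  fitted parameter scales (ka 0.3/h, kE ≈ 0.12/h, km ≈ 2.1/h).
* **Steady state for finite regimens.** `ode_profile()` realizes `n = ∞` as
  enough doses to cover seven terminal half-lives. The day-30 trough of the
  joint model (parent t1/2 ≈ 6 h) is within 1e−6 of the analytic limit; for
  the weight-linear pediatric model (t1/2 ≈ 143 h) 30 days is only ~5
  half-lives and the finite trough sits ~3% below the limit — the package
  therefore keeps finite-superposition dosing as an explicit mode and the
  simulation engine always uses it.
* **Degenerate inputs.** Zero dose, `F_M = 0`, and washout after a single
  dose all return exact zeros/limits rather than relying on cancellation.

## 2. Model repository and conventions

`builtin_model()` returns the three parameterizations used throughout; YAML
fixtures under `inst/extdata/` round-trip them bit-exactly, so a serialized
model is a complete, faithful record.

Conventions fixed once and used everywhere:

* **Printed CV% → log-scale SD**: `ω = CV/100`. The alternative
  `ω = sqrt(ln(1+CV²))` differs by <3% at the magnitudes involved (≤52%);
  one convention had to be chosen and this is the common reporting reading.
* **Sex coding**: female = 0 (reference), male = 1; the male shift enters as
  `(1 + θ)^SEX`, so reference-class covariate factors are exactly 1.
* **Correlation between the two clearance random effects**: none is
  reported, so the generator and simulator draw them independently. Positive
  correlation would widen, negative would narrow, the active-moiety trough
  distribution; this is the main unverifiable assumption of the simulation
  layer.
* **Covariate substitution**: a model evaluated on data lacking one of its
  covariates substitutes the central value recorded in the model object
  (e.g. 53.6 kg for the weight-linear model, the midpoint of its source
  population's child/adolescent group means), mirroring standard external-
  evaluation practice.

## 3. Synthetic cohort generator

`generate_cohort(cohort_design())` emulates the real-world trough-only TDM
dataset that motivated the analysis: 198 subjects with an exact 146/52
female/male split; ages from a pediatric (12–17, ~median 15) / adult (18–56,
median 21, right-skewed) mixture weighted 102:92; weights log-normal with
median 59 kg, the printed range [35.9, 115] kg treated as the 0.1/99.9
percentiles (σ_log ≈ 0.19) and enforced by resampling; once-daily doses
drawn from {20, 40, 60} mg with probabilities {0.4, 0.4, 0.2} (20 and 40 mg
are described as the most common prescriptions; only qualitative frequency
is available); and 1 trough with probability 0.78 or 2 with 0.22, matching
the observed 241/198 ≈ 1.22 samples per patient. Observations are paired
parent/metabolite troughs at exact interval ends (24 h, 48 h), with combined
residual noise `y = f(1+ε_p) + ε_a`, floored at zero and flagged below the
1 ng/mL LLOQ.

What the generator deliberately does **not** emulate: dose-titration
histories, irregular sampling times, CYP2D6/CYP2C19 genotype strata,
within-subject correlation of residuals, and assay batch effects. Passing
tests on generated cohorts therefore demonstrate internal consistency of the
estimation/evaluation machinery under the stated model, not robustness to
real-data violations of it.

BLQ observations are retained with a flag and excluded from fitting by
default; at the simulated concentration scales (medians >100 ng/mL) this
affects a fraction of a percent of observations.

## 4. MAP estimation

Per-subject random effects are estimated by minimizing

    Σ_j [ (y_j − f_j(η))² / g_j(η) + ln g_j(η) ] + Σ_k η_k² / ω_k²,
    g = (σ_p f)² + σ_a²,

a quasi-Newton search from η = 0 plus one fixed-offset restart (keeping the
lower objective), so results are deterministic. Because the interaction term
`ln g(η)` depends on η through f, the conditional mode is *not* exactly zero
even when the data sit on the typical prediction — it shifts by O(ω²); the
test suite checks the first-order condition rather than pretending the shift
away.

## 5. Population estimation (FOCE-I)

The marginal likelihood uses the first-order-conditional approximation with
interaction: conditional modes `η̂_i` (damped Newton, vectorized across all
subjects simultaneously), linearization `F_i = ∂f/∂η|η̂`, and

    OFV = Σ_i [ ln det V_i + r_i' V_i⁻¹ r_i ] + N ln 2π,
    V_i = F_i Ω F_i' + diag(g_i(η̂_i)),   r_i = y_i − f_i(η̂_i) + F_i η̂_i.

Numerical design choices, each adopted after observing the alternative fail:

* **Trust-region cap on inner Newton steps** (|Δη| ≤ 2 per iteration, then
  up to 8 halvings): with proportional-dominant error the inner objective
  has negative curvature far from the mode, where an uncapped Newton step
  can overshoot irrecoverably.
* **Anchored optimization cycles**: the raw FOCE objective has rare step
  discontinuities where a subject's conditional mode switches between local
  basins; these stall BFGS line searches. Each cycle solves the modes cold
  at the current parameters, freezes them as the warm start for every
  objective/gradient evaluation (the smooth local branch of the same
  objective), runs BFGS on that branch, and re-anchors — repeating until the
  OFV stops improving (`cycle_tol`, default 1e−5).
* **Standard errors** come from a central-difference observed-information
  matrix evaluated on the same warm branch; RSEs are delta-method on the
  estimation transforms (log for positive parameters, `log(1+θ)` for
  fractional shifts). Shrinkage is SD-based, `100(1 − SD(η̂)/ω)` per key and
  `100(1 − SD(IWRES))` per analyte.

### Identifiability of the volumes

With every observation a trough at a fixed 24-h interval, the mean structure
constrains one function of (CL, V) per analyte, and the remaining
information about the volumes comes only weakly through the variance
structure. Profiling the exact marginal likelihood (30×30 Gauss–Hermite
quadrature, used as an oracle during development) confirms a nearly flat
ridge: the full maximum-likelihood optimum on synthetic cohorts can land at
physically implausible volumes while improving the OFV by only a few units.
The package therefore treats "clearances + sex effect + variabilities, with
both volumes fixed" as the identifiable free set for trough-only data, and
the parameter-recovery studies in the tests and the acceptance script use
it. This is the same reasoning that motivates fixing `ka` in the first
place; users with richer sampling can free the volumes via the `free`
argument of `pkfit()`.

Measured operating characteristics at the study design (198 subjects, ~1.2
paired troughs each): parent clearance shows a ≈ +7% small-sample upward
bias (10-seed mean 3.12 vs 2.91 L/h) — a known trait of
conditional-linearization estimators with large proportional error on sparse
data — while metabolite clearance is essentially unbiased. The sex effect is
weakly estimable: its seed-to-seed spread corresponds to a standard error of
6–7 percentage points, consistent with the published 44% RSE for that
parameter; recovery studies therefore average over ≥16 independent cohorts.

### Stepwise covariate selection

Forward inclusion requires an OFV drop ≥ 6.635 (χ²₁ at 1%), backward
elimination retains an effect only if its removal costs ≥ 10.828 (0.1%). At
the published 16.5% sex-effect magnitude and n = 198, the expected OFV drop
is ≈ 9 — *between* the two thresholds — so selection of a true effect of
that size is close to a coin flip by construction of the thresholds; the
unit tests therefore exercise the machinery at a decisively detectable
effect size, and the recovery studies re-estimate the effect with it already
in the model rather than re-selecting it.

### Bootstrap

`pk_bootstrap()` resamples subjects with replacement within sex strata,
refits warm-started from the original estimates, and reports medians with
2.5/97.5 percentiles; replicates that error or fail to converge are counted
and >20% failures flag the result unstable.

## 6. External evaluation and diagnostics

* **Prediction errors**: `PE = (pred − obs)/obs` per observation; median PE,
  `MPE = mean(PE)` and `RMSE = sqrt(mean(PE²))` reported in percent, at both
  the population (η = 0) and individual (conditional-mode) level. Under this
  sign convention a positive MPE is overprediction. The exact identity
  `RMSE² = MPE² + Var(PE)` (population variance) is asserted in the tests.
  Observations ≤ 0 are excluded with a warning count.
* **NPDE**: per subject, `n_sim` replicate vectors (new η and ε) are
  simulated; observed and simulated vectors are decorrelated with the
  empirical mean and Cholesky factor of the simulated covariance
  (ridge-regularized with a warning if singular); the mid-rank of each
  decorrelated observation among its simulations, clamped to
  (1/(2·n_sim), 1 − 1/(2·n_sim)), is mapped through Φ⁻¹. Three tests are run
  on the pooled vector: Wilcoxon signed-rank (location 0), a two-sided χ²
  variance test (variance 1), and Shapiro–Wilk (normality; skipped outside
  its 3–5000 sample-size domain). Note that requiring *all three* 5%-level
  tests to pass simultaneously has a joint null pass rate of roughly 86%
  per dataset if the tests were independent — a well-specified model will
  "fail" such a joint screen on a nontrivial fraction of replicates, which
  matters when interpreting repeated-calibration experiments.
* **CWRES**: residuals of the FOCE linearization about the conditional
  modes, scaled by the Cholesky square root of `V_i`; pooled CWRES are
  approximately standard normal under the true model.
* **VPC**: dose-level binning by default (the natural axis for trough-only
  data; time binning available), bins under 5 observations merged upward,
  observed 5/50/95th percentiles against 95% simulation intervals from
  `n_sim` replicate cohorts. Prediction correction scales each value by
  `median(PRED in bin)/PRED`, which pools dose levels when bins mix doses
  (e.g. time bins).

## 7. Dose-regimen simulation and PTA

`run_scenario()` draws virtual subjects (covariates from a cohort, a design,
or the scenario's sex stratum), samples clearance random effects, computes
the day-30 trough per analyte by *finite* superposition (30 doses — for the
joint model indistinguishable from the steady-state limit), and classifies
the active-moiety trough against the 120–500 ng/mL window. Residual
(assay-level) noise is off by default — target attainment is judged on the
underlying concentration, and a sensitivity test shows medians are
insensitive to the flag; when on, negative draws are floored at zero and
counted.

A structural observation that matters for interpreting PTA: at the joint
model's rate constants the trough is a steep function of clearance
(d log C / d log CL ≈ −2.3), so the 31.6% IIV on parent clearance expands to
roughly a 0.7 log-SD trough distribution. Medians consequently reproduce
tightly (the simulated female/male 60-mg medians land within ~1% of their
reference values) while tail-sensitive quantities such as "fraction inside
the window" sit close to, and at the range edges slightly below, the 70%
mark (about 68–69% at female 20 mg and male 30/50 mg). Without the source
dataset's interquartile tables there is nothing to calibrate the spread
against, and none of the generator's inputs is adjusted to move these
fractions.

## 8. Problem sizes used by the tests and acceptance script

Simulation checks use 1000 virtual subjects per scenario; null-calibration
studies 20 replicate cohorts of 50 subjects with 1000 Monte Carlo
simulations each; parameter-recovery 198-subject cohorts with 20 replicate
fits in the tests and 16 in the acceptance script; closed-form/ODE
cross-checks 100 random parameter sets spanning a 10-fold log-uniform range
around the shipped values. These sizes are the package's chosen balance of
Monte Carlo precision against a desk-scale run.

## 9. Known limitations

* Linear PK only: no saturable elimination, enterohepatic recirculation,
  absorption lag or transit chains — none of the shipped models has them.
* Milk exposure is a scalar milk-to-plasma multiplier; no milk kinetics.
* No inter-occasion variability or η-correlation estimation.
* FOCE-I at desk scale: OFVs are not bit-comparable with other software, and
  the estimator inherits conditional-linearization small-sample bias (~+7%
  on parent clearance at the study design).
* Trough-only designs do not identify volumes; the package makes this
  explicit rather than papering over it.
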