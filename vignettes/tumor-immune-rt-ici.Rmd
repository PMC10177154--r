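---
title: "Modeling tumor response to combined radiotherapy and CTLA-4 blockade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor response to combined radiotherapy and CTLA-4 blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtici)
```

## The model

`rtici` simulates four interacting compartments of a patient with two
lesion classes -- one inside and one outside the radiation field -- and a
systemic immune pool:

* $T_I$: viable tumor cells in the irradiated lesion,
* $I$: dying (inactivated) tumor cells produced by radiation,
* $T_{NI}$: viable tumor cells in the non-irradiated (metastatic) lesion,
* $L$: circulating lymphocytes.

Between treatment events the compartments obey

$$
\begin{aligned}
\frac{dT_I}{dt} &= a\,T_I - \omega_1 \frac{T_I}{g + T_I + T_{NI}}\,L, \\
\frac{dI}{dt} &= -r\,I, \\
\frac{dT_{NI}}{dt} &= a\,T_{NI} - \omega_1 \frac{T_{NI}}{g + T_I + T_{NI}}\,L, \\
\frac{dL}{dt} &= \omega_2\,(1 + \delta(t))\,\frac{T_I + T_{NI}}{g + T_I + T_{NI}}\,L
  + \omega_3 \frac{I}{g + I}\,L + s - f\,L .
\end{aligned}
$$

Tumor cells grow exponentially at rate $a$ and are killed by lymphocytes
through a saturating contact term ($\omega_1$, half-saturation $g$).
Viable and dying tumor burden both recruit lymphocytes ($\omega_2$,
$\omega_3$); lymphocytes regenerate at rate $s$ and turn over at rate $f$.
The CTLA-4 checkpoint inhibitor enters through the dimensionless efficacy
$\delta(t)$, which amplifies the tumor-driven recruitment term
$\omega_2$: blockade of CTLA-4 produces a mild systemic expansion of
activated lymphocytes rather than a direct increase in per-cell killing.

A sensitivity switch (`model_parameters(delta_target = "omega3")`) attaches
the amplification to the dying-cell term $\omega_3$ instead.  The default
is $\omega_2$: only the $\omega_2$ route lets drug monotherapy act at all
(without radiation there are no dying cells, so an $\omega_3$-coupled drug
would be inert in the drug-only arm that the calibration reproduces).  The
switch exists because the indirect, $\omega_3$-mediated reading is a
plausible alternative mechanism for CTLA-4 agents and is worth probing in
sensitivity analyses.

### Radiation: impulsive linear-quadratic kill

Radiation cell death is not folded into the differential equations.  Each
fraction with tumor dose $D_T$ and effective lymphocyte (whole blood) dose
$D_L$ is an instantaneous map applied at the scheduled time:

$$
T_I \mapsto T_I\,e^{-\alpha_T D_T - \beta_T D_T^2}, \qquad
I \mapsto I + T_I\,(1 - e^{-\alpha_T D_T - \beta_T D_T^2}), \qquad
L \mapsto L\,e^{-\alpha_L D_L},
$$

with $\beta_T = \alpha_T / (\alpha_T/\beta_T)$ derived from the fixed
$\alpha/\beta$ ratio and lymphocyte kill purely linear in dose (no
$\beta_L$ term is carried by the model).  Killed tumor cells move to the
dying compartment, so each fraction conserves cells exactly: the viable
loss equals the dying-compartment gain, a property the test suite enforces
to a relative tolerance of $10^{-10}$.  The integrator is stopped and
restarted at every event so no impulse is smeared across a step.

### Checkpoint-inhibitor pharmacodynamics

The efficacy decays exponentially from each administration,
$\delta(t) = \delta_0\,e^{-\lambda\,(t - t_{\text{dose}})}$ with
$\lambda = \ln 2 / t_{1/2}$.  Two quantities are deliberate assumptions,
prominently configurable in `ici_pharmacodynamics()`:

* **Half-life** $t_{1/2} = 22$ d, the published elimination half-life of
  tremelimumab.
* **Dosing**: one administration every 90 days (decay clock resetting at
  each dose), the quarterly regimen used in the tremelimumab monotherapy
  trial whose response rates calibrate the model.  A single administration
  is available via `repeat_interval = NULL`, but it is not the default: a
  single dose decaying with a 22-day half-life is pharmacologically
  extinct after three months, every response-curve column then collapses
  into near-universal progression, and the calibration objective becomes
  flat -- no efficacy distribution can reproduce a trial in which most
  patients had stable disease.  Quarterly maintenance is both what the
  trial did and the minimal structure under which the calibration is
  well-posed.

## Parameters

| Symbol | Meaning | Default | Units |
|---|---|---|---|
| $a$ | tumor growth rate | 0.01 | 1/d |
| $\omega_1$ | lymphocyte killing efficiency | 0.119 | 1/d |
| $\omega_2$ | viable-tumor-driven recruitment (drug target) | 0.003 | 1/d |
| $\omega_3$ | dying-cell-driven recruitment | 0.009 | 1/d |
| $g$ | half-saturation constant | $7.33\times10^{10}$ | cells |
| $s$ | lymphocyte regeneration | $1.47\times10^{8}$ | cells/d |
| $f$ | lymphocyte decay | 0.033 | 1/d |
| $r$ | dying-cell clearance | 0.14 | 1/d |
| $\alpha_T$ | tumor LQ alpha | 0.139 | 1/Gy |
| $\alpha_T/\beta_T$ | tumor alpha/beta ratio | 14.3 | Gy |
| $\alpha_L$ | lymphocyte LQ alpha | 0.737 | 1/Gy |
| density | tumor cells per unit volume | $10^{9}$ | cells/cm$^3$ |

The tumor-free lymphocyte equilibrium is $L^\ast = s/f \approx
4.45\times10^{9}$ cells; an untreated tumor-free patient sits exactly at
this fixed point, which the tests assert.

The default radiotherapy regimen -- five daily fractions of 8 Gy to the
tumor with an effective whole-blood dose of 0.5 Gy per fraction -- is an
assumption (the calibrating trial's regimen is not published) and is
carried, flagged as such, in every experiment's provenance block.

## Virtual cohorts

`sample_cohort()` draws per-patient baseline tumor diameter, lymphocyte
count, radiosensitivity $\alpha_T$ and drug efficacy $\delta_0$ from
normal distributions truncated at zero by rejection (rejection rather than
clipping, so the retained density keeps its shape; the truncated mass is
tiny for all defaults).  Defaults:

* tumor diameter $\mathcal N(5, 1.5^2)$ cm, converted to cells through the
  spherical volume $(\pi/6)d^3$ and the $10^9$ cells/cm$^3$ density, then
  split between $T_I$ and $T_{NI}$ by the prescribed irradiated tumor
  fraction (ITF);
* lymphocytes $\mathcal N(4.45\times10^9, (10^9)^2)$, centered on the
  tumor-free equilibrium $s/f$;
* $\alpha_T \sim \mathcal N(0.139, 0.0139^2)$ (10% coefficient of
  variation), with $\beta_T$ co-varying through the fixed $\alpha/\beta$;
* $\delta_0 \sim \mathcal N(37, 4^2)$ until replaced by a calibrated fit.

The baseline diameter and lymphocyte spreads are assumptions: the
calibrating trial's baseline distributions are unpublished.  This matters
more than it may appear.  The height of the stable-disease plateau in the
response curve is governed almost entirely by how heterogeneous the cohort
is -- each patient has a narrow window of efficacies that hold their tumor
inside the stable-disease band for a year, and the category fraction at
any one efficacy is the probability that a random patient's window covers
it.  Narrower baseline spreads give taller stable-disease peaks.  The
defaults here produce a peak near 50%; cohorts drawn from tighter
(unpublished) baseline distributions can reach the higher peaks reported
for this model class.  We keep the declared defaults rather than tuning
the spread to the target.

What the generator does **not** emulate: correlated baselines (tumor size
and immune status are drawn independently), measurement noise on
diameters, inter-lesion heterogeneity within a patient (both lesions share
one growth rate and one radiosensitivity), and dropout or death before the
one-year assessment.  Passing tests therefore demonstrate internal
consistency of the model and procedures, not fidelity to any real-world
cohort beyond the reproduced summary rates.

## RECIST 1.1 evaluation

Simulated cell counts are converted to lesion diameters by inverting the
sphere volume.  The irradiated lesion comprises viable **plus dying**
cells -- radiation moves cells between those compartments instantaneously,
and a lesion does not shrink on the day of irradiation; regression follows
as the dying compartment clears at rate $r$.  Assessments are monthly over
a one-year horizon; the baseline is the pre-treatment state at $t = 0$.

Classification (`classify_response()`, thresholds in `recist_rules()`):

* **PD** if any assessment is $\ge 20\%$ above the running nadir
  (baseline included) *and* at least 5 mm above it; progression takes
  precedence over anything that happens later.
* otherwise **CR** if the best diameter falls below 1 mm (a concrete
  surrogate for "disappearance"), **PR** at a best change of $-30\%$ or
  better from baseline, **SD** otherwise.

Whole-patient (trial-style) classification applies the rules to the sum
of the two lesion diameters; per-lesion classification applies them to
each lesion separately, and a lesion absent at baseline is non-evaluable
(`NA`) rather than misclassified.  New-lesion and non-target rules of the
full RECIST specification are out of scope: the model has exactly two
lesions by construction.

The nadir reference makes the classifier strict about regrowth: a tumor
that dips and then recovers by 20% is progressive disease even if it ends
the year smaller than it started.  Because the drug efficacy decays
between quarterly doses, late regrowth windows are common, and this rule
materially lowers stable-disease and clinical-benefit rates relative to a
baseline-referenced variant (`recist_rules(pd_min_abs_cm = 0)` and the
threshold arguments let users explore such variants).

## Calibration

The efficacy distribution is calibrated in two stages
(`response_curve()`, then `fit_delta_distribution()`):

1. **Response curve.**  One cohort of 10,000 patients is sampled and
   reused across a grid of efficacies $\delta \in \{0, 1, \dots, 99\}$
   (common random numbers).  For each grid value every patient's
   $\delta_0$ is fixed to it, the drug-only schedule is simulated, and the
   whole-patient RECIST fractions are recorded.
2. **Convolution and grid search.**  A candidate $\mathcal N(\mu,
   \sigma^2)$ is scored by mixing the curve's rows with normal-density
   weights evaluated at the grid points (truncated to the grid and
   renormalized -- the weights sum to one to $10^{-12}$, enforced by
   tests), and the discrepancy to the reference rates (CR 0%, PR 17.6%,
   SD 58.8%, PD 23.6%) is the sum of absolute differences over PR, SD and
   PD.  CR is excluded by default because its reference is exactly zero
   and its column is zero over most of the grid; `categories =` includes
   it on request.  The search runs over $\mu \in \{0,\dots,99\}$ and
   $\sigma \in \{0.5,\dots,20\}$ (step 0.5), ties broken toward the
   smallest $\sigma$, then the smallest $\mu$.

The fit is exactly self-consistent: a reference synthesized from the curve
itself by `convolve_rates()` at any grid point $(\mu^\ast, \sigma^\ast)$
is recovered exactly, which the acceptance tests assert.
`validate_calibration()` then draws a *fresh* cohort with
$\delta_0 \sim \mathcal N(\hat\mu, \hat\sigma^2)$ (truncated at zero) and
re-simulates, giving an honest out-of-sample closure check whose rates the
acceptance script reports.

## In-silico experiments

* `run_modality_comparison()` simulates one seeded cohort under four arms
  (none / drug only / RT only / combination) and reports per-lesion
  summaries and waterfall values.  Default 100 patients (the size used
  for waterfall displays) and ITF 0.5 (an assumption, configurable).
* `run_itf_sweep()` re-splits the same sampled patients across a grid of
  irradiated tumor fractions in $(0, 1]$; values above 1 are rejected
  because the fraction $T_I/(T_I+T_{NI})$ cannot exceed 1.
* `run_sequencing_sweep()` anchors radiotherapy at day 180 of the horizon
  and starts the drug `offset` months before it (positive offset: drug
  first).  Anchoring one modality is forced by the requirement that an
  inert drug make all offsets equivalent -- if both start times moved with
  the offset, the radiation-only dynamics would differ across offsets.
  With the mid-horizon anchor the drug start stays within $[0, 360]$ d
  for the full $\pm 6$ month range; schedules that would outrun a custom
  horizon extend it with a warning.

Every experiment result carries a provenance block (seed, parameter
fingerprint, the assumed RT regimen and drug schedule, package version)
and reruns byte-identically for a given seed and configuration.

## Numerical choices

* **Integrator.**  Single patients use `lsoda` (adaptive,
  stiff-capable).  Cohorts are stacked into one vectorized system (4
  states per patient) and use the non-stiff Adams method: between events
  the dynamics are smooth with rates well below 1/d, and a stiff solver
  would allocate a dense Jacobian quadratic in the stacked dimension.
  Tolerances are `rtol = 1e-8`, `atol = 1e-2` cells (compartments span
  roughly $10^0$ to $10^{11}$).  Agreement between `lsoda` and an
  independent implicit Runge-Kutta integration (`radau` at halved
  tolerances) is below $10^{-6}$ relative error at the one-year horizon.
* **Events.**  Integration restarts at every RT fraction and drug
  administration; when the drug is inert ($\delta_0 = 0$ or no drug),
  administration times are not treated as events, so the reduced model
  reproduces the RT-only model bit for bit.
* **Eradication floor.**  A viable tumor compartment below one cell at an
  event time or segment end is set to zero and stays there: cell counts
  are physical, and sub-cellular remnants must not regrow.  Within a
  segment the floor is not checked (the continuous dynamics cannot reach
  zero from a positive state).
* **Degenerate inputs.**  Zero doses are identities; `sigma = 0`
  convolution is a point mass at the nearest grid point; candidate
  distributions with essentially no mass on the grid are rejected (and
  scored as infinitely bad inside the grid search); a lesion class absent
  at baseline is non-evaluable rather than an error at the cohort level.

## Problem sizes

Calibration and its validation use 10,000-patient cohorts (the scale at
which the reference rates are quoted); the response curve costs about
100 stacked integrations of 40,000 ODEs and runs in minutes on one CPU.
Waterfall-style comparisons default to 100 patients; rate contrasts that
must resolve differences of a percentage point or less are run at 1,000.

## Known limitations

* The stable-disease plateau of the response curve is capped by the
  assumed baseline heterogeneity (see above); closure against the
  reference rates is correspondingly imperfect on the PR and SD margins,
  while CR and PD close well.  The acceptance script reports the achieved
  rates; nothing is tuned toward the targets.
* Under the strict nadir-referenced progression rule, the distant lesion
  usually locks in progression during the radiation-induced lymphopenic
  window before the drug (whose effect multiplies $\omega_2 L$ and is
  therefore silenced while $L$ is depleted) can act; the combination's
  benefit over RT alone on the non-irradiated lesion is then essentially
  a tie at the default blood dose of 0.5 Gy/fraction.  Lower effective
  blood doses separate the arms; the default is kept as declared.
* The model carries no drug concentration compartment (efficacy decay
  stands in for pharmacokinetics), no spatial dose distribution, no
  organ-at-risk constraints, and no survival endpoints.
* Irradiated tumor fractions above 1 (irradiating normal tissue beyond
  the tumor) are not expressible in the model's state and are rejected.
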