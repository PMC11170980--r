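---
title: "Modeling the cardiovascular response to hemorrhage and fluid resuscitation"
author: "cvfluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cardiovascular response to hemorrhage and fluid resuscitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cvfluid` implements a low-order lumped-parameter model of the
cardiovascular response to fluid perturbation — hemorrhage, urine loss and
fluid infusion — together with the statistical machinery needed to use it
as an in-silico evaluation tool for fluid-resuscitation controllers:
maximum-likelihood calibration, compartment-method virtual-cohort
generation, and predictive-capability (credibility) metrics.  This
vignette documents the model, the numerical and statistical design
choices, and what the packaged synthetic experiments do and do not
demonstrate.

## The model

The model takes two non-negative input rates, the infusion rate $U(t)$ and
the loss rate $V(t)$ (both l/min, piecewise constant in practice), and
produces six observables: blood volume $BV$ (l), hematocrit $HCT$ (%),
heart rate $H$ (bpm), stroke volume $SV$ (l), cardiac output
$CO = H \cdot SV$ (l/min) and mean arterial pressure $BP = CO \cdot TPR$
(mmHg).  It is an 11-state ODE system assembled from four sub-models.

**Blood volume.**  Two first-order references track the steady-state
volume change each input channel is driving toward,
$$\dot r_U = A_{U,BV}\, r_U + \frac{U}{1+\alpha_U}, \qquad
  \dot r_V = A_{V,BV}\, r_V - \frac{V}{1+\alpha_V},$$
with distribution ratios $\alpha_U, \alpha_V$ splitting fluid between the
intravascular and interstitial spaces.  A proportional controller mimics
trans-capillary fluid shift toward the reference change
$r_{BV} = r_U + r_V$:
$$\dot{BV} = U - V - q, \qquad
  q = K_{P,BV}\,\bigl(BV - BV_0 - r_{BV}\bigr).$$
Red-cell content is depleted only by loss, $\dot{RBC} = -V \cdot HCT$ with
$HCT = RBC / BV$; hematocrit is carried in percent, so $RBC$ has units
%·l (the ratio definitions are invariant to this scaling).

**Heart rate.**  Loss produces a transient rise
$\dot H_{V,T} = G_{V,T} V$ and a controller-mediated long-term rise
$H_{V,L}$ tracking the reference $\dot r_{HV,L} = G_{V,L} V^{P_{V,L}}$
through a PI law on the error $e = r_{HV,L} - H_{V,T} - H_{V,L}$:
$$\dot H_{V,L} = K_{P,H}\, e + K_{I,H} \int e .$$
Infusion produces a transient drop integrated as
$\dot H_{U,T} = G_{U,T} U^{P_{U,T}}$ (the dimensional bookkeeping of the
summed heart-rate channels requires this infusion response to be a rate,
so it is integrated like the other channels).  Heart rate itself is
evaluated algebraically, $H = H_0 + H_{V,T} + H_{V,L} - H_{U,T}$, rather
than integrated as a redundant twelfth state, which removes a source of
numerical drift while being exactly the integral of the summed channel
rates.

**Stroke volume.**  Relaxation around the baseline and toward a
subject-specific contractility reference $r_{SV}$, a proportional coupling
to blood-volume change, and an inverse coupling to heart-rate change:
$$\dot{SV} = A_{SV}(SV - SV_0) + G_{BV}\,\dot{BV}
  + K_{P,SV}(r_{SV} - SV) - G_{HR}\,\dot H .$$
The sign of the $G_{HR}$ term deserves a note: composing the
channel definitions literally yields $+G_{HR}\dot H$, but the stated
physiology (faster heart rate shortens ventricular filling and lowers
stroke volume — the Frank–Starling rationale) requires the net effect to
be negative.  The package implements the physiological reading by default
and exposes `sv_hr_sign = "literal"` for the alternative composition.

**Blood pressure.**  Total peripheral resistance relaxes around its
baseline and responds to the pressure error against a subject-specific
reference $r_{BP}$:
$$\dot{TPR} = A_{BP}(TPR - TPR_0) + K_{P,BP}(r_{BP} - BP), \qquad
  BP = H \cdot SV \cdot TPR .$$

A subject is then 25 parameters: 20 dynamic parameters grouped into BV
(5), HR (7), SV (5) and BP (3) compartments plus the five baselines
$HCT_0, BV_0, H_0, SV_0, TPR_0$.  The packaged reference table contains 27
calibrated sheep parameter vectors (`reference_subjects()`), which anchor
the parameter scales, the search bounds and the virtual-cohort donors.

### Numerical choices

* **Power terms at rest.**  $V^{P_{V,L}}$ and $U^{P_{U,T}}$ are defined as
  0 whenever the rate is 0, for any exponent (including 0): both terms
  model perturbation responses that must vanish at rest.
* **Integrator.**  The production solver is a compiled fixed-step
  classical RK4 at `dt = 0.01` min that restarts exactly at protocol
  breakpoints, so piecewise-constant inputs are never smoothed across a
  discontinuity.  The system is non-stiff — all rate constants in the
  reference set are at most about 1/min — so a fixed 0.01-min step is far
  inside the accuracy budget, and a fixed-step compiled kernel keeps the
  cost of cohort-scale studies (tens of thousands of piecewise-protocol
  simulations) at a few milliseconds per subject, where an adaptive solver
  restarted ~30 times per protocol would spend most of its time in
  per-segment setup.  An independent `solver = "lsoda"` path integrates
  the pure-R right-hand side with `deSolve` and is cross-checked against
  the compiled kernel in the test suite, alongside a brute-force Euler
  oracle at `dt = 0.001` min.
* **Failure semantics.**  Non-finite states or exhausted blood volume
  (`BV <= 0`) terminate the integration; the partial trajectory is
  returned flagged unsuccessful rather than raising, because cohort
  screening and optimization both need to survive bad parameter draws.
* **Degenerate equilibria.**  `equilibrium_tpr()` refuses the case
  $A_{BP} = K_{P,BP}\,H\,SV$ (with the sign constraints this requires both
  terms to vanish), where the resistance dynamics have no fixed point.

## Synthetic experiment fixtures

No animal data ship with the package; the `fixtures` module emulates the
two experiment designs the model targets so that every downstream module
is testable end to end.

* **Sheep-like protocol** (`make_sheep_protocol()`): a 180-min experiment
  with a 25 ml/kg hemorrhage spread over minutes 0–15, 5 ml/kg hemorrhages
  over minutes 50–55 and 70–75, and resuscitation infusion over the final
  150 minutes.  The original experiments drove the infusion with a
  closed-loop controller whose law is not available; the package stand-in
  is a discrete PI law updating every 5 min to steer the simulated
  pressure of a reference subject (default: reference subject LR1) back to
  its baseline, clamped to [0, 0.3] l/min, and the resulting profile is
  frozen into an open-loop piecewise-constant protocol shared by all
  subjects.  This reproduces the qualitative shape of a resuscitation
  profile; it makes no claim about the original device.
* **Swine-like protocol** (`make_swine_protocol()`): hemorrhage at a
  configurable weight-scaled rate (default 1 ml/kg/min, a package choice)
  until the simulated pressure of the supplied subject first crosses a
  stop target (default 40 mmHg), then repeated boluses of 500 ml per 70 kg
  body weight with 60-min washouts.
* **Measurements** (`sample_measurements()`): the trajectory is sampled
  every 5 or 10 min and perturbed with zero-mean i.i.d. Gaussian noise
  whose SD is a fraction of the variable's baseline — 2% for hematocrit
  (a tight assay) and 5% for the hemodynamic variables by default, chosen
  once to make parameter recovery non-trivial but feasible.  Readings that
  come out non-positive (possible when a trajectory collapses toward zero)
  are censored as missing, mirroring monitor dropout during hemodynamic
  collapse; downstream metrics skip missing values.  Urine loss is folded
  into $V(t)$ and off by default.
* **Body weight.**  When a reference subject serves as a synthetic test
  subject, its protocol is scaled to the body weight implied by its own
  measured blood volume at the standard 60 ml/kg — a fixed weight would
  over-hemorrhage small-blood-volume subjects far beyond the 35 ml/kg
  total the design prescribes.

What the fixtures do **not** emulate: anesthesia physiology (the swine
experiments were anesthetized, which shifts compensation substantially),
autocorrelated or heteroscedastic measurement error, missing-data
patterns of real monitors, and inter-animal protocol deviations.  Passing
the packaged synthetic suites therefore demonstrates self-consistency of
the pipeline — recovery of known parameters and coverage of held-out
*synthetic* subjects — not fidelity to any animal dataset.

## Calibration

Measurements $v(t_k) = \hat v(t_k \mid \Theta) + e(t_k)$ are modeled with
independent Gaussian errors per variable; the per-variable log-likelihood
is
$$L^*(\Theta,\sigma) = -\tfrac{K}{2}\ln(2\pi) - \tfrac{K}{2}\ln\sigma^2
  - \tfrac{1}{2\sigma^2}\textstyle\sum_k e(t_k)^2 ,$$
and the fitted parameters minimize
$-\sum_v L^*_v + 2\beta\,\lVert\Theta\rVert^2$ over
$v \in \{HCT, HR, SV, BP\}$ — cardiac output is excluded from the
likelihood because it is the product of two fitted variables, but it is
reported in the fit metrics.  Design choices:

* $\sigma$ is concentrated out analytically per variable
  ($\hat\sigma^2 = \frac1K\sum e^2$, floored at $10^{-6}$ in the
  variable's units so noiseless data cannot send the likelihood to
  $-\infty$); this is equivalent at the optimum and much better
  conditioned than joint optimization.
* The penalty norm is taken over *scale-normalized* free parameters
  $\theta_j / s_j$, with $s_j$ the largest magnitude parameter $j$ attains
  across the reference subjects: the parameters span five orders of
  magnitude, and an unscaled norm would regularize only the largest ones.
  The squared-norm reading of the penalty is the default; a literal-norm
  reading is available (`penalty = "norm"`).  $\beta$ defaults to
  $10^{-3}$ and is configuration-exposed.
* The 22 free parameters (everything except the measured $BV_0$, $HCT_0$,
  $SV_0$) are optimized with bounded L-BFGS-B in the scaled space, within
  sign-constrained boxes obtained by widening the reference-set ranges
  threefold (stability parameters non-positive, gains non-negative,
  exponents in [0, 1], distribution ratios above −0.95 so the input gains
  keep their sign).
* **Multi-start feasibility.**  Almost the entire widened box corresponds
  to dynamically unstable closed loops whose simulations diverge
  (empirically under 1% of uniform draws even complete a simulation), so
  unconditional uniform starts would leave every start on a flat failure
  plateau.  Two measures address this: a failed simulation returns a
  *graded* finite penalty, $10^{10}(2 - t_{\text{fail}}/T)$, so finite
  differences point toward longer-surviving parameter regions; and the 16
  default starts are uniform draws within the bounds *rejection-sampled*
  until the initial simulation succeeds (cap 500 tries per start).  The
  best start by final objective is returned, with per-start diagnostics.
* **Staged initialization.**  The model has a cascade structure: the
  hematocrit/blood-volume states depend only on the BV compartment, the
  heart-rate states only on the HR compartment (plus $H_0$), stroke volume
  on the BV, HR and SV compartments, and pressure on everything.  One of
  the multi-start seeds is therefore built by fitting each compartment in
  that order to its own variable (HCT, HR, SV, BP) with a small bounded
  search, starting from an inert, guaranteed-stable base point (zero gains
  and state parameters, mid-box references).  This start typically lands
  in the basin of the joint optimum; the random starts guard against the
  cascade itself being misleading.  Joint refinement always optimizes the
  full objective, and the most promising starts get a longer iteration
  budget (`polish_top`, `polish_maxit`).  Gradients are forward finite
  differences of a fast objective path that calls the compiled kernel
  directly (step $10^{-6}$ in scaled units, integration step 0.02 min
  during optimization).

## Virtual cohort generation

The compartment method transplants whole parameter blocks so that the
within-block parameter combinations of every virtual subject come from
(or are averages of) actually-calibrated subjects: a **mixing** subject
takes its BV, HR, SV and BP compartments from four distinct donors drawn
from the calibration set; an **average** subject takes each compartment as
the arithmetic (unweighted) mean over three distinct donors.  With $N$
calibration subjects the ordered enumeration has $N^4$ mixing and $N^3$
average constructions — 474,552 in total for the leave-one-out
configuration ($N = 26$) and 551,124 for independent validation
($N = 27$); `count_mixing()`, `count_average()` and `count_total()` expose
these counts.  The counting convention is the ordered assignment with
repetition (which is what those totals enumerate), while the
runtime sampler enforces distinct donors within each tuple; the sampler
draws mixing subjects with probability $N/(N+1)$, the mixing share of the
pool.  Whether compartments are matched to donors in a fixed or random
order is not specified anywhere; the sampler assigns them in the (random)
order the donors are drawn.

Baselines are *not* inherited from donors: each virtual subject's five
baselines are drawn independently from
$\mathrm{Normal}(\text{measured}, 0.10 \times \text{measured})$ around the
test subject's values, truncated at zero by redraw (and hematocrit below
50%), which at 10% SD is a vanishingly rare correction.  This focuses the
credibility assessment on dynamic-pattern similarity rather than
initial-condition similarity.  $TPR_0$ is not directly observable and is
derived as $BP_0 / (H_0 \cdot SV_0)$ when building test baselines from
observations.

## Credibility assessment

Against a test subject, `assess_cohort()` runs the three-step pipeline:

1. **Physiological filter**: a simulation survives if over its whole
   output grid $HCT \in (0, 50]$ %, $H \in (0, 300]$ bpm,
   $SV \in (0, 0.100]$ l and $BP \in (0, 150]$ mmHg (boundary values kept,
   cardiac output unconstrained, failed simulations excluded).
2. **Relevance filter**: NRMSE against the test measurements at or below
   25% on *every* one of HCT, HR, SV, CO, BP; one bad variable
   disqualifies a simulation.
3. **Envelope metrics**: the prediction envelope is the pointwise min/max
   across relevant simulations at the measurement times.  Coverage is the
   per-variable fraction of observations inside the envelope, averaged
   unweighted across the five variables.  The normalized interval score
   per observation is the relative envelope width plus a $2/\alpha$
   penalty (at $\alpha = 0.05$) on the relative distance outside the
   envelope; the per-variable NIS is the mean over measurement times
   (the per-point score is defined pointwise; averaging over time is this
   package's aggregation choice).  The best virtual subject minimizes the
   average NRMSE across the five variables (ties broken by smaller
   maximum NRMSE, then by cohort order), and its negative log-likelihood
   against the test data reuses the calibration error model over
   HCT/HR/SV/BP.

If no simulation passes the relevance filter the report carries a
no-envelope flag instead of metrics — with small cohorts this genuinely
happens, and it is part of the method's output, not an error.

## Problem sizes in the packaged experiments

The package's own test suite exercises the pipeline at desk scale, chosen
once as the smallest sizes at which the stochastic checks are stable:
parameter-recovery calibration uses one reference subject, 5-min sampling
(37 samples per variable), default noise and 16 starts; the leave-one-out
credibility study uses all 27 reference subjects as synthetic test
subjects with cohorts of 2,000 virtual subjects each.  The enumeration
counts, equilibrium identities, conservation laws and metric formulas are
checked exactly; the solver is checked against the Euler oracle on all 27
subjects with per-variable scaled relative error (pointwise relative error
at stroke-volume values near zero would measure the first-order oracle's
own error, not the solver's).

## Known limitations

* The model is a lumped, non-pulsatile description; it has no arterial
  tree, no baroreflex transfer dynamics beyond the lumped controllers, and
  no pharmacokinetic distinction between fluids beyond parameter values.
* Calibration is maximum-likelihood with an L2 penalty; no posterior
  uncertainty or formal identifiability analysis is provided.
* The closed-loop infusion law used by the sheep fixture is a documented
  stand-in, and the swine hemorrhage rate default is a package choice —
  neither should be read as a property of any animal experiment.
* Credibility conclusions from the packaged experiments are statements
  about synthetic subjects generated by this model; they quantify
  pipeline self-consistency, not agreement with animal data.
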