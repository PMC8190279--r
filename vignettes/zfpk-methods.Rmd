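---
title: "Modelling whole-body fluorescence pharmacokinetics in zebrafish eleuthero-embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-body fluorescence pharmacokinetics in zebrafish eleuthero-embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpk)
```

## The problem

Zebrafish eleuthero-embryos (hatched, 3–5 days post-fertilization) are a
standard vertebrate system for pharmacology and toxicity screening. Compounds
are usually administered by immersion in the bath medium, but hydrophilic
compounds may barely be absorbed, producing false-negative screens.
Microinjection into the pericardial cavity (PC) or intraperitoneally (IP)
bypasses absorption but is laborious. Deciding between routes — or combining
them — requires knowing how much compound is actually inside the animal over
time.

`zfpk` models that question for fluorescent compounds, where the whole-body
integrated fluorescence of a micrograph is a direct readout of the intrabody
amount. The package covers the full chain: quantifying fluorescence from
images and body contours, fitting a one-compartment disposition model,
deriving route-comparison metrics from AUCs, and regressing the
pharmacokinetic parameters on molecular descriptors (QSPkR). A seeded
synthetic-data generator reproduces the statistical structure of such a study
so that every stage is testable without any raw imaging data.

## The model

The intrabody amount $A(t)$ (ng) follows a one-compartment balance with
passive bidirectional exchange with the medium and first-order elimination:

$$\frac{dA}{dt} = -k_e A + Q M, \qquad A(0) = \mathrm{Dose},$$

with closed-form solution

$$A(t) = \mathrm{Dose}\,e^{-k_e t} + \frac{M Q}{k_e}\bigl(1 - e^{-k_e t}\bigr).$$

Here $k_e$ (h$^{-1}$) is the total elimination rate constant — the lumped
$(Q + CL)/V$ of the underlying mass balance, where one-way clearance $CL$ and
volume $V$ are not separately identifiable and therefore not represented —
$Q$ (L/h) is the passive exchange clearance, $M$ (ng/L) the medium
concentration, and Dose (ng) the injected amount. Pure immersion sets
Dose $= 0$; pure injection sets $M = 0$; a combined treatment keeps both, and
because the model is linear the combination trajectory is exactly the sum of
the two single-route trajectories.

Fluorescence enters through a compound-specific constant:
$\mathrm{RFU} = \mathrm{FLUOR} \cdot A$. FLUOR depends on quantum yield,
filter set and camera settings, so absolute fluorescence cannot be compared
across compounds; all reported comparison metrics are constructed to be
FLUOR-free.

Units are fixed internally: amount ng, time h, concentration ng/L, clearance
L/h, fluorescence RFU. On this scale a 2 mg/kg microinjection into a 0.25 mg
embryo is 0.5 ng exactly, and exchange clearances come out at the 1e-9 L/h
magnitude.

Assumptions worth stating: the medium is an infinite reservoir ($M$ constant;
a 5 mL well vastly exceeds embryo uptake over 48 h); distribution from the
injection site is fast relative to the sampling grid (no absorption-lag
term, so $A(0) = \mathrm{Dose}$ exactly); elimination is first order (no
saturable transport).

## Exposure metrics

Let $AUC(0, t_1)$ denote the closed-form integral of $A(t)$. Two
FLUOR-independent metrics compare routes:

* **Relative Exposure**, $RE = AUC_{imm}/AUC_{inj}$ over the same window,
  for the standard design of 10 µM immersion against a 0.5 ng (2 mg/kg)
  microinjection. $RE$ grows with the window: the injection limb decays
  while immersion accumulates toward the steady state $MQ/k_e$, so $RE(t_1)$
  is strictly increasing whenever $Q > 0$.
* **Relative Contribution**, $RC = 100 \cdot AUC_{route}/AUC_{comb}$ for a
  combined treatment. Linearity makes $AUC_{comb} = AUC_{imm} + AUC_{inj}$,
  so the two contributions sum to 100 exactly.

For the reference panel (`reference_compounds()`, `reference_pk_parameters()`)
these reproduce the known behaviour: short immersions underexpose strongly
(RE at 3 h is 0.14 for the most lipophilic compound and below 0.05 for all
others), while at 48 h RE spans 0.08 to 2.90 across the LogD range.

## Fitting

`fit_pk()` estimates (FLUOR, $k_e$, $Q$) per compound by nonlinear least
squares over all routes jointly — one shared parameter set, since both model
limbs are governed by the same $k_e$ and $Q$ and a single-route dataset
cannot identify all three parameters (FLUOR is then confounded with the dose
scale or with $Q$; the package warns and fixes $Q$ at its starting value).
Details:

* Optimization by Levenberg–Marquardt damped Gauss–Newton
  (`minpack.lm::nlsLM`), parameters on the log scale to enforce positivity;
  standard errors are mapped back by the delta method. Defaults: 200
  iterations, relative tolerance 1e-8.
* Starting values (`initial_estimates()`): $k_e$ from a log-linear
  regression of injection-route timepoint means from 1 h onward (the late
  window dodges the quench artifact), FLUOR from the back-extrapolated
  intercept over the dose, $Q$ from the initial immersion uptake slope over
  $\mathrm{FLUOR} \cdot M$; all clipped positive.
* Residual standard error is $\sqrt{SSE/(n-3)}$; half-life is
  $\ln 2 / k_e$.

### Censoring quench artifacts

Shortly after microinjection the compound is concentrated at the injection
spot and self-quenches, so the earliest injection observations underestimate
the amount present. The pipeline automates the residual-plot screening used
to exclude such points: alternate fit → flag → refit (`fit_pk_censored()`,
at most 3 rounds by default), flagging observations whose standardized
residual exceeds 2.5.

The standardization scale is a robust MAD estimate of the residual scale,
not the classical residual standard error. The artifact is a coherent
cluster (all replicates of the early injection cells), and in simulation a
non-robust scale is inflated by the cluster enough that the points mask one
another: at the study design (CV 10%, 10 replicates, 3 routes, 50%
attenuation before 1 h) the classical scale flags only ~72% of
artifact-bearing points within the default rounds, the MAD scale 100%. The
trade-off is that under proportional noise a single robust scale is
conservative for high-signal observations, censoring some legitimate noise
tails (of order 10–25% of points in heavy-noise designs); because that
censoring is symmetric about the fitted curve, simulations show the
parameter estimates are essentially unchanged (median $k_e$ error ~2%
either way). Censoring is monotone (flags only accumulate), refuses to
remove more than half of a compound's data, and stops when no new points
are flagged.

A `"window"` censoring mode is also provided, dropping all
injection-bearing observations before a cutoff (1 h or 3 h per compound) —
the hand-censoring practice the residual rule automates.

## QSPkR

With seven compounds, descriptor regression must be frugal:

* `covariance_screen()` first reduces the descriptor set (LogD, MW, TPSA,
  MR, HBA, HBD, rotatable bonds) so that no retained pair has |Pearson r|
  above 0.7 (greedy in column order; constant columns excluded with a
  warning).
* `stepwise_select()` searches forward and backward from the intercept-only
  model, minimizing AIC in the Gaussian convention
  $n \log(SSE/n) + 2k$. The centered square of LogD is offered as an extra
  candidate, admitted only alongside the linear term (hierarchy), and model
  size is capped at 2 non-intercept terms so at least 4 residual degrees of
  freedom remain. A selected model is only *reported* if its overall F-test
  has $p < 0.05$; on pure-noise responses this returns "no significant
  model" in the large majority of seeds, which is exactly the expected null
  behaviour (and what the rate constants show on the reference panel).
* `fit_centered_quadratic()` is the parabolic lipophilicity model
  $y = \beta_0 + \beta_1 \mathrm{LogD} + \beta_2(\mathrm{LogD} -
  \overline{\mathrm{LogD}})^2$. The quadratic term is centered at the
  sample mean (−0.177 for the reference panel), recomputed from the data;
  predictions are invariant to the centering constant even though the
  printed coefficients are not. On the reference panel this reproduces the
  known fits: $Q$ on LogD with $R^2_{adj} = 0.818$, RMSE 1.20e−9; RE at
  48 h with $R^2_{adj} = 0.756$, linear coefficient 0.540.

Fit statistics are computed from first principles
($R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-p-1)$,
$\mathrm{RMSE} = \sqrt{SSE/(n-p-1)}$, overall F), and the OLS solution is
tested against an explicit normal-equations solve.

## Shake-flask LogD and imaging

The LogD layer mirrors the shake-flask workflow: calibration lines are
fitted on level means (replicate %RSD kept as QC metadata; gates at
$R^2 \ge 0.998$ and %RSD $< 10$), concentrations are inverse-predicted, and
$\mathrm{LogD} = \log_{10}(C_{octanol}) - \log_{10}(C_{aqueous})$ — written
as a difference of logarithms so the antisymmetry under phase swap is exact
in floating point. The logarithm matters: hydrophilic dyes partition mostly
into the aqueous phase and carry negative LogD.

The imaging layer fixes conventions that manual-delineation workflows leave
implicit: 0-based row-major pixel grid, pixel centers at
$(col + 0.5, row + 0.5)$, even-odd point-in-polygon rasterization of the
body contour, and integrated intensity as the raw masked pixel sum (no
background subtraction by default). Exposure-time correction rescales
intensities linearly to a reference exposure. TIFF I/O is 16-bit lossless;
PNG is quantised to 8-bit depth by the underlying library.
`render_synthetic_embryo()` draws a teardrop-shaped body whose
within-contour sum equals $\mathrm{FLUOR} \cdot A$ exactly before Poisson
background, closing the test loop from pixels to amount.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: 7 compounds × 4 regimens
(10 µM immersion, 2 mg/kg PC and IP injections, combination) × 6 sampling
times (0.25, 1, 3, 6, 24, 48 h) × 10 replicates. Observations are
$\mathrm{FLUOR} \cdot A(t)$ under mean-one lognormal multiplicative noise
(default CV 20%; the mean-one convention is recorded in the provenance so
that large-sample means converge to the model curve), with an optional
quench artifact multiplying injection-route observations before 1 h by 0.5.
FLUOR truth values default to the 1e3–1e4 RFU/ng range, arbitrary per
compound, as absolute fluorescence scales are not comparable anyway. A
single user seed feeds an independent substream per (compound, route), so
extending a design never shifts existing draws.

What the generator deliberately does *not* emulate: per-embryo random
effects (only residual noise is generated, as no replicate-level variance
structure is known), spatial distribution within the body, yolk entrapment
after intra-yolk injection, or bath depletion. Passing tests therefore
validate the estimation machinery under the stated error model, not the
biological variance structure of a real experiment.

## Numerical choices and degenerate inputs

* ODE oracle: `deSolve::ode` (lsoda), rtol 1e-9 / atol 1e-12 — strictly
  tighter than the 1e-6 closed-form equivalence it certifies.
* Robust-scale and fit floors: the censoring scale is floored at
  $\sqrt{\varepsilon}$ times the mean signal so a perfect fit never censors
  its own rounding noise; $Q$ starting values are clipped to 1e-12 L/h when
  immersion data are flat (flagged).
* Degenerate inputs raise classed errors: empty regimen lists, nonpositive
  MW or ke, zero injection AUC in RE, zero-variance responses in
  regression, polygons with fewer than 3 vertices, zero calibration slopes.
* Problem sizes used by the test suite (chosen to make the statistical
  checks sharp at interactive runtimes): 100 random draws for the
  closed-form/ODE equivalence, 50 seeds for parameter recovery and quench
  detection, 100 seeds for the stepwise null, 20 seeds for image-background
  statistics.

## Limitations

One compartment only: compounds with slow internal redistribution would
need a peripheral compartment the data here cannot identify. $CL$ and $V$
are not separable from whole-body fluorescence. RE values are specific to
the 10 µM / 2 mg/kg design and do not extrapolate across immersion
concentrations. The QSPkR regressions rest on seven compounds; they
describe this panel and should not be read as general absorption models.
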