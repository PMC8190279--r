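# zfpk

Pharmacokinetics of fluorescent compounds in zebrafish eleuthero-embryos.

Zebrafish eleuthero-embryos (hatched, 3–5 dpf) are widely used to screen
compounds for pharmacological activity and toxicity. The standard exposure
route — immersion in the bath medium — can drastically under-deliver
hydrophilic compounds, producing false negatives; microinjection (pericardial
or intraperitoneal) delivers a known dose but is laborious. For fluorescent
compounds, the whole-body integrated fluorescence of a micrograph reads out
the intrabody amount directly, which makes the route comparison quantitative.

`zfpk` is for experimentalists and modellers designing such studies. It
implements:

* a **one-compartment disposition model** with passive medium exchange:

  $$A(t) = \mathrm{Dose}\,e^{-k_e t} + \frac{MQ}{k_e}\left(1 - e^{-k_e t}\right),
    \qquad \mathrm{RFU} = \mathrm{FLUOR}\cdot A,$$

  with closed-form AUCs, steady state, and an independent ODE oracle;
* **nonlinear least-squares estimation** of (FLUOR, $k_e$, $Q$) per compound
  jointly across routes, with iterative residual-based censoring of
  quench-depressed early injection points (or window-based censoring);
* **exposure metrics**: Relative Exposure $RE = AUC_{imm}/AUC_{inj}$ and
  Relative Contribution $RC = 100\,AUC_{route}/AUC_{comb}$, both
  fluorescence-independent;
* **QSPkR regression**: descriptor collinearity screening, AIC-based
  stepwise selection with a significance gate, and the centered-quadratic
  LogD model;
* **shake-flask LogD** calculation with calibration QC gates, and
  **image quantification** (contour rasterization, integrated intensity,
  exposure-time correction) with a synthetic embryo renderer;
* a **seeded synthetic-data generator** emulating the full study design
  (7 compounds × 4 routes × 6 times × 10 replicates) so the entire pipeline
  is testable end to end.

The reference seven-compound panel (three sulfonated cyanines, two
xanthenes, a rhodamine and a non-sulfonated cyanine, LogD −1.96 to 1.73) and
its pharmacokinetic parameter table ship with the package
(`reference_compounds()`, `reference_pk_parameters()`).

## Worked example

How does immersion at 10 µM compare with a 2 mg/kg microinjection for the
most lipophilic panel compound (CY3A: MW 530.14, $k_e$ = 0.049 h⁻¹,
$Q$ = 8.37e−9 L/h)?

```r
library(zfpk)
p <- pk_parameters(fluor = 1, ke = 0.049, q = 8.37e-9)
relative_exposure(p, mw = 530.14, t1 = 3)    # 0.1363784
relative_exposure(p, mw = 530.14, t1 = 48)   # 2.896738
relative_contribution(p, mw = 530.14, t1 = 48)
# rc_immersion rc_injection
#     74.33751     25.66249
```

A 3 h immersion delivers only ~14% of the injection exposure, but over 48 h
immersion overtakes it almost threefold — and in a combined treatment,
immersion carries 74% of the total exposure. Which molecular property drives
this? Regressing $Q$ on LogD with a mean-centered quadratic term:

```r
fit_centered_quadratic(reference_compounds()$logd,
                       reference_pk_parameters()$q, "Q")
# <qspkr_model> Q = 1.357e-09 + 1.699e-09 LogD + 8.428e-10 (LogD - -0.177)^2
#   n 7, R2 0.879, R2adj 0.818, RMSE 1.198e-09, F p-value 0.01475
```

Fitting works on data, not just published parameters. Simulate the study
design for one compound (CV 10% noise plus a 50% quench artifact on
injection routes before 1 h) and recover the truth with automatic censoring:

```r
d <- default_study_design()
sim <- simulate_dataset(list(CY3A = pk_parameters(5000, 0.049, 8.37e-9)),
                        d$compounds, d$regimens[c("immersion", "PC", "IP")],
                        n_replicates = 10, noise = noise_model(0.1),
                        quench = quench_spec(), seed = 42)
fit_pk_censored(sim, "CY3A")$fit
# <pk_fit> CY3A: FLUOR 4852 RFU/ng, ke 0.04768 1/h, t1/2 14.5 h, Q 8.819e-09 L/h
#   residual SE 86.83 RFU, n used 129, censored 51, converged TRUE
```

All quench-depressed points are flagged and the parameters land within a few
percent of truth. `run_pipeline()` chains simulate → fit → exposure metrics
→ QSPkR and writes tidy CSVs plus a provenance JSON; a thin command-line
wrapper lives at `inst/scripts/zfpk-cli.R`. See the methods vignette
(`vignettes/zfpk-methods.Rmd`) for the model assumptions, censoring design
and the generator's scope.

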