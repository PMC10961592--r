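---
title: "Microdialysis PK-PD analysis with mdpkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdialysis PK-PD analysis with mdpkpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdpkpd)
```

## The problem

Brain microdialysis samples the extracellular fluid of awake animals
through a semi-permeable probe. In a typical drug study, a probe sits in
the hippocampus, artificial cerebrospinal fluid (aCSF) is perfused at a
few microlitres per minute, and consecutive dialysate fractions are
collected — here one fraction every 20 minutes for 480 minutes after an
oral dose, after a pre-dose blank fraction. Each fraction is quantified
by LC-MS/MS for both the drug (in the motivating application, a panel of
*Schisandra chinensis* lignans, eight of which are detectable in
hippocampal dialysate) and endogenous neurotransmitters (aspartate,
glutamate, taurine, acetylcholine), in animal groups such as a healthy
control (`BLA`), a disease model (`ADM`), and a treated group (`SCH`).

Two physical facts shape every downstream computation:

1. **Samples are interval averages.** A fraction collected over
   \[t, t+20\] min reports the mean concentration across that window,
   not a point value.
2. **The probe attenuates.** Only a fraction (the *relative recovery*,
   here around 0.19–0.31) of the surrounding concentration crosses the
   membrane; measured dialysate concentrations must be divided by the
   recovery to estimate tissue concentrations.

`mdpkpd` implements the full analysis chain — calibration and method
validation statistics, probe recovery, non-compartmental and
compartmental PK, sigmoid Emax/Imax PD, effect-compartment linking and
hysteresis quantification — together with a synthetic-experiment
generator whose ground truth exercises every stage.

## Models

### Calibration and validation statistics

Peak area is regressed on nominal concentration by ordinary least
squares, separately per concentration range. Bioanalytical methods for
wide dynamic ranges often use two overlapping ranges (e.g. 1–100 and
10–1000 ng/mL); at back-calculation time the range whose interval
contains the back-calculated value is used, the lower range winning on
overlap (its low end is more densely calibrated). LOD and LOQ follow the
signal-to-noise convention `LOD = 3 sd_blank / slope`,
`LOQ = 10 sd_blank / slope`; the blank-region response SD is supplied by
the caller, since the package does not parse chromatograms. QC levels sit
at 3× LLOQ, 40% ULOQ and 80% ULOQ; precision is the n−1 relative
standard deviation, accuracy the relative error of the replicate mean;
the matrix effect is the percent ratio of mean response in blank
dialysate versus aCSF. Regression is unweighted by default (a 1/x²
option exists) — no weighting is assumed unless the method demands it.

### Non-compartmental analysis

`nca_full()` reports Cmax, Tmax (earliest maximum on ties), AUC0–t,
λz with its half-life, AUC0–∞ = AUC0–t + Clast/λz, and
MRT0–∞ = AUMC0–∞/AUC0–∞. λz comes from log-linear regression over the
terminal window, searched over all contiguous terminal windows of ≥3
points after (and excluding) Cmax, keeping the window with the highest
adjusted R²; ties go to the longer window. Below-LOQ values are dropped
from the λz regression but kept in the AUC as observed.

**AUC for interval data.** Each sample is assigned to its window
midpoint. For *point* samples the linear trapezoid (anchored at
(dose time, 0) for extravascular dosing) is used, with a
linear-up/log-down option. For *interval-averaged* samples, however, the
exact integral over the sampled span is simply `sum(conc * width)` —
the average times the window width — so when a series carries its
collection-window width the default is this interval sum. The
distinction matters: on a 20-min grid over 480 min the trapezoid on
midpoints underestimates a typical absorption profile's integral by
about 1.7%, while the interval sum reproduces it exactly up to noise.

### Compartmental models

One-compartment oral absorption (the Bateman function)

$$C(t) = \frac{D\,k_a}{V/F\,(k_a-k_e)}\left(e^{-k_e t}-e^{-k_a t}\right)$$

and the two-compartment macro form

$$C(t) = A e^{-\alpha t} + B e^{-\beta t} - (A+B) e^{-k_a t},
\qquad \alpha > \beta$$

are fitted by Levenberg–Marquardt least squares in log-parameter space
(positivity for free; for the 2C model the *gap* α−β is the transformed
quantity so α>β always holds). Because only oral data are available,
only the apparent volume V/F is estimable; dose is carried from
configuration. **The model is fitted to what the probe measures**: when
the series carries a collection-window width, the predicted observation
is the closed-form window average, not the point concentration — a point
model fitted to interval-averaged data incurs a systematic ~6% bias on
ka on this grid.

Starting values come from curve stripping (terminal log-linear fit for
ke/β, residual feathering for ka), plus log-jittered restarts. For the
2C model a single stripped start is not enough: the SSR surface has
collapsed-to-monoexponential local optima, so several scale-relative
(ka, α) combinations anchored on the terminal strip are tried and the
best SSR kept.

Two identifiability conventions are applied and reported as such:

* **Flip-flop.** The Bateman function is invariant under exchanging
  ka and ke (with V/F rescaled), so fits are canonicalized to ka > ke.
* **Model selection on noise-free data.** Fit scores use the
  concentrated Gaussian likelihood, AIC = n ln(SSR/n) + 2p and
  BIC = n ln(SSR/n) + p ln n. `select_model()` takes the minimal AIC,
  prefers fewer parameters within a ΔAIC band of 2, and — when several
  fits are *numerically perfect* (relative RMSE < 1e−6) so that the
  Gaussian AIC degenerates — picks the most parsimonious perfect fit.

Per-parameter CV% comes from the asymptotic covariance at the optimum
(Jacobian of the weighted residuals with respect to log-parameters), so
it reads directly as a relative standard error.

### Pharmacodynamics and the effect-compartment link

Neurotransmitter series are baseline-normalized so the first pre-dose
sample is exactly 100% (a mean-of-window option exists). Effects follow
a Hill model: stimulation

$$E(C) = E_0 + E_{max}\frac{C^n}{EC_{50}^n + C^n}$$

and inhibition in the multiplicative fractional form

$$E(C) = E_0\left(1 - I_{max}\frac{C^n}{IC_{50}^n + C^n}\right),
\qquad I_{max} \in (0,1],$$

chosen so the effect stays nonnegative and Imax is independent of the
baseline scale. The Hill coefficient is bounded to [0.1, 10] to prevent
step-function degeneracy; EC50/IC50 and ke0 are fitted on the log scale,
Imax on the logit scale. EC50/IC50 is additionally constrained to a wide
window around the observed concentration scale — when the response never
approaches saturation only the ratio Emax/EC50^n is identified and
unconstrained estimates diverge along that ridge without improving the
fit; fits landing on the bound are flagged `c50_at_bound`.

Effect delay is modelled by a hypothetical effect compartment
equilibrating with the concentration profile at rate ke0:
dCe/dt = ke0 (Cp − Ce). For a sum-of-exponentials Cp this has the closed
form used throughout; the λ = ke0 coincidence is handled by its analytic
limit. Estimation is sequential (two-stage): PK parameters are frozen at
their fit and (ke0, PD parameters) estimated by least squares of effect
against `pd_predict(Ce(t))`, multi-started over a log-spaced ke0 grid
because the delay surface is multimodal.

**The fitting unit is the group-mean profile.** Concentration and effect
fits operate on the per-group mean across subjects, mirroring the pooled
"average concentration, average effect" workflow this package models.
This is also statistically material: on a *single* noisy 24-point
profile at 10% measurement CV, the ke0 least-squares surface has a
competing minimum (large ke0 with a steep Hill slope) that wins in
roughly a third of noise realizations, making single-profile ke0
estimates unstable; on 6-subject group means the median ke0 error drops
to ~10–20%. Users fitting single subjects should treat ke0 CV% and
multimodality warnings seriously.

### Hysteresis loops

The time-ordered (concentration, effect) trajectory, closed last→first,
is a polygon whose shoelace signed area quantifies hysteresis;
concentration is on x and effect on y, so **counterclockwise = positive
area**. The area is normalized by the bounding box
(range(C) × range(E)), giving a dimensionless value in [−1, 1];
|normalized area| < 0.01 is classified as no hysteresis, and a closure
chord longer than 20% of the bounding-box diagonal flags an open loop.
A delayed stimulatory response (effect lags rising concentration)
always produces a counterclockwise loop and a delayed suppressive
response a clockwise one — the excitatory (Asp/Glu, suppressed) versus
Tau/Ach (enhanced) pattern — and `classify_relationship()` labels the
(direction, mode) pair accordingly. As ke0 → ∞ the loop collapses onto
the single-valued dose-response curve; the residual area is then only
the sliver between the closure chord and that curve.

## The synthetic-data generator

`simulation_config()` defaults encode the study conditions the analysis
targets, chosen once:

* sampling: one 20-min pre-dose baseline window, then 24 windows of
  20 min over 480 min; oral dose at t = 0;
* eight detectable lignans with one-compartment truth, ka
  0.030–0.055/min, ke 0.007–0.012/min (absorption-limited profiles
  peaking between ~40 and ~90 min on this grid);
* probe recovery per lignan in 0.19–0.31, maximal at a perfusion rate of
  2 µL/min (shape 0.8 / 1.0 / 0.6 across 1 / 2 / 3 µL/min), measured in
  triplicate at 100/500/1000 ng/mL;
* group exposure multipliers BLA 1.0 < SCH 1.4 < ADM 1.8 (a compromised
  blood–brain barrier raises exposure in the disease model; treatment
  partially restores it), giving the AUC ordering ADM > SCH > BLA;
* four neurotransmitters driven by the effect-site concentration of the
  index lignan (schisandrol A): Asp and Glu inhibitory (Imax 0.5/0.4,
  IC50 30/25 ng/mL), Tau and Ach stimulatory (Emax 60/80, EC50
  20/35 ng/mL), Hill 1.2–2, ke0 0.015–0.030/min; disease-model baselines
  raised for Asp/Glu and lowered for Tau/Ach;
* noise: 10% proportional CV plus a 0.02 ng/mL additive floor, truncated
  at zero; calibration response noise one tenth of that; recovery
  replicate scatter 0.4× of it.

Sampling is simulated as the analytic window average of the true profile
(attenuated by recovery, then noised), so the generator exercises the
midpoint-assignment and interval-integration decisions above rather than
assuming them. Every (group, subject, analyte) series draws from its own
RNG stream derived from the seed, so regeneration is byte-identical and
adding analytes does not perturb existing series.

What the generator does **not** emulate: probe depletion and in-vivo
recovery drift, inter-animal PK variability beyond sampling noise
(group multipliers are deterministic), circadian baselines, LC-MS raw
signals, below-LOQ censoring. Passing the round-trip tests therefore
shows the estimators are mutually consistent and unbiased under the
stated noise model — not that real dialysate data meet those
assumptions.

## Validation study sizes

The packaged tests and `scripts/acceptance.R` use: 20 replicate
experiments for each noisy recovery study (10% per-sample CV, 6-subject
group means); a 15-point rich design with early samples (5–45 min) for
the 1C-versus-2C selection study, since the 2C truth's distribution
half-life (~3.5 min) is invisible on a 20-min grid; and a noise-free
single-subject experiment for the end-to-end round trip, where every PK,
PD and link parameter is recovered to well under the stated tolerances
and only the 20-min sampling resolution limits Tmax.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, n_subjects = 6)
experiment <- generate_experiment(cfg)
result <- run_pipeline(experiment)

result$flow_rate          # 2 uL/min, the recovery-optimal perfusion rate
subset(result$nca, analyte == "schisandrol A")
subset(result$link_table, neurotransmitter == "Ach")
subset(result$hysteresis, group == "ADM")
```

## Known limitations

* Sequential (PK-then-PD) estimation propagates no PK uncertainty into
  ke0; a simultaneous mode would, but is not the workflow modelled here.
* The Hill coefficient is weakly identified from single noisy profiles;
  its CV% should be consulted before interpreting steepness.
* Recovery correction assumes in-vitro gain-mode recovery transfers to
  the in-vivo probe; no-net-flux calibration is out of scope.
* Only one driving analyte links PK to PD per fit; co-acting lignans are
  fitted independently, not jointly.
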