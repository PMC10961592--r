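# mdpkpd — microdialysis PK-PD analysis

`mdpkpd` analyses brain-microdialysis drug studies: time series of
dialysate concentrations collected as consecutive interval averages
(e.g. 20-min fractions over 480 min after an oral dose), attenuated by
the probe's relative recovery, quantified by LC-MS/MS for both drug
analytes and endogenous neurotransmitters. It is written for
pharmacometricians and bioanalysts who need the whole chain in one
reproducible place:

* **Calibration & validation** — dual-range OLS calibration curves with
  back-calculation, LOD/LOQ from signal-to-noise (3σ/10σ), QC levels
  (3×LLOQ, 40%/80% ULOQ), precision/accuracy (RSD/RE) and matrix-effect
  statistics.
* **Probe recovery** — gain-mode relative recovery `R = C_dial/C_medium`
  per flow rate and concentration, flow-rate selection, and correction
  `C_tissue = C_dial / R`.
* **NCA** — Cmax, Tmax, AUC0–t, AUC0–∞, λz, t½, MRT0–∞; AUC uses the
  exact interval sum for interval-averaged samples and the linear
  trapezoid for point samples.
* **Compartmental PK** — one-compartment (Bateman,
  `C(t) = D·ka/(V/F·(ka−ke))·(e^(−ke·t) − e^(−ka·t))`) and
  two-compartment (`C(t) = A·e^(−αt) + B·e^(−βt) − (A+B)·e^(−ka·t)`)
  oral models, fitted to the predicted *window averages* when the data
  are interval samples; model selection by AIC/BIC with a parsimony
  band; per-parameter CV%.
* **PD** — sigmoid Emax (`E = E0 + Emax·Cⁿ/(EC50ⁿ + Cⁿ)`) and
  multiplicative Imax (`E = E0·(1 − Imax·Cⁿ/(IC50ⁿ + Cⁿ))`) models on
  baseline-normalized effects (first basal sample ≡ 100%).
* **PK-PD link** — effect compartment `dCe/dt = ke0·(Cp − Ce)` solved in
  closed form for exponential-sum profiles; sequential (fixed-PK)
  estimation of (ke0, PD parameters).
* **Hysteresis** — shoelace signed area of the time-ordered
  (concentration, effect) loop, normalized by its bounding box;
  counterclockwise = delayed enhancement, clockwise = delayed
  suppression.
* **Synthetic experiments** — a seeded generator producing complete
  studies (three groups, eight drug analytes, four neurotransmitters,
  recovery and calibration tables) with known ground truth, used by the
  test suite to validate every stage end to end.

## Worked example

```r
library(mdpkpd)

cfg <- simulation_config(seed = 1, n_subjects = 6)   # defaults: 3 groups,
experiment <- generate_experiment(cfg)               # 20-min x 480-min grid
result <- run_pipeline(experiment, analytes = "schisandrol A")

result$flow_rate
#> [1] 2

result$nca[, c("analyte", "group", "cmax", "tmax", "auc_0_inf", "t_half")]
#>         analyte group  cmax tmax auc_0_inf t_half
#> 1 schisandrol A   BLA 34.12   50      5512  77.38
#> 2 schisandrol A   ADM 56.88   30      9880  77.65
#> 3 schisandrol A   SCH 47.40   50      7609  55.15

result$hysteresis[result$hysteresis$group == "ADM",
                  c("neurotransmitter", "normalized_area", "direction")]
#>   neurotransmitter normalized_area        direction
#> 5              Asp          -0.477        clockwise
#> 6              Glu          -0.440        clockwise
#> 7              Tau           0.540 counterclockwise
#> 8              Ach           0.465 counterclockwise
```

Reading the output: the probe's recovery is maximal at a perfusion rate
of 2 µL/min, so that flow rate is selected and its per-analyte recovery
used to correct concentrations. Exposure to the index lignan is highest
in the disease-model group and partially restored by treatment
(AUC0–∞ 9880 > 7609 > 5512 ng·min/mL for ADM > SCH > BLA), while the
elimination half-life (~55–78 min) is group-independent, as it should be
when only exposure differs. The excitatory transmitters Asp and Glu
trace clockwise concentration-effect loops (delayed suppression), Tau
and Ach counterclockwise loops (delayed enhancement) — the signature of
an effect that lags concentration through an effect compartment.
`result$link_table` holds the fitted ke0 and sigmoid parameters per
(lignan, neurotransmitter, group); estimates whose EC50 lands on the
identifiability bound (effect never approaches saturation in the
observed range) are flagged.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/mdpkpd.R simulate --seed 1 --out data/
Rscript inst/cli/mdpkpd.R report --data data/ --out results/
```

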