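# invivobe

Stability of standard base excess under acute in vivo CO2 variation, and
calibration of the buffer power at which base excess really is
CO2-invariant.

## The problem

Base excess is the acute-care index of the *metabolic* side of an acid-base
disturbance, computed as

```
BE = (HCO3⁻ − 24.8) + (pH − 7.40) · β
```

with the buffer power β (mmol/L per pH unit) expressing how strongly
non-bicarbonate buffers resist pH change during CO2 titration. Standard
base excess (SBE) fixes β = 16.2 — a value rooted in *in vitro* titration
of diluted blood. If that β were right for the whole organism, regressing
SBE on PCO2 over in vivo CO2-titration data would give slope zero. This
package tests that premise and inverts it into an estimator: evaluate the
pooled OLS slope of BE(β) on PCO2 for 10,000 candidate β between 5 and 20,
and report β*, the candidate whose regression coefficient is closest to
zero, with a test-inversion confidence interval (all β whose slope CI
contains zero). Because BE is linear in β, the slope curve is exactly
`slope(β) = a + b·β` (a, b = OLS slopes of the bicarbonate and pH deviation
terms on PCO2), giving a closed-form cross-check `β* = −a/b` that the grid
sweep must match.

The package is for acid-base physiology researchers and methodologically
minded intensivists: it bundles the SBE equation family (generalized β,
standard 16.2, and the Schlichtig variant `0.9287·{(HCO3⁻ − 24.8) +
(pH − 7.40)·14.83}`), the sweep calibration, a multi-study ANCOVA
(SBE ~ PCO2 × study) for comparing titration experiments, per-subject SBE
excursions over the hypercapnic range, a seeded synthetic CO2-titration
generator for parameter-recovery validation, and a CSV/JSON command-line
pipeline.

## Worked example

Simulate a volunteer-like chamber study (14 subjects titrated at 40, 55,
70, 85 mmHg; true buffer power drawn around 12.1) and analyze it:

```r
library(invivobe)
d <- generate_study(study_design("volunteers", seed = 42L))

fit_sbe_slope(d, beta = 16.2)
#> SBE ~ PCO2 regression (beta = 16.2): slope -0.0201 mmol/L/mmHg (95% CI -0.0356 to -0.0047), p = 0.0116, n = 56

beta_sweep(d)
#> Buffer-power sweep: 10000 betas in [5, 20], n = 56 observations
#>   beta_star = 12.85 (slope 2.68e-06 mmol/L/mmHg)
#>   95% test-inversion CI: 10.47 to 15.39
#>   closed form -a/b = 12.85 (delta-method CI 10.39 to 15.31)

max_delta_sbe(d, beta = 16.2)
#> SBE change from lowest-PCO2 baseline at beta = 16.2 (14 subjects)
#>   cohort range: -2.38 to 1.52 mmol/L
```

Read: at the conventional β = 16.2 this cohort's SBE is *not*
CO2-invariant — it drifts −0.02 mmol/L per mmHg of PCO2 (p = 0.01), and
individual subjects lose up to 2.4 mmol/L of apparent base across the
hypercapnic range, enough to mimic a mild superimposed metabolic acidosis.
The sweep locates the CO2-invariant buffer power for this cohort at
β* ≈ 12.9 (95% CI 10.5–15.4), and the closed-form zero crossing agrees to
grid resolution.

The same analyses run from the shell on CSV data
(columns `study_id, subject_id, exposure_id, pco2_mmhg, ph[, hco3_mmol_l]`):

```sh
Rscript inst/cli/invivobe.R simulate --designs designs.json --seed 7 --out obs.csv
Rscript inst/cli/invivobe.R run-all  --input obs.csv --seed 7 --out report.json
```

`report.json` is schema-versioned, byte-stable, and carries the full
slope(β) curve plus a config echo (seed, grid, level); a plain-text summary
lands next to it.

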