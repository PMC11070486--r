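# scarindent

Ultrasound indentation analysis of thin soft-tissue layers — built for
studies of hypertrophic scar thickness and viscoelasticity under
negative-pressure therapy (NPT), and for anyone who needs a tested,
self-contained implementation of the motor-driven ultrasound indentation
measurement chain.

A motor-driven indenter (the ultrasound transducer itself, behind a
cylindrical standoff gel pad of radius *a* = 4.5 mm) cyclically compresses
a scar layer lying over bone while two channels are recorded: M-mode echo
frames at 22.5 Hz, whose two echoes (transducer–skin and tissue–bone
interfaces) give the instantaneous layer thickness, and a 100 Hz force
channel from an in-series load cell. The effective Young's modulus of the
layer follows from the thin-layer rigid-punch relation

```
E = (1 - v^2) / (2 a kappa(v, a/h)) * P / w
```

where *v* is the Poisson's ratio (0.45 for soft tissue), *P* the
indentation force, *w* the indentation depth, *h* the layer thickness, and
`kappa` the correction factor for a flat cylindrical punch on an elastic
layer bonded to a rigid base — computed here from the dual integral
equations of that contact problem and embedded as an interpolation grid.
Because skin's stress–strain response is J-shaped, the modulus is evaluated
in three strain regions: the elastin-dominated toe (**E1**, ~5% strain),
the fiber-realignment heel (**E2**, ~10%) and the collagen-dominated linear
region (**E3**, ~15%).

No raw clinical recordings are publicly deposited for this kind of study,
so the package includes a first-class synthetic acquisition generator: a
ground-truth cohort (three NPT arms at −105/−125/−145 mmHg with 11/13/12
subjects by default, calibrated to published arm summaries), a forward
simulator of the cyclic indentation response (J-shaped secant law plus a
standard-linear-solid viscous term), and a renderer that produces raw
M-mode frames and the force channel with configurable SNR. Every analysis
stage is therefore testable against known truth.

The statistical layer reproduces a three-arm pre/post study plan: paired
t-tests per arm, post/pre percentage ratios compared across arms by one-way
ANOVA with Fisher LSD post hoc, and per-arm Pearson correlation matrices,
reported with `*` (p < 0.05) / `**` (p < 0.01) notation.

## Worked example

Simulate one subject with a J-shaped law, render the raw channels at 20 dB
echo SNR, and recover thickness and regional moduli by echo tracking:

```r
library(scarindent)

tr <- tissue_ground_truth("S01", group = -125, h0 = 3.7, toe_modulus = 40,
                          stiffening_rate = 4, relax_time = 0.3)
traj <- simulate_indentation(tr)
rec  <- render_recording(traj, acquisition_config(echo_snr = 20, seed = 2))
res  <- analyze_recording(rec)
res$h0_mm
#> [1] 3.697296
res$triplet
#> Regional moduli (h0 = 3.70 mm): E1 = 51.6, E2 = 62.2, E3 = 74.2 kPa
round(truth_regional_moduli(tr), 1)
#>   E1   E2   E3
#> 48.9 59.7 72.9
```

The preload-state thickness is recovered to a few micrometres and the
three regional moduli land within a few percent of the subject's true
secant moduli at 5/10/15% strain (the residual reflects echo noise and the
mild viscous hysteresis of the forward model).

A full three-arm cohort run, from generator to report tables:

```r
out <- run_pipeline(run_config(cohort = cohort_spec(seed = 1), mode = "fast"))
out$report$ratios[, c("measure", "mean_-105", "mean_-125", "mean_-145",
                      "anova_p", "anova_sig")]
#>     measure mean_-105 mean_-125 mean_-145      anova_p anova_sig
#> 1 thickness  70.78389  92.87603  87.96426 4.042461e-06        **
#> 2        E1 171.19348 103.87560 429.68923 2.719032e-05        **
#> 3        E2 147.50124 119.96933 682.03383 7.238381e-04        **
#> 4        E3 147.00244 142.04869 528.83997 2.234360e-03        **
```

Each row gives the arm means of the post/pre percentage ratio of one
measure, the across-arm ANOVA p-value and its significance stars; with the
default calibration the −105 mmHg arm shows the strongest thickness
reduction (ratio ≈ 71%) and the −145 mmHg arm the largest modulus
increases, mirroring the treatment-effect structure the generator encodes.
`mode = "full"` replaces the fast trajectory readout with the complete
echo-rendering and tracking chain (~25 s for 36 subjects). A thin CLI over
the same functions lives at `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --seed 4 --n-per-arm 3,3,3 --out run --report-format json
```

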