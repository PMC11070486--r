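---
title: "Models and methods behind scarindent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scarindent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarindent)
```

## The measurement problem

A thin soft-tissue layer (a hypertrophic scar) lies over bone. A rigid
cylindrical indenter — the ultrasound transducer behind a standoff gel pad
of radius $a = 4.5$ mm — compresses it cyclically. Two channels are
recorded: M-mode echo frames at 22.5 Hz, whose first echo marks the
transducer–skin interface and second the tissue–bone interface, and a
100 Hz force channel from an in-series load cell (49 N range). The layer
thickness is the depth separation of the two echoes; the indentation depth
$w$ is the drop of thickness below its preload value $h_0$; and the
effective Young's modulus follows from the thin-layer rigid-punch relation

$$E \;=\; \frac{1-\nu^2}{2a\,\kappa(\nu, a/h)}\,\frac{P}{w},$$

a secant relation: $P/w$ is a chord stiffness, so $E$ is a secant modulus
at the sampled strain. Because skin's stress–strain curve is J-shaped, the
analysis reports three regional moduli at target strains of 5, 10 and 15%
of $h_0$: the toe region E1 (elastin-dominated), the heel region E2 (fiber
realignment) and the linear region E3 (collagen-dominated). Some reports
label the same three quantities superficial/medium/deep *layer*
viscoelasticity; this package implements the strain-region definition,
which is the operational one. Similarly, published tables sometimes print
these moduli as "N/mm²" while quoting the same numbers in kPa in the text;
the package reports kPa throughout (1 N/mm² = 1 MPa = 1000 kPa, so the two
labels differ by three orders of magnitude and cannot both be right).

## The layer correction factor $\kappa$

$\kappa(\nu, a/h)$ corrects the classical half-space flat-punch stiffness
$P/w = 2aE/(1-\nu^2)$ for a layer of finite thickness bonded to a rigid
base. It is computed from the dual integral equations of that mixed
boundary-value problem, reduced to a Fredholm integral equation of the
second kind and solved by Nyström discretisation (Simpson rule, 241 nodes;
the kernel is the cosine transform of the bonded-layer surface-compliance
function, evaluated by 1600-node Gauss–Legendre quadrature on $[0, 30]$,
beyond which the integrand is exponentially negligible). The script
`tools/make_kappa_grid.R` regenerates the embedded grid:
$a/h \in [0, 10]$ in steps of 0.05 and $\nu \in \{0.30, \dots, 0.50\}$ in
steps of 0.05. `hayes_kappa()` interpolates it bilinearly, is exactly 1 at
$a/h = 0$, and refuses to extrapolate beyond the grid rather than clamp
silently.

The test suite validates the grid against an independent oracle that never
shares code with the solver: a Ritz–Galerkin expansion of the contact
pressure in the edge-singular punch basis $(1-r^2/a^2)^{n-1/2}$, with the
half-space part of the stiffness matrix in closed form
(Weber–Schafheitlin integrals) and the finite-layer correction by
quadrature. The two routes agree to far better than the 1% the tests
assert. The grid range deliberately exceeds the nominal study geometry
($a/h \approx 1$–2): with the instantaneous-thickness convention, a 2 mm
layer indented to 15% strain already queries $a/h \approx 2.6$, and
strongly thinned post-treatment subjects query beyond 3.

Two conventions are switchable where the analysis is genuinely open:

* **$h$ inside $\kappa$** — default is the instantaneous thickness
  $h_0 - w$ (the correction depends on current geometry);
  `h_convention = "initial"` restores $h_0$ for sensitivity checks.
* **Cycle policy** — the first loading cycle is discarded as
  preconditioning (standard indentation practice) and the remaining cycles
  are averaged; `cycles =` overrides. Whether a study pooled cycles or
  averaged per-cycle moduli is rarely stated; both give identical results
  for stationary cycles, and the per-cycle average is used here.

## Forward model (the synthetic subject)

Each subject carries a secant-modulus law
$E(\varepsilon) = E_0 e^{\gamma \varepsilon}$ with toe modulus $E_0$ (kPa)
and dimensionless stiffening rate $\gamma$ ($\gamma = 0$ is linear
elastic). This is the minimal invertible J-shaped law: the analysis
recovers exactly $E(\varepsilon^\star)$ at each target strain, so truth is
well defined at every region. When region-specific treatment effects are
applied (see below), the post-treatment law interpolates log-linearly
through the three anchored moduli instead, so region multipliers are
represented exactly rather than least-squares-fitted to an exponential.

The elastic force is the punch relation run forward,
$P_e = 2a\,\kappa(\nu, a/(h_0-w))\,E(w/h_0)\,w/(1-\nu^2)$. A viscous
component in standard-linear-solid form is added by exponential
convolution of $\dot P_e$ with time constant `relax_time` (default 0.3 s)
and relative weight `relax_strength` (default 0.1). These defaults were
chosen once, a priori, to produce visible hysteresis loops over the five
cycles while keeping the secant inversion that the method itself assumes
meaningful; a strongly viscous tissue would bias all secant moduli upward
on the loading branch, most at low strain where the relative viscous
contribution is largest. Total force is clamped at zero (the indenter
cannot pull on the tissue).

The loading protocol mirrors the clinical one: preload below 0.5 N, then
five triangular cycles of 8 s each (40 s), to a peak indentation of 20% of
$h_0$; advisory compliance windows of 2–4 mm ramp travel per 4 s and
400–600 gram-force peak response (`validate_protocol()`, using
1 gf = 9.80665 mN) are flagged, never enforced.

**The preload convention matters.** The instrument defines $h_0$ as the
thickness measured under the sub-0.5 N preload; the simulator therefore
treats the seating phase as force transmitted through the coupling (rising
toward the preload ceiling, or toward ~30% of the expected cyclic peak for
very soft subjects) while the tissue is still at $h_0$, and the cyclic
indentation starts from that state. Modelling the preload as an elastic
indentation instead would displace the reference state by ~0.1–0.2 mm for
typical scar stiffness — an order of magnitude above the echo-tracking
resolution — and make the nominal strain targets unattainable as defined.

## Rendering and echo tracking

Frames are rendered at 22.5 Hz on a depth axis sampled at
$c/(2f_s) = 19.25\ \mu$m (1540 m/s, 40 MHz): two Gaussian-modulated pulses
(12 MHz carrier, envelope $\sigma$ = 0.1 µs ≙ 77 µm in depth; second echo
at 0.8 relative amplitude) at the transducer–skin interface $z_1$ and at
$z_2 = z_1 + h(t)$, plus white noise at `echo_snr` dB relative to the
first-echo peak ($\infty$ renders both channels noise-free). Force is
resampled at 100 Hz with Gaussian sensor noise (sd 5 mN) and saturates at
the 49 N load-cell range. If the layer thins below the axial pulse
resolution ($4\sigma_z$) the render is flagged as overlapped, not silently
produced.

Tracking computes the envelope as the magnitude of the analytic signal
(FFT along depth), picks the two largest envelope peaks separated by at
least the pulse resolution, and refines each to sub-sample precision by a
parabolic fit on the log-envelope — exact for a Gaussian envelope, which
is why noise-free tracking errors sit far below the one-sample
half-wavelength tolerance asserted in the tests. Frames without a second
resolvable peak (secondary/primary envelope ratio < 0.25) are rejected,
never interpolated; a recording with > 20% rejected frames fails with a
diagnostic. $h_0$ is the mean thickness over the first contiguous contact
episode (force in $[0.1, 0.5)$ N); restricting to the *first* episode is
essential because each loading ramp also passes through that force band.
The force channel (fast) is interpolated linearly onto frame times (slow)
— never the reverse, so no thickness values are invented between frames.
Cycles are segmented at force minima (2% of peak floor) and qualified by
deformation amplitude (≥ 50% of peak $w$), which excludes the seating
episode regardless of subject stiffness; below-floor shoulder samples are
attached to the nearest cycle so the toe-region window survives even for
strongly J-shaped subjects whose force at 4% strain is negligible.
Regional moduli average the per-sample inversion over a strain window of
±0.01 around each target, per cycle, then across analysis cycles; an empty
window or a curve short of 15% strain is an explicit error.

## The synthetic cohort

`cohort_spec()` encodes the three-arm study conditions: arms at
−105/−125/−145 mmHg with 11/13/12 subjects; per-arm pre-treatment
thickness normal with means 3.7/4.3/3.5 mm and subject SDs reconstructed
from published standard errors ($SD = SE\sqrt{n}$: 0.66/1.80/1.04 mm,
truncated below at 1.5 mm); pre-treatment toe-region moduli log-normal
with arm means 51.2/52.6/42.1 kPa and CVs reconstructed the same way;
stiffening rates log-normal with arm means 1.23/3.66/10.0 (chosen so the
arm-mean E3/E1 ratios match the published pre-treatment profiles) and CV
0.2. Treatment multiplies thickness by a **mean-one** log-normal ratio
(arm means 0.745/0.913/0.844) and the three regional moduli by correlated
mean-one log-normal multipliers (arm × region means from the published
ratio table; latent Gaussian noise with exchangeable correlation
$\rho = 0.9$, matching the strong reported inter-region correlations).
Mean-one parameterisation makes the expected arm ratio equal the
configured mean exactly, which is what the large-$n$ recovery test checks.
NPT magnitudes are group labels only — no pressure-to-tissue coupling is
modelled, because no such model is available to implement.

Per-subject child seeds are derived deterministically from the master
seed, so cohorts are bit-reproducible and insensitive to generation order;
the renderer similarly takes a per-recording seed.

The **null configuration** (`null_cohort_spec()`) sets every effect
multiplier to 1 and replaces the treated-arm effect CVs with test–retest
repeatability noise (CV 0.2 on moduli, SD 0.05 on the thickness ratio),
chosen a priori: the treated-arm CVs describe treatment-effect
heterogeneity, not repeatability, and zero noise would make post ≡ pre and
the false-positive rate identically zero. The type-I calibration counts
significance stars over the paired, ANOVA and LSD p-values (whose nulls
are true under this configuration); correlation tests are excluded because
the generator makes their null false by design. With skewed mean-one
log-normal retest noise at $n = 11$–13 the t-family tests run slightly
conservative, which is expected small-sample behaviour, and the star rate
is asserted within the nominal band rather than at exactly 5%.

Pearson correlations on raw log-normal ratios are attenuated relative to
the latent $\rho$ (the log-normal transform of a bivariate normal shrinks
correlation, increasingly so at large $\sigma$); the $\rho$-recovery
property is therefore tested at repeatability-level noise where the
attenuation is within the asserted 0.05.

## What the generator does and does not emulate

It emulates: the two-channel acquisition at the protocol's rates; M-mode
echo structure with realistic axial resolution and SNR; J-shaped
constitutive behaviour with mild viscoelastic hysteresis; arm-level
treatment-effect structure including inter-region correlation; and
subject-level heterogeneity at the spread the published summaries imply.

It does not emulate: 2-D B-mode speckle or lateral beam effects (M-mode
lines only); RF phase-based motion (envelope tracking only); frequency-
dependent attenuation or multiple reflections; pressure-cup fluid
mechanics or any wound-healing biology; creep/relaxation parameter
identification (viscosity exists only in the forward model, and the
analysis deliberately ignores it, as the secant method does); and operator
variability (probe angulation, repositioning). Passing tests therefore
demonstrate correctness of the analysis chain under the stated acquisition
physics, not robustness to everything a clinic can produce.

## Numerical and degenerate-input conventions

* Paired t-test with all-zero differences: $t = 0$, $p = 1$ (no evidence
  of change); constant non-zero differences: $p = 0$ with infinite $t$.
* ANOVA with zero total variance is an error; LSD p-values are uncorrected
  pairwise pooled-MSE t-tests, as Fisher LSD prescribes, and are computed
  regardless of the omnibus result (the report prints both).
* The between-arm comparison is a between-subjects one-way ANOVA: each
  subject receives exactly one magnitude, so a repeated-measures layout
  has no within-subject factor to exploit.
* Zero-variance measures yield flagged `NA` correlation cells; arms with
  fewer than 3 subjects skip the correlation table with a message.
* Report tables print both SE and SD columns (published tables are
  ambiguous about which spread they show).
* Negative force excursions from sensor noise are clamped to zero before
  inversion; deformation is clamped at $w \ge 0$.
* All tests are two-sided; significance stars are `*` p < 0.05 and `**`
  p < 0.01.
* Problem sizes used by the test suite and acceptance script (e.g. 200
  J-shape subjects, 50 noise-robustness subjects, 200 null replicates,
  500 per arm for effect recovery) are the package's chosen trade-off
  between Monte-Carlo resolution and a test suite that runs in minutes.

## Known limitations

The Hayes-type correction assumes a frictionless flat punch on a
homogeneous isotropic layer perfectly bonded to a rigid base; scars are
layered, anisotropic and imperfectly coupled, so recovered moduli are
*effective* in the contact-mechanics sense. The secant inversion folds
viscous stress into the reported moduli (loading branch only). The
gel-pad standoff is treated as the indenter itself (contact radius =
gel-pad radius), since the standoff geometry's effect on the effective
contact radius is not characterised. Calibration targets come from
published arm-level summaries, not raw subject data, so the generator
reproduces means, spreads and correlations — not the joint distribution of
a real clinic's population.
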