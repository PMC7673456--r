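---
title: "GluCEST pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GluCEST pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucest)
```

This vignette is the package's own account of the science it implements:
the saturation-transfer model, the processing chain, every tunable that
matters, and the choices made where the underlying methodology is
genuinely open.

## The Bloch-McConnell model

The simulator evolves the magnetization of $N$ exchanging proton pools
under continuous-wave RF irradiation. For pool $i$ with transverse and
longitudinal rates $R_{2i}, R_{1i}$, offset $\Delta\omega_i$ between the
RF and the pool resonance, and nutation rate $\omega_1 = 2\pi\gamma B_1$:

$$
\begin{aligned}
\dot M_{xi} &= -R_{2i} M_{xi} + \Delta\omega_i M_{yi} \\
\dot M_{yi} &= -\Delta\omega_i M_{xi} - R_{2i} M_{yi} + \omega_1 M_{zi} \\
\dot M_{zi} &= -\omega_1 M_{yi} - R_{1i}(M_{zi} - M_{0i}),
\end{aligned}
$$

plus two-site exchange between water (pool 1, $M_{01}=1$) and each solute
pool at rate $k_i$ (pool $\to$ water), with the reverse rate $k_i M_{0i}$
fixed by detailed balance. The Z-spectrum is the water $M_z$ at the end
of saturation, starting from thermal equilibrium, normalized by $M_0$.

Two independent numerical routes exist deliberately:

* `method = "expm"` — the system is linear with constant coefficients
  under CW irradiation, so the end-of-saturation state is one matrix
  exponential of the augmented $(3N{+}1)$ system matrix per offset
  (exact up to the exponential's own numerics; compiled, used
  everywhere).
* `method = "rk4"` — a fixed fine-step classic Runge-Kutta integration
  of the same equations, with the derivative written out independently
  in component form. The two routes only agree if both encode the
  physics correctly, which is asserted to $10^{-6}$ in the tests. The
  default step `dt = 1e-5` s is stable for semisolid-pool relaxation
  rates up to $\sim 2\times10^5\,\mathrm{s^{-1}}$ (RK4 stability
  boundary $\approx 2.78/\lambda$) and resolves the fastest precession
  on a $\pm 5$ ppm grid at 7 T ($\sim$1.5 kHz) with ample accuracy.

What is *not* modeled: the readout. Saturation is a single constant
2 s block and the "image" is $M_z$ at its end. The spoiled-gradient-echo
readout train, TR/TE weighting and spoiling are deliberately absent:
GluCEST is formed from the ratio $I/I_0$ of identically read-out images,
so readout weighting cancels to first order. Pulsed saturation trains,
k-space artifacts, motion and multi-slice geometry are out of scope.

## Default pool and protocol parameters

| parameter | default | why |
|---|---|---|
| saturation amplitude | 5.9 μT (251.2 Hz via $\gamma/2\pi$ = 42.577 MHz/T) | standard high-field GluCEST power |
| saturation time | 2 s | approaches steady state for amine exchange |
| offsets | −5…+5 ppm, 0.2 ppm steps (51) | places ±3 ppm on exact grid nodes |
| reference offset | 100 ppm | effectively unsaturated normalization image |
| reference frequency | 300 MHz | nominal 7 T proton frequency; configurable |
| amine shift | +3.0 ppm | glutamate amine resonance |
| amine exchange rate | 5500 s⁻¹ | literature-typical for glutamate amine at physiological pH |
| amine T1 / T2 | 1 s / 10 ms | literature-typical; contrast is insensitive to these at this regime |
| water T1 / T2 | from the phantom's per-ROI T1/T2 (1425.3 / 74.8 ms defaults) | ties the CEST water pool to the relaxometry ground truth |

True in-vivo amine exchange parameters for rat brain are not pinned down;
all of these are explicit arguments, not constants. An optional semisolid
MT pool is available but off by default.

The phantom's default control-group amine proton fraction (0.00026) was
fixed once by bisection so that the noiseless whole-brain contrast is
0.021, a typical healthy-brain GluCEST level under this protocol
(`calibrate_amine_fraction()`); the fatigue group uses 1.5× control,
producing the ~50% group difference the pipeline is designed to detect.

## The synthetic study

`build_phantom_study()` emulates one imaging session per subject:

* **Geometry** — a single 2-mm-slice elliptical "whole brain" on a
  64 × 32 grid (half the acquired 128 × 64, for speed; configurable)
  containing three disjoint disc ROIs (PFC, HP, Str). ROI overlap is
  rejected by construction.
* **CEST** — 51 offset frames plus one I0 frame at 100 ppm, each voxel
  simulated through the Bloch-McConnell propagator at its own B0 shift
  and B1 scale. One I0 frame per subject.
* **Field maps** — smooth low-order polynomial B0 (ppm, default peak
  0.3 ppm) and B1 (multiplicative, default ±10%) surfaces, drawn
  per subject; the dual-echo phase pair (ΔTE 2 ms, first echo 5 ms) and
  the 60°/120° double-angle magnitude pair are generated consistently
  with these fields.
* **Relaxometry** — 7 log-spaced TIs over 100–7500 ms with ideal
  inversion ($S = |1 - 2e^{-TI/T_1}|$), and 5 linear TEs over 40–400 ms
  ($S = e^{-TE/T_2}$). The ranges and counts follow the acquisition
  protocol; log/linear spacing within them is this package's choice, as
  only range and count are specified by such protocols.
* **Noise** — Rician on magnitude images: independent Gaussians of
  SD $I_0/\mathrm{SNR}$ on the real and imaginary channels; matched
  small-angle Gaussian noise on phase images. `snr = Inf` disables
  noise, and noiseless round-trips recover every generating parameter to
  solver tolerance (asserted in the tests).
* **Determinism** — the master seed spawns one per-subject seed via a
  single `sample.int()` draw; each subject's acquisitions then consume
  that stream in a fixed documented order. Same config + seed gives
  bit-identical studies.
* **Activity** — nightly counts are log-normal; post-fatigue night $k$
  carries a multiplicative factor $d^{\,g^{k-1}}$ with dip $d$ (default
  0.5) and relaxation $g = 1/3$, i.e. the full dip on night 1 decaying
  geometrically to within a few percent of baseline by night 4. The
  geometric-relaxation rate is not dictated by the fatigue model itself;
  $g = 1/3$ was chosen once to reproduce the qualitative
  dip-and-recover-within-3-days pattern.

What passing tests on this phantom do **not** show about real data:
manual ROI drawing, partial-volume and motion effects, non-ideal
inversion, B1-dependent readout weighting, physiological B0 drift, and
the actual in-vivo exchange regime are all absent. The phantom validates
the *processing*, not the biology.

## Processing chain: numerical choices

* **Brain mask** — Otsu threshold on I0, largest connected component,
  hole filling. An empty mask is an error, never silently ignored.
* **Z-assembly** — frames are re-ordered to an ascending ppm grid
  (scanners acquire descending); duplicate offsets and frame/offset
  count mismatches are rejected; division by I0 only on the mask.
* **B0 map** — phase difference wrapped to $(-\pi, \pi]$ (the $+\pi$
  boundary maps to the positive limit by convention), divided by
  $2\pi\,\Delta TE$; the unaliased range at ΔTE = 2 ms is ±250 Hz. No
  spatial unwrapping by default: a gradient-shimmed rodent brain at 7 T
  stays well inside the range, and out-of-range values should be seen,
  not "fixed". The B0 map is stored in Hz; ppm views always go through
  the sidecar reference frequency.
* **B1 map** — double-angle $\cos\hat\alpha = S(2\alpha)/2S(\alpha)$
  with the ratio clamped to $[-1, 1]$; voxels with sub-threshold
  single-angle signal are invalid. The nominal angle must lie in
  (0°, 90°) or the arccos branch is ambiguous. B1 is computed and
  reported as a QC map only — it is **not** fed back into the contrast,
  mirroring common practice for this acquisition.
* **B0 realignment** — per voxel, the spectrum is interpolated with a
  natural cubic spline and resampled at `grid + δ` (positive map value =
  water above nominal shifts the apparent minimum to +δ); a sign-flip
  flag accommodates the opposite vendor convention, and linear
  interpolation is available for sensitivity checks. Voxels with
  |δ| > 1 ppm are invalidated rather than corrected — beyond that the
  ±3 ppm evaluation would lean on extrapolation of the ±5 ppm grid.
  Resample points past the grid ends use clamped-end values and raise a
  per-voxel edge flag. An alternative realignment to the spectral
  minimum (rather than the measured B0 map) is a conceivable variant;
  the B0-map route is the implemented default because the map is part of
  the acquisition.
* **Contrast** — read exactly at the ±3.0 ppm grid nodes when present
  (they are, on the 0.2-ppm grid); spline-evaluated otherwise; no
  multi-point averaging band. |contrast| ≥ 0.5 triggers a QC warning,
  not an error.
* **T1 fit** — 3-parameter magnitude model $|a + b\,e^{-TI/T_1}|$ with
  polarity restoration (flip samples before the minimum-signal TI, try
  both polarities of the boundary sample, keep the lower magnitude-domain
  residual), then bounded Levenberg-Marquardt (T1 ∈ (0, 10000] ms,
  200 iterations, ftol 1e−10). The 3-parameter form is robust to
  imperfect inversion; the 2-parameter ideal-inversion model is a special
  case. Initializer: $T_1 \approx TI_{\min}/\ln 2$ from the null
  crossing.
* **T2 fit** — $S_0 e^{-TE/T_2}$ with a variance-weighted log-linear
  initializer (weights $S^2$, the first-order correct weighting for
  log-transformed additive noise), then bounded Levenberg-Marquardt
  (T2 ∈ (0, 2000] ms). No Rician noise-floor term by default — the fit
  is plain least squares, matching standard practice. Consequence worth
  knowing: with 5 TEs reaching 400 ms and SNR 50, the noise floor at the
  late echoes biases fitted T2 upward by roughly 3–4% for T2 ≈ 75 ms;
  the tests compute this bias honestly rather than hiding it, and an
  independent re-implementation reproduces it. Voxels at the parameter
  bounds, non-finite, constant, or underdetermined are invalid, never
  clamped.
* **Statistics** — "Student's t-test" is the classical pooled
  equal-variance test (that is what the name denotes); Welch is a flag.
  Zero pooled variance with equal means returns p = 1; with unequal
  means it is an error, since no finite statistic exists. The activity
  ANOVA treats time point as a between-level one-way factor with the
  pooled pre-fatigue baseline (one mean per animal) as one level — the
  default mirrors the plain reading of "compare activity at different
  time points"; a repeated-measures variant (animal as blocking factor,
  paired post-hoc tests) is available behind a flag because the design
  is in truth paired. Bonferroni family size is the number of post
  nights (4 by default); $p_{adj} = \min(1, m\,p)$. Percent change uses
  the control mean as denominator and α = 0.05 throughout. Group sizes
  are always taken from the data, never assumed.

## Problem sizes used in the tests

The shipped tests run the full chain on 24×12 to 64×32 phantoms with 1–2
subjects per group, 500-voxel Monte-Carlo relaxometry recovery, a
10 000-replicate type-I-error simulation, and 20-seed direction checks;
these sizes make the statistical assertions sharp while keeping the
suite comfortably desk-scale. The full acquisition matrix (128 × 64) and
group sizes (10 + 6) are available through `phantom_config()`.

## Known limitations

* The contrast is the weighted asymmetry only — no Lorentzian-difference
  or multi-pool fitting, no WASSR, no absolute glutamate concentration.
* No B1 correction of the contrast (B1 is QC only).
* No multi-compartment T2, no T2*, no stimulated-echo or slice-profile
  corrections.
* The activity model is phenomenological (log-normal with a geometric
  dip), suitable for testing the normalization and ANOVA machinery, not
  for modeling circadian structure.
* No DICOM or vendor-raw ingestion; NIfTI + JSON sidecars are the
  interchange format.
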