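# glucest

Glutamate-weighted CEST (GluCEST) MRI analysis for small-animal brain
studies, end to end: from raw saturation-frequency image stacks to
B0-corrected Z-spectra, GluCEST contrast maps, quantitative T1/T2/B0/B1
maps, ROI group statistics, and nightly home-cage activity analysis. A
seeded Bloch-McConnell simulator builds complete two-group synthetic
studies with known ground truth, so every stage of the pipeline can be
validated without scanner data.

## Who this is for

Preclinical MRI groups measuring brain glutamate by chemical exchange
saturation transfer at high field (e.g. 7 T rodent scanners), and anyone
who needs a tested, reproducible implementation of the standard GluCEST
processing chain rather than one-off scripts.

## The measurement

Glutamate amine protons resonate about 3 ppm downfield of water and
exchange rapidly with it. Selective RF saturation at their frequency is
transferred to the water pool, attenuating the water signal in proportion
to glutamate concentration. Sweeping the saturation offset Δω gives the
per-voxel **Z-spectrum**

    Z(Δω) = I(Δω) / I0,

with I0 acquired far off-resonance (100 ppm). The asymmetry of the
Z-spectrum at ±3 ppm is the **Glu-weighted CEST contrast**:

    GluCEST = ( I(−3 ppm) − I(+3 ppm) ) / I0 = Z(−3) − Z(+3).

Because B0 inhomogeneity shifts each voxel's apparent water frequency,
the Z-spectrum is realigned voxel-by-voxel with a dual-echo B0 map before
the contrast is computed; T1, T2 and B1 maps complete the
multi-parametric session. The simulator evolves the coupled
Bloch-McConnell equations for a water + glutamate-amine pool system
(optionally + a semisolid MT pool) under continuous-wave irradiation,
with a matrix-exponential propagator cross-checked against an
independent fine-step Runge-Kutta integrator.

## Worked example

Simulate a Z-spectrum at the default 7 T protocol (5.9 μT / 2 s CW
saturation, offsets −5…+5 ppm in 0.2 ppm steps):

```r
library(glucest)
sat <- saturation_params()
ps  <- pool_system(pool_water(), pool_amine(proton_fraction = 0.00026))
z   <- simulate_zspectrum(ps, sat)
z[abs(sat$offsets + 3) < 1e-6] - z[abs(sat$offsets - 3) < 1e-6]
#> 0.021  (Z(-3) = 0.4218, Z(+3) = 0.4008)
```

Run a whole synthetic two-group study through the full pipeline:

```r
cfg <- list(simulate = list(matrix_size = c(32, 16),
                            n_control = 3, n_fatigue = 3, snr = 50),
            activity = list(n_animals = 5, seed = 7))
rep <- run_pipeline(cfg, seed = 11)
rep
```

prints a Table-1-style group summary (excerpt):

```
   roi  metric  ctl_mean  fat_mean pct_change        t df         p
1   WH glucest 1.940e-02 2.956e-02     52.383 -17.9357  4 0.0000568
5   WH   t1_ms 1.428e+03 1.427e+03     -0.109   0.9352  4 0.4026130
9   WH   t2_ms 7.713e+01 7.756e+01      0.553  -1.5789  4 0.1894992

Activity ANOVA: F(4, 20) = 11.321, p = 5.779e-05
Post-hoc vs baseline (Bonferroni):
  night   mean         t df         p     p_adj
1     1 0.5124 -9.602597  8 1.148e-05 4.592e-05
2     2 0.8325 -1.740699  8 1.199e-01 4.797e-01
...
```

The fatigue group's whole-brain GluCEST is ~52% above control (the
designed 1.5× amine-pool difference), relaxation times are unchanged
between groups, and home-cage activity dips on the first post-fatigue
night only — each read off the printed summary. `run_pipeline(..., out =
"dir")` additionally writes NIfTI maps, CSV tables and a JSON run report;
`inst/cli/glucest.R` wraps the same call for shell use.

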