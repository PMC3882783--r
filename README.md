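# cinedense

Quantitative analysis of **cine DENSE** (Displacement ENcoding with
Stimulated Echoes) cardiovascular magnetic resonance of the mouse left
ventricle, together with an **analytic deformation phantom** that makes
every processing stage verifiable against closed-form ground truth.

DENSE encodes the displacement each tissue element has accumulated since
the end-diastolic R-wave trigger into image phase: a pixel with unwrapped
phase φ at encoding frequency k_e (cycles/mm) has moved u = φ / (2π k_e)
mm along the encoded axis. From the magnitude and two phase channels of a
five-slice cine protocol (basal / mid / apical short-axis plus two- and
four-chamber long-axis views), the package computes the advanced measures
of left-ventricular function used in small-animal cardiology:

- **Strain** — per-pixel Lagrangian deformation gradients fitted by local
  weighted least squares; Green–Lagrange tensors projected on radial,
  circumferential and longitudinal directions; reported as percent length
  change by transmural layer (endo / mid / epi thirds) and the standard
  16-segment model;
- **Twist and torsion** — slice rotation about the LV axis; torsion =
  (apical − basal twist) / end-diastolic epicardial long-axis length,
  in °/cm;
- **Synchrony** — the circumferential and radial uniformity ratio
  estimates (CURE, RURE): Fourier-harmonic ratios
  ΣP₀ / Σ(P₀ + P₁) of the sector strain profile, 1 = synchronous;
- **Volumetrics** — EDV, ESV, EF and myocardial mass from a smooth
  surface reconstruction of the short-axis contours;
- **Group statistics** — exact small-sample Mann–Whitney U tests by
  complete enumeration, percent change, correlation, and a two-group
  comparison report.

The pipeline follows the standard DENSE workflow: quality-guided phase
unwrapping → displacement decoding → motion-guided contour propagation →
tissue tracking → strain, torsion, synchrony, volumetrics.

## Worked example

Generate the packaged control phantom (parameters transcribed from the
low-fat-diet group means: subendocardial circumferential stretch 0.83,
subepicardial 0.906, longitudinal 0.88, 8.8° apical twist over a 1 cm long
axis, 457 bpm, 18 frames) and run the full analysis:

```r
library(cinedense)

cfg <- phantom_config_from_yaml(
  system.file("extdata", "lowfat.yaml", package = "cinedense"))
rs <- render_study(cfg)     # five DENSE slices + analytic ground truth
an <- analyze_study(rs$study)
an
#> cine DENSE analysis of 'phantom_seed1'
#> peak layer strains (%):
#>         ecc   err
#> endo -16.96  3.38
#> mid  -12.94 11.62
#> epi   -9.35 18.83
#> longitudinal (global): -11.98%
#> peak torsion 8.80 deg/cm; CURE 1.0000, RURE 1.0000
#> EDV 61.1 uL, ESV 40.0 uL, EF 34.5%, mass 99.4 mg (1.63 mg/uL)
```

The configured stretches are the layer ground truths, so the analysis
recovers −17% subendocardial and −9.4% subepicardial circumferential
strain, −12% longitudinal strain and 8.8 °/cm torsion to within a few
hundredths; with zero activation delay the uniformity indices are exactly
1, and EDV/mass match the analytic geometry (61 µL, 99.4 mg). The
phantom's ejection fraction reflects in-plane contraction only (see the
methods vignette). A dyssynchronous, hypertrophic counterpart ships as
`highfat.yaml`.

Exact group statistics at typical cohort sizes (n = 5 vs 5):

```r
mw <- mannwhitney_exact(c(8.2, 9.9, 7.1, 10.4, 8.8),
                        c(6.3, 6.9, 6.1, 7.0, 6.5))
#> U = 0, p = 0.008   (2 / 252 labelings, two-sided)
```

Studies round-trip to disk as NIfTI volumes plus JSON sidecars
(`write_study()` / `read_study()`); metrics and tidy per-segment strain
curves export with `export_metrics()` / `export_strain_curves()`;
two-group tables are built with `build_report()`.

## Documentation

The methods vignette (`vignettes/cine-dense-methods.Rmd`) describes the
deformation model and its assumptions, what the phantom does and does not
emulate, the numerical choices (unwrapping, tracking, fit orders,
reconstruction basis, tie-breaks) and known limitations.
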