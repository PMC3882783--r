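---
title: "Cine DENSE analysis: models, phantom and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cine DENSE analysis: models, phantom and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinedense)
```

## What the package computes

Cine DENSE (displacement encoding with stimulated echoes) CMR encodes the
in-plane displacement of each myocardial pixel — relative to an
end-diastolic reference — into image phase.  With encoding frequency $k_e$
(cycles/mm), a pixel with unwrapped phase $\phi$ has moved

$$u = \frac{\phi}{2\pi k_e}$$

millimetres along the encoded axis since the R-wave trigger.  From the two
phase channels of each cine frame this package reconstructs displacement
fields, tracks material points, and derives the standard advanced measures
of left-ventricular (LV) function in the mouse:

* **Strains** $E_{cc}, E_{rr}, E_{\ell\ell}$, reported as percent change in
  length (shortening negative, thickening positive), by transmural layer
  (endo/mid/epi thirds) and the 16-segment model (6 basal, 6 mid, 4 apical).
* **Twist and torsion**: mean rotation of each short-axis slice about the LV
  axis; torsion is the basal-to-apical twist difference normalised by the
  end-diastolic epicardial long-axis length (degrees/cm).
* **Synchrony** (CURE/RURE): for $N$ angular sectors with strain profile
  $s_j(t)$, the discrete Fourier powers $P_0(t) = |c_0(t)|^2$ and
  $P_1(t) = |c_1(t)|^2 + |c_{N-1}(t)|^2$ give the uniformity ratio
  $\sum_t P_0 / \sum_t (P_0 + P_1) \in (0, 1]$, with 1 = perfectly
  synchronous.  The cited literature leaves the exact normalisation open
  (with or without a square root, per-frame or pooled ratios); the pooled
  power-ratio form is used here because it is bounded, equals 1 exactly for
  uniform contraction, and decreases strictly under a growing
  first-harmonic perturbation — the properties reported uniformity values
  rely on.  The sector count (24 per slice) and the slice-averaged "Average"
  index are fixed conventions of this implementation.
* **Volumetrics**: EDV, ESV, EF, myocardial mass (density 1.05 mg/µL) from
  a smooth surface reconstruction of the three short-axis contours.

The processing chain mirrors the established DENSE workflow: phase
unwrapping, motion-guided segmentation, tissue tracking, strain
calculation, then the global indices.

## The analytic deformation phantom

No scanner data ship with the package.  Instead, `render_study()` generates
complete five-slice studies (3 short-axis + 2 long-axis views, as the
imaging protocol prescribes) from an analytic LV model whose ground truth
is known in closed form, so every pipeline stage can be verified
quantitatively.

**Geometry.** The end-diastolic LV is a half-ellipsoid of revolution:
endocardial and epicardial squared-radius profiles are quadratic in the
height $z$ above the apex.  The packaged `lowfat.yaml` geometry (mid-slice
radii 1.41/2.26 mm, long axis 10 mm, apical wall 1 mm) reproduces the
control-group means: EDV ≈ 61 µL and mass ≈ 99.5 mg.

**Deformation.** Each material ring at wall depth $d \in [0,1]$ contracts
circumferentially by a peak stretch $\lambda_c(d)$ that is linear in depth
and anchored at the *layer centres*: $\lambda_c(1/6)$ equals the configured
subendocardial stretch and $\lambda_c(5/6)$ the subepicardial one.  The
configured values are therefore exactly the layer-mean strains a correct
analysis should report, matching how strain tables quote "Endo" and "Epi"
values.  Short-axis planes additionally rotate by a twist angle linear in
$z$ through the basal and apical slice positions; long-axis planes contract
longitudinally toward the apex with stretch $\lambda_\ell$.  All motion is
modulated by a raised-cosine activation envelope (onset-to-peak interval
50 ms, a typical murine systole at these heart rates) with per-sector onset
delays following a septal-to-lateral gradient — the dyssynchrony control.
Frame times follow the trigger: frame 1 is end-diastole, and the frame
count is $\lfloor 60000 / \mathrm{HR} / \mathrm{TR} \rfloor$ (18 frames at
457 bpm and TR = 7.1 ms).

**Radial strain is emergent, not prescribed.** With the in-plane map
$r(R) = \lambda_c(d(R))\,R$, the radial stretch is
$\partial r/\partial R = \lambda_c + R\,\lambda_c'$, fixed by kinematic
consistency once $\lambda_c(d)$ is chosen.  For the packaged configurations
it is positive everywhere (wall thickening), but — unlike in a real,
nearly incompressible myocardium — it *increases* toward the epicardium,
because the map does not enforce volume conservation.  The phantom's radial
ground truth is therefore its own analytic $\partial r/\partial R$, checked
against a finite-difference oracle, and only the printed radial values'
sign and order of magnitude are meaningful for comparison, not their
transmural ordering.

**What the phantom does not emulate.** k-space acquisition and
stimulated-echo physics, off-resonance/fat artifacts, papillary muscles,
through-plane motion (short-axis slices deform strictly in plane; long-axis
slices carry the longitudinal motion), intensity variation in the magnitude
channel, and respiratory motion.  Noise enters only as seeded Gaussian
phase noise — where scanner noise appears in DENSE — so passing tests
demonstrate correctness of the *computational* chain under realistic mouse
geometry and kinematics, not robustness to every acquisition artifact.

`ground_truth()` also reports cavity volumes under the same fixed-plane
convention the 2-D analysis uses (the end-systolic cavity follows the
in-plane endocardial contraction only).  The phantom's ejection fraction is
consequently smaller than in vivo values, which include longitudinal
shortening and through-plane effects; volume recovery is judged against
the phantom's own analytic truth.

## Numerical and design choices

**Unwrapping.** Quality-guided region growing within the myocardial mask
(quality = negative local variance of wrapped gradients; deterministic
row-major tie-breaks), with the per-frame global $2\pi$ multiple resolved
by temporal consistency, anchored at frame 1 where displacement is
identically zero.  The mask comes from thresholding the magnitude image at
half its maximum; a disconnected mask is an error rather than a guess.

**Tracking.** One material point per end-diastolic myocardial pixel.  The
Eulerian samples give scattered pairs (deformed position, reference
position); the trajectory $x(t)$ solving $x - u(x,t) = X$ is found by local
least-squares polynomial (quadratic) inverse interpolation over all samples
within 2.5 pixels — a purely geometric neighbourhood rule, chosen over
k-nearest selection so the interpolation inherits the symmetries of the
pixel grid.  A point is flagged invalid (monotonically, once lost) when its
Lagrangian residual exceeds 0.1 pixel or no sample lies within 2.5 pixels.

**Strain.** The deformation gradient at each point is fitted by weighted
least squares to the motion of neighbours within 4 pixels (Gaussian
distance weights, scale 2 pixels), using a cubic local motion model whose
linear part is $F$; the model order drops automatically in sparse
neighbourhoods (minimum 6 neighbours, affine).  The cubic term matters: the
mouse wall spans only ~3.5 pixels at 0.25 mm resolution, and an affine fit
over such a stencil underestimates subendocardial shortening by more than
one strain point, while the weighted cubic fit is accurate to under 0.3
strain-% pointwise.  Green–Lagrange tensors are projected on radial/
circumferential directions defined from the fixed end-diastolic epicardial
centroid and converted to engineering percent via
$100(\sqrt{2E_{dir}+1}-1)$.

**Layers, segments, peaks.** Depth is measured along the centroid ray
between the end-diastolic contours; layers are transmural thirds (the
figure convention showing three layers).  The segment origin sits at image
"up" and is configurable — without the right ventricle the anterior-septal
insertion is not identifiable, and the choice affects labelling only.
Global and layer curves average the per-segment curves (the
"averaged-curve" reading); taking the peak per segment first is exposed as
an option (`peak_per_segment`).  Peak strain is the curve minimum for
circumferential/longitudinal and the maximum for radial.

**Longitudinal strain.** Both long-axis views are analysed with the same
track-and-fit machinery; strain is projected on the local wall tangent
taken from the epicardial silhouette with its base-plane closure segments
excluded (they are valve plane, not wall).  Points below 30% of the
long-axis length are excluded — the stated apical exclusion with an
explicit cutoff, since the convention itself fixes none.  The reported curve averages the
two views.

**Volumetrics.** Per angular ray, the *squared* radius is interpolated
polynomially through the apex (pinned to zero) and the three slice radii
and integrated to the base plane; the squared-radius parameterisation makes
the reconstruction exact for ellipsoids of revolution, and the 5% phantom
bound—not a particular basis—defines acceptable fidelity.  End-systole is
the frame of minimum reconstructed cavity volume.

**Statistics.** The exact Mann–Whitney test enumerates all
$\binom{n_1+n_2}{n_1}$ labelings (mid-ranks under ties, a choice the source
leaves open); the two-sided p doubles the one-sided tail, capped at 1.  At
$n = 5$ vs 5 the attainable two-sided p values include 0.008, 0.016, 0.032
and 0.056 — exactly the p values such cohort comparisons report.  Percent
change uses the control mean as denominator.  Correlation goes through
`stats::cor.test`.

**Dyssynchrony calibration.** The packaged `highfat.yaml` fixes its
septal-to-lateral delay amplitude at 33.05 ms, found by bisection so that
the *analytic* slice-averaged RURE equals 0.91, the obese-group mean; the
synchronous control keeps RURE = 1.  Because dyssynchrony is modelled
purely as activation delays shared by all strain components, CURE and RURE
degrade together in the phantom — the observed dissociation between the
two indices in real obese mice (preserved CURE, reduced RURE) is not
reproducible by timing delays alone and is out of scope here.

## Problem sizes and verification

The test-suite and acceptance computations use the protocol's full
acquisition geometry — 128 × 128 matrix over a 32 mm field of view, 18 frames, five
slices, roughly a thousand tracked material points per study — so the
phantom recovery checks run the genuine problem size, in one to two minutes
per study.  Verified bounds on the noise-free control phantom include:
layer circumferential strains within 0.5 strain-% of truth, peak torsion
within 0.2 °/cm, propagated contours within 0.05 pixel of the analytic
boundary, displacement round trip (encode → unwrap → decode) exact to
10⁻¹⁴ mm in unwrapped slices and under 1% of a pixel where the long-axis
phases wrap, volumes within 5%, and CURE = RURE = 1 to 10⁻⁶.  Interior
deformation gradients agree with the analytic map to ~10⁻³ Frobenius
(median; 2.5 × 10⁻³ maximum) — the residual is set by the 3.5-pixel wall,
not by the fitting order.

## Known limitations

* 2-D slices only: no shear/principal 3-D strain tensor, no through-plane
  correction.
* The raised-cosine activation waveform is an artifact convention; only its
  peak values and peak *times* carry information; its shape is a
  convention.
* Single-component dyssynchrony (timing delays); amplitude heterogeneity
  between walls is not modelled.
* The unwrapping algorithm is validated against the phantom, not against
  scanner data with low-SNR regions; multi-island myocardium is rejected
  rather than unwrapped per component.
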