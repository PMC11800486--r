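---
title: "Why phase imaging over-calls paramagnetic rims: the qsmrim in-silico study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why phase imaging over-calls paramagnetic rims: the qsmrim in-silico study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

A tissue susceptibility distribution $\chi(\mathbf{r})$ (in ppm) placed in a
main field $B_0$ shifts the local resonance frequency. In the Fourier
domain the induced relative field perturbation is

$$ B(\mathbf{k}) = D(\mathbf{k})\, X(\mathbf{k}), \qquad
   D(\mathbf{k}) = \tfrac{1}{3} - \frac{(\mathbf{k}\cdot\hat b_0)^2}{|\mathbf{k}|^2}, $$

the unit dipole kernel. `forward_field()` implements this as an FFT
convolution with the zero-frequency term nulled (the absolute field offset
is unobservable, so all field maps are zero-mean over the periodic grid).
Two closed forms anchor the implementation:

* a uniform sphere of radius $a$ and contrast $\Delta\chi$ has zero
  (Lorentz-corrected) internal field and the pure dipole
  $\tfrac{\Delta\chi}{3}\left(\tfrac{a}{r}\right)^3 (3\cos^2\theta - 1)$
  outside;
* a shell with radii $a_{in} < a_{out}$ is the superposition of two such
  spheres: zero field in the cavity, and outside the shell *exactly* the
  field of a solid sphere of matched moment
  $\Delta\chi\,(a_{out}^3 - a_{in}^3)$.

The second identity is the confound this package exists to demonstrate: no
measurement of the field outside a lesion can tell an iron rim (shell) from
a demyelinated solid core of equal total moment. The test suite verifies
the FFT model against both closed forms to within 5 % of the peak external
amplitude on the inner half-grid (discretization and circular wrap-around
account for the residual; an optional `pad = TRUE` doubles the FOV), and
the matched-moment identity to $10^{-12}$ in closed form.

Multi-echo gradient-echo signal is synthesized per voxel as
$m_0\, e^{-R_2^* TE}\, e^{i\, 2\pi \bar\gamma B_0\, b\, 10^{-6}\, TE}$
with $\bar\gamma = 42.577$ MHz/T, plus i.i.d. complex Gaussian noise.
Sequence parameters that only scale the steady-state magnitude (TR, flip
angle) are folded into $m_0$; phase and QSM depend only on the field and
the echo times.

## The two reconstructions

**HPF phase.** Per 2D slice of the echo closest to TE = 20 ms: multiply the
k-space data by a circularly symmetric low-pass Hanning kernel
$w(k) = \tfrac12(1 + \cos(\pi |k| / R))$, transform back, and take the
phase of the complex division of the original slice by its low-pass
version. The complex division sidesteps phase unwrapping and removes the
smooth background phase — and with it the smooth interior phase of any
lesion, leaving the sharp external dipole pattern as a rim-like residue.
`hpf_phase()` defaults to the protocol radius $R = 128$ k-space voxels.

**QSM.** `estimate_field()` fits phase against TE per voxel
(magnitude-weighted, free intercept) after temporal unwrapping: each echo's
principal phase is shifted by the multiple of $2\pi$ closest to the
prediction of a running slope estimate seeded by the first-echo phase.
This recovers fields whose per-ΔTE increment exceeds $\pi$ (verified on a
$1.2\pi$-increment fixture where a principal-value fit fails), and is valid
while $|\phi(TE_1)| < \pi$, i.e. up to ~1.4 ppm at 3 T with
$TE_1 = 3.4$ ms. Dipole inversion is either thresholded k-space division
(TKD; division by $D$ floored at $|D| \ge t$, default $t = 0.2$) or a
Tikhonov-regularized total-field inversion minimising
$\|W(d \circledast \chi - f)\|^2 + \lambda \|\nabla\chi\|^2$ by conjugate
gradients ($\lambda = 10^{-3}$ default, forward differences with periodic
boundary, diagonal right-preconditioner boosting the expected dynamic range
outside the reliability mask). The published reconstructions this study
emulates use a nonlinear preconditioned total-field solver; the linear
solvers here keep the property that matters for the rim question — dipole
deconvolution of the unprocessed total field — while remaining small,
deterministic and testable. No background-field removal stage exists
because the phantoms have no air interface; the total-field formulation
absorbs a smooth background if one is added.

The end-to-end experiment defaults to TKD: it is linear, exactly
reproducible, an order of magnitude cheaper than the CG solver at 128³,
and the cohort-level conclusions are identical under either method. The CG
solver carries the parameter-recovery tests (rank correlation between true
rim susceptibility and the reconstructed rim-annulus mean exceeds 0.8 on a
20-phantom cohort; in practice it is ≈ 0.99).

## The reader surrogate

Human readers judged lesions rim-positive or negative per modality; the
package replaces them with a deterministic score computed in the 2D slice
through the lesion-mask centroid (the plane the 2D filter operates in):

$$ z = \frac{\text{boundary mean} - \text{core mean}}{\hat\sigma_{bg}}, $$

with $\hat\sigma_{bg}$ the median-absolute-deviation spread (× 1.4826) of
background pixels in the same slice, and an angular-coverage gate: the
fraction of 12 azimuthal sectors of the boundary band deviating from the
core by ≥ 2 noise units in the direction of the overall contrast must reach
0.25. A QSM rim call requires $z \ge z_{thr}$ (hyperintense rim), a phase
call $z \le -z_{thr}$ (hypointense rim); $z_{thr} = 2$ by default and the
study conclusions are checked over $z_{thr} \in [1.5, 3]$.

The boundary band is placed where each modality's rim signature physically
lives, a choice forced by the shell field geometry. HPF phase is a
*nonlocal field* image: with $B_0$ along the slice normal, the in-plane
field is negative just *outside* any paramagnetic lesion (solid or
shell — matched moments make them identical there), while inside the rim
material itself it is positive; a single fixed-sign rule can therefore only
work on the outside annulus. QSM is a *local tissue property* image: the
iron rim is elevated susceptibility in the outermost shell of the lesion,
inside its T2-visible boundary, and is invisible from outside. Hence phase
scores the 2-voxel annulus outside the lesion mask (`band = "outside"`),
and QSM scores the outermost 2-voxel shell of the mask against a doubly
eroded core (`band = "edge"`). The lesion mask is the full T2-visible
extent — demyelinated core plus rim — matching what a T2-based lesion
segmentation would supply.

## The synthetic cohort

Four lesion classes, one lesion per 128³ phantom at 0.5 mm isotropic
(64 mm FOV), placed near the grid centre with ±2 mm jitter to stay clear of
circular-convolution wrap-around:

| parameter | default | rationale |
|---|---|---|
| core radius | U(2.5, 4.5) mm | typical supratentorial WM lesion sizes |
| core $\chi$ | U(0.04, 0.10) ppm | full demyelination removes the ≈ −0.05 ppm myelin contribution; diffuse microglial iron varies lesion to lesion |
| rim $\chi$ | U(0.10, 0.20) ppm | iron-laden rim on top of the demyelinated substrate |
| rim thickness | U(0.8, 1.2) mm | thin histological rim, 2 voxels at 0.5 mm |
| partial-rim coverage | U(0.3, 0.7) of 4π | rims need not span the full circumference |
| vein | radius U(0.3, 0.5) mm, 0.30 ppm | deoxygenated central vein |
| B0, echoes | 3 T; 8 echoes, 3.4 + 5.6 k ms | acquisition protocol |
| noise | 0.02 of $m_0$ | SNR 50 at the first echo: long ex-vivo acquisitions are high-SNR |
| $R_2^*$ | 15 s⁻¹ | fixed white matter at 3 T |
| experiment filter radius | 51 | preserves the protocol's passband *fraction* (128-voxel radius on a ≈ 320-voxel slab matrix) at the simulated 128 matrix; with $R$ equal to the matrix size the Hanning high-pass passes almost nothing of a lesion-scale ring, as the filter-radius monotonicity test shows |

A lesion is ground-truth iron-positive when it has a rim of nonzero
thickness and susceptibility covering at least 0.25 of the sphere —
the same fixed, configurable floor the classifier's coverage gate uses.
Truth is a pure function of the lesion parameters.

Susceptibility contrasts deserve a note: an early design sketch fixed the
demyelinated core at +0.02 ppm on the argument that absolute values only
set SNR. Implementation showed otherwise — the solid-lesion phase artifact
scales with core $\chi \cdot TE$ against the filtered noise floor, and at
+0.02 ppm a solid sphere's filtered ring sits near 1 noise unit, below any
reasonable reader threshold even in the unfiltered limit. The defaults
above use the literature range for *complete* demyelination (all cohort
lesions here have fully demyelinated cores), under which the artifact is
detectable, as the ex-vivo readings imply it was.

The generator emulates: sphericity, sharp class structure, uniform
background, noise-limited reading. It does **not** emulate irregular lesion
shapes, partial-volume gradients at lesion borders, background fields from
air/tissue interfaces, field-dependent $R_2^*$ within the rim, reader
variability (readers are replaced by one deterministic surrogate; panels
only appear as synthetic Bernoulli-corrupted rating matrices for the
agreement statistics), or multi-slice reading — the surrogate scores a
single slice, so partial rims whose cap misses the central slice are
missed, depressing simulated sensitivity relative to a human who scrolls.
Passing tests therefore demonstrate the mechanism and the statistics, not
clinical operating points.

## Numerical choices

* Voxelization by voxel-centre membership; the convergence test bounds the
  moment error (summed over several radii to average out lattice-phase
  oscillation, it at least halves when resolution doubles).
* FFT convolution without padding by default; oracle comparisons restrict
  to the inner half-grid; `pad = TRUE` available.
* Division guard in the HPF step: low-pass magnitudes below
  $10^{-12} \times$ the slice maximum yield zero phase and are flagged in a
  validity mask.
* Echo-selection ties break toward the earlier echo; kernel band edges are
  closed on the right (a Landis–Koch κ of exactly 0.60 is "moderate").
* Percentages round half-up to integers (10/16 prints as 63 %), matching
  the convention evident in the reported values; raw fractions are kept
  alongside.
* Cohen's κ with degenerate marginals ($p_e = 1$) is defined as 1 under
  perfect agreement and flagged undefined otherwise; Fleiss' κ likewise.
  With two raters Fleiss' pooled-marginal chance term makes it equal to
  Cohen's κ exactly when the raters' marginals coincide, and only then —
  both facts are pinned by tests.
* Per-lesion noise seeds derive deterministically from the experiment seed,
  so cohorts re-run bit-identically.
* The κ interpretation bands are standard Landis–Koch; published readings
  sometimes label values inconsistently with those bands, and such labels
  are not reproduced.

## Problem sizes

Unit tests run on 16³–64³ grids; the end-to-end confound check runs the
full 32-lesion cohort (16 solid + 16 full-rim) at the native 128³ study
grid and SNR 50; the inversion parameter-recovery cohort uses 20 rim
phantoms at 64³, where the CG solver's runtime is modest and recovery is
already near-perfect. `scripts/acceptance.R` re-runs the 4-class 32-lesion
cohort at 128³.

## Known limitations

* The linear Tikhonov/TKD inversions underestimate susceptibility steps
  (regularization bias ≈ 15–20 % at the defaults); conclusions rely on
  contrast, not absolute recovery.
* The surrogate reader is single-slice and mean-based; it understates
  sensitivity to partial rims and cannot model reader-specific bias, so
  the published κ values have no in-silico counterpart (the agreement
  machinery is exercised on synthetic rating matrices instead).
* No air/tissue background field is simulated; the total-field inversion's
  preconditioner is exercised only through its mask-exterior weighting.
* Lesions are spheres; rim-appearance dependence on lesion shape and
  orientation is outside the phantom family, except through B0-direction
  configurability.
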