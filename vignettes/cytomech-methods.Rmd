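---
title: "Methods: microtubule-network morphometry and Sneddon elasticity fitting"
author: "cytomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microtubule-network morphometry and Sneddon elasticity fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
parameters matter, and where the numerical and design choices were
genuinely open.

# Morphometry arm

## Segmentation chain

A reconstructed superresolution image is processed as:

1. **Cell-area detection** (`detectCellArea`): Gaussian smoothing
   (sigma 10 px by default — coarse enough to merge the filament
   texture into one blob), Otsu threshold on the smoothed image, hole
   filling, and selection of the largest connected component. An
   all-zero image is an "empty field" error; a constant positive image
   is, by convention, entirely cell.
2. **Top-hat enhancement** (`enhanceTophat`): white top-hat with a disk
   of radius 5 px by default. The radius must exceed the apparent
   filament width and stay below the typical inter-filament spacing;
   it flattens smooth background while passing thin ridges unchanged.
3. **Binarisation** (`binarize`): a single manual threshold, applied
   uniformly to all images of a run. Strict inequality
   (intensity > threshold) makes the edge cases unambiguous.
4. **Skeletonization** (`skeletonize`): two-subiteration parallel
   thinning (Guo–Hall) to a 1-px, 8-connected, topology-preserving
   skeleton. Deletion conditions are evaluated on the whole frame per
   subiteration and iterated to a fixed point, so the operation is
   idempotent by construction and the skeleton is always a subset of
   the mask.
5. **Branch points** (`detectBranchpoints`): skeleton pixels with at
   least three 8-connected skeleton neighbours; because thinning can
   emit 2-px junction clusters, 8-connected clusters of branch pixels
   are merged and counted once.

Per cell, *MT density* = skeleton length / cell area and *crossing
density* = branch points / skeleton length. Skeleton length defaults to
the plain pixel count; a geodesic variant (diagonal steps weighted
$\sqrt 2$) is available behind `diagonalWeight = TRUE` since the
measure is not uniquely determined by its verbal definition. With an
empty skeleton the crossing density is undefined and flagged rather
than silently zero.

## Orientation and alignment

Each pixel is probed with a digitized (Bresenham) line of 11 px at
angles $0, 10, \dots, 170^\circ$ — axial angles, since a filament has
no polarity. The response is the morphological opening with that line;
by default the binary opening of the MT mask (exact, and makes the
tie-break deterministic), optionally the grayscale opening of the
image. The best angle is the argmax, ties resolved to the smallest
angle.

The local alignment statistic at a pixel is the mean resultant length
of doubled angles over MT pixels in a circular window (diameter 51 px,
truncated at the frame border, no padding):
$$S = \Bigl|\; \tfrac1n \sum_{j} e^{2 i \theta_j} \;\Bigr| \in [0, 1].$$
$S = 1$ means locally parallel filaments; doubling maps the axial
identification $\theta \equiv \theta + 180^\circ$ onto the full circle
so antipodal cancellation behaves correctly (e.g. an equal mix of 0°
and 90° gives exactly 0). The per-cell readout is the arithmetic mean
of $S$ over all MT pixels. Note the naming: this quantity is the
*mean resultant length*; the circular variance in the textbook sense is
$1 - S$. The per-pixel display convention (bright = aligned or bright =
disordered) is left to the caller; the statistic itself is fixed.

## Angular selectivity and its consequences

An 11-px line inside a filament band of width $w$ px tolerates an
angular mismatch of roughly $\arctan(w/11)$ — about $\pm 15^\circ$ at
$w = 3$. Consequently several elements often respond equally and the
smallest-angle tie-break systematically snaps labels toward the lower
grid angle. Two practical consequences, both verified in the tests:

- per-pixel angles are accurate only to about one 10° grid step, so
  rotation equivariance holds to one grid step in the modal angle and
  to a mean absolute change in the per-cell statistic below 0.05;
- the per-cell statistic remains strictly monotone in the true
  orientation dispersion (rank correlation 1.0 across dispersion
  levels in the test conditions), which is what the between-group
  comparison consumes.

A perfectly parallel horizontal network — the canonical on-grid single
angle — scores exactly 1; off-grid single angles score slightly below
(≥ 0.95 at 30° in the test fixture) because line digitization splits
labels across adjacent grid angles near junction and end pixels.

# Elasticity arm

## Model

A rigid sphere of radius $R_s$ indenting an elastic half-space
(Sneddon), parametrised by the contact radius $a$:
$$F(a) = \frac{E}{1-\nu^2}\left[\frac{a^2+R_s^2}{2}
\ln\frac{R_s+a}{R_s-a} - a R_s\right],\qquad
\delta(a) = \frac{a}{2}\ln\frac{R_s+a}{R_s-a}.$$
$\delta(a)$ is strictly increasing on $(0, R_s)$, so the inversion
$\delta \mapsto a$ is unique; it is computed by a safeguarded,
vectorised Newton iteration (bracket $(0, R_s)$, convergence at
$10^{-13}$ relative, converged elements frozen). For
$\delta/R_s \lesssim 0.005$ the force agrees with the Hertz paraboloid
expression $(4/3)\,E/(1-\nu^2)\sqrt{R_s}\,\delta^{3/2}$ to better than
0.1%, which serves as an independent closed-form check. Units are nm,
Pa and nN throughout ($F = k d$ is N/m × nm = nN with no conversion
constant).

Assumptions inherited from the model: linear elasticity, small strain,
frictionless contact, sample much thicker than the indentation, and a
fixed Poisson ratio (0.5 for cells, configurable).

## Fitting

The deflection baseline is a straight line fitted to the leading 30%
of samples (configurable; it must lie before contact, and fewer than
10 baseline samples is an error). After baseline subtraction,
$F = k d$ and $\delta = (z - z_0) - d$.

The fit at depth $D$ (200/400/600 nm) minimises
$\sum (F_{obs} - E\,\phi(\delta))^2$ with $\phi$ the unit-modulus
Sneddon force and model force 0 before contact. Two structural
decisions:

- **E is profiled out.** The model is linear in $E$, so for fixed
  $z_0$ the optimal $E$ is the conditional least-squares solution
  (clamped to $[1, 10^6]$ Pa). The remaining 1-D problem in $z_0$ is
  solved by a deterministic grid (201 candidates) whose local minima
  are each refined with `optimize`; the landscape can be multimodal at
  shallow depths because $E$ partially compensates contact-point
  error.
- **The fitted sample range is fixed, then iterated.** A least-squares
  objective whose sample window moves with the candidate $z_0$ is
  ill-posed: placing $z_0$ in the flat pre-contact region excludes the
  force rise from the residual entirely and "fits" zero data. The
  package therefore fixes the fitted range — curve start up to the
  sample where the indentation reaches $D$ — computes the best
  $(E, z_0)$ over that range, and recomputes the range from the fitted
  $z_0$ until it stabilises (at most 6 iterations). The initial range
  comes from the first sample whose force exceeds
  $\max(3\sigma_{baseline}, 1\%\ \text{of peak force})$.

Noiseless generator round trips recover $E$ to machine precision and
$z_0$ to $\ll 1$ nm at every depth; with 1 nm deflection noise the
median recovered modulus over 100 replicates stays within a few
percent at 400 nm depth. Per cell, the median modulus over its 8–10
curves is reported (robust to occasional bad curves; the mean is
available via `summaryFun`).

## Group comparison

`compareGroups` implements the Mann–Whitney U test on midranks: exact
permutation enumeration when both groups have at most 10 observations
(valid under ties, and gives $p = 1$ exactly for identical groups),
otherwise the normal approximation with tie-corrected variance. The
two-sided p is $\min(1, 2\min(P(U \le u), P(U \ge u)))$.

# Synthetic data

`generateFilamentImage` draws straight lines (centre uniform in the
frame, axial angle from a single angle, a uniform axial law, or a
wrapped normal on doubled angles with concentration `dispersion`;
concentration 0 falls back to uniform), records the exact ground truth
*before* rendering — per-filament angles, Bresenham centerline pixels,
pairwise segment intersections inside the frame, and the axial
resultant length of the angle population — then renders by dilating
the centerlines to the requested width, Gaussian blur, constant
background and additive Gaussian noise. Straight lines were chosen so
crossings and angles are exact; real microtubules are gently curved,
so curvature-induced label spread is not emulated. Neither are the
dSTORM localization artefacts (blinking, drift, variable labelling
density). Passing tests therefore demonstrate correctness of the
measurement chain, not robustness to every artefact of real imaging.

`generateForceCurve` samples piezo positions on a grid and solves, per
sample, the implicit self-consistency $d = F((z - z_0) - d)/k$ by a
safeguarded Newton iteration to $10^{-10}$ relative tolerance, adding
a linear pre-contact drift and Gaussian deflection noise. Generation
refuses z-ranges that would drive the indentation beyond $R_s$.
Defaults mirror the experimental setup being emulated: $R_s$ = 2250 nm
(4.5 µm silica bead), $k$ = 0.08 N/m, $\nu$ = 0.5, moduli of a few
hundred Pa, ~500 pN peak loads. Cantilever dynamics and hydrodynamic
drag are not modelled.

Determinism: every stochastic step is seeded from the spec, and the
generator restores the caller's RNG state. Identical spec implies
bit-identical output, which the pipeline inherits (byte-identical CSV
outputs under a fixed config and seed, asserted in the tests).

# Problem sizes and defaults used by the test suite

Image fixtures are 128–256 px squares with 10–40 filaments; force
curves use a 0–1800 nm sweep at 5 nm steps with contact at 600 nm; the
noisy-recovery study uses 100 seeded replicates at 1 nm deflection
noise. These sizes keep full generator → analysis round trips exact
and fast while exercising every code path; all of them are plain
function arguments, so larger studies only change the config.

# Known limitations

- Angular resolution is limited to the 10° grid and further degraded
  by the binary-opening capture basin discussed above; sub-degree
  methods (structure tensor, steerable filters) are out of scope.
- Branch-point counts are a proxy for crossings: thinning may split a
  thick junction into several nearby branch clusters (counts are
  monotone in, and never below, the rendered crossing number in the
  test conditions, but not equal to it in general).
- The morphometry is strictly 2-D; depth-coded stacks are analysed as
  single planes.
- The elasticity model is purely elastic; viscoelastic relaxation,
  adhesion and finite sample thickness are not modelled, and only the
  approach segment of a force curve is used.
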