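# cytomech

Quantitative analysis of the microtubule cytoskeleton and of cell
mechanics in cultured cells (e.g. dorsal root ganglion sensory neurons),
with a synthetic-data module that makes every stage testable against
known ground truth.

The package implements two measurement arms:

**1. Microtubule-network morphometry from superresolution images.**
Reconstructed dSTORM-style images of immunostained microtubules are
enhanced with a white top-hat filter, binarised with a fixed manual
threshold, and thinned to a 1-px topology-preserving skeleton. From the
skeleton the package reports, per cell,

- *MT density* = skeleton length / imaged cell area (px⁻¹),
- *crossing density* = number of merged branch points / skeleton length (px⁻¹),
- *angular alignment*: each pixel is probed with a rotating linear
  structuring element (length 11 px, angles 0–170° in 10° steps) and
  assigned the angle of maximal response; in a sliding circular window
  (diameter 51 px) the axial angles θ are doubled and the mean resultant
  length S = |mean<sub>j</sub> e<sup>2iθⱼ</sup>| is computed. S = 1
  where microtubules run locally parallel and falls toward 0 where they
  cross at diverse angles; the per-cell value is the mean of S over all
  microtubule pixels. (Conventionally S is the mean resultant length of
  axial data; the circular variance is 1 − S.)

**2. Cell elasticity from AFM force spectroscopy.** Approach
force–distance curves acquired with a spherical bead indenter
(radius R<sub>s</sub>, cantilever spring constant k) are converted to
force–indentation data (F = k·d, δ = (z − z₀) − d after baseline
correction) and fitted with the Sneddon rigid-sphere contact model

F(a) = E/(1−ν²) · [ (a²+R<sub>s</sub>²)/2 · ln((R<sub>s</sub>+a)/(R<sub>s</sub>−a)) − aR<sub>s</sub> ],
δ(a) = a/2 · ln((R<sub>s</sub>+a)/(R<sub>s</sub>−a)),

with the contact radius a as parameter, jointly estimating the Young's
modulus E and the contact point z₀ at fixed indentation depths (200,
400, 600 nm). Groups of cells are compared with an exact small-sample
Mann–Whitney rank test.

The synthetic-data module renders straight-filament networks with exact
centerline, crossing and orientation ground truth, and forward-models
approach curves from the Sneddon force with the implicit cantilever
deflection self-consistency d = F(δ)/k — so generator → analysis round
trips validate every stage.

## Worked example

```r
library(cytomech)

## synthetic microtubule network with ground truth
spec <- NetworkSpec(nFilaments = 40L, dispersion = 2, seed = 11L)
out  <- generateFilamentImage(spec)
morph <- analyzeMorphometry(out$image, threshold = 0.3,
  cellMaskOverride = CellMask(matrix(TRUE, 256, 256)))
morph$result
#> MorphometryResult: skeleton length 6153 px, 235 branch point(s)
#>   MT density 0.09389 px^-1, crossing density 0.03819 px^-1

ori <- analyzeOrientation(morph$binary)
round(ori$alignment, 3)                  # per-cell alignment statistic
#> 0.887   (ground-truth axial resultant length of this network: 0.864)

## AFM: noisy synthetic approach curve, fitted at 400 nm indentation
fc <- generateForceCurve(CurveSpec(youngsModulus = 500,
                                   deflectionNoiseSd = 1, seed = 3L))
fitHertz(fc, fitDepth = 400)
#> HertzFitResult [ok]: E = 455.83 Pa, z0 = 623.007 nm at depth 400 nm
#>   (81 points, RMS 0.0799 nN)

## two groups of per-cell moduli (Pa): exact rank-sum comparison
compareGroups(c(412, 388, 441, 405), c(892, 1104, 951, 874))$p
#> [1] 0.02857143
```

The morphometry readout says this network carries ~0.094 px of skeleton
per px² of cell area, one detected crossing every ~26 skeleton pixels,
and locally fairly parallel filaments (S ≈ 0.89, tracking the known
orientation spread of the generator). The fit recovers the generating
500 Pa modulus to within the noise-limited scatter of a single curve;
medians over the 8–10 curves of a cell are the per-cell readout.

`runPipeline(config, outDir)` orchestrates both arms end-to-end from a
YAML/list config (synthetic or on-disk inputs), writes per-cell and
per-curve CSV tables plus group summaries, and is byte-reproducible
under a fixed seed.

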