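---
title: "Quantifying optic nerve head perfusion from OMAG OCT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic nerve head perfusion from OMAG OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(onhperf)
```

## The measurement problem

Optical microangiography (OMAG) turns a Fourier-domain OCT scanner into an
angiograph: at each slow-axis location of the optic nerve head (ONH) the
device acquires R = 4 consecutive B-scans a few milliseconds apart (245
A-scans per B-scan at a 68 kHz A-scan rate gives an inter-B-scan period of
about 3.6 ms). Static tissue returns a stable complex signal; moving red
blood cells decorrelate it. The flow signal at each voxel is the mean
magnitude of consecutive complex B-scan differences,

$$ I_{Flow}(x,z) \;=\; \frac{1}{R-1}\sum_{i=1}^{R-1}
   \lvert C_{i+1}(x,z) - C_i(x,z)\rvert , $$

implemented in `compute_flow()`. Because an 840 nm source penetrates
poorly below the lamina cribrosa, analysis is restricted to the
*pre-laminar tissue* (preLC): the slab between the inner limiting membrane
(ILM) and the anterior lamina cribrosa surface, inside the disc margin
defined by the termination of Bruch's membrane. Within that region three
unitless perfusion metrics are computed on the en-face maximum intensity
projection (MIP):

* **flux** — mean of $I_{Flow}/255$ over disc pixels,
* **vessel area density** — detected vessel area / disc area,
* **normalized flux** — mean of $I_{Flow}/255$ over vessel pixels only,

which satisfy exactly
$\mathrm{flux} = d\cdot nf + (1-d)\cdot \bar b$ with $d$ the density, $nf$
the normalized flux and $\bar b$ the mean normalized flow over non-vessel
disc pixels. This identity is verified to $10^{-12}$ in the test suite.

## The synthetic world

No raw scans are distributed with studies of this kind, so the package
carries a first-class simulator. `scene_spec()` + `generate_volume()`
render a repeated-B-scan complex volume with known ground truth:

* **Signal model.** Every voxel gets a fixed speckle phase and a
  structural amplitude (dark vitreous 0.05, tissue 1.0, lamina 1.4,
  RPE/Bruch's band 2.2, with the band absent inside the disc). Static
  voxels are bit-identical across repeats. A vessel voxel with
  decorrelation magnitude $\delta \in [0,1]$ receives, per repeat, a phase
  offset uniform on $[0, 2\pi\delta]$ and an amplitude jitter uniform on
  $1 \pm 0.3\delta$. This one-parameter model is deliberately not a
  physical scatterer model: its single purpose is a knob that maps
  monotonically onto the flow signal, and the monotonicity is
  property-tested. Because the random draws are ordered so their count
  never depends on $\delta$, two scenes differing only in $\delta$ share
  the same noise realization.
* **Noise floor.** Additive complex Gaussian noise, SD 0.05 per channel
  (5% of tissue reflectivity). The underlying study does not characterize
  the flow noise floor in avascular tissue, so this is a free parameter of
  the simulated world; 5% makes the static-tissue flow roughly 15% of the
  vessel flow at $\delta = 0.6$, a contrast comparable to the published
  en-face angiograms. It was fixed once, before the acceptance
  experiments were frozen.
* **Geometry.** Default desk-scale grid 128×128×256 over 2.4×2.4 mm
  (the full 245-location geometry is available by configuration; tests use
  96 px cubes for runtime). Vessels are tubes of radius 2–4 px threaded
  mid-slab along the fast axis with a golden-angle-staggered sinusoidal
  wobble — at desk-scale sampling (~25 µm/px) this spans capillary to
  mid-calibre disc vessels. The disc is a centred circle (default radius
  0.75 mm, a typical optic disc).

What a green test on this world does **not** establish: robustness to eye
motion (the device's motion tracking is out of scope and not simulated),
real speckle statistics, flow-velocity dependence (only decorrelation
magnitude is modelled), vessel branching geometry, or pathology-specific
layer morphology.

`cohort_spec()` + `generate_cohort()` simulate the clinical stage: per-eye
records drawn from group-specific multivariate Gaussians (normal / POAG /
NTG) whose means and SDs default to the published group summaries, and
whose metric–covariate correlations default to signed square roots of the
published univariate $R^2$ values (signs follow the reported clinical
directions: perfusion is higher with better VF mean deviation, thicker
RNFL, smaller cup/disc ratio, larger rim area). The metric–metric and
covariate–covariate correlations are not published; they are fixed at
plausible values (e.g. flux–normalized-flux 0.9, SBP–DBP 0.6, MD–PSD
−0.7) chosen once and verified to leave every group matrix positive
definite. Normal-group visual fields were not measured in the study;
healthy defaults (MD 0 ± 1 dB, PSD 1.8 ± 0.5 dB) are used. MOPP is derived
from the drawn pressures via `compute_mopp()` rather than sampled, keeping
the record internally consistent.

## Numerical and design choices

**Dynamic range.** The study's metrics divide the flow signal by 255, its
full display range, but never state how raw $\lvert\Delta C\rvert$ maps to
that range. `scale_to_dynamic_range()` defaults to dividing by the
volume's 99.5th percentile and clipping (robust to isolated hot voxels);
`mode = "max"` and an explicit `ref` divisor are available. The explicit
`ref` matters for controlled comparisons: when volumes differing only in
$\delta$ are each self-normalized, the $\delta$ dependence divides out, so
the $\delta$-monotonicity experiment shares one reference taken from the
strongest-decorrelation condition — the analogue of a device's fixed
display mapping.

**Layer segmentation.** Per A-scan the depth profile is Gaussian-smoothed
(σ = 2 samples), the axial gradient taken by central differences, and
boundaries must exceed an adaptive mean + 2 SD threshold (with a small
absolute floor so featureless profiles fail loudly rather than latch onto
rounding noise). The ILM is the first crossing refined to the local
gradient maximum, ties resolved to the deeper sample — this pins the
step-edge convention testably: an edge with its first bright sample at
depth $z$ yields exactly $z$. The anterior-LC/RPE surface is the strongest
positive gradient at least `3σ` deeper (the margin must clear the ILM's
own smoothed gradient tail, which is why it defaults to `ceiling(3*sigma)`
rather than a fixed 3 samples). Surfaces are median-filtered 3×3 and the
ordering invariant enforced. Manual overrides — full matrices or sparse
control points interpolated by a thin-plate smooth — always win verbatim,
which is the package's reproducible version of the study's semi-automatic
operator guidance; how the original operators interacted with their
algorithm is not stated anywhere, so the override contract is this
package's own definition.

**Disc margin.** Bruch's membrane presence is detected per A-scan as a
bright reflector well below the ILM (Otsu-separated), traced inward from
both lateral edges of each B-scan; sustained disappearance marks a
terminus, and a direct least-squares ellipse fit to all termini defines
the margin. At least six termini are required (an ellipse has five
degrees of freedom); fewer is reported as failure, and a manual polygon
contour may be supplied instead. Depth intervals are half-open
($z_{ilm} \le z < z_{alc}$) so the preLC voxel count is exactly
$\sum (z_{alc}-z_{ilm})$.

**Vessel detection.** The en-face MIP is filtered with a multiscale
Hessian (Frangi-type) bright-ridge response at scales {1, 2, 3, 4} px,
$\beta = 0.5$. The structureness sensitivity $c$ is **one global value
per call** — half the maximum Frobenius norm of the scale-normalized
Hessian across all scales. The alternative (a per-scale $c$) renormalizes
the weak, spatially broad response of the largest scales upward and was
measured to wrap every vessel in a ~1 px spurious halo. Binarization
defaults to Otsu-seeded **hysteresis** within the disc: strong seeds at
the Otsu threshold of the disc-restricted vesselness, grown by
4-connected propagation into the region above half that level (the
canonical 2:1 hysteresis ratio). The design rationale, measured on
scenes with known vessel masks: any single class-midpoint threshold
erodes ridge edges by roughly 20% of area (density −0.10 to −0.17 against
truth), while hysteresis recovers edge pixels contiguous to seeds without
admitting isolated speckle (density within ±0.06 of truth across
fractions 0.31–0.65, Dice 0.84–0.92). A strict `"fixed"` threshold and
plain `"otsu"` remain selectable; the published density range
(0.68–0.77) itself indicates the original rule was permissive rather
than strict. Whether the original study thresholded at all or integrated
the probability map is unknowable from the text; the method switch keeps
both interpretations reachable.

**Degenerate inputs.** All-zero flow volumes scale to all-zero and are
flagged; an empty vessel∩disc set makes normalized flux `NA` with a
warning, never 0 — a 0 would fake total ischemia and silently corrupt
group means; a constant vesselness map under the adaptive thresholds
falls back to the fixed rule with a warning; records with missing signal
strength are excluded by QC with a warning.

**Statistics.** `sample_size_two_group()` defaults to the classic
normal-quantile formula
$n = 2\,\big((z_{1-\alpha/2}+z_{power})\,\sigma/\delta\big)^2$, rounded
up, which reproduces the published planning value of 28 per group for a
normalized-flux mean 0.300, SD 0.06, 15% difference, 80% power,
$\alpha = 0.05$. The exact noncentral-t solution (`method = "exact"`,
cross-checked in the tests against `stats::power.t.test`) gives 29 for
the same inputs; the realized power at n = 28 is ≈ 0.787, which the
Monte-Carlo check (`power_montecarlo()`) reproduces within simulation
error. Group comparisons use one-way fixed-effects ANOVA (three groups)
and two-sided t-tests (pooled variance by default, Welch by flag — the
study names only "independent samples t-tests"); associations use
univariate least squares with $R^2$ and the slope's two-sided p. 95%
confidence intervals are t-based on per-group SD/√n, matching the
"mean ± SD (95% CI)" presentation. No multiple-testing correction is
applied anywhere, deliberately mirroring the study's analysis; p-values
in the regression grid are therefore nominal.

## Running the pipeline

```{r pipeline, eval = FALSE}
cfg <- run_config(
  scene  = list(nx = 96, ny = 96, nz = 128, z_ilm = 26, z_alc = 70,
                vessels = make_vessel_tree(9, nx = 96, ny = 96)),
  cohort = list(n = c(normal = 28, POAG = 30, NTG = 31)),
  seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")
res$metrics          # one tidy row: flux, density, normalized flux, QC
res$tables$table2    # metric summaries by group with ANOVA p-values
```

Each stage commits its artifacts only on success; a failing stage
quarantines partial output under `.staging/` and later stages are not
attempted, with everything recorded in `manifest.json`. Volumes are
exchanged as raw float64 + JSON sidecar and all tables as CSV — there is
no TIFF codec in this package's dependency footprint, and the formats
round-trip bit-exactly.

## Known limitations

* The decorrelation knob is not a velocity model: equal flow signal does
  not imply equal blood velocity, only equal inter-repeat decorrelation.
* Vessel detection is 2-D and en-face; no 3-D tracing, no
  capillary/large-vessel separation, no sectoral sub-disc metrics.
* The simulator's vessels are smooth tubes; real ONH vasculature
  branches, crosses, and shadows deeper tissue.
* The cohort generator draws Gaussians; real clinical covariates are
  skewed and bounded, and published group differences are reproduced by
  construction, not discovered.
* Segmentation assumes the layered contrast of the synthetic scenes;
  performance on pathological real scans is untested by design.
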