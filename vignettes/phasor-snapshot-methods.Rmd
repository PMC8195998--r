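---
title: "Methods: spectral phasors from sine/cosine filter snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral phasors from sine/cosine filter snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorsnap)
```

## The model

A spectral phasor maps an emission spectrum $I(\lambda)$ over a detection
range $[\lambda_{\min}, \lambda_{\max}]$ to a point in the unit disk via
its first Fourier harmonic on the phase axis
$\theta(\lambda) = 2\pi(\lambda-\lambda_{\min})/(\lambda_{\max}-\lambda_{\min})$:

$$G = \frac{\sum_\lambda I(\lambda)\cos\theta(\lambda)}{\sum_\lambda I(\lambda)},
\qquad
S = \frac{\sum_\lambda I(\lambda)\sin\theta(\lambda)}{\sum_\lambda I(\lambda)}.$$

Phase $\varphi = \mathrm{atan2}(S, G)$ encodes the spectral center of
mass (mapped back to a *center wavelength*); modulation
$M = \sqrt{G^2+S^2}$ is 1 for a line spectrum and decreases with spectral
width, reaching 0 for a flat spectrum. Because the transform is linear in
intensity, the phasor of any mixture is the intensity-fraction-weighted
convex combination of the component phasors — the *rule of linear
addition* that every analysis in this package exploits. Two species span
a segment, three a triangle, four a quadrilateral; conversely a 2-D
phasor point determines at most three independent fractions (two
coordinates plus the sum-to-one constraint), which is why the package
offers pairwise and triangle solvers plus polygon gating, and
deliberately does **not** attempt simultaneous four-component unmixing.

The snapshot instrument realizes the transform in hardware: a *sine*
filter with transmission $T_s = o_s + m_s\sin\theta$, a *cosine* filter
with $T_c = o_c + m_c\cos\theta$ (ideally $o = m = 1/2$, one full period
across the detection range), and an open exposure. With camera offset
$b$,

$$G = \frac{(I_{\cos}-b)/(I_{\mathrm{total}}-b) - o_c}{m_c}, \qquad
S = \frac{(I_{\sin}-b)/(I_{\mathrm{total}}-b) - o_s}{m_s},$$

which for the ideal calibration reduces to the familiar
$2\left((I-b)/(I_{\mathrm{total}}-b) - 0.5\right)$ normalization mapping
the 0–1 transmission range onto the −1…1 range of the sinusoids. The
ideal sine filter reaches zero transmission at phase 270° and the cosine
filter at 180°; spectral information very close to those minima is
encoded with few photons, which is the motivation for supporting
calibrated filters with a raised transmission floor (below).

## Numerical conventions

* **Bin-center sampling.** A `wavelength_grid` places its $n$ samples at
  bin centers $\lambda_{\min} + (k-\tfrac12)\Delta$. Over the full
  period, $\sum_k \cos\theta_k = \sum_k \sin\theta_k = 0$ *exactly*, so a
  flat spectrum maps to the origin to machine precision and the mean
  transmission of an ideal filter equals its offset exactly. Both
  identities are tested.
* **First harmonic only.** Single-period filters exist in hardware;
  higher harmonics are out of scope.
* **Truncation without renormalization.** Emission mass outside the
  detection range is silently discarded, as the physical bandpass does.
  A red-edge emitter therefore shows a shifted center of mass and raised
  modulation — but truncation is linear, so the rule of linear addition
  survives unchanged, and mixture tests use truncated spectra on purpose.
* **No clamping of noisy phasors.** Under noise $(G,S)$ may leave
  $[-1,1]^2$; values are retained so voxel statistics stay unbiased.
  Only the display histogram clips (dropping and counting out-of-range
  points, so counts always conserve the number of binned voxels).
* **Histogram binning.** 256 uniform bins per axis on $[-1,1]$,
  left-closed right-open, last bin closed.
* **Display-only transforms.** Histogram jitter (uniform in
  $\pm h$, default $h = 0.02$, up to $0.08$ for weak signals), the
  display percentile cutoff (clip at the brightest 5 % of voxels), and
  pseudocolor renders never feed any quantitative output; selection and
  projection always use unjittered coordinates.
* **Degenerate inputs.** Segments shorter than $10^{-6}$, triangles with
  $|2\times\text{area}| \le 10^{-9}$, zero-area polygons, zero-total
  spectra, and non-positive fitted filter amplitudes are rejected with
  errors rather than propagated.
* **Ties.** Half-plane pair coloring assigns points exactly on the
  dividing line to half 1; polygon boundaries are inclusive (even-odd
  rule); a center wavelength exactly on a shared window boundary joins
  the upper (half-open) window.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Detection range | 400–700 | nm | visible range of one filter period |
| Grid samples | 300 | — | 1-nm bins; quadrature error far below analysis tolerances |
| Camera offset $b$ | 100 | a.u. | typical sCMOS baseline; subtracted before ratios |
| Intensity threshold | 50 | a.u. | inside the useful 25–100 a.u. range for removing unspecific background; per-sample tuning exposed |
| Jitter half-width | 0.02 | phasor units | standard display jitter; 0.08 for weak signals |
| Histogram bins | 256 | — | standard phasor-plot resolution |
| Display cutoff | 5 | % | clip at the brightest 5 % of voxels, display only |
| Ratio cap | 100 | — | $rr, dr = t/(1-t)$ diverge as $t \to 1$; the cap keeps maps displayable and is recorded in the map metadata |
| Photon budget | $10^4$ | photons/voxel/exposure | bright-voxel budget of the simulated acquisitions; a fixture choice, the raw a.u. scale of real data being instrument-specific |

Fractions everywhere are **intensity fractions** (the linear-combination
weights of the phasor), not molar fractions; converting would require
brightness ratios and is left to the caller.

## The simulator: what it emulates, what it does not

`scene_phantom` assigns each voxel a label, a fluorophore mixture, and a
photon budget; `render_triplet` integrates each mixture against the
filter transmissions to get expected photon counts, then applies Poisson
photon noise, gain, additive offset, Gaussian read noise, hot pixels
(planted independently per exposure — the three exposures are distinct
frames behind a filter wheel), and 16-bit integer quantization. One
seeded generator drives everything, so an entire simulation is
reproducible from a single integer. `render_spectral_stack` renders the
same scene through an $n$-channel spectral detector for dual-path
comparisons; noiseless channel sums equal the open channel exactly
because channel binning partitions the grid samples.

Emission spectra are Gaussians in wavelength parameterized by peak and
FWHM. This is deliberately generic: it gives controllable positions and
widths on the phasor plot and reproduces truncation behavior, but it does
not model vibronic shoulders, environment-dependent lineshapes, or
excitation cross-sections. The simulator also omits optics (PSF,
light-sheet shadowing, scattering), photobleaching, and registration
error between exposures (a filter wheel keeps the camera fixed, so
co-registration is assumed). Passing tests therefore demonstrate the
*analysis chain* — transform, calibration, preprocessing, fraction
estimation, selection — under realistic photon statistics; they do not
validate instrument-specific optical effects on real tissue.

Two phantom families drive the end-to-end tests: layered stacks
(homogeneous mixtures per z-layer, emulating stratified tissue such as
retinal cell layers) and linear gradients. The gradient phantom
normalizes component concentrations by each fluorophore's in-band
spectrum total, so the *programmed per-slice intensity fraction is
exact* even for truncated spectra — making parameter-recovery tests
sharp rather than approximate.

### Fixture dye choices

The six-dye comparison set uses peaks 505–605 nm with FWHM 32–36 nm.
These widths keep out-of-band spectral mass below $10^{-9}$ of the
total, so the analysis-grid quadrature agrees with a 10× fine-grid
oracle to better than $10^{-9}$ — the regime in which the noiseless
triplet path, the 32-channel computational path, and the reference
transform must coincide. The redox fixtures (peaks 460/535 nm, FWHM
80/70 nm) are intentionally broad and blue enough to be truncated at the
400 nm edge, exercising the truncation-linearity property along the
trajectory. The demonstration photon budget is $10^4$ expected photons
per bright voxel per exposure, giving per-voxel fraction noise of about
0.015 and per-slice (1024-voxel) standard errors well below 0.001; test
scenes are kept at $\le 5\times10^4$ voxels so the full suite runs in
seconds.

## Calibration of non-ideal filters

Manufactured filters cannot reach exactly zero transmission, and a
redesign with a 5–10 % floor trades a small loss of dynamic range for
better accuracy near the minima. `fit_calibration` least-squares fits
$o + m\sin\theta$ (or $\cos$) to a measured transmission curve;
transforming with the fitted $(o, m)$ instead of the ideal $(0.5, 0.5)$
removes the phasor bias entirely for in-family curves and to first order
otherwise. The acceptance suite verifies that a 10 %-floor filter biased
by $>0.01$ under the ideal calibration returns to within $5\times10^{-3}$
of truth with the fitted one.

## Preprocessing order

The 3×3 median filter (per z-plane, reflect padding) is applied to the
three *raw intensity stacks before* the phasor division: hot pixels
corrupt the ratio nonlinearly, so they must be removed pre-division.
Whether offset subtraction happens before or after the median is
immaterial — the median commutes with adding a constant — so the
implementation filters raw intensities and subtracts afterwards. The 2×2
binning *sums* rather than averages, preserving photon statistics; an
odd trailing row/column is dropped with a warning.

## Design choices that were genuinely open

* **Orthogonal projection for off-line voxels** (not nearest point in
  the disk): noise displaces points symmetrically perpendicular to a
  mixing line, so the orthogonal projection is the unbiased estimator of
  the position along it. Raw (unclamped) and clamped fractions are both
  kept so out-of-range mass can be audited.
* **Negative barycentric coordinates** are clamped to zero and the rest
  renormalized in the reported values, with the signed solution retained.
* **Polygon overlap precedence is explicit list order** — overlapping
  selections need a deterministic rule, and list order is the one the
  user controls.
* **16-bit integer recording in the camera model.** Real sCMOS data are
  digitized; quantizing in the simulator both matches practice and makes
  TIFF serialization exact. Noiseless renders skip quantization because
  they serve as analytic expectations for oracle-equivalence tests.
* **Floating-point maps in TIFF** are stored on a per-file affine scale
  recorded in a YAML sidecar (quantization ~$10^{-9}$ of the data
  range), since the underlying TIFF writer stores 32-bit samples as
  scaled integers. Validity masks travel alongside as 8/16-bit stacks.
* **CLI as a thin wrapper.** All orchestration lives in `phasor_cli()`;
  the installed script only forwards `commandArgs`. This keeps the
  pipeline testable in-process and the shell interface trivial.

## Known limitations

* Four simultaneous fractions are under-determined from a single 2-D
  phasor; use pairwise/triangle analyses within polygon gates instead.
* Spectra are first-harmonic summaries: distinct spectra can share a
  phasor point (metamers); window mapping labels by center wavelength
  only.
* The Gaussian emission model and the absence of optical effects mean
  simulator-based validation speaks to the analysis, not to a specific
  instrument's point-spread or scattering behavior.
* Image registration between the three exposures is assumed perfect;
  flat-field/vignetting correction is out of scope.
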