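# phasorsnap

Spectral phasor analysis for sine/cosine-filter hyperspectral snapshot
fluorescence microscopy.

## The problem

Conventional hyperspectral microscopy records a full emission spectrum per
pixel by spatial or spectral scanning, which is slow and light-inefficient —
prohibitive for live, three-dimensional tissue. The snapshot alternative
replaces the spectral detector with a pair of optical filters whose
transmission follows one raised **sine** and one raised **cosine** period
across the detection range (here 400–700 nm). Three camera exposures per
plane — through the sine filter, through the cosine filter, and without
filter — then encode each voxel's *spectral phasor* directly in hardware.

The spectral phasor of an emission spectrum I(λ) is its first-harmonic
projection on the phase axis θ(λ) = 2π·(λ − λ_min)/(λ_max − λ_min):

    G = Σ I(λ) cos θ(λ) / Σ I(λ)
    S = Σ I(λ) sin θ(λ) / Σ I(λ)

The angular coordinate (phase) encodes the spectral center of mass; the
radial coordinate (modulation) is inversely related to spectral width.
From the three exposures, with camera offset b:

    G(x,y,z) = 2 ( (I_cos − b)/(I_total − b) − 0.5 )
    S(x,y,z) = 2 ( (I_sin − b)/(I_total − b) − 0.5 )

Because the phasor is linear in intensity, a mixture of species lies at the
intensity-fraction-weighted combination of the pure-species positions (the
rule of linear addition). This enables fit-free analyses that need no a
priori spectra: two-component fractions along a mixing segment,
three-component barycentric fractions in a triangle, the NADH/FAD **optical
redox ratio** `rr = t/(1−t)` from the projection t along the NADH–FAD
trajectory, the **dipolar relaxation index** `dr` of solvatochromic probes,
polygon gating of the phasor plot with image↔phasor reciprocity, and
emission-window mapping.

The package implements all of this plus a forward simulator of the
acquisition (Gaussian emission models, Poisson photon noise, camera offset,
read noise, hot pixels, 16-bit quantization), the stated preprocessing
(3×3 per-plane median filter, 2×2 binning, intensity thresholds, display
jitter, display percentile cutoff), filter calibration for non-ideal
transmission floors, and TIFF/CSV/YAML I/O with a CLI pipeline.

## Worked example: axial metabolic gradient in a synthetic crypt

A gradient phantom programs the NADH-like intensity fraction to rise
linearly from 0.2 to 0.8 along z (a stem-to-differentiated metabolic
gradient). Rendering the filter triplet at 10⁴ photons/voxel with camera
noise, transforming to phasors, and projecting on the NADH–FAD trajectory
recovers the programmed ramp:

```r
library(phasorsnap)
grid  <- wavelength_grid(400, 700, 300)
nadh  <- fluorophore("NADH-like", 460, 80)
fad   <- fluorophore("FAD-like", 535, 70)
crypt <- make_gradient_phantom("z", t_start = 0.2, t_end = 0.8,
                               fluor_a = nadh, fluor_b = fad,
                               shape = c(16, 32, 32), grid = grid)
triplet <- render_triplet(crypt, camera = camera_model(seed = 11))
field   <- triplet_to_phasor(triplet, threshold = 50, median_filter = TRUE)
ep <- lapply(list(nadh, fad),
             function(f) spectrum_phasor(gaussian_spectrum(f, grid)))
rr   <- redox_ratio(field, ep[[1]], ep[[2]])
prof <- slice_profile(rr$fraction, "z")
head(round(prof, 4))
#>   slice   mean     sd    n
#> 1     1 0.1997 0.0059 1024
#> 2     2 0.2397 0.0057 1024
#> 3     3 0.2798 0.0062 1024
#> 4     4 0.3198 0.0065 1024
#> 5     5 0.3597 0.0066 1024
#> 6     6 0.3994 0.0069 1024
```

Each row is one xy plane: the mean projected NADH fraction t tracks the
programmed ramp (0.20, 0.24, 0.28, …) to within a few thousandths at this
photon budget; `rr$index` holds the capped ratio `t/(1−t)`. The pure
endpoints printed by `spectrum_phasor` are (0.2121, 0.7789) for the
NADH-like and (−0.7835, 0.2546) for the FAD-like emitter.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "phasorsnap.R", package = "phasorsnap"))')
Rscript $CLI simulate  --phantom gradient --seed 7 --out /tmp/run
Rscript $CLI transform --sin /tmp/run_sin.tif --cos /tmp/run_cos.tif \
                       --open /tmp/run_open.tif --median true --out /tmp/ph
Rscript $CLI profile   --map /tmp/ph_G.tif --axis z --out /tmp/profile.csv
```

## Layout

* `R/` — spectral model, acquisition simulator, phasor core, unmixing,
  selection, I/O, configuration, CLI.
* `tests/testthat/` — unit, property, and end-to-end pipeline tests with
  independent brute-force oracles.
* `vignettes/phasor-snapshot-methods.Rmd` — the methods notes: model,
  parameter choices, simulator scope, numerical conventions, limitations.
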