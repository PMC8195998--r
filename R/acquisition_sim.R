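# Forward model of the three-exposure snapshot acquisition (sine filter,
# cosine filter, open channel) on synthetic 3-D phantoms, with photon noise
# and camera artifacts.  Axis order is (z, y, x) throughout, matching
# plane-by-plane acquisition and multi-page TIFF layout.

#' Camera model for the acquisition simulator
#'
#' Describes the detector: additive electronic offset `b` (subtracted again
#' before ratio formation in the phasor transform), linear gain, Gaussian
#' read noise, and a rate of hot pixels planted independently per exposure
#' (the three exposures are distinct frames behind a filter wheel).
#' Recorded values are quantized to integers and clipped to the 16-bit
#' range, as a real sCMOS camera digitizes them.
#'
#' @param offset Camera offset `b` in a.u. (>= 0).
#' @param gain a.u. per detected photon (> 0).
#' @param read_noise_sd Read noise standard deviation in a.u. (>= 0).
#' @param hot_pixel_rate Probability per voxel per exposure of a hot pixel.
#' @param hot_pixel_value Recorded value of a hot pixel, a.u.
#' @param seed Integer seed; one seeded generator drives Poisson noise,
#'   read noise, and hot-pixel placement so a whole simulation is
#'   reproducible from this one number.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, gain = 1, read_noise_sd = 2,
                         hot_pixel_rate = 1e-4, hot_pixel_value = 4095,
                         seed = 1L) {
  stopifnot(is.numeric(offset), offset >= 0,
            is.numeric(gain), gain > 0,
            is.numeric(read_noise_sd), read_noise_sd >= 0,
            is.numeric(hot_pixel_rate),
            hot_pixel_rate >= 0, hot_pixel_rate < 1,
            is.numeric(hot_pixel_value), hot_pixel_value >= 0)
  structure(list(offset = offset, gain = gain,
                 read_noise_sd = read_noise_sd,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_value = hot_pixel_value,
                 seed = as.integer(seed)),
            class = "camera_model")
}

#' Synthetic 3-D scene phantom
#'
#' A voxel grid of integer labels, a composition table mapping each label to
#' a fluorophore mixture, and a per-voxel brightness (expected photons per
#' exposure through the open channel for a unit-intensity composition).
#' The phantom is the synthetic stand-in for tissue used throughout the
#' test-bench analyses.
#'
#' @param labels 3-D integer array, dim `(nz, ny, nx)`.
#' @param composition Named list: for each label value (as character), a
#'   list of components, each `list(fluor = <fluorophore>, concentration =)`.
#' @param grid A [wavelength_grid()].
#' @param brightness Scalar or 3-D array (same dim as `labels`) of
#'   nonnegative photon-budget multipliers.
#' @return An object of class `scene_phantom`.
#' @export
scene_phantom <- function(labels, composition, grid = wavelength_grid(),
                          brightness = 1e4) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            inherits(grid, "wavelength_grid"), is.list(composition))
  labels <- array(as.integer(labels), dim = dim(labels))
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(present), names(composition))
  if (length(missing))
    stop("labels without composition entry: ", paste(missing, collapse = ", "))
  if (is.array(brightness)) {
    stopifnot(identical(dim(brightness), dim(labels)))
  } else {
    stopifnot(is.numeric(brightness), length(brightness) == 1L)
    brightness <- array(brightness, dim = dim(labels))
  }
  if (any(brightness < 0)) stop("brightness must be >= 0")
  structure(list(labels = labels, composition = composition, grid = grid,
                 brightness = brightness, shape = dim(labels)),
            class = "scene_phantom")
}

#' Per-label mixed emission spectra of a phantom
#'
#' @param scene A [scene_phantom()].
#' @return Named list (by label) of [emission_spectrum()] objects; labels
#'   whose composition is empty (background) map to `NULL`.
#' @export
label_spectra <- function(scene) {
  stopifnot(inherits(scene, "scene_phantom"))
  out <- lapply(names(scene$composition), function(lab) {
    comp <- scene$composition[[lab]]
    if (length(comp) == 0L) return(NULL)
    specs <- lapply(comp, function(cc) gaussian_spectrum(cc$fluor, scene$grid))
    w <- vapply(comp, function(cc) cc$concentration, numeric(1))
    mix_spectra(specs, w)
  })
  names(out) <- names(scene$composition)
  out
}

#' Axial stack of homogeneous labeled layers
#'
#' Builds a phantom of stacked z-layers, each with its own fluorophore
#' mixture -- a simple emulation of a layered tissue (e.g. retinal cell
#' layers) for end-to-end tests of selection and unmixing.
#'
#' @param layers List of layers, each `list(thickness = <z voxels>,
#'   composition = list(list(fluor =, concentration =), ...))`.
#' @param ny,nx Lateral extent in voxels.
#' @param grid A [wavelength_grid()].
#' @param brightness Photon budget per voxel per exposure (open channel).
#' @return A [scene_phantom()]; layer `i` carries label `i`.
#' @export
make_layered_phantom <- function(layers, ny = 32L, nx = 32L,
                                 grid = wavelength_grid(),
                                 brightness = 1e4) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  thick <- vapply(layers, function(l) as.integer(l$thickness), integer(1))
  if (any(thick <= 0L)) stop("layer thickness must be >= 1 voxel")
  nz <- sum(thick)
  lab_z <- rep(seq_along(layers), times = thick)
  labels <- array(rep(lab_z, times = ny * nx), dim = c(nz, ny, nx))
  composition <- lapply(layers, `[[`, "composition")
  names(composition) <- as.character(seq_along(layers))
  scene_phantom(labels, composition, grid = grid, brightness = brightness)
}

#' Linear two-fluorophore gradient phantom
#'
#' Per-slice intensity fraction of fluorophore `fluor_a` varies linearly
#' from `t_start` to `t_end` along the chosen axis; the component
#' concentrations are normalized by each fluorophore's in-band spectrum
#' total so the *programmed intensity fraction is exact* even when a
#' spectrum is truncated by the detection range.  Emulates, e.g., an axial
#' metabolic gradient along an intestinal crypt.
#'
#' @param axis `"z"`, `"y"`, or `"x"`.
#' @param t_start,t_end Intensity fraction of `fluor_a` at the first/last
#'   slice, in `[0, 1]`.
#' @param fluor_a,fluor_b [fluorophore()] endpoints of the gradient.
#' @param shape `(nz, ny, nx)` voxel counts.
#' @param grid A [wavelength_grid()].
#' @param brightness Photon budget per voxel per exposure (open channel).
#' @return A [scene_phantom()] with attribute `fractions`, the programmed
#'   per-slice intensity fraction of `fluor_a`.
#' @export
make_gradient_phantom <- function(axis = c("z", "y", "x"),
                                  t_start = 0.2, t_end = 0.8,
                                  fluor_a, fluor_b,
                                  shape = c(16L, 32L, 32L),
                                  grid = wavelength_grid(),
                                  brightness = 1e4) {
  axis <- match.arg(axis)
  stopifnot(t_start >= 0, t_start <= 1, t_end >= 0, t_end <= 1,
            length(shape) == 3L)
  shape <- as.integer(shape)
  d <- switch(axis, z = 1L, y = 2L, x = 3L)
  n <- shape[d]
  t_slice <- if (n == 1L) (t_start + t_end) / 2 else
    seq(t_start, t_end, length.out = n)
  # unit-concentration in-band totals, used to program exact intensity fractions
  tot_a <- sum(gaussian_spectrum(fluor_a, grid)$intensity)
  tot_b <- sum(gaussian_spectrum(fluor_b, grid)$intensity)
  composition <- lapply(t_slice, function(t) {
    comp <- list()
    if (t > 0) comp <- c(comp, list(list(fluor = fluor_a,
                                         concentration = t / tot_a)))
    if (t < 1) comp <- c(comp, list(list(fluor = fluor_b,
                                         concentration = (1 - t) / tot_b)))
    comp
  })
  names(composition) <- as.character(seq_len(n))
  idx <- slice.index(array(0, dim = shape), d)
  labels <- array(idx, dim = shape)
  ph <- scene_phantom(labels, composition, grid = grid,
                      brightness = brightness)
  attr(ph, "fractions") <- t_slice
  attr(ph, "axis") <- axis
  ph
}

# Expected photons -> recorded a.u. for one exposure.  Must be called inside
# a seeded RNG context; consumes Poisson, Gaussian, and uniform draws in a
# fixed order so a whole render is reproducible from one seed.
.record_exposure <- function(N, camera) {
  n <- length(N)
  v <- camera$gain * stats::rpois(n, N) + camera$offset
  if (camera$read_noise_sd > 0)
    v <- v + stats::rnorm(n, 0, camera$read_noise_sd)
  if (camera$hot_pixel_rate > 0) {
    hot <- stats::runif(n) < camera$hot_pixel_rate
    v[hot] <- camera$hot_pixel_value
  }
  pmin(pmax(round(v), 0), 65535)
}

#' Render the three-exposure filter triplet of a phantom
#'
#' Forward model of snapshot acquisition: for each voxel the expected
#' photon count through each channel is `brightness * sum(X(lambda) *
#' T(lambda))`, with `T == 1` on the grid for the open channel (the fixed
#' detection bandpass) and `X` the voxel's mixed spectrum.  Noisy renders
#' apply Poisson photon noise, camera gain and offset, Gaussian read noise,
#' hot pixels (independently per exposure), and 16-bit quantization.
#' Noiseless renders return the analytic expectation `gain * N + b`
#' unquantized.
#'
#' @param scene A [scene_phantom()].
#' @param sine,cosine [filter_curve()]s on the scene grid; defaults are the
#'   ideal `o = m = 0.5` filters.
#' @param camera A [camera_model()].
#' @param noiseless Skip all noise and quantization.
#' @return An object of class `triplet_stack` with 3-D arrays `I_sin`,
#'   `I_cos`, `I_total`, plus `camera` and `grid` metadata.
#' @export
render_triplet <- function(scene, sine = NULL, cosine = NULL,
                           camera = camera_model(), noiseless = FALSE) {
  stopifnot(inherits(scene, "scene_phantom"),
            inherits(camera, "camera_model"))
  if (is.null(sine)) sine <- ideal_filter("sine", scene$grid)
  if (is.null(cosine)) cosine <- ideal_filter("cosine", scene$grid)
  stopifnot(inherits(sine, "filter_curve"), inherits(cosine, "filter_curve"))
  if (!grids_identical(sine$grid, scene$grid) ||
      !grids_identical(cosine$grid, scene$grid))
    stop("filters must share the scene's wavelength grid")
  specs <- label_spectra(scene)
  # per unit brightness: expected photons per channel for each label
  resp <- vapply(specs, function(sp) {
    if (is.null(sp)) return(c(sin = 0, cos = 0, open = 0))
    c(sin = sum(sp$intensity * sine$transmission),
      cos = sum(sp$intensity * cosine$transmission),
      open = sum(sp$intensity))
  }, numeric(3))
  li <- match(as.character(scene$labels), colnames(resp))
  dims <- scene$shape
  N_sin <- array(resp["sin", li], dims) * scene$brightness
  N_cos <- array(resp["cos", li], dims) * scene$brightness
  N_tot <- array(resp["open", li], dims) * scene$brightness
  if (noiseless) {
    I_sin <- camera$gain * N_sin + camera$offset
    I_cos <- camera$gain * N_cos + camera$offset
    I_tot <- camera$gain * N_tot + camera$offset
  } else {
    rec <- withr::with_seed(camera$seed, list(
      s = .record_exposure(N_sin, camera),
      c = .record_exposure(N_cos, camera),
      o = .record_exposure(N_tot, camera)))
    I_sin <- array(rec$s, dims)
    I_cos <- array(rec$c, dims)
    I_tot <- array(rec$o, dims)
  }
  structure(list(I_sin = I_sin, I_cos = I_cos, I_total = I_tot,
                 camera = camera, grid = scene$grid,
                 noiseless = noiseless),
            class = "triplet_stack")
}

#' Channel centers of an n-channel spectral binning of a grid
#'
#' @param grid A [wavelength_grid()].
#' @param n_channels Number of equal wavelength bins spanning the grid.
#' @return List with `lambda` (channel-center wavelengths, nm), `theta`
#'   (channel-center phases), and `assign` (channel index of each grid
#'   sample).
#' @export
channel_centers <- function(grid, n_channels) {
  stopifnot(inherits(grid, "wavelength_grid"))
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L) stop("`n_channels` must be >= 2")
  w <- (grid$lambda_max - grid$lambda_min) / n_channels
  lam <- grid$lambda_min + (seq_len(n_channels) - 0.5) * w
  a <- pmin(floor((wavelengths(grid) - grid$lambda_min) / w) + 1L, n_channels)
  list(lambda = lam, theta = wavelength_to_phase(grid, lam),
       assign = as.integer(a))
}

#' Render a conventional multichannel spectral stack of a phantom
#'
#' The comparison path: photons are integrated over `n_channels` equal
#' wavelength bins spanning the grid (a multichannel spectral detector),
#' with the same per-channel noise model as [render_triplet()].  Summing a
#' noiseless stack over channels reproduces the open-channel photon count
#' exactly (channel binning is a complete partition of the grid samples).
#'
#' @param scene A [scene_phantom()].
#' @param n_channels Number of spectral channels (>= 2), default 32.
#' @param camera A [camera_model()].
#' @param noiseless Skip noise and quantization.
#' @return An object of class `spectral_stack`: 4-D array `data` with dim
#'   `(nz, ny, nx, n_channels)` plus `grid`, `n_channels`, `camera`.
#' @export
render_spectral_stack <- function(scene, n_channels = 32L,
                                  camera = camera_model(),
                                  noiseless = FALSE) {
  stopifnot(inherits(scene, "scene_phantom"),
            inherits(camera, "camera_model"))
  ch <- channel_centers(scene$grid, n_channels)
  nch <- as.integer(n_channels)
  specs <- label_spectra(scene)
  resp <- vapply(specs, function(sp) {
    out <- numeric(nch)
    if (is.null(sp)) return(out)
    rs <- rowsum(sp$intensity, ch$assign)
    out[as.integer(rownames(rs))] <- rs[, 1L]
    out
  }, numeric(nch))
  li <- match(as.character(scene$labels), colnames(resp))
  dims <- c(scene$shape, nch)
  nvox <- prod(scene$shape)
  N <- matrix(0, nvox, nch)
  for (k in seq_len(nch))
    N[, k] <- resp[k, li] * as.vector(scene$brightness)
  if (noiseless) {
    dat <- camera$gain * N + camera$offset
  } else {
    dat <- withr::with_seed(camera$seed, {
      out <- matrix(0, nvox, nch)
      for (k in seq_len(nch)) out[, k] <- .record_exposure(N[, k], camera)
      out
    })
  }
  structure(list(data = array(dat, dims), grid = scene$grid,
                 n_channels = nch, channel_lambda = ch$lambda,
                 channel_theta = ch$theta,
                 camera = camera, noiseless = noiseless),
            class = "spectral_stack")
}
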