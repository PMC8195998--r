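# Wavelength grids, emission spectra, filter transmission curves, and the
# reference (spectral-DFT) phasor transform.

#' Uniform wavelength sampling of the detection range
#'
#' A `wavelength_grid` divides the detection range `[lambda_min, lambda_max]`
#' into `n_samples` equal bins and places the sample points at the bin
#' *centers*.  The grid also defines the phasor phase axis: one full period
#' of the sine/cosine transform is mapped onto the detection range, so
#' `theta(lambda) = 2*pi*(lambda - lambda_min)/(lambda_max - lambda_min)`.
#'
#' Bin-center sampling makes the full-period sums `sum(cos(theta))` and
#' `sum(sin(theta))` vanish exactly, so a spectrally flat signal maps to the
#' phasor origin without discretization bias.
#'
#' @param lambda_min,lambda_max Detection range in nm. Default 400-700 nm,
#'   the visible range covered by a single sine/cosine filter period.
#' @param n_samples Number of uniformly spaced samples (>= 2). The default
#'   300 gives 1-nm bins on the default range.
#' @return An object of class `wavelength_grid`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' head(wavelengths(g))
wavelength_grid <- function(lambda_min = 400, lambda_max = 700,
                            n_samples = 300L) {
  stopifnot(is.numeric(lambda_min), is.numeric(lambda_max),
            length(lambda_min) == 1L, length(lambda_max) == 1L,
            is.finite(lambda_min), is.finite(lambda_max))
  if (!(lambda_min < lambda_max))
    stop("`lambda_min` must be strictly less than `lambda_max`")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be an integer >= 2")
  structure(
    list(lambda_min = as.numeric(lambda_min),
         lambda_max = as.numeric(lambda_max),
         n_samples = n_samples,
         delta = (lambda_max - lambda_min) / n_samples),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, %d samples (%.3g nm bins)\n",
              x$lambda_min, x$lambda_max, x$n_samples, x$delta))
  invisible(x)
}

#' Bin-center wavelengths of a grid
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of length `n_samples` (nm).
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$lambda_min + (seq_len(grid$n_samples) - 0.5) * grid$delta
}

#' Phase axis of a grid
#'
#' Maps each bin-center wavelength to its phase on the single-period axis,
#' `theta = 2*pi*(lambda - lambda_min)/(lambda_max - lambda_min)`.
#'
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of phases in radians, all in `[0, 2*pi)`.
#' @export
phase_axis <- function(grid) {
  wavelength_to_phase(grid, wavelengths(grid))
}

#' Convert between wavelength and phase on a grid's phase axis
#'
#' @param grid A [wavelength_grid()].
#' @param lambda Wavelengths in nm.
#' @param phase Phases in radians.
#' @return `wavelength_to_phase()` returns phases in radians;
#'   `phase_to_wavelength()` returns wavelengths in nm.
#' @export
wavelength_to_phase <- function(grid, lambda) {
  stopifnot(inherits(grid, "wavelength_grid"))
  2 * pi * (lambda - grid$lambda_min) / (grid$lambda_max - grid$lambda_min)
}

#' @rdname wavelength_to_phase
#' @export
phase_to_wavelength <- function(grid, phase) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$lambda_min + phase / (2 * pi) * (grid$lambda_max - grid$lambda_min)
}

grids_identical <- function(a, b) {
  inherits(a, "wavelength_grid") && inherits(b, "wavelength_grid") &&
    isTRUE(all.equal(a$lambda_min, b$lambda_min)) &&
    isTRUE(all.equal(a$lambda_max, b$lambda_max)) &&
    a$n_samples == b$n_samples
}

#' Fluorophore descriptor
#'
#' A minimal emitter model: Gaussian emission in wavelength with a given
#' peak and full width at half maximum, and a relative brightness (photons
#' per unit concentration).  This is the fixture emission model used by the
#' acquisition simulator; it is deliberately generic rather than a fit to
#' any measured dye spectrum.
#'
#' @param name Label.
#' @param peak Emission peak in nm.
#' @param fwhm Full width at half maximum in nm (> 0).
#' @param brightness Relative photons per unit concentration (>= 0).
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, peak, fwhm, brightness = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(peak), length(peak) == 1L, is.finite(peak),
            is.numeric(fwhm), length(fwhm) == 1L, is.finite(fwhm),
            is.numeric(brightness), length(brightness) == 1L)
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  if (brightness < 0) stop("`brightness` must be >= 0")
  structure(list(name = name, peak = peak, fwhm = fwhm,
                 brightness = brightness),
            class = "fluorophore")
}

#' Emission spectrum tabulated on a wavelength grid
#'
#' @param grid A [wavelength_grid()].
#' @param intensity Nonnegative finite intensity per bin (relative photons).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(grid, intensity) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(intensity))
  if (length(intensity) != grid$n_samples)
    stop("`intensity` must have one value per grid sample")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  structure(list(grid = grid, intensity = as.numeric(intensity)),
            class = "emission_spectrum")
}

#' Gaussian emission spectrum of a fluorophore
#'
#' Evaluates a Gaussian (in wavelength) with the fluorophore's peak and
#' FWHM at the grid bin centers, scaled so that the untruncated total equals
#' the fluorophore brightness.  Mass falling outside the grid range is
#' silently discarded without renormalization -- this reproduces the fixed
#' detection bandpass of the instrument: a spectrum whose tail extends past
#' the detection range loses that tail, which shifts its spectral center of
#' mass and raises its apparent modulation.
#'
#' @param fluor A [fluorophore()].
#' @param grid A [wavelength_grid()].
#' @return An [emission_spectrum()].
#' @export
gaussian_spectrum <- function(fluor, grid) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(grid, "wavelength_grid"))
  sigma <- fluor$fwhm / (2 * sqrt(2 * log(2)))
  intensity <- fluor$brightness *
    stats::dnorm(wavelengths(grid), mean = fluor$peak, sd = sigma) * grid$delta
  if (sum(intensity) <= 0)
    stop(sprintf("emission of '%s' (peak %g nm) lies entirely outside %g-%g nm",
                 fluor$name, fluor$peak, grid$lambda_min, grid$lambda_max))
  emission_spectrum(grid, intensity)
}

#' Mix emission spectra by nonnegative weights
#'
#' Pointwise weighted sum of spectra sharing one grid.  Because the phasor
#' transform is linear in intensity, the phasor of the mixture is the
#' intensity-fraction-weighted combination of the component phasors (the
#' rule of linear addition).
#'
#' @param spectra List of [emission_spectrum()] objects on one grid.
#' @param weights Nonnegative weights, at least one positive.
#' @return An [emission_spectrum()].
#' @export
mix_spectra <- function(spectra, weights) {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            is.numeric(weights), length(weights) == length(spectra))
  if (any(weights < 0) || !any(weights > 0))
    stop("weights must be >= 0 with at least one positive")
  grid <- spectra[[1L]]$grid
  for (s in spectra) {
    stopifnot(inherits(s, "emission_spectrum"))
    if (!grids_identical(s$grid, grid))
      stop("all spectra must share one wavelength grid")
  }
  intensity <- Reduce(`+`, Map(function(s, w) w * s$intensity,
                               spectra, as.list(weights)))
  emission_spectrum(grid, intensity)
}

#' Spectral phasor of an emission spectrum
#'
#' First-harmonic projection of the spectrum onto the phase axis:
#' `G = sum(I * cos(theta)) / sum(I)` and `S = sum(I * sin(theta)) / sum(I)`.
#' For any nonnegative spectrum the result lies in the closed unit disk;
#' only a single-bin (line) spectrum reaches the circle.
#'
#' @param spec An [emission_spectrum()] with positive total intensity.
#' @return A [phasor_point()].
#' @export
spectrum_phasor <- function(spec) {
  stopifnot(inherits(spec, "emission_spectrum"))
  tot <- sum(spec$intensity)
  if (tot <= 0) stop("phasor undefined: total intensity is zero")
  theta <- phase_axis(spec$grid)
  phasor_point(sum(spec$intensity * cos(theta)) / tot,
               sum(spec$intensity * sin(theta)) / tot)
}

#' Phasor point
#'
#' A single `(G, S)` coordinate pair, stored as a named numeric vector so
#' that points support ordinary vector arithmetic (convex combinations,
#' differences).
#'
#' @param G,S Dimensionless phasor coordinates.
#' @return Named numeric vector `c(G =, S =)`.
#' @export
phasor_point <- function(G, S) {
  stopifnot(is.numeric(G), is.numeric(S), length(G) == 1L, length(S) == 1L,
            is.finite(G), is.finite(S))
  c(G = as.numeric(G), S = as.numeric(S))
}

#' Phase, modulation, and spectral center of mass of a phasor point
#'
#' The angular coordinate (phase) encodes the spectral center of mass of
#' the emission; the radial coordinate (modulation) is inversely related to
#' the spectral width (1 for a line spectrum, 0 for a flat one).  When a
#' grid is supplied the phase is mapped back to a center wavelength.
#'
#' @param p A [phasor_point()] or numeric `c(G, S)`.
#' @param grid Optional [wavelength_grid()] used to report the center
#'   wavelength.
#' @return List with `phase` (radians in `[0, 2*pi)`, `NA` at the origin),
#'   `modulation`, and `center_wavelength` (nm, `NA` if no grid or origin).
#' @export
phase_modulation <- function(p, grid = NULL) {
  stopifnot(is.numeric(p), length(p) == 2L)
  G <- p[[1L]]; S <- p[[2L]]
  modulation <- sqrt(G^2 + S^2)
  if (modulation == 0) {
    return(list(phase = NA_real_, modulation = 0,
                center_wavelength = NA_real_))
  }
  phase <- atan2(S, G) %% (2 * pi)
  cw <- if (is.null(grid)) NA_real_ else phase_to_wavelength(grid, phase)
  list(phase = phase, modulation = modulation, center_wavelength = cw)
}

#' Ideal sine/cosine filter transmission curve
#'
#' Constructs the raised-sinusoid transmission `o + m*sin(theta)` (sine) or
#' `o + m*cos(theta)` (cosine) over one period of the grid's phase axis.
#' With the default `o = m = 0.5` the sine filter reaches zero transmission
#' at phase 270 degrees and the cosine filter at 180 degrees, and recorded
#' intensity ratios encode the phasor coordinates directly.
#'
#' @param kind `"sine"` or `"cosine"`.
#' @param grid A [wavelength_grid()].
#' @param offset,amplitude Sinusoid offset `o` and amplitude `m`;
#'   feasibility requires `o - m >= 0` and `o + m <= 1` (transmission is a
#'   physical fraction).
#' @return An object of class `filter_curve` carrying the sampled
#'   transmission and the analytic descriptor.
#' @export
ideal_filter <- function(kind = c("sine", "cosine"), grid = wavelength_grid(),
                         offset = 0.5, amplitude = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(offset), is.numeric(amplitude),
            length(offset) == 1L, length(amplitude) == 1L)
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  if (offset - amplitude < -1e-12 || offset + amplitude > 1 + 1e-12)
    stop("infeasible filter: need 0 <= offset - amplitude and offset + amplitude <= 1")
  theta <- phase_axis(grid)
  trans <- offset + amplitude * if (kind == "sine") sin(theta) else cos(theta)
  trans <- pmin(pmax(trans, 0), 1)  # guard tiny round-off at the extremes
  filter_curve(grid, trans, kind = kind, offset = offset, amplitude = amplitude)
}

#' Filter transmission curve on a wavelength grid
#'
#' @param grid A [wavelength_grid()].
#' @param transmission Transmission fraction in `[0, 1]` per sample.
#' @param kind Optional `"sine"`/`"cosine"` tag.
#' @param offset,amplitude Optional analytic sinusoid descriptor; when both
#'   are given the curve is flagged analytic and downstream code may use the
#'   closed form.
#' @return An object of class `filter_curve`.
#' @export
filter_curve <- function(grid, transmission, kind = NULL,
                         offset = NULL, amplitude = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(transmission))
  if (length(transmission) != grid$n_samples)
    stop("`transmission` must have one value per grid sample")
  if (any(!is.finite(transmission)) ||
      any(transmission < -1e-9) || any(transmission > 1 + 1e-9))
    stop("transmission values must lie in [0, 1]")
  structure(
    list(grid = grid, transmission = pmin(pmax(transmission, 0), 1),
         kind = kind, offset = offset, amplitude = amplitude,
         analytic = !is.null(offset) && !is.null(amplitude)),
    class = "filter_curve")
}

#' Phase of minimum transmission of a filter curve
#'
#' Locates the phase at which the transmission is minimal.  The minimum is
#' bracketed by a grid search over the tabulated curve (or a fine evaluation
#' of the analytic form) and refined by golden-section search, so the result
#' is continuous rather than quantized to the sample spacing.
#'
#' @param filt A [filter_curve()].
#' @param degrees Report the phase in degrees instead of radians.
#' @return Phase of minimum transmission.
#' @export
filter_minimum_phase <- function(filt, degrees = FALSE) {
  stopifnot(inherits(filt, "filter_curve"))
  if (filt$analytic) {
    f <- if (identical(filt$kind, "cosine")) {
      function(th) filt$offset + filt$amplitude * cos(th)
    } else {
      function(th) filt$offset + filt$amplitude * sin(th)
    }
    th_grid <- seq(0, 2 * pi, length.out = 4097L)
  } else {
    th_tab <- phase_axis(filt$grid)
    f <- stats::splinefun(th_tab, filt$transmission, method = "fmm")
    th_grid <- seq(min(th_tab), max(th_tab), length.out = 4097L)
  }
  i <- which.min(f(th_grid))
  lo <- th_grid[max(i - 1L, 1L)]
  hi <- th_grid[min(i + 1L, length(th_grid))]
  th <- stats::optimize(f, lower = lo, upper = hi, tol = 1e-12)$minimum
  if (degrees) th * 180 / pi else th
}
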