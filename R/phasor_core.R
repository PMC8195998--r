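# The in-hardware phasor transform with generalized filter calibration,
# image preprocessing (median filter, 2x2 binning), and phasor histograms.

#' Filter calibration (sinusoid offsets/amplitudes of both filters)
#'
#' The default `o = m = 0.5` for both filters corresponds to ideal filters
#' whose transmission spans the full 0-1 range; with it the transform
#' reduces exactly to `G = 2((I_cos - b)/(I_total - b) - 0.5)` and
#' `S = 2((I_sin - b)/(I_total - b) - 0.5)`.  Manufactured filters with a
#' nonzero transmission floor (e.g. a 5-10 percent minimum) are handled by
#' supplying their fitted offset/amplitude instead; see [fit_calibration()].
#'
#' @param o_s,m_s Sine-filter offset and amplitude.
#' @param o_c,m_c Cosine-filter offset and amplitude.
#' @return An object of class `filter_calibration`.
#' @export
filter_calibration <- function(o_s = 0.5, m_s = 0.5, o_c = 0.5, m_c = 0.5) {
  stopifnot(is.numeric(o_s), is.numeric(m_s), is.numeric(o_c), is.numeric(m_c))
  if (m_s <= 0 || m_c <= 0) stop("calibration amplitudes must be > 0")
  structure(list(o_s = o_s, m_s = m_s, o_c = o_c, m_c = m_c),
            class = "filter_calibration")
}

#' Per-voxel phasor field
#'
#' `G` and `S` carry defined values only where `valid` is `TRUE`; invalid
#' voxels (total signal at or below the intensity threshold) carry `NA`.
#' Values outside `[-1, 1]`, possible under noise, are retained unclamped so
#' downstream statistics stay unbiased; only the display histogram clips.
#'
#' @param G,S 3-D numeric arrays of phasor coordinates (`NA` where invalid).
#' @param valid 3-D logical array.
#' @param threshold Intensity threshold (a.u.) used to build the mask.
#' @param offset Camera offset `b` (a.u.) that was subtracted.
#' @param grid Optional [wavelength_grid()] the phase axis refers to.
#' @param calibration Optional [filter_calibration()] used.
#' @return An object of class `phasor_field`.
#' @export
phasor_field <- function(G, S, valid, threshold = NA_real_,
                         offset = NA_real_, grid = NULL,
                         calibration = NULL) {
  stopifnot(is.array(G), is.array(S), is.array(valid),
            identical(dim(G), dim(S)), identical(dim(G), dim(valid)),
            length(dim(G)) == 3L)
  structure(list(G = G, S = S, valid = valid, threshold = threshold,
                 offset = offset, shape = dim(G), grid = grid,
                 calibration = calibration),
            class = "phasor_field")
}

#' Transform a filter triplet to a phasor field
#'
#' The snapshot transform: per voxel,
#' `G = ((I_cos - b)/(I_total - b) - o_c)/m_c` and
#' `S = ((I_sin - b)/(I_total - b) - o_s)/m_s`,
#' which with the default calibration is the standard normalization
#' mapping the 0-1 transmission range onto the -1..1 range of the
#' sine/cosine functions.  Voxels with `I_total - b <= threshold` are
#' masked invalid (the threshold also guards the division).
#'
#' @param t A `triplet_stack` (see [render_triplet()]) or a list with 3-D
#'   arrays `I_sin`, `I_cos`, `I_total`.
#' @param b Camera offset in a.u.; defaults to the triplet's camera
#'   metadata when present, else 0.
#' @param threshold Intensity threshold in a.u. applied to `I_total - b`.
#'   The default 50 sits inside the 25-100 a.u. range appropriate for
#'   removing unspecific background; tune per sample.
#' @param cal A [filter_calibration()].
#' @param median_filter Apply the 3x3 per-plane median filter
#'   ([median3()]) to the three raw intensity stacks before the ratio.
#'   Hot pixels corrupt the ratio nonlinearly, so they must be removed
#'   before the division, not after.
#' @return A [phasor_field()].
#' @export
triplet_to_phasor <- function(t, b = NULL, threshold = 50,
                              cal = filter_calibration(),
                              median_filter = FALSE) {
  stopifnot(is.list(t), is.numeric(threshold), threshold >= 0,
            inherits(cal, "filter_calibration"))
  if (is.null(b)) b <- if (!is.null(t$camera)) t$camera$offset else 0
  stopifnot(is.numeric(b), b >= 0)
  I_sin <- t$I_sin; I_cos <- t$I_cos; I_tot <- t$I_total
  if (!identical(dim(I_sin), dim(I_cos)) ||
      !identical(dim(I_sin), dim(I_tot)))
    stop("triplet stacks must share one shape")
  if (median_filter) {
    I_sin <- median3(I_sin); I_cos <- median3(I_cos); I_tot <- median3(I_tot)
  }
  denom <- I_tot - b
  valid <- denom > threshold
  G <- S <- array(NA_real_, dim = dim(I_tot))
  G[valid] <- ((I_cos[valid] - b) / denom[valid] - cal$o_c) / cal$m_c
  S[valid] <- ((I_sin[valid] - b) / denom[valid] - cal$o_s) / cal$m_s
  phasor_field(G, S, valid, threshold = threshold, offset = b,
               grid = t$grid, calibration = cal)
}

#' Transform a multichannel spectral stack to a phasor field
#'
#' The computational comparison path: per voxel the offset-subtracted
#' channel values are treated as a sampled spectrum and projected onto the
#' first harmonic with phases at the channel centers.
#'
#' @param stack A `spectral_stack` (see [render_spectral_stack()]) or a
#'   4-D array with the channel as the fourth dimension (then `grid` must
#'   be given).
#' @param grid [wavelength_grid()] (taken from the stack when present).
#' @param b Camera offset per channel image, a.u.
#' @param threshold Threshold on the summed offset-subtracted signal.
#' @return A [phasor_field()].
#' @export
spectral_stack_to_phasor <- function(stack, grid = NULL, b = NULL,
                                     threshold = 50) {
  if (inherits(stack, "spectral_stack")) {
    dat <- stack$data
    grid <- stack$grid
    theta <- stack$channel_theta
    if (is.null(b)) b <- stack$camera$offset
  } else {
    stopifnot(is.array(stack), length(dim(stack)) == 4L,
              inherits(grid, "wavelength_grid"))
    dat <- stack
    theta <- channel_centers(grid, dim(dat)[4L])$theta
    if (is.null(b)) b <- 0
  }
  nch <- dim(dat)[4L]
  if (nch < 2L) stop("need at least 2 spectral channels")
  dims <- dim(dat)[1:3]
  m <- matrix(dat, prod(dims), nch) - b
  tot <- rowSums(m)
  valid <- tot > threshold
  G <- S <- rep(NA_real_, length(tot))
  G[valid] <- (m[valid, , drop = FALSE] %*% cos(theta)) / tot[valid]
  S[valid] <- (m[valid, , drop = FALSE] %*% sin(theta)) / tot[valid]
  phasor_field(array(G, dims), array(S, dims), array(valid, dims),
               threshold = threshold, offset = b, grid = grid)
}

#' 3x3 per-plane median filter
#'
#' Removes salt-and-pepper noise from hot/cold camera pixels.  The median
#' is taken over the 3x3 neighborhood within each z-plane independently
#' (acquisition is plane-by-plane), with reflect padding at the borders.
#'
#' @param stack 3-D array `(nz, ny, nx)` (a single plane may be passed as
#'   a matrix).
#' @return Filtered array of the same shape.
#' @export
median3 <- function(stack) {
  mat_in <- is.matrix(stack)
  if (mat_in) stack <- array(stack, dim = c(1L, dim(stack)))
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  d <- dim(stack)
  ny <- d[2L]; nx <- d[3L]
  iy <- c(1L, seq_len(ny), ny)   # reflect: duplicate edge row/col
  ix <- c(1L, seq_len(nx), nx)
  out <- stack
  for (z in seq_len(d[1L])) {
    p <- matrix(stack[z, , ], ny, nx)[iy, ix]
    nb <- cbind(
      as.vector(p[1:ny, 1:nx]),       as.vector(p[1:ny, 2:(nx + 1)]),
      as.vector(p[1:ny, 3:(nx + 2)]), as.vector(p[2:(ny + 1), 1:nx]),
      as.vector(p[2:(ny + 1), 2:(nx + 1)]),
      as.vector(p[2:(ny + 1), 3:(nx + 2)]),
      as.vector(p[3:(ny + 2), 1:nx]), as.vector(p[3:(ny + 2), 2:(nx + 1)]),
      as.vector(p[3:(ny + 2), 3:(nx + 2)]))
    # median of 9 = 5th order statistic, row-wise
    med <- apply(nb, 1L, function(r) sort.int(r, partial = 5L)[5L])
    out[z, , ] <- matrix(med, ny, nx)
  }
  if (mat_in) matrix(out[1L, , ], ny, nx) else out
}

#' 2x2 lateral binning
#'
#' Sums 2x2 blocks in y/x within each plane (summing, not averaging,
#' preserves photon statistics).  An odd trailing row/column is dropped
#' with a warning.
#'
#' @param stack 3-D array `(nz, ny, nx)`.
#' @return Array with halved y/x extents.
#' @export
bin2 <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  d <- dim(stack)
  ny2 <- d[2L] %/% 2L; nx2 <- d[3L] %/% 2L
  if (ny2 < 1L || nx2 < 1L) stop("stack too small to bin 2x2")
  if (d[2L] %% 2L || d[3L] %% 2L)
    warning("odd trailing row/column dropped in 2x2 binning")
  s <- stack[, seq_len(2L * ny2), seq_len(2L * nx2), drop = FALSE]
  s[, seq(1L, 2L * ny2, 2L), seq(1L, 2L * nx2, 2L), drop = FALSE] +
    s[, seq(2L, 2L * ny2, 2L), seq(1L, 2L * nx2, 2L), drop = FALSE] +
    s[, seq(1L, 2L * ny2, 2L), seq(2L, 2L * nx2, 2L), drop = FALSE] +
    s[, seq(2L, 2L * ny2, 2L), seq(2L, 2L * nx2, 2L), drop = FALSE]
}

#' 2-D phasor histogram for display
#'
#' Bins the valid voxels of a phasor field on a `bins x bins` grid over
#' `[-1, 1]^2` (left-closed right-open bins, last bin closed).  A small
#' uniform jitter is added to each coordinate before binning purely to
#' avoid binning artifacts in the display; jittered coordinates are never
#' used for any quantitative analysis.  Jittered points that leave
#' `[-1, 1]^2` are dropped from the counts but tallied, so
#' `sum(counts) + n_out_of_range` always equals the number of binned
#' voxels.
#'
#' @param f A [phasor_field()].
#' @param jitter_halfwidth Half-width `h` of the `Uniform(-h, h)` display
#'   jitter. Use 0.02 normally; weak signals may need up to 0.08.
#' @param seed Integer seed for the jitter.
#' @param mask Optional logical array restricting which voxels contribute
#'   (combined with the validity mask).
#' @param bins Number of bins per axis (default 256).
#' @return An object of class `phasor_histogram`: integer `counts` matrix
#'   (rows index G, columns S), `jitter_halfwidth`, `seed`,
#'   `n_out_of_range`, `n_valid`, `bins`.
#' @export
phasor_histogram <- function(f, jitter_halfwidth = 0.02, seed = 1L,
                             mask = NULL, bins = 256L) {
  stopifnot(inherits(f, "phasor_field"), jitter_halfwidth >= 0)
  bins <- as.integer(bins)
  keep <- f$valid
  if (!is.null(mask)) {
    stopifnot(is.array(mask), identical(dim(mask), f$shape))
    keep <- keep & mask
  }
  g <- f$G[keep]; s <- f$S[keep]
  n <- length(g)
  if (n > 0 && jitter_halfwidth > 0) {
    j <- withr::with_seed(as.integer(seed),
                          stats::runif(2L * n, -jitter_halfwidth,
                                       jitter_halfwidth))
    g <- g + j[seq_len(n)]
    s <- s + j[n + seq_len(n)]
  }
  inr <- g >= -1 & g <= 1 & s >= -1 & s <= 1
  ig <- pmin(floor((g[inr] + 1) / 2 * bins) + 1L, bins)
  is_ <- pmin(floor((s[inr] + 1) / 2 * bins) + 1L, bins)
  counts <- matrix(tabulate((is_ - 1L) * bins + ig, nbins = bins * bins),
                   bins, bins)
  structure(list(counts = counts, bins = bins,
                 jitter_halfwidth = jitter_halfwidth,
                 seed = as.integer(seed),
                 n_out_of_range = sum(!inr), n_valid = n),
            class = "phasor_histogram")
}

#' Fit the sinusoid calibration of a measured filter curve
#'
#' Least-squares fit of `o + m*sin(theta)` (or `cos`) to a measured
#' transmission curve.  Used to calibrate manufactured filters whose
#' transmission does not span the full 0-1 range (e.g. a redesign with a
#' 5-10 percent minimum-transmission floor): transforming with the fitted
#' offset/amplitude removes the phasor bias the ideal default calibration
#' would exhibit.
#'
#' @param measured A [filter_curve()].
#' @param kind `"sine"` or `"cosine"`; defaults to the curve's own tag.
#' @return List with `offset`, `amplitude`, `residual_norm`, `kind`.
#' @export
fit_calibration <- function(measured, kind = NULL) {
  stopifnot(inherits(measured, "filter_curve"))
  if (is.null(kind)) kind <- measured$kind
  if (is.null(kind)) stop("`kind` must be given for an untagged curve")
  kind <- match.arg(kind, c("sine", "cosine"))
  theta <- phase_axis(measured$grid)
  x <- if (kind == "sine") sin(theta) else cos(theta)
  fit <- stats::lm(measured$transmission ~ x)
  o <- unname(stats::coef(fit)[1L])
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m <= 0)
    stop("calibration failure: fitted amplitude is not positive")
  list(offset = o, amplitude = m,
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       kind = kind)
}

#' Build a full calibration from measured sine and cosine curves
#'
#' @param sine,cosine Measured [filter_curve()]s.
#' @return A [filter_calibration()].
#' @export
calibration_from_curves <- function(sine, cosine) {
  fs <- fit_calibration(sine, "sine")
  fc <- fit_calibration(cosine, "cosine")
  filter_calibration(o_s = fs$offset, m_s = fs$amplitude,
                     o_c = fc$offset, m_c = fc$amplitude)
}
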