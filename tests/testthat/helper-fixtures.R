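# Shared fixtures and independent brute-force oracles.  Oracles are kept
# deliberately naive (explicit loops, different algorithms) so they stay
# independent of the vectorized implementations they check.

default_grid <- function() wavelength_grid(400, 700, 300L)

# six synthetic dyes with negligible out-of-band mass (tails < 1e-9 of the
# total), so grid quadrature agrees with a 10x fine-grid oracle to < 1e-9
six_dyes <- function() {
  peaks <- c(505, 525, 545, 565, 585, 605)
  fwhms <- c(32, 34, 36, 36, 34, 36)
  Map(function(p, w, i) fluorophore(paste0("dye", i), p, w),
      peaks, fwhms, seq_along(peaks))
}

# phasor by quadrature at 10x grid resolution (independent of the
# analysis-grid path)
fine_phasor <- function(fluor, grid, factor = 10L) {
  gf <- wavelength_grid(grid$lambda_min, grid$lambda_max,
                        grid$n_samples * factor)
  spectrum_phasor(gaussian_spectrum(fluor, gf))
}

# single-label uniform scene of one mixture
uniform_scene <- function(composition, shape = c(2L, 4L, 4L),
                          grid = default_grid(), brightness = 1e4) {
  scene_phantom(array(1L, shape), list("1" = composition),
                grid = grid, brightness = brightness)
}

# phasor field holding given points, one voxel each
field_from_points <- function(G, S, grid = NULL) {
  n <- length(G)
  phasor_field(array(G, c(1L, n, 1L)), array(S, c(1L, n, 1L)),
               array(TRUE, c(1L, n, 1L)), grid = grid)
}

# concentrations programming exact intensity fractions w on the grid
programmed_composition <- function(fluors, w, grid = default_grid()) {
  Map(function(fl, wi) {
    tot <- sum(gaussian_spectrum(fl, grid)$intensity)
    list(fluor = fl, concentration = wi / tot)
  }, fluors, w)
}

oracle_median3_plane <- function(p) {
  ny <- nrow(p); nx <- ncol(p)
  out <- p
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    vals <- numeric(9L); k <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      yy <- min(max(y + dy, 1L), ny)  # reflect pad = clamp at width 1
      xx <- min(max(x + dx, 1L), nx)
      k <- k + 1L
      vals[k] <- p[yy, xx]
    }
    out[y, x] <- sort(vals)[5L]
  }
  out
}

oracle_bin2 <- function(stack) {
  d <- dim(stack)
  ny2 <- d[2L] %/% 2L; nx2 <- d[3L] %/% 2L
  out <- array(0, c(d[1L], ny2, nx2))
  for (z in seq_len(d[1L])) for (y in seq_len(ny2)) for (x in seq_len(nx2))
    out[z, y, x] <- sum(stack[z, (2 * y - 1):(2 * y), (2 * x - 1):(2 * x)])
  out
}

# winding-number point-in-polygon (different algorithm from the even-odd
# ray casting in the package); boundary handled by segment distance
oracle_point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  nv <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    # boundary check
    for (j in seq_len(nv)) {
      k <- if (j == nv) 1L else j + 1L
      ex <- vx[k] - vx[j]; ey <- vy[k] - vy[j]
      len2 <- ex^2 + ey^2
      t <- ((x - vx[j]) * ex + (y - vy[j]) * ey) / len2
      t <- min(max(t, 0), 1)
      d2 <- (vx[j] + t * ex - x)^2 + (vy[j] + t * ey - y)^2
      if (d2 <= eps^2) return(TRUE)
    }
    ang <- 0
    for (j in seq_len(nv)) {
      k <- if (j == nv) 1L else j + 1L
      a1 <- atan2(vy[j] - y, vx[j] - x)
      a2 <- atan2(vy[k] - y, vx[k] - x)
      da <- a2 - a1
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      ang <- ang + da
    }
    abs(ang) > pi
  }, logical(1))
}

oracle_mip <- function(stack, axis = "z") {
  d <- dim(stack)
  if (axis == "z") {
    out <- matrix(-Inf, d[2L], d[3L])
    for (z in seq_len(d[1L])) out <- pmax(out, matrix(stack[z, , ],
                                                      d[2L], d[3L]))
  } else if (axis == "y") {
    out <- matrix(-Inf, d[1L], d[3L])
    for (y in seq_len(d[2L])) out <- pmax(out, matrix(stack[, y, ],
                                                      d[1L], d[3L]))
  } else {
    out <- matrix(-Inf, d[1L], d[2L])
    for (x in seq_len(d[3L])) out <- pmax(out, matrix(stack[, , x],
                                                      d[1L], d[2L]))
  }
  out
}

# explicit type-7 percentile followed by min, the definition of the clip
oracle_percentile_clip <- function(img, upper_percent) {
  v <- sort(as.vector(img))
  n <- length(v)
  p <- 1 - upper_percent / 100
  h <- (n - 1) * p + 1
  lo <- floor(h)
  cut <- v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  pmin(img, cut)
}
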