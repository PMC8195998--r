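# Fit-free linear-combination analyses on phasor coordinates: segment and
# triangle fractions, trajectory-projection indices (optical redox ratio,
# dipolar relaxation index), two-half pair coloring, spectral-window
# mapping, and per-slice profiles.
#
# All fractions are intensity-weighted fractions (the linear-combination
# weights of the phasor are fractional intensities), not molar fractions;
# conversion would require brightness ratios and is left to the caller.

#' Segment between two pure-species phasor positions
#'
#' @param endpoint_a,endpoint_b [phasor_point()]s; a two-species mixture
#'   lies on this segment with fraction `t = 1` at `endpoint_a` and
#'   `t = 0` at `endpoint_b`.
#' @return An object of class `phasor_segment`.
#' @export
phasor_segment <- function(endpoint_a, endpoint_b) {
  stopifnot(is.numeric(endpoint_a), length(endpoint_a) == 2L,
            is.numeric(endpoint_b), length(endpoint_b) == 2L)
  if (sqrt(sum((endpoint_a - endpoint_b)^2)) <= 1e-6)
    stop("degenerate segment: endpoints coincide")
  structure(list(a = c(G = unname(endpoint_a[1L]), S = unname(endpoint_a[2L])),
                 b = c(G = unname(endpoint_b[1L]), S = unname(endpoint_b[2L]))),
            class = "phasor_segment")
}

#' Triangle of three pure-species phasor positions
#'
#' @param v1,v2,v3 [phasor_point()] vertices; must be non-degenerate
#'   (twice the signed area exceeds 1e-9 in magnitude).
#' @return An object of class `phasor_triangle`.
#' @export
phasor_triangle <- function(v1, v2, v3) {
  stopifnot(is.numeric(v1), length(v1) == 2L, is.numeric(v2),
            length(v2) == 2L, is.numeric(v3), length(v3) == 2L)
  det2 <- (v2[1L] - v1[1L]) * (v3[2L] - v1[2L]) -
    (v3[1L] - v1[1L]) * (v2[2L] - v1[2L])
  if (abs(det2) <= 1e-9) stop("degenerate triangle: vertices are collinear")
  structure(list(v = rbind(v1, v2, v3), det2 = unname(det2)),
            class = "phasor_triangle")
}

# orthogonal projection parameter of points onto a segment's line;
# t = 1 at a, 0 at b
.segment_t <- function(G, S, seg) {
  d <- seg$a - seg$b
  ((G - seg$b[["G"]]) * d[["G"]] + (S - seg$b[["S"]]) * d[["S"]]) /
    sum(d^2)
}

.fraction_map <- function(raw, valid) {
  value <- pmin(pmax(raw, 0), 1)
  value[!valid] <- NA_real_
  structure(list(value = value, raw = raw, valid = valid, shape = dim(raw)),
            class = "fraction_map")
}

#' Two-component fraction along a mixing segment
#'
#' Orthogonally projects each valid voxel's `(G, S)` onto the line through
#' the segment endpoints and reports the position `t` along it (`t = 1` at
#' `endpoint_a`, `t = 0` at `endpoint_b`).  By the rule of linear addition
#' a noiseless two-species mixture with intensity fraction `t` of species
#' `a` projects exactly to `t`.  Orthogonal projection (rather than
#' nearest-point-in-disk) is used because noise displaces points
#' symmetrically perpendicular to the mixing line, making the projection
#' the unbiased estimator of the position along the line.
#'
#' @param f A [phasor_field()].
#' @param seg A [phasor_segment()].
#' @return An object of class `fraction_map` with `value` (clamped to
#'   `[0, 1]`, `NA` where invalid), `raw` (unclamped projection), and the
#'   inherited `valid` mask.
#' @export
fraction_on_segment <- function(f, seg) {
  stopifnot(inherits(f, "phasor_field"), inherits(seg, "phasor_segment"))
  raw <- array(.segment_t(f$G, f$S, seg), dim = f$shape)
  .fraction_map(raw, f$valid)
}

#' Three-component barycentric fractions in a triangle
#'
#' Solves `P = f1*V1 + f2*V2 + f3*V3` with `f1 + f2 + f3 = 1` per voxel
#' (the standard barycentric 2x2 linear system).  Raw coordinates always
#' sum to 1 exactly; negative coordinates (voxels outside the triangle,
#' e.g. under noise) are clamped to 0 and the remainder renormalized in
#' `value`, while `raw` retains the signed solution for auditing.
#'
#' @param f A [phasor_field()].
#' @param tri A [phasor_triangle()].
#' @return List of three `fraction_map`s, one per vertex, in vertex order.
#' @export
barycentric_fractions <- function(f, tri) {
  stopifnot(inherits(f, "phasor_field"), inherits(tri, "phasor_triangle"))
  v <- tri$v
  dG <- f$G - v[3L, 1L]
  dS <- f$S - v[3L, 2L]
  a11 <- v[1L, 1L] - v[3L, 1L]; a12 <- v[2L, 1L] - v[3L, 1L]
  a21 <- v[1L, 2L] - v[3L, 2L]; a22 <- v[2L, 2L] - v[3L, 2L]
  det <- a11 * a22 - a12 * a21
  r1 <- (a22 * dG - a12 * dS) / det
  r2 <- (-a21 * dG + a11 * dS) / det
  r3 <- 1 - r1 - r2
  raw <- list(r1, r2, r3)
  pos <- lapply(raw, function(r) pmax(r, 0))
  tot <- pos[[1L]] + pos[[2L]] + pos[[3L]]
  lapply(seq_len(3L), function(i) {
    m <- .fraction_map(array(raw[[i]], f$shape), f$valid)
    m$value <- array(pos[[i]] / tot, f$shape)
    m$value[!f$valid] <- NA_real_
    m
  })
}

.index_map <- function(t_map, cap, kind) {
  t <- t_map$value
  idx <- ifelse(t >= cap / (1 + cap), cap, t / (1 - t))
  idx <- pmin(idx, cap)
  structure(list(value = idx, kind = kind, cap = cap,
                 valid = t_map$valid, shape = t_map$shape),
            class = "index_map")
}

#' Optical redox ratio from the NADH-FAD phasor trajectory
#'
#' The optical redox ratio `rr` is the ratio of NADH to FAD fluorescence
#' intensity.  Here it is estimated fit-free from the projected position
#' `t` along the phasor trajectory whose endpoints are the pure NADH and
#' FAD positions (from solution measurements or simulation): `t` is the
#' NADH intensity fraction, and `rr = t/(1 - t)`, capped at `cap` so maps
#' stay displayable as `t -> 1`.
#'
#' @param f A [phasor_field()].
#' @param nadh,fad [phasor_point()] trajectory endpoints (NADH emits
#'   around 420-500 nm, FAD around 520-600 nm).
#' @param cap Maximum reportable ratio (default 100, recorded in the map).
#' @return List with `index` (an `index_map` of `rr`) and `fraction` (the
#'   `fraction_map` of `t`); profile plots may consume either.
#' @export
redox_ratio <- function(f, nadh, fad, cap = 100) {
  stopifnot(cap > 0)
  tmap <- fraction_on_segment(f, phasor_segment(nadh, fad))
  list(index = .index_map(tmap, cap, "redox"), fraction = tmap)
}

#' Dipolar relaxation index from a solvatochromic-probe trajectory
#'
#' For a solvatochromic probe (e.g. ACDAN) whose emission shifts from blue
#' (unrelaxed environment) to green (relaxed, e.g. bulk water), the
#' dipolar relaxation index `dr` is the green-to-blue ratio projected
#' along the relaxed-unrelaxed phasor trajectory: `t` is the fraction
#' toward the relaxed endpoint and `dr = t/(1 - t)`, capped at `cap`.
#'
#' @param f A [phasor_field()].
#' @param relaxed,unrelaxed [phasor_point()] trajectory endpoints.
#' @param cap Maximum reportable ratio.
#' @return List with `index` (an `index_map` of `dr`) and `fraction`.
#' @export
dipolar_relaxation <- function(f, relaxed, unrelaxed, cap = 100) {
  stopifnot(cap > 0)
  tmap <- fraction_on_segment(f, phasor_segment(relaxed, unrelaxed))
  list(index = .index_map(tmap, cap, "dipolar"), fraction = tmap)
}

#' Two-half pair coloring of a phasor field
#'
#' Divides the phasor plane by the line through the midpoints of the
#' segments connecting the two pairs' corresponding pure positions
#' (midpoint of `pair1$a`-`pair2$a` and midpoint of `pair1$b`-`pair2$b`).
#' Each valid voxel is assigned to the half containing it and, within that
#' half, to its fraction along that half's own mixing segment.  Voxels
#' exactly on the dividing line go to half 1 (the `pair1` side) by the tie
#' rule.
#'
#' @param f A [phasor_field()].
#' @param pair1,pair2 [phasor_segment()]s of the two fluorophore pairs.
#' @return List with `half` (integer array, 1 or 2, `NA` invalid) and `t`
#'   (fraction along the assigned pair's segment, clamped), plus `raw`.
#' @export
halfplane_pair_coloring <- function(f, pair1, pair2) {
  stopifnot(inherits(f, "phasor_field"),
            inherits(pair1, "phasor_segment"),
            inherits(pair2, "phasor_segment"))
  m1 <- (pair1$a + pair2$a) / 2
  m2 <- (pair1$b + pair2$b) / 2
  d <- m2 - m1
  if (sqrt(sum(d^2)) <= 1e-9)
    stop("dividing line undefined: pair midpoints coincide")
  side <- function(G, S) d[["G"]] * (S - m1[["S"]]) - d[["S"]] * (G - m1[["G"]])
  s1a <- side(pair1$a[["G"]], pair1$a[["S"]])
  s1b <- side(pair1$b[["G"]], pair1$b[["S"]])
  ref <- if (abs(s1a) >= abs(s1b)) s1a else s1b
  if (ref == 0)
    stop("pair 1 lies on the dividing line; halves are ambiguous")
  sgn <- side(f$G, f$S) * sign(ref)
  half <- array(ifelse(sgn >= 0, 1L, 2L), dim = f$shape)  # ties -> half 1
  half[!f$valid] <- NA_integer_
  t1 <- .segment_t(f$G, f$S, pair1)
  t2 <- .segment_t(f$G, f$S, pair2)
  raw <- array(ifelse(half == 1L, t1, t2), dim = f$shape)
  tmap <- .fraction_map(raw, f$valid)
  list(half = half, t = tmap$value, raw = raw)
}

#' Map voxels to emission-wavelength windows
#'
#' Assigns each valid voxel the index of the half-open wavelength window
#' `[lambda_lo, lambda_hi)` containing its spectral center of mass (the
#' phase of its phasor mapped back to a wavelength).  Used to pseudocolor
#' structures by emission band, e.g. separating four organelle stains into
#' four windows.
#'
#' @param f A [phasor_field()] carrying a grid.
#' @param windows Data frame or matrix with columns `lambda_lo_nm`,
#'   `lambda_hi_nm` (ordered rows = window indices); windows must not
#'   overlap and must lie within the grid range.
#' @return List with `label` (integer array; `NA` where invalid or in no
#'   window) and `center_wavelength` (numeric array, nm).
#' @export
wavelength_window_mapping <- function(f, windows) {
  stopifnot(inherits(f, "phasor_field"))
  if (is.null(f$grid)) stop("phasor field carries no wavelength grid")
  windows <- as.data.frame(windows)
  stopifnot(all(c("lambda_lo_nm", "lambda_hi_nm") %in% names(windows)))
  lo <- windows$lambda_lo_nm; hi <- windows$lambda_hi_nm
  if (any(hi <= lo)) stop("each window needs lambda_lo < lambda_hi")
  if (any(lo < f$grid$lambda_min - 1e-9) ||
      any(hi > f$grid$lambda_max + 1e-9))
    stop("windows must lie within the grid range")
  o <- order(lo)
  if (any(lo[o][-1L] < hi[o][-length(o)]))
    stop("windows must not overlap")
  phase <- atan2(f$S, f$G) %% (2 * pi)
  cw <- array(phase_to_wavelength(f$grid, phase), dim = f$shape)
  lab <- array(.assign_windows(cw, lo, hi), dim = f$shape)
  lab[!f$valid] <- NA_integer_
  cw[!f$valid] <- NA_real_
  list(label = lab, center_wavelength = cw)
}

# half-open window assignment: cw in [lo_i, hi_i) -> i, else NA; a value
# exactly on a shared boundary belongs to the upper window
.assign_windows <- function(cw, lo, hi) {
  lab <- rep(NA_integer_, length(cw))
  for (i in seq_along(lo)) lab[!is.na(cw) & cw >= lo[i] & cw < hi[i]] <- i
  lab
}

#' Per-slice profile of a map along an axis
#'
#' For every slice orthogonal to the chosen axis, the mean, standard
#' deviation, and count of the map over valid (and optionally masked)
#' voxels -- e.g. the axial profile of a redox-ratio map along a crypt.
#' Empty slices are reported with `n = 0` and `NA` statistics.
#'
#' @param m A `fraction_map`, `index_map`, or plain 3-D numeric array.
#' @param axis `"z"`, `"y"`, or `"x"`.
#' @param mask Optional logical array.
#' @return Data frame with columns `slice`, `mean`, `sd`, `n`.
#' @export
slice_profile <- function(m, axis = c("z", "y", "x"), mask = NULL) {
  axis <- match.arg(axis)
  if (inherits(m, "fraction_map") || inherits(m, "index_map")) {
    vals <- m$value
    ok <- m$valid
  } else {
    stopifnot(is.array(m), length(dim(m)) == 3L)
    vals <- m
    ok <- !is.na(m)
  }
  if (!is.null(mask)) {
    stopifnot(is.array(mask), identical(dim(mask), dim(vals)))
    ok <- ok & mask
  }
  ok <- ok & !is.na(vals)
  d <- switch(axis, z = 1L, y = 2L, x = 3L)
  n_slice <- dim(vals)[d]
  idx <- slice.index(vals, d)
  out <- data.frame(slice = seq_len(n_slice), mean = NA_real_,
                    sd = NA_real_, n = 0L)
  for (i in seq_len(n_slice)) {
    v <- vals[ok & idx == i]
    out$n[i] <- length(v)
    if (length(v) > 0L) {
      out$mean[i] <- mean(v)
      out$sd[i] <- if (length(v) > 1L) stats::sd(v) else 0
    }
  }
  out
}
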