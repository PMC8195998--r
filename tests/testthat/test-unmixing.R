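# Linear-combination analyses: fractions, trajectory indices, halves,
# windows, profiles.

test_that("segment fractions project endpoints, midpoints, and mixtures", {
  a <- phasor_point(-0.2, 0.8)
  b <- phasor_point(0.6, -0.1)
  seg <- phasor_segment(a, b)
  f <- field_from_points(c(a[1], b[1], (a[1] + b[1]) / 2, 1.5),
                         c(a[2], b[2], (a[2] + b[2]) / 2, 1.5))
  m <- fraction_on_segment(f, seg)
  expect_equal(unname(m$value[1, 1:3, 1]), c(1, 0, 0.5), tolerance = 1e-12)
  # off-line voxels: raw kept, value clamped into [0, 1]
  expect_true(m$raw[1, 4, 1] > 1 || m$raw[1, 4, 1] < 0 ||
                abs(m$raw[1, 4, 1]) <= 1.5)
  expect_true(all(m$value[f$valid] >= 0 & m$value[f$valid] <= 1))
  expect_error(phasor_segment(a, a), "degenerate")
})

test_that("noiseless two-dye mixtures recover the programmed fraction", {
  g <- default_grid()
  dyes <- six_dyes()
  a <- dyes[[2]]; b <- dyes[[5]]
  pa <- spectrum_phasor(gaussian_spectrum(a, g))
  pb <- spectrum_phasor(gaussian_spectrum(b, g))
  seg <- phasor_segment(pa, pb)
  sc <- uniform_scene(programmed_composition(list(a, b), c(0.3, 0.7), g),
                      grid = g)
  tr <- render_triplet(sc, camera = camera_model(), noiseless = TRUE)
  m <- fraction_on_segment(triplet_to_phasor(tr), seg)
  expect_equal(max(abs(m$value - 0.3)), 0, tolerance = 1e-9)
})

test_that("segment fractions are invariant under rigid motions", {
  set.seed(31)
  for (rep in 1:10) {
    a <- stats::runif(2, -0.8, 0.8)
    b <- stats::runif(2, -0.8, 0.8)
    if (sqrt(sum((a - b)^2)) < 0.1) next
    pts_G <- stats::runif(20, -1, 1)
    pts_S <- stats::runif(20, -1, 1)
    t0 <- fraction_on_segment(field_from_points(pts_G, pts_S),
                              phasor_segment(a, b))$raw
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    sh <- stats::runif(2, -0.5, 0.5)
    rot <- function(p) as.numeric(R %*% p + sh)
    pr <- t(apply(cbind(pts_G, pts_S), 1, rot))
    t1 <- fraction_on_segment(field_from_points(pr[, 1], pr[, 2]),
                              phasor_segment(rot(a), rot(b)))$raw
    expect_equal(t1, t0, tolerance = 1e-9)
  }
})

test_that("barycentric fractions solve the triangle exactly", {
  v1 <- phasor_point(-0.5, 0.7)
  v2 <- phasor_point(0.6, 0.2)
  v3 <- phasor_point(-0.1, -0.6)
  tri <- phasor_triangle(v1, v2, v3)
  cen <- (v1 + v2 + v3) / 3
  mixp <- 0.5 * v1 + 0.3 * v2 + 0.2 * v3
  out <- phasor_point(1.2, 1.2)  # outside the triangle
  f <- field_from_points(c(v1[1], cen[1], mixp[1], out[1]),
                         c(v1[2], cen[2], mixp[2], out[2]))
  fr <- barycentric_fractions(f, tri)
  got <- sapply(fr, function(m) m$raw[1, , 1])
  expect_equal(unname(got[1, ]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(unname(got[2, ]), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(got[3, ]), c(0.5, 0.3, 0.2), tolerance = 1e-12)
  # raw coordinates always sum to one; clamped values renormalize
  expect_equal(rowSums(got), rep(1, 4), tolerance = 1e-12)
  vals <- sapply(fr, function(m) m$value[1, 4, 1])
  expect_equal(sum(vals), 1, tolerance = 1e-12)
  expect_true(all(vals >= 0))
  # independent 2x2 linear-system oracle per voxel
  for (i in 1:4) {
    A <- rbind(c(v1[1] - v3[1], v2[1] - v3[1]),
               c(v1[2] - v3[2], v2[2] - v3[2]))
    rhs <- c(f$G[1, i, 1] - v3[1], f$S[1, i, 1] - v3[2])
    sol <- solve(A, rhs)
    expect_equal(unname(got[i, ]), unname(c(sol, 1 - sum(sol))),
                 tolerance = 1e-10)
  }
  expect_error(phasor_triangle(v1, v2, (v1 + v2) / 2), "degenerate")
})

test_that("noiseless three-dye mixtures recover their fractions", {
  g <- default_grid()
  dyes <- six_dyes()
  trio <- dyes[c(1, 3, 6)]
  pts <- lapply(trio, function(d) spectrum_phasor(gaussian_spectrum(d, g)))
  tri <- phasor_triangle(pts[[1]], pts[[2]], pts[[3]])
  w <- c(0.5, 0.3, 0.2)
  sc <- uniform_scene(programmed_composition(trio, w, g), grid = g)
  f <- triplet_to_phasor(render_triplet(sc, camera = camera_model(),
                                        noiseless = TRUE))
  fr <- barycentric_fractions(f, tri)
  for (i in 1:3)
    expect_equal(max(abs(fr[[i]]$raw - w[i])), 0, tolerance = 1e-9)
})

test_that("redox ratio maps the NADH-FAD trajectory position", {
  nadh <- phasor_point(0.1, 0.9)
  fad <- phasor_point(0.7, 0.3)
  mid <- (nadh + fad) / 2
  f <- field_from_points(c(mid[1], nadh[1], fad[1]),
                         c(mid[2], nadh[2], fad[2]))
  rr <- redox_ratio(f, nadh, fad, cap = 100)
  expect_equal(unname(rr$fraction$value[1, , 1]), c(0.5, 1, 0))
  expect_equal(unname(rr$index$value[1, , 1]), c(1, 100, 0))
  expect_equal(rr$index$kind, "redox")
  # rr = t/(1-t) is strictly increasing in t below the cap
  ts <- seq(0.05, 0.9, by = 0.05)
  ft <- field_from_points(nadh[1] * ts + fad[1] * (1 - ts),
                          nadh[2] * ts + fad[2] * (1 - ts))
  rr2 <- redox_ratio(ft, nadh, fad)
  expect_true(all(diff(rr2$index$value[1, , 1]) > 0))
  expect_true(all(diff(rr2$fraction$value[1, , 1]) > 0))
})

test_that("dipolar relaxation separates programmed regions significantly", {
  g <- default_grid()
  blue <- fluorophore("acdan-unrelaxed", 470, 60)
  green <- fluorophore("acdan-relaxed", 525, 60)
  p_rel <- spectrum_phasor(gaussian_spectrum(green, g))
  p_unrel <- spectrum_phasor(gaussian_spectrum(blue, g))
  # region 1 (z 1-16): mostly unrelaxed; region 2 (z 17-32): mostly relaxed
  layers <- list(
    list(thickness = 16L,
         composition = programmed_composition(list(green, blue),
                                              c(0.35, 0.65), g)),
    list(thickness = 16L,
         composition = programmed_composition(list(green, blue),
                                              c(0.65, 0.35), g)))
  sc <- make_layered_phantom(layers, ny = 8L, nx = 8L, grid = g)
  cam <- camera_model(seed = 17L, hot_pixel_rate = 0)
  f <- triplet_to_phasor(render_triplet(sc, camera = cam))
  dr <- dipolar_relaxation(f, p_rel, p_unrel)
  prof <- slice_profile(dr$index, "z")
  w <- stats::wilcox.test(prof$mean[1:16], prof$mean[17:32])
  expect_lt(w$p.value, 0.05)
  expect_lt(mean(prof$mean[1:16]), mean(prof$mean[17:32]))
  # endpoint semantics: unrelaxed endpoint maps to dr = 0
  fe <- field_from_points(p_unrel[1], p_unrel[2])
  expect_equal(unname(dipolar_relaxation(fe, p_rel,
                                         p_unrel)$index$value[1, 1, 1]), 0)
})

test_that("halfplane pair coloring assigns halves and fractions", {
  pair1 <- phasor_segment(c(0, 1), c(1, 0))
  pair2 <- phasor_segment(c(0, 0.5), c(0.5, 0))
  m1 <- c(0, 0.75)  # midpoint of the two 'a' endpoints
  f <- field_from_points(c(0, 0.5, m1[1], 0.1),
                         c(1, 0, m1[2], 0.1))
  hp <- halfplane_pair_coloring(f, pair1, pair2)
  expect_equal(unname(hp$half[1, , 1]), c(1L, 2L, 1L, 2L))
  expect_equal(unname(hp$t[1, 1, 1]), 1)   # pure endpoint a of pair 1
  expect_equal(unname(hp$t[1, 2, 1]), 0)   # pure endpoint b of pair 2
  expect_error(halfplane_pair_coloring(f, pair1, pair1), "ambiguous")
})

test_that("four-dye layers get the half/fraction of their pair", {
  g <- default_grid()
  cfp <- fluorophore("cfp-like", 475, 30)
  gfp <- fluorophore("gfp-like", 510, 30)
  so <- fluorophore("so-like", 570, 30)
  rfp <- fluorophore("rfp-like", 610, 30)
  pp <- function(fl) spectrum_phasor(gaussian_spectrum(fl, g))
  pair1 <- phasor_segment(pp(cfp), pp(rfp))
  pair2 <- phasor_segment(pp(gfp), pp(so))
  layers <- list(
    list(thickness = 2L,
         composition = programmed_composition(list(cfp, rfp), c(0.7, 0.3), g)),
    list(thickness = 2L,
         composition = programmed_composition(list(gfp, so), c(0.6, 0.4), g)))
  sc <- make_layered_phantom(layers, ny = 4L, nx = 4L, grid = g)
  f <- triplet_to_phasor(render_triplet(sc, camera = camera_model(),
                                        noiseless = TRUE))
  hp <- halfplane_pair_coloring(f, pair1, pair2)
  expect_true(all(hp$half[1:2, , ] == 1L))
  expect_true(all(hp$half[3:4, , ] == 2L))
  expect_equal(max(abs(hp$t[1:2, , ] - 0.7)), 0, tolerance = 1e-9)
  expect_equal(max(abs(hp$t[3:4, , ] - 0.6)), 0, tolerance = 1e-9)
})

test_that("wavelength windows label voxels by spectral center of mass", {
  g <- default_grid()
  windows <- data.frame(label = c("w1", "w2", "w3", "w4"),
                        lambda_lo_nm = c(400, 470, 530, 600),
                        lambda_hi_nm = c(470, 530, 600, 700))
  th450 <- wavelength_to_phase(g, 450)
  f <- field_from_points(cos(th450), sin(th450), grid = g)
  wm <- wavelength_window_mapping(f, windows)
  expect_equal(unname(wm$label[1, 1, 1]), 1L)
  expect_equal(unname(wm$center_wavelength[1, 1, 1]), 450,
               tolerance = 1e-9)
  # the half-open rule: a boundary value joins the upper window
  lab <- phasorsnap:::.assign_windows(c(470, 469.9999, 699, 705),
                                      windows$lambda_lo_nm,
                                      windows$lambda_hi_nm)
  expect_equal(lab, c(2L, 1L, 4L, NA_integer_))
  over <- data.frame(label = c("a", "b"),
                     lambda_lo_nm = c(400, 450),
                     lambda_hi_nm = c(500, 550))
  expect_error(wavelength_window_mapping(f, over), "overlap")
  # four spectrally overlapping dyes are still separated by window
  fl <- list(fluorophore("n", 440, 25), fluorophore("g", 500, 25),
             fluorophore("m", 560, 25), fluorophore("l", 630, 25))
  layers <- lapply(fl, function(d)
    list(thickness = 1L, composition = programmed_composition(list(d), 1, g)))
  sc <- make_layered_phantom(layers, ny = 4L, nx = 4L, grid = g)
  fld <- triplet_to_phasor(render_triplet(sc, camera = camera_model(),
                                          noiseless = TRUE))
  wm2 <- wavelength_window_mapping(fld, windows)
  for (z in 1:4) {
    tab <- table(wm2$label[z, , ])
    expect_equal(as.integer(names(tab)[which.max(tab)]), z)
  }
})

test_that("slice profiles summarize maps per plane", {
  homo <- array(0.4, c(3L, 4L, 5L))
  p <- slice_profile(homo, "z")
  expect_equal(p$mean, rep(0.4, 3))
  expect_equal(p$sd, rep(0, 3))
  expect_equal(p$n, rep(20L, 3))
  ramp <- array(rep(1:4 / 10, each = 1), c(4L, 3L, 3L))
  for (z in 1:4) ramp[z, , ] <- z / 10
  pz <- slice_profile(ramp, "z")
  expect_equal(pz$mean, (1:4) / 10)
  py <- slice_profile(ramp, "y")
  expect_equal(py$mean, rep(mean((1:4) / 10), 3))
  expect_true(all(py$sd > 0))
  # single-voxel mask
  mask <- array(FALSE, dim(ramp))
  mask[2, 1, 1] <- TRUE
  pm <- slice_profile(ramp, "z", mask = mask)
  expect_equal(pm$n, c(0L, 1L, 0L, 0L))
  expect_equal(pm$mean[2], 0.2)
  expect_equal(pm$sd[2], 0)
  expect_true(all(is.na(pm$mean[c(1, 3, 4)])))
})
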