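# The snapshot transform, preprocessing, histograms, and calibration.

test_that("triplet transform implements the ratio normalization", {
  dims <- c(1L, 2L, 2L)
  b <- 100
  I_tot <- array(1100, dims)
  mk <- function(I_sin, I_cos)
    list(I_sin = array(I_sin, dims), I_cos = array(I_cos, dims),
         I_total = I_tot)
  # both ratios 0.5 -> origin (flat spectrum)
  f0 <- triplet_to_phasor(mk(600, 600), b = b, threshold = 50)
  expect_equal(max(abs(f0$G)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f0$S)), 0, tolerance = 1e-12)
  # cosine ratio 1, sine ratio 0.5 -> (1, 0), a line at the range start
  f1 <- triplet_to_phasor(mk(600, 1100), b = b, threshold = 50)
  expect_equal(unname(f1$G[1, 1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(f1$S[1, 1, 1]), 0, tolerance = 1e-12)
  # threshold masks weak voxels with NA markers
  t3 <- mk(600, 600)
  t3$I_total[1, 1, 1] <- 120  # I_total - b = 20 <= 50
  f3 <- triplet_to_phasor(t3, b = b, threshold = 50)
  expect_false(f3$valid[1, 1, 1])
  expect_true(is.na(f3$G[1, 1, 1]))
  expect_true(all(f3$valid[1, , 2]))
  expect_error(triplet_to_phasor(list(I_sin = array(0, dims),
                                      I_cos = array(0, dims),
                                      I_total = array(0, c(1L, 2L, 3L)))),
               "shape")
})

test_that("triplet path equals the spectral transform for any offset", {
  g <- default_grid()
  fl <- fluorophore("a", 560, 45)
  truth <- spectrum_phasor(gaussian_spectrum(fl, g))
  for (b in c(0, 50, 500)) {
    sc <- uniform_scene(list(list(fluor = fl, concentration = 1)), grid = g)
    tr <- render_triplet(sc, camera = camera_model(offset = b),
                         noiseless = TRUE)
    f <- triplet_to_phasor(tr, b = b, threshold = 10)
    expect_equal(max(abs(f$G - truth[["G"]])), 0, tolerance = 1e-9)
    expect_equal(max(abs(f$S - truth[["S"]])), 0, tolerance = 1e-9)
  }
})

test_that("median filter matches the brute-force oracle and kills hot pixels", {
  const <- array(5, c(2L, 6L, 7L))
  expect_equal(median3(const), const)
  hot <- const
  hot[1, 3, 4] <- 9999
  expect_equal(median3(hot), const)
  set.seed(5)
  r <- array(stats::runif(3 * 9 * 11), c(3L, 9L, 11L))
  got <- median3(r)
  for (z in 1:3)
    expect_equal(matrix(got[z, , ], 9, 11),
                 oracle_median3_plane(matrix(r[z, , ], 9, 11)))
  # planes are filtered independently
  two <- array(0, c(2L, 5L, 5L))
  two[2, , ] <- 100
  expect_equal(median3(two), two)
})

test_that("2x2 binning sums blocks and drops odd trailing edges", {
  const <- array(3, c(2L, 4L, 6L))
  expect_true(all(bin2(const) == 12))
  chk <- array(0, c(1L, 4L, 4L))
  chk[1, , ] <- outer(1:4, 1:4, function(a, b) (a + b) %% 2)
  expect_true(all(bin2(chk) == 2))
  set.seed(6)
  r <- array(stats::rpois(2 * 8 * 10, 50), c(2L, 8L, 10L))
  expect_equal(bin2(r), oracle_bin2(r))
  odd <- array(1, c(1L, 5L, 4L))
  expect_warning(b <- bin2(odd), "odd trailing")
  expect_equal(dim(b), c(1L, 2L, 2L))
})

test_that("histograms conserve counts and reproduce from the seed", {
  n <- 64L
  f <- field_from_points(rep(0.25, n), rep(-0.5, n))
  h0 <- phasor_histogram(f, jitter_halfwidth = 0, seed = 1L)
  expect_equal(sum(h0$counts), n)
  expect_equal(sum(h0$counts > 0), 1L)
  expect_equal(h0$n_out_of_range, 0L)
  h1 <- phasor_histogram(f, jitter_halfwidth = 0.02, seed = 9L)
  h2 <- phasor_histogram(f, jitter_halfwidth = 0.02, seed = 9L)
  expect_identical(h1$counts, h2$counts)
  h3 <- phasor_histogram(f, jitter_halfwidth = 0.02, seed = 10L)
  expect_false(identical(h1$counts, h3$counts))
  # jittered points beyond [-1,1]^2 are dropped but counted
  fe <- field_from_points(rep(0.999, 500L), rep(0.999, 500L))
  he <- phasor_histogram(fe, jitter_halfwidth = 0.02, seed = 2L)
  expect_gt(he$n_out_of_range, 0L)
  expect_equal(sum(he$counts) + he$n_out_of_range, he$n_valid)
  expect_equal(he$n_valid, 500L)
})

test_that("display jitter is uniform over its square", {
  n <- 20000L
  f <- field_from_points(rep(0, n), rep(0, n))
  h <- phasor_histogram(f, jitter_halfwidth = 0.02, seed = 7L)
  expect_equal(sum(h$counts), n)
  # bins overlapping [-0.02, 0.02]: indices 126..131 on each axis
  sub <- h$counts[126:131, 126:131]
  expect_equal(sum(sub), n)  # counts confined to the jitter square
  dbin <- 2 / 256
  edges <- seq(-1, 1, by = dbin)[126:132]
  cover <- pmin(edges[-1], 0.02) - pmax(edges[-length(edges)], -0.02)
  p1 <- cover / 0.04
  p2 <- as.vector(outer(p1, p1))
  chi <- stats::chisq.test(as.vector(sub), p = p2)
  expect_gt(chi$p.value, 0.01)
})

test_that("calibration fits recover sinusoid parameters", {
  g <- default_grid()
  ideal <- ideal_filter("sine", g)
  fit <- fit_calibration(ideal)
  expect_equal(fit$offset, 0.5, tolerance = 1e-12)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-12)
  expect_lt(fit$residual_norm, 1e-10)
  floor10 <- ideal_filter("cosine", g, offset = 0.55, amplitude = 0.45)
  fitf <- fit_calibration(floor10)
  expect_equal(fitf$offset, 0.55, tolerance = 1e-12)
  expect_equal(fitf$amplitude, 0.45, tolerance = 1e-12)
  noisy <- filter_curve(g, pmin(pmax(
    ideal$transmission + withr::with_seed(4L, stats::rnorm(300, 0, 0.01)),
    0), 1))
  fitn <- fit_calibration(noisy, kind = "sine")
  expect_equal(fitn$offset, 0.5, tolerance = 0.01)
  expect_equal(fitn$amplitude, 0.5, tolerance = 0.01)
  flat <- filter_curve(g, rep(0.5, 300))
  expect_error(fit_calibration(flat, kind = "sine"), "calibration failure")
})

test_that("fitted calibration removes the bias of non-ideal filters", {
  g <- default_grid()
  fl <- fluorophore("a", 545, 40)
  truth <- spectrum_phasor(gaussian_spectrum(fl, g))
  fs <- ideal_filter("sine", g, offset = 0.55, amplitude = 0.45)
  fc <- ideal_filter("cosine", g, offset = 0.55, amplitude = 0.45)
  sc <- uniform_scene(list(list(fluor = fl, concentration = 1)), grid = g)
  tr <- render_triplet(sc, sine = fs, cosine = fc,
                       camera = camera_model(), noiseless = TRUE)
  f_default <- triplet_to_phasor(tr)
  bias_default <- max(abs(f_default$G[1] - truth[["G"]]),
                      abs(f_default$S[1] - truth[["S"]]))
  cal <- calibration_from_curves(fs, fc)
  f_cal <- triplet_to_phasor(tr, cal = cal)
  bias_cal <- max(abs(f_cal$G[1] - truth[["G"]]),
                  abs(f_cal$S[1] - truth[["S"]]))
  expect_gt(bias_default, 0.01)
  expect_lt(bias_cal, 0.005)
})

test_that("noisy phasor estimates are unbiased at 1e4 photons", {
  g <- default_grid()
  fl <- fluorophore("a", 530, 45)
  truth <- spectrum_phasor(gaussian_spectrum(fl, g))
  sc <- uniform_scene(list(list(fluor = fl, concentration = 1)),
                      shape = c(1L, 32L, 32L), grid = g)
  cam <- camera_model(read_noise_sd = 2, hot_pixel_rate = 0, seed = 21L)
  f <- triplet_to_phasor(render_triplet(sc, camera = cam))
  expect_gte(sum(f$valid), 1000L)
  expect_lt(abs(mean(f$G[f$valid]) - truth[["G"]]), 0.005)
  expect_lt(abs(mean(f$S[f$valid]) - truth[["S"]]), 0.005)
})
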