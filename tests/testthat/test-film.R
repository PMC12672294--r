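test_that("netOD follows the background-subtracted log-ratio convention", {
  expect_equal(compute_netOD(30000, 30000, 1000), 0)
  expect_equal(compute_netOD(1000 + 4000, 1000 + 40000, 1000), 1)  # one decade
  # unexposed film reads zero netOD regardless of the background level
  for (bkg in c(0, 500, 5000))
    expect_equal(compute_netOD(20000, 20000, bkg), 0)
  expect_error(compute_netOD(1000, 2000, 1500), "exposed")
  expect_error(compute_netOD(2000, 1000, 1500), "unexposed")
})

test_that("netOD matches a pixelwise brute-force recomputation", {
  set.seed(21)
  pv <- matrix(stats::runif(100, 5000, 40000), 10, 10)
  un <- matrix(stats::runif(100, 41000, 43000), 10, 10)
  bkg <- 1200
  got <- compute_netOD(pv, un, bkg)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    brute[i, j] <- log10((un[i, j] - bkg) / (pv[i, j] - bkg))
  expect_equal(got, brute, tolerance = 1e-15)
})

test_that("calibration fit recovers an exact cubic and refuses bad designs", {
  od <- c(0, 0.1, 0.2, 0.3)
  pts <- data.frame(netOD = od, dose_cGy = 100 * od^3 + 50 * od)
  cal <- fit_calibration(pts)
  expect_equal(cal$poly_coeffs, c(0, 50, 0, 100), tolerance = 1e-8)
  expect_equal(cal$fit_residual_sd, 0, tolerance = 1e-8)
  expect_equal(predict(cal, 0.25), 100 * 0.25^3 + 50 * 0.25, tolerance = 1e-8)
  expect_error(fit_calibration(pts[1:3, ]), "4 distinct")
  expect_error(fit_calibration(data.frame(netOD = c(0, 0, 0.1, 0.2),
                                          dose_cGy = 1:4)), "rank-deficient")
  dec <- data.frame(netOD = od, dose_cGy = c(100, 80, 60, 40))
  expect_error(fit_calibration(dec), "monotone")
})

test_that("calibration coefficients are recovered within 3 SE under noise", {
  set.seed(1234)
  od <- seq(0, 0.45, length.out = 10)
  truth <- c(0, 3000, 800, 4000)
  dose <- truth[1] + truth[2] * od + truth[3] * od^2 + truth[4] * od^3 +
    stats::rnorm(10, 0, 1)
  cal <- fit_calibration(data.frame(netOD = od, dose_cGy = dose))
  ref <- stats::lm(dose ~ od + I(od^2) + I(od^3))
  expect_equal(cal$poly_coeffs, unname(stats::coef(ref)), tolerance = 1e-10)
  se <- unname(sqrt(diag(stats::vcov(ref))))
  expect_true(all(abs(cal$poly_coeffs - truth) <= 3 * se))
  expect_equal(cal$fit_residual_sd, summary(ref)$sigma, tolerance = 1e-10)
})

test_that("film-to-dose conversion round-trips a known dose plane", {
  od <- seq(0, 0.4, length.out = 6)
  cal <- fit_calibration(data.frame(netOD = od,
                                    dose_cGy = 2000 * od + 5000 * od^3))
  un <- 42000; bkg <- 1200
  # uniform image at the unexposed level converts to uniform zero dose
  flat <- film_to_dose(matrix(un, 4, 4), cal, un, bkg)
  expect_equal(flat$dose, matrix(0, 4, 4), tolerance = 1e-9)
  expect_equal(flat$n_out_of_range, 0)
  # invert the calibration from a known dose plane (exact pixel values)
  set.seed(5)
  od_true <- matrix(stats::runif(400, 0, 0.4), 20, 20)
  dose_true <- predict(cal, od_true)
  pv <- (un - bkg) * 10^(-od_true) + bkg
  got <- film_to_dose(pv, cal, un, bkg)
  expect_equal(got$dose, dose_true, tolerance = 1e-9)
  expect_equal(got$n_out_of_range, 0)
  expect_equal(got$n_saturated, 0)
})

test_that("out-of-range and saturated pixels are flagged, not extrapolated", {
  od <- seq(0, 0.3, length.out = 5)
  cal <- fit_calibration(data.frame(netOD = od, dose_cGy = 1000 * od))
  un <- 40000; bkg <- 1000
  pv <- matrix(c((un - bkg) * 10^(-0.5) + bkg,   # netOD 0.5, above range
                 (un - bkg) * 10^(-0.1) + bkg,   # fine
                 66000,                          # saturated
                 (un - bkg) * 10^(-0.2) + bkg), 2, 2)
  got <- film_to_dose(pv, cal, un, bkg, saturation_level = 65535)
  expect_equal(got$n_out_of_range, 1)
  expect_equal(got$n_saturated, 1)
  expect_true(is.na(got$dose[1, 1]))
  expect_equal(got$flags[1, 1], 1L)
  expect_equal(got$flags[1, 2], 2L)
})

test_that("16-bit film TIFFs round-trip through the tiff container", {
  set.seed(9)
  pv <- matrix(sample.int(65535, 600), 20, 30)
  path <- file.path(tempdir(), "film.tif")
  write_film_tiff(pv, path)
  expect_equal(read_film_tiff(path), pv)
  rgb <- array(sample.int(65535, 300), c(10, 10, 3))
  write_film_tiff(rgb, path)
  expect_equal(read_film_tiff(path, "green"), rgb[, , 2])
  unlink(path)
})

test_that("film-plane pixels map to the documented polar coordinates", {
  map <- list(u_cm = c(0, sqrt(3)), v_cm = 0, dose = matrix(c(5, 1), 2, 1),
              offset_cm = 1)
  s <- map_film_plane_to_polar(map)
  expect_equal(s$r_cm, c(1, 2))
  expect_equal(s$theta_deg, c(90, 30))
  expect_equal(s$valid, c(TRUE, TRUE))
  # polar angles below the film limit are masked
  steep <- list(u_cm = 10, v_cm = 0, dose = matrix(1), offset_cm = 1)
  s2 <- map_film_plane_to_polar(steep)
  expect_lt(s2$theta_deg, 20)
  expect_false(s2$valid)
  expect_error(map_film_plane_to_polar(list(u_cm = 0, v_cm = 0,
                                            dose = matrix(1), offset_cm = 0)),
               "positive")
})

test_that("the minimum measurable radius at 20 degrees is 1/sin(20 deg)", {
  # constraint r sin(theta) >= d with d = 1 cm
  r_min <- 1 / sinpi(20 / 180)
  expect_equal(r_min, 2.924, tolerance = 1e-3)
  # on the film lattice: cells at theta = 20 deg are only valid from ~2.9 cm
  u <- seq(-4.8, 4.8, by = 0.1); v <- seq(-4.8, 4.8, by = 0.1)
  map <- list(u_cm = u, v_cm = v,
              dose = matrix(1, length(u), length(v)), offset_cm = 1)
  s <- map_film_plane_to_polar(map)
  lat <- bin_polar_samples(s, radii = seq(1, 5, by = 0.2),
                           theta_deg = c(20, 50, 90))
  # with the 1-degree cell half-width, the first populated node sits at
  # 2.8-3.0 cm, matching where the published 20-degree film row begins
  v20 <- lat[lat$theta_deg == 20, ]
  expect_true(all(v20$r_cm[v20$valid] >= 2.8 - 1e-9))
  expect_false(any(v20$valid & v20$r_cm < 2.8))
})

test_that("the film validity mask is monotone in r at fixed theta", {
  u <- seq(-4.5, 4.5, by = 0.04); v <- seq(-4.5, 4.5, by = 0.04)
  map <- list(u_cm = u, v_cm = v,
              dose = matrix(1, length(u), length(v)), offset_cm = 1)
  lat <- bin_polar_samples(map_film_plane_to_polar(map),
                           radii = seq(1, 4.4, by = 0.2),
                           theta_deg = seq(20, 90, by = 10))
  for (th in unique(lat$theta_deg)) {
    vv <- lat$valid[lat$theta_deg == th]
    first <- which(vv)[1]
    if (!is.na(first)) expect_true(all(vv[first:length(vv)]))
  }
})

test_that("the film route reproduces the generating kernel after polar mapping", {
  p <- default_kernel_params(noise_sd = 0)
  g <- small_grid(p, "abs", half_cm = 3.3, voxel_mm = 1, reference = 1000)
  plane <- sample_film_plane(g, offset_cm = 1)
  s <- map_film_plane_to_polar(plane)
  keep <- which(s$valid & s$r_cm < 3)
  set.seed(3)
  keep <- sample(keep, 300)
  expected <- kernel_closed_form(p, "abs", s$r_cm[keep], s$theta_deg[keep],
                                 s$phi_deg[keep], reference = 1000)
  expect_equal(s$dose[keep], expected, tolerance = 5e-3)
})
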