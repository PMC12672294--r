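#' Miniature X-ray tube source description
#'
#' Operating point and physical envelope of the vacuum-sealed CNT-cathode
#' miniature X-ray tube. The source is modeled as a point (the TG-43
#' point-source geometry function is used throughout); the tube body enters
#' only through these descriptive fields.
#'
#' @param operating_voltage_kvp anode voltage in kVp; must be in (0, 70].
#' @param operating_current_uA tube current in microampere.
#' @param air_kerma_strength air-kerma strength S_K in Gy cm^2 min^-1
#'   (adopted input constant, not re-derived here).
#' @param tube_length_mm,tube_outer_diameter_mm tube envelope dimensions.
#' @param source_origin_cm position of the source in grid coordinates (cm).
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(operating_voltage_kvp = 50, operating_current_uA = 252,
                        air_kerma_strength = 108.1, tube_length_mm = 47,
                        tube_outer_diameter_mm = 7, source_origin_cm = c(0, 0, 0)) {
  if (operating_voltage_kvp <= 0 || operating_voltage_kvp > 70)
    stop("operating voltage must be in (0, 70] kVp")
  if (operating_current_uA <= 0) stop("operating current must be positive")
  if (air_kerma_strength <= 0) stop("air-kerma strength must be positive")
  if (length(source_origin_cm) != 3L) stop("source_origin_cm must have length 3")
  structure(list(operating_voltage_kvp = operating_voltage_kvp,
                 operating_current_uA = operating_current_uA,
                 air_kerma_strength = air_kerma_strength,
                 tube_length_mm = tube_length_mm,
                 tube_outer_diameter_mm = tube_outer_diameter_mm,
                 source_origin_cm = source_origin_cm),
            class = "source_spec")
}

#' Synthetic dose-kernel parameters
#'
#' Parametric stand-in for Monte Carlo photon transport. The kernel is
#' \deqn{D(r,\theta,\phi) = K r^{-2} c_m A_m(r) f(\theta)
#'       (1 + \epsilon h(\phi)) (1 + \mathrm{noise})}
#' with a two-component exponential attenuation
#' `A_m(r) = w exp(-mu_fast r) + (1 - w) exp(-mu_slow r)` per medium (a
#' soft/hard spectral mixture reproducing beam hardening; `A_m(0) = 1` by
#' construction), a polar emission profile
#' `f(theta) = 1 + sum_k a_k cos^k(theta)` (so `f(90 deg) = 1` exactly), and
#' an azimuthal ripple `h(phi) = sin(2 phi + phase)`.
#'
#' @param medium_scale named vector of dimensionless per-medium absorption
#'   scales `c_m`, names `water` and `abs`.
#' @param attenuation_coeffs named list (per medium) of vectors
#'   `c(w, mu_fast, mu_slow)` with `w` in \[0, 1\] and attenuation
#'   coefficients in cm^-1.
#' @param polar_coeffs coefficients `a_k` of `cos^k(theta)`, k = 1, 2, ...
#'   The resulting profile must be positive on \[0, 180\] degrees.
#' @param azimuthal_amplitude ripple amplitude epsilon, in \[0, 0.10\].
#' @param azimuthal_phase_deg phase of the ripple, degrees.
#' @param noise_sd relative SD of multiplicative Gaussian scoring noise.
#' @param seed integer seed for the noise; required at generation time when
#'   `noise_sd > 0`.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(medium_scale = c(water = 1, abs = 1),
                          attenuation_coeffs = list(
                            water = c(w = 1, mu_fast = 0, mu_slow = 0),
                            abs = c(w = 1, mu_fast = 0, mu_slow = 0)),
                          polar_coeffs = 0,
                          azimuthal_amplitude = 0,
                          azimuthal_phase_deg = 0,
                          noise_sd = 0,
                          seed = NULL) {
  stopifnot(all(c("water", "abs") %in% names(medium_scale)),
            all(c("water", "abs") %in% names(attenuation_coeffs)))
  if (any(medium_scale <= 0)) stop("medium scales must be positive")
  for (m in names(attenuation_coeffs)) {
    ac <- attenuation_coeffs[[m]]
    if (length(ac) != 3L || ac[1] < 0 || ac[1] > 1 || any(ac[2:3] < 0))
      stop("attenuation coefficients for ", m,
           " must be c(w, mu_fast, mu_slow) with w in [0,1], mu >= 0")
  }
  if (azimuthal_amplitude < 0 || azimuthal_amplitude > 0.10)
    stop("azimuthal amplitude must be in [0, 0.10]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  th <- seq(0, 180, by = 0.5)
  if (any(polar_profile(th, polar_coeffs) <= 0))
    stop("polar profile must be positive over [0, 180] degrees")
  structure(list(medium_scale = medium_scale,
                 attenuation_coeffs = attenuation_coeffs,
                 polar_coeffs = polar_coeffs,
                 azimuthal_amplitude = azimuthal_amplitude,
                 azimuthal_phase_deg = azimuthal_phase_deg,
                 noise_sd = noise_sd, seed = seed),
            class = "kernel_params")
}

#' Default calibrated kernel parameters
#'
#' Attenuation mixtures and medium scales were fit by least squares to the
#' packaged transverse-plane radial-dose tables for water and ABS jointly
#' with the two conversion-factor endpoints (water/ABS dose ratio 1.23 at
#' 1 cm and 0.85 at 5 cm); the polar profile is a cubic in cos(theta) fit to
#' the packaged per-angle anisotropy means under the constraints
#' f(0 deg) = 1.16 (forward bremsstrahlung enhancement) and
#' f(180 deg) = 0.85 (backward reduction by the tube body). These values are
#' frozen; they are the study conditions the rest of the pipeline assumes.
#'
#' @param seed integer noise seed (needed whenever `noise_sd > 0`).
#' @param noise_sd relative SD of the multiplicative scoring noise;
#'   default 0.007.
#' @return a [kernel_params] object.
#' @export
default_kernel_params <- function(seed = NULL, noise_sd = 0.007) {
  kernel_params(
    medium_scale = c(water = 2.4408779, abs = 1),
    attenuation_coeffs = list(
      water = c(w = 0.9864012, mu_fast = 5.9521660, mu_slow = 0.3775754),
      abs   = c(w = 0.9759823, mu_fast = 5.1884954, mu_slow = 0.2805037)),
    polar_coeffs = c(-0.1417056, 0.005, 0.2967056),
    azimuthal_amplitude = 0.03,
    azimuthal_phase_deg = 150,
    noise_sd = noise_sd,
    seed = seed)
}

#' Radial attenuation factor A_m(r)
#'
#' @param r radial distance in cm (vectorized).
#' @param coeffs vector `c(w, mu_fast, mu_slow)`.
#' @return dimensionless attenuation, `A(0) = 1`.
#' @export
attenuation_factor <- function(r, coeffs) {
  coeffs[[1]] * exp(-coeffs[[2]] * r) + (1 - coeffs[[1]]) * exp(-coeffs[[3]] * r)
}

#' Polar emission profile f(theta)
#'
#' `1 + sum_k a_k cos^k(theta)`; equals 1 at 90 degrees by construction.
#'
#' @param theta_deg polar angle in degrees (vectorized).
#' @param coeffs coefficients `a_k` of `cos^k`.
#' @return dimensionless profile value.
#' @export
polar_profile <- function(theta_deg, coeffs) {
  ct <- cospi(theta_deg / 180)
  out <- rep(1, length(ct))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * ct^k
  out
}

azimuthal_factor <- function(phi_deg, amplitude, phase_deg) {
  1 + amplitude * sinpi((2 * phi_deg + phase_deg) / 180)
}

# normalization K: azimuthally averaged, noise-free transverse dose at
# r = 1 cm in water equals the reference level
kernel_norm <- function(params, reference_dose_rate) {
  cw <- params$medium_scale[["water"]]
  reference_dose_rate / (cw * attenuation_factor(1, params$attenuation_coeffs$water))
}

# noise-free kernel evaluation (the generating closed form)
kernel_eval <- function(params, medium, r, theta_deg, phi_deg,
                        reference_dose_rate = 1344.14) {
  K <- kernel_norm(params, reference_dose_rate)
  K / r^2 * params$medium_scale[[medium]] *
    attenuation_factor(r, params$attenuation_coeffs[[medium]]) *
    polar_profile(theta_deg, params$polar_coeffs) *
    azimuthal_factor(phi_deg, params$azimuthal_amplitude, params$azimuthal_phase_deg)
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic dose-rate grid
#'
#' Evaluates the parametric dose kernel at every voxel centre of a regular
#' lattice, standing in for a Monte Carlo dose calculation. The overall scale
#' `K` is chosen so that the azimuthally averaged, noise-free transverse dose
#' at r = 1 cm in water equals `reference_dose_rate`; the same `K` is used
#' for every medium so water and ABS grids generated from one parameter set
#' are mutually consistent. Any voxel whose centre coincides with the source
#' (r = 0) is flagged `NA` rather than given a value. Deterministic for a
#' fixed seed.
#'
#' @param spec a [source_spec].
#' @param params a [kernel_params].
#' @param medium `"water"` or `"abs"`.
#' @param grid_shape integer vector (nx, ny, nz) of voxel counts.
#' @param voxel_mm voxel edge length, mm.
#' @param reference_dose_rate water transverse dose rate at 1 cm,
#'   cGy h^-1 uA^-1 (default 1344.14).
#' @return a [dose_grid].
#' @export
generate_dose_grid <- function(spec, params, medium = c("water", "abs"),
                               grid_shape = c(105, 105, 105), voxel_mm = 1,
                               reference_dose_rate = 1344.14) {
  medium <- match.arg(medium)
  stopifnot(inherits(spec, "source_spec"), inherits(params, "kernel_params"))
  if (length(grid_shape) != 3L || any(grid_shape < 2))
    stop("grid_shape must be three counts >= 2")
  if (params$noise_sd > 0 && is.null(params$seed))
    stop("a seed must be set when noise_sd > 0")
  origin <- (grid_shape + 1) / 2 + spec$source_origin_cm * 10 / voxel_mm
  if (any(origin < 1) || any(origin > grid_shape))
    stop("source origin lies outside the grid")
  xs <- (seq_len(grid_shape[1]) - origin[1]) * voxel_mm / 10
  ys <- (seq_len(grid_shape[2]) - origin[2]) * voxel_mm / 10
  zs <- (seq_len(grid_shape[3]) - origin[3]) * voxel_mm / 10
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  r <- sqrt(r2)
  n <- length(r)
  cos_t <- array(rep(zs, each = grid_shape[1] * grid_shape[2]), dim(r2)) / r
  theta <- acos(pmin(pmax(cos_t, -1), 1)) * 180 / pi
  phi2d <- outer(xs, ys, function(a, b) atan2(b, a)) * 180 / pi
  ripple <- azimuthal_factor(phi2d, params$azimuthal_amplitude,
                             params$azimuthal_phase_deg)
  K <- kernel_norm(params, reference_dose_rate)
  vals <- K / r2 * params$medium_scale[[medium]] *
    attenuation_factor(r, params$attenuation_coeffs[[medium]]) *
    polar_profile(theta, params$polar_coeffs) *
    array(rep(ripple, grid_shape[3]), dim(r2))
  vals[r == 0] <- NA_real_  # singular source voxel, flagged unusable
  if (params$noise_sd > 0) {
    noise <- with_preserved_rng(params$seed,
                                stats::rnorm(n, 0, params$noise_sd))
    vals <- vals * pmax(1 + array(noise, dim(r2)), 0)
  }
  dose_grid(vals, voxel_mm = voxel_mm, origin = origin, medium = medium,
            meta = list(seed = params$seed, noise_sd = params$noise_sd,
                        reference_dose_rate = reference_dose_rate,
                        kernel = "inverse-square x mixture attenuation x polar x ripple"))
}

#' Transverse depth-dose curve
#'
#' @param radii strictly increasing radial distances, cm.
#' @param doses dose rates, cGy h^-1 uA^-1; must be positive.
#' @param medium `"water"` or `"abs"`.
#' @return an object of class `depth_dose_curve` (a data.frame with columns
#'   `r_cm`, `dose` and a `medium` attribute).
#' @export
depth_dose_curve <- function(radii, doses, medium = c("water", "abs")) {
  medium <- match.arg(medium)
  if (length(radii) != length(doses)) stop("radii and doses differ in length")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(doses <= 0)) stop("doses must be positive")
  structure(data.frame(r_cm = radii, dose = doses),
            medium = medium, class = c("depth_dose_curve", "data.frame"))
}

#' Extract the transverse depth-dose curve from a grid
#'
#' Returns the azimuthally averaged dose in the transverse plane
#' (theta = 90 degrees) at each requested radius, by trilinear interpolation
#' around the transverse ring.
#'
#' @param grid a [dose_grid].
#' @param radii radial distances in cm; all must lie inside the grid.
#' @param phi_step_deg azimuthal sampling step for the ring average.
#' @return a [depth_dose_curve].
#' @export
extract_depth_dose <- function(grid, radii, phi_step_deg = 2.5) {
  stopifnot(inherits(grid, "dose_grid"))
  if (any(radii <= 0)) stop("radii must be positive")
  phis <- seq(0, 360 - phi_step_deg, by = phi_step_deg) * pi / 180
  doses <- vapply(radii, function(r) {
    pts <- cbind(r * cos(phis), r * sin(phis), 0)
    mean(dose_at(grid, pts))
  }, 0)
  depth_dose_curve(radii, doses, grid$medium)
}

#' Sample the dose on a film plane parallel to the tube axis
#'
#' The film lies in a plane at perpendicular distance `offset_cm` from the
#' source axis (the experimental geometry places it 1 cm below the tube).
#' In-plane coordinates are `u` along the tube axis (+z) and `v` lateral;
#' the plane normal is +y. The map value at (u, v) is the grid dose
#' trilinearly interpolated at position (x = v, y = offset, z = u), i.e. at
#' polar coordinates r = sqrt(u^2 + v^2 + offset^2),
#' theta = arccos(u / r).
#'
#' @param grid a [dose_grid].
#' @param offset_cm perpendicular source-axis-to-plane distance, cm (> 0).
#' @param u_cm,v_cm in-plane sample coordinates (defaults: 0.3387 mm pitch,
#'   the 75 dpi scan pitch, spanning what the grid supports).
#' @param pixel_mm pixel pitch used for the default coordinate vectors.
#' @return an object of class `film_plane_map`: list with `u_cm`, `v_cm`,
#'   `dose` (length(u) x length(v) matrix), `offset_cm`, `pixel_mm`.
#' @export
sample_film_plane <- function(grid, offset_cm = 1, u_cm = NULL, v_cm = NULL,
                              pixel_mm = 25.4 / 75) {
  stopifnot(inherits(grid, "dose_grid"))
  if (offset_cm <= 0) stop("offset_cm must be positive")
  co <- grid_coords(grid)
  if (offset_cm > max(co$y)) stop("film plane offset lies outside the grid")
  if (is.null(u_cm)) {
    ext <- min(abs(min(co$z)), max(co$z)) - grid$voxel_mm / 10
    u_cm <- seq(-ext, ext, by = pixel_mm / 10)
  }
  if (is.null(v_cm)) {
    ext <- min(abs(min(co$x)), max(co$x)) - grid$voxel_mm / 10
    v_cm <- seq(-ext, ext, by = pixel_mm / 10)
  }
  pts <- cbind(rep(v_cm, each = length(u_cm)), offset_cm,
               rep(u_cm, times = length(v_cm)))
  vals <- matrix(dose_at(grid, pts), nrow = length(u_cm))
  structure(list(u_cm = u_cm, v_cm = v_cm, dose = vals,
                 offset_cm = offset_cm, pixel_mm = pixel_mm,
                 medium = grid$medium),
            class = "film_plane_map")
}
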