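# shared synthetic-kernel configurations for the tests

test_spec <- function() source_spec()

# pure inverse-square kernel: no attenuation, isotropic, no ripple/noise
params_inverse_square <- function(ripple = 0, noise_sd = 0, seed = NULL) {
  kernel_params(
    medium_scale = c(water = 1, abs = 1),
    attenuation_coeffs = list(water = c(w = 1, mu_fast = 0, mu_slow = 0),
                              abs = c(w = 1, mu_fast = 0, mu_slow = 0)),
    polar_coeffs = 0, azimuthal_amplitude = ripple,
    azimuthal_phase_deg = 150, noise_sd = noise_sd, seed = seed)
}

# single-exponential water attenuation, everything else trivial
params_single_exp <- function(mu = 0.2) {
  kernel_params(
    medium_scale = c(water = 1, abs = 1),
    attenuation_coeffs = list(water = c(w = 1, mu_fast = mu, mu_slow = mu),
                              abs = c(w = 1, mu_fast = 0, mu_slow = 0)),
    polar_coeffs = 0)
}

# small fast grids for unit tests (coarser voxels, truncated phantom)
small_grid <- function(params, medium = "water", half_cm = 4.4, voxel_mm = 2,
                       reference = 1000) {
  n <- 2L * ceiling(half_cm * 10 / voxel_mm) + 1L
  generate_dose_grid(test_spec(), params, medium, grid_shape = rep(n, 3),
                     voxel_mm = voxel_mm, reference_dose_rate = reference)
}

# closed-form kernel dose (the generating model), for recovery oracles
kernel_closed_form <- function(params, medium, r, theta_deg, phi_deg = 0,
                               reference = 1000) {
  cw <- params$medium_scale[["water"]]
  K <- reference / (cw * attenuation_factor(1, params$attenuation_coeffs$water))
  K / r^2 * params$medium_scale[[medium]] *
    attenuation_factor(r, params$attenuation_coeffs[[medium]]) *
    polar_profile(theta_deg, params$polar_coeffs) *
    (1 + params$azimuthal_amplitude *
       sinpi((2 * phi_deg + params$azimuthal_phase_deg) / 180))
}

table1_fixture <- function() load_fixtures(verify_checksums = FALSE)$table1
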