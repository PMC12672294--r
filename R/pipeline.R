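#' Bin mapped film pixels onto a polar (r, theta) lattice
#'
#' Averages film-plane samples (from [map_film_plane_to_polar()]) into
#' lattice cells `|r - R| <= r_tol`, `|theta - T| <= theta_tol`, keeping a
#' cell valid only when it contains at least `min_n` valid pixels. Within a
#' cell each sample is referred to the node radius through the inverse-square
#' geometry factor (`dose * r^2 / R^2`) before averaging; without this the
#' cell at the reference point -- where the film plane is tangent to the
#' r = r0 sphere and every pixel sits at r > r0 -- would be biased low by
#' several percent.
#'
#' @param samples a [polar_dose_samples] data.frame (typically every film
#'   pixel, with its measurability mask).
#' @param radii,theta_deg lattice node positions.
#' @param r_tol_cm,theta_tol_deg half-widths of a lattice cell.
#' @param min_n minimum pixel count for a valid cell.
#' @return a [polar_dose_samples] data.frame on the full lattice with
#'   validity mask.
#' @export
bin_polar_samples <- function(samples, radii, theta_deg,
                              r_tol_cm = 0.05, theta_tol_deg = 1, min_n = 3) {
  stopifnot(inherits(samples, "polar_dose_samples"))
  ok <- samples$valid & !is.na(samples$dose)
  out <- expand.grid(r_cm = radii, theta_deg = theta_deg,
                     KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(R, Th) {
    sel <- ok & abs(samples$r_cm - R) <= r_tol_cm &
      abs(samples$theta_deg - Th) <= theta_tol_deg
    n <- sum(sel)
    c(if (n >= min_n)
        mean(samples$dose[sel] * samples$r_cm[sel]^2) / R^2
      else NA_real_, n)
  }, out$r_cm, out$theta_deg)
  polar_dose_samples(out$r_cm, out$theta_deg, res[1, ],
                     valid = !is.na(res[1, ]))
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Defaults reproduce the
#' study design: 1 mm voxels, the 22 tabulated radii from 1.0 to 5.0 cm,
#' polar angles 0-90 degrees in 10-degree steps (film-valid subset starting
#' at 20 degrees), azimuthal sampling every 30 degrees from 0 to 180, the
#' reference point at r0 = 1 cm / theta0 = 90 degrees, and the film plane
#' 1 cm below the source.
#'
#' @param seed integer; drives every random stage.
#' @param params a [kernel_params]; defaults to the calibrated
#'   [default_kernel_params()] with this seed.
#' @param half_extent_cm half-width of the simulated (truncated) phantom
#'   cube, cm.
#' @param voxel_mm scoring voxel size, mm.
#' @param radii radial distances, cm (strictly increasing).
#' @param theta_deg polar angles, degrees.
#' @param phi_deg azimuthal angles, degrees (must include 0).
#' @param r0_cm,theta0_deg reference point.
#' @param film_offset_cm film plane distance below the source axis, cm.
#' @param film_theta_min_deg minimum measurable polar angle on film.
#' @param reference_dose_rate water transverse dose rate at 1 cm,
#'   cGy h^-1 uA^-1.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, params = NULL,
                            half_extent_cm = 5.2, voxel_mm = 1,
                            radii = c(1, 1.1, 1.2, seq(1.4, 5, by = 0.2)),
                            theta_deg = seq(0, 90, by = 10),
                            phi_deg = seq(0, 180, by = 30),
                            r0_cm = 1, theta0_deg = 90,
                            film_offset_cm = 1, film_theta_min_deg = 20,
                            reference_dose_rate = 1344.14) {
  if (r0_cm <= 0) stop("r0 must be positive")
  if (any(diff(radii) <= 0)) stop("radius set must be strictly increasing")
  if (!any(abs(phi_deg) < 1e-9)) stop("phi = 0 must be among the azimuths")
  if (is.null(params)) params <- default_kernel_params(seed = seed)
  radii <- round(radii, 6)
  structure(list(seed = seed, params = params,
                 half_extent_cm = half_extent_cm, voxel_mm = voxel_mm,
                 radii = radii, theta_deg = theta_deg, phi_deg = phi_deg,
                 r0_cm = r0_cm, theta0_deg = theta0_deg,
                 film_offset_cm = film_offset_cm,
                 film_theta_min_deg = film_theta_min_deg,
                 reference_dose_rate = reference_dose_rate),
            class = "pipeline_config")
}

# stable polynomial rolling hash of the configuration for provenance lines
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# deterministic synthetic film chain: known cubic calibration, image built
# by inverting it, then converted back through the film module
film_chain <- function(plane, seed) {
  cal_points <- data.frame(netOD = seq(0, 0.35, length.out = 8))
  cal_points$dose_cGy <- 3000 * cal_points$netOD + 800 * cal_points$netOD^2 +
    4000 * cal_points$netOD^3
  cal <- fit_calibration(cal_points, channel = "red")
  grid_od <- seq(0, 0.35, by = 1e-4)
  od_of_dose <- stats::approxfun(predict(cal, grid_od), grid_od)
  pv_unexposed <- 42000; pv_background <- 1200
  od <- od_of_dose(pmin(plane$dose, max(cal_points$dose_cGy)))
  pv <- round((pv_unexposed - pv_background) * 10^(-od) + pv_background)
  dm <- film_to_dose(matrix(pv, nrow(plane$dose)), cal,
                     pv_unexposed = pv_unexposed,
                     pv_background = pv_background)
  list(calibration = cal, dose_map = dm,
       map = list(u_cm = plane$u_cm, v_cm = plane$v_cm, dose = dm$dose,
                  offset_cm = plane$offset_cm))
}

#' Run the end-to-end dosimetric characterization
#'
#' Executes the full analysis: simulate ABS and water dose grids with the
#' synthetic kernel; extract transverse depth-dose curves; derive the
#' distance-dependent ABS-to-water conversion function; extract ABS-side
#' TG-43 parameters along two routes (directly from the grid, and through
#' the film plane including the netOD calibration round trip); convert the
#' ABS parameters to water and compare them with the directly simulated
#' water parameters; evaluate the azimuthal dependence and the per-region
#' Monte-Carlo-style uncertainty estimators; and assemble the measurement
#' uncertainty budget. When `out_dir` is given every table is written as
#' CSV plus a plain-text summary with provenance (seed, configuration hash,
#' package version); outputs are byte-identical for identical seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the report bundle.
#' @return a list of class `mxt43_pipeline` (see elements in the summary).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- source_spec()
  n1 <- 2L * ceiling(config$half_extent_cm * 10 / config$voxel_mm) + 1L
  shape <- rep(n1, 3)
  pw <- config$params; pw$seed <- config$seed
  pa <- config$params; pa$seed <- config$seed + 1L
  grid_w <- generate_dose_grid(spec, pw, "water", shape, config$voxel_mm,
                               config$reference_dose_rate)
  grid_a <- generate_dose_grid(spec, pa, "abs", shape, config$voxel_mm,
                               config$reference_dose_rate)

  dd_w <- extract_depth_dose(grid_w, config$radii)
  dd_a <- extract_depth_dose(grid_a, config$radii)
  cf <- derive_cf(dd_w, dd_a)

  # ABS-side parameters, grid route
  lambda_abs <- dose_rate_constant(
    transverse_reference_dose(dd_a$r_cm, dd_a$dose, config$r0_cm))
  g_abs <- radial_dose_function(dd_a, r0 = config$r0_cm)
  samp_a <- extract_polar_samples(grid_a, config$radii, config$theta_deg)
  f_abs <- anisotropy_function(samp_a, theta0_deg = config$theta0_deg)

  # ABS-side parameters, film route (plane sampling + netOD round trip)
  plane <- sample_film_plane(grid_a, offset_cm = config$film_offset_cm)
  chain <- film_chain(plane, config$seed)
  film_samples <- map_film_plane_to_polar(chain$map,
                                          theta_min_deg = config$film_theta_min_deg)
  film_thetas <- config$theta_deg[config$theta_deg >= config$film_theta_min_deg]
  film_lattice <- bin_polar_samples(film_samples, config$radii,
                                    unique(c(film_thetas, config$theta0_deg)))
  # the reference-point film reading is the pixel right below the source
  iu <- which.min(abs(chain$map$u_cm)); iv <- which.min(abs(chain$map$v_cm))
  lambda_abs_film <- dose_rate_constant(chain$map$dose[iu, iv])
  f_film <- suppressWarnings(
    anisotropy_function(film_lattice, theta0_deg = config$theta0_deg))
  g_film <- radial_dose_function(film_lattice, r0 = config$r0_cm,
                                 theta0_deg = config$theta0_deg)

  # conversion to water and comparisons against the direct water simulation
  lambda_water <- apply_cf(lambda_abs, cf, r = config$r0_cm)
  g_water_conv <- apply_cf(g_abs, cf)
  g_water <- radial_dose_function(dd_w, r0 = config$r0_cm)
  samp_w <- extract_polar_samples(grid_w, config$radii, config$theta_deg)
  f_water <- anisotropy_function(samp_w, theta0_deg = config$theta0_deg)
  cmp_g_ratio <- compare_tables(g_water, g_abs, "ratio")
  cmp_g_conv <- compare_tables(g_water_conv, g_water, "difference")
  cmp_f <- compare_tables(f_film, f_abs, "ratio")

  # azimuthal dependence at the reference ring (transverse plane)
  az_pts <- cbind(config$r0_cm * cospi(config$phi_deg / 180),
                  config$r0_cm * sinpi(config$phi_deg / 180), 0)
  az <- azimuthal_ratios(data.frame(phi_deg = config$phi_deg,
                                    dose = dose_at(grid_a, az_pts)))

  # per-region uncertainty estimators and the packaged budget
  geo <- vapply(c(1, 3), function(r)
    mc_geometric_uncertainty(transverse_ring_doses(grid_a, r)), 0)
  budget <- default_budget()

  res <- structure(list(
    config = config, cf = cf,
    depth_dose = list(water = dd_w, abs = dd_a),
    lambda = c(abs = lambda_abs, abs_film = lambda_abs_film,
               water = lambda_water),
    g = list(abs = g_abs, abs_film = g_film, water = g_water,
             water_converted = g_water_conv),
    f = list(abs = f_abs, abs_film = f_film, water = f_water),
    comparisons = list(g_water_over_abs = cmp_g_ratio,
                       g_converted_minus_water = cmp_g_conv,
                       f_film_over_grid = cmp_f),
    azimuthal = az,
    geometric_uncertainty_pct = c(`1cm` = geo[1], `3cm` = geo[2]),
    budget = budget,
    film = list(calibration = chain$calibration,
                n_out_of_range = chain$dose_map$n_out_of_range,
                n_saturated = chain$dose_map$n_saturated)),
    class = "mxt43_pipeline")
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

#' @export
print.mxt43_pipeline <- function(x, ...) {
  cat("<mxt43_pipeline> seed", x$config$seed, "\n")
  cat(sprintf("  dose-rate constant: ABS %.2f (film route %.2f), water %.2f cGy/h/uA\n",
              x$lambda["abs"], x$lambda["abs_film"], x$lambda["water"]))
  cat(sprintf("  CF(%g cm) = %.4f, CF(%g cm) = %.4f, relative RMSE %.3g\n",
              min(x$cf$radii), x$cf$cf_values[1],
              max(x$cf$radii), x$cf$cf_values[length(x$cf$cf_values)],
              x$cf$rmse))
  cat(sprintf("  azimuthal max ratio %.3f at %g deg\n",
              attr(x$azimuthal, "max_ratio"), attr(x$azimuthal, "max_phi_deg")))
  cat(sprintf("  total budget uncertainty %.2f%%\n", x$budget$total))
  invisible(x)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Write the pipeline report bundle
#'
#' CSV tables for every derived parameter set plus `summary.md` with
#' provenance (seed, configuration hash, package version). Deterministic:
#' identical seeds give byte-identical files.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(result, out_dir) {
  stopifnot(inherits(result, "mxt43_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  for (m in names(result$g))
    write_csv_plain(result$g[[m]], p(sprintf("g_%s.csv", m)))
  for (m in names(result$f))
    write_csv_plain(result$f[[m]], p(sprintf("f_%s.csv", m)))
  write_csv_plain(data.frame(r_cm = result$cf$radii, cf = result$cf$cf_values),
                  p("cf.csv"))
  write_csv_plain(as.data.frame(result$azimuthal), p("azimuthal.csv"))
  write_csv_plain(result$budget$components, p("budget_components.csv"))
  cmp <- result$comparisons
  sm <- c(
    "# Dosimetric characterization report", "",
    sprintf("- seed: %d", result$config$seed),
    sprintf("- config hash: %s", config_hash(result$config)),
    sprintf("- package: mxt43 %s", as.character(utils::packageVersion("mxt43"))),
    sprintf("- voxel: %g mm, half extent: %g cm", result$config$voxel_mm,
            result$config$half_extent_cm), "",
    sprintf("- dose-rate constant (ABS, grid): %.4f cGy/h/uA", result$lambda["abs"]),
    sprintf("- dose-rate constant (ABS, film): %.4f cGy/h/uA", result$lambda["abs_film"]),
    sprintf("- dose-rate constant (water): %.4f cGy/h/uA", result$lambda["water"]),
    sprintf("- CF at r0: %.4f; CF at %g cm: %.4f; relative RMSE: %.5f",
            cf_value(result$cf, result$config$r0_cm),
            max(result$cf$radii),
            result$cf$cf_values[length(result$cf$cf_values)], result$cf$rmse),
    sprintf("- water/ABS g ratio: mean %.4f, sd %.4f",
            cmp$g_water_over_abs$mean, cmp$g_water_over_abs$sd),
    sprintf("- converted-vs-direct water g: mean diff %.5f, max |diff| %.5f",
            cmp$g_converted_minus_water$mean, cmp$g_converted_minus_water$max_abs),
    sprintf("- film/grid F ratio: mean %.4f, max %.4f",
            cmp$f_film_over_grid$mean, cmp$f_film_over_grid$max_abs),
    sprintf("- azimuthal max ratio: %.4f at %g deg",
            attr(result$azimuthal, "max_ratio"),
            attr(result$azimuthal, "max_phi_deg")),
    sprintf("- geometric uncertainty: %.2f%% at 1 cm, %.2f%% at 3 cm",
            result$geometric_uncertainty_pct[1],
            result$geometric_uncertainty_pct[2]),
    sprintf("- film pixels out of calibration range: %d; saturated: %d",
            result$film$n_out_of_range, result$film$n_saturated),
    sprintf("- budget: Type A %.2f%%, Type B %.2f%%, total %.2f%%",
            result$budget$quadrature_sum_A, result$budget$quadrature_sum_B,
            result$budget$total))
  writeLines(sm, p("summary.md"))
  invisible(out_dir)
}
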