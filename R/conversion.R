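#' Derive the distance-dependent ABS-to-water conversion function
#'
#' The conversion factor CF(r) is the ratio of the water and ABS transverse
#' depth-dose curves, `CF(r) = D_water(r) / D_ABS(r)`, evaluated on the
#' radii common to both curves (curves on different lattices are first
#' interpolated -- monotone cubic in log dose -- onto the overlap). The
#' default fit form keeps the pointwise ratios and interpolates between them
#' with a monotone cubic; a low-order polynomial fit is optional. The
#' relative, dose-weighted RMSE between the converted ABS curve and the
#' direct water curve on the derivation radii is stored as the CF
#' uncertainty.
#'
#' @param water,abs_curve [depth_dose_curve]s in water and ABS.
#' @param fit_form `"pointwise"` (default) or `"polynomial"`.
#' @param degree polynomial degree when `fit_form = "polynomial"`.
#' @return an object of class `conversion_function`: `radii`, `cf_values`,
#'   `fit_form`, `fit_coeffs` (polynomial form only), `rmse`.
#' @export
derive_cf <- function(water, abs_curve, fit_form = c("pointwise", "polynomial"),
                      degree = 2) {
  fit_form <- match.arg(fit_form)
  stopifnot(inherits(water, "depth_dose_curve"),
            inherits(abs_curve, "depth_dose_curve"))
  if (any(water$dose <= 0) || any(abs_curve$dose <= 0))
    stop("doses must be positive")
  lo <- max(min(water$r_cm), min(abs_curve$r_cm))
  hi <- min(max(water$r_cm), max(abs_curve$r_cm))
  if (lo >= hi) stop("depth-dose curves do not overlap in radius")
  same <- isTRUE(all.equal(water$r_cm, abs_curve$r_cm, tolerance = 1e-9))
  radii <- if (same) water$r_cm else {
    r <- sort(unique(c(water$r_cm, abs_curve$r_cm)))
    r[r >= lo & r <= hi]
  }
  at <- function(curve, r) {
    if (length(curve$r_cm) >= 4)
      exp(stats::splinefun(curve$r_cm, log(curve$dose), method = "monoH.FC")(r))
    else exp(stats::approx(curve$r_cm, log(curve$dose), xout = r)$y)
  }
  dw <- at(water, radii); da <- at(abs_curve, radii)
  cf <- dw / da
  coeffs <- NULL
  if (fit_form == "polynomial") {
    fit <- stats::lm(cf ~ stats::poly(radii, degree, raw = TRUE))
    coeffs <- unname(stats::coef(fit))
  }
  out <- structure(list(radii = radii, cf_values = cf, fit_form = fit_form,
                        fit_coeffs = coeffs, rmse = 0),
                   class = "conversion_function")
  out$rmse <- cf_rmse(out, water, abs_curve)
  out
}

#' Evaluate a conversion function at given radii
#'
#' @param cf a [derive_cf()] result.
#' @param r radii in cm. Extrapolation beyond the derivation range is an
#'   error unless `allow_extrapolation = TRUE`.
#' @param allow_extrapolation permit evaluation outside the derivation
#'   range (constant-endpoint for the pointwise form).
#' @return CF values at `r`.
#' @export
cf_value <- function(cf, r, allow_extrapolation = FALSE) {
  stopifnot(inherits(cf, "conversion_function"))
  rng <- range(cf$radii)
  if (!allow_extrapolation && any(r < rng[1] - 1e-9 | r > rng[2] + 1e-9))
    stop("radius outside the conversion-function range [", rng[1], ", ",
         rng[2], "] cm; extrapolation must be requested explicitly")
  if (cf$fit_form == "polynomial") {
    out <- rep(cf$fit_coeffs[1], length(r))
    for (k in seq_len(length(cf$fit_coeffs) - 1))
      out <- out + cf$fit_coeffs[k + 1] * r^k
    return(out)
  }
  rc <- pmin(pmax(r, rng[1]), rng[2])
  if (length(cf$radii) >= 4)
    stats::splinefun(cf$radii, cf$cf_values, method = "monoH.FC")(rc)
  else stats::approx(cf$radii, cf$cf_values, xout = rc)$y
}

#' @export
print.conversion_function <- function(x, ...) {
  cat("<conversion_function> ", x$fit_form, " over [",
      min(x$radii), ", ", max(x$radii), "] cm\n", sep = "")
  cat(sprintf("  CF(%g) = %.4f ... CF(%g) = %.4f, relative RMSE %.3g\n",
              min(x$radii), x$cf_values[1], max(x$radii),
              x$cf_values[length(x$cf_values)], x$rmse))
  invisible(x)
}

#' Apply a conversion function to an ABS-measured quantity
#'
#' Doses are converted multiplicatively: `value * CF(r)`. A radial-dose
#' table (class `g_table`) is converted pointwise and then renormalized so
#' that `g(r0) = 1` again (mandatory for normalized quantities); a
#' [depth_dose_curve] is converted pointwise and relabeled as water.
#'
#' @param x numeric value(s), a [depth_dose_curve], or a `g_table`.
#' @param cf a [derive_cf()] result.
#' @param r radii (cm) for numeric `x`; taken from the table otherwise.
#' @param allow_extrapolation passed to [cf_value()].
#' @return converted object of the same shape/class.
#' @export
apply_cf <- function(x, cf, r = NULL, allow_extrapolation = FALSE) {
  stopifnot(inherits(cf, "conversion_function"))
  if (inherits(x, "g_table")) {
    r0 <- attr(x, "r0")
    g <- x$g * cf_value(cf, x$r_cm, allow_extrapolation)
    g0 <- g[abs(x$r_cm - r0) < 1e-9]
    if (!length(g0)) {
      if (length(x$r_cm) >= 4)
        g0 <- stats::splinefun(x$r_cm, g, method = "monoH.FC")(r0)
      else g0 <- stats::approx(x$r_cm, g, xout = r0)$y
    }
    g <- g / g0[1]
    g[abs(x$r_cm - r0) < 1e-9] <- 1
    return(structure(data.frame(r_cm = x$r_cm, g = g), r0 = r0,
                     class = c("g_table", "data.frame")))
  }
  if (inherits(x, "depth_dose_curve")) {
    return(depth_dose_curve(x$r_cm,
                            x$dose * cf_value(cf, x$r_cm, allow_extrapolation),
                            medium = "water"))
  }
  if (is.null(r)) stop("`r` is required for plain numeric values")
  x * cf_value(cf, r, allow_extrapolation)
}

#' Residual error of a conversion function
#'
#' Relative, dose-weighted root-mean-square error of the converted ABS curve
#' against the direct water curve:
#' `sqrt(mean(((CF(r) D_ABS(r) - D_water(r)) / D_water(r))^2))` over the
#' shared radii.
#'
#' @param cf a [derive_cf()] result.
#' @param water,abs_curve the two [depth_dose_curve]s.
#' @return relative RMSE (dimensionless).
#' @export
cf_rmse <- function(cf, water, abs_curve) {
  stopifnot(inherits(cf, "conversion_function"))
  common <- intersect(round(water$r_cm, 9), round(abs_curve$r_cm, 9))
  common <- common[common >= min(cf$radii) - 1e-9 & common <= max(cf$radii) + 1e-9]
  if (!length(common)) stop("no shared radii to evaluate the RMSE on")
  dw <- water$dose[match(common, round(water$r_cm, 9))]
  da <- abs_curve$dose[match(common, round(abs_curve$r_cm, 9))]
  rel <- (cf_value(cf, common) * da - dw) / dw
  sqrt(mean(rel^2))
}
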