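#' Net optical density of radiochromic film
#'
#' Standard background-subtracted log-ratio convention:
#' `netOD = log10((pv_unexposed - pv_background) / (pv_exposed - pv_background))`.
#' Exposure darkens the film (lowers the pixel value), so netOD is
#' non-negative for exposed film.
#'
#' @param pv_exposed,pv_unexposed,pv_background scanner pixel values
#'   (vectorized; matrices allowed). Net signals must be positive.
#' @return netOD, same shape as `pv_exposed`.
#' @export
compute_netOD <- function(pv_exposed, pv_unexposed, pv_background = 0) {
  net_u <- pv_unexposed - pv_background
  net_e <- pv_exposed - pv_background
  if (any(net_u <= 0)) stop("unexposed signal must exceed background")
  if (any(net_e <= 0)) stop("exposed signal must exceed background")
  log10(net_u / net_e)
}

#' Fit a film calibration curve
#'
#' Least-squares third-order polynomial mapping netOD to dose (dose as a
#' cubic in netOD, the conventional direction). The fit is refused when the
#' calibrated dose response is not monotone non-decreasing over the
#' calibrated netOD range, or when the design is rank-deficient (duplicated
#' netOD values).
#'
#' @param points data.frame with columns `netOD` and `dose_cGy` (at least 4
#'   distinct netOD values).
#' @param channel scanner color channel the calibration applies to.
#' @return an object of class `film_calibration`: coefficients (intercept
#'   first), calibration points, residual SD (cGy) and netOD range.
#' @export
fit_calibration <- function(points, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(points),
            all(c("netOD", "dose_cGy") %in% names(points)))
  if (anyDuplicated(points$netOD))
    stop("duplicated netOD values make the design rank-deficient")
  if (length(unique(points$netOD)) < 4)
    stop("at least 4 distinct netOD values are required for a cubic fit")
  fit <- stats::lm(dose_cGy ~ netOD + I(netOD^2) + I(netOD^3), data = points)
  co <- unname(stats::coef(fit))
  rng <- c(min(0, min(points$netOD)), max(points$netOD))
  grid <- seq(rng[1], rng[2], length.out = 401)
  deriv <- co[2] + 2 * co[3] * grid + 3 * co[4] * grid^2
  scale <- max(abs(points$dose_cGy)) / max(diff(rng), 1e-12)
  if (any(deriv < -1e-8 * max(scale, 1)))
    stop("fitted dose response is not monotone non-decreasing over the ",
         "calibrated netOD range [", round(rng[1], 4), ", ",
         round(rng[2], 4), "]; refusing the calibration")
  res <- stats::residuals(fit)
  dfres <- fit$df.residual
  residual_sd <- if (dfres > 0) sqrt(sum(res^2) / dfres) else 0
  if (abs(co[1]) > max(3 * residual_sd, 1e-6))
    warning("dose at netOD = 0 (", signif(co[1], 3),
            " cGy) is not within the fit residual of zero")
  structure(list(channel = channel, poly_coeffs = co,
                 calibration_points = points, fit_residual_sd = residual_sd,
                 netod_range = rng),
            class = "film_calibration")
}

#' Evaluate a film calibration polynomial
#'
#' @param object a [fit_calibration()] result.
#' @param netOD netOD values (vectorized).
#' @param ... unused.
#' @return predicted dose in cGy.
#' @export
predict.film_calibration <- function(object, netOD, ...) {
  co <- object$poly_coeffs
  co[1] + co[2] * netOD + co[3] * netOD^2 + co[4] * netOD^3
}

#' @export
print.film_calibration <- function(x, ...) {
  cat("<film_calibration> channel =", x$channel, "\n")
  cat("  dose(netOD) =", paste(signif(x$poly_coeffs, 6),
                               c("", "netOD", "netOD^2", "netOD^3"),
                               collapse = " + "), "\n")
  cat(sprintf("  %d points, residual SD %.3g cGy, netOD range [%.3g, %.3g]\n",
              nrow(x$calibration_points), x$fit_residual_sd,
              x$netod_range[1], x$netod_range[2]))
  invisible(x)
}

#' Convert a scanned film image to a planar dose map
#'
#' Pixelwise netOD followed by the calibration polynomial. Pixels whose
#' netOD lies above the calibrated range are set `NA` and flagged rather
#' than extrapolated; saturated pixels are flagged too.
#'
#' @param pixel_values numeric matrix of scanner pixel values for the
#'   calibration's channel.
#' @param calibration a [fit_calibration()] result.
#' @param pv_unexposed unexposed-film reference pixel value (scalar or
#'   matrix).
#' @param pv_background scanner background (opaque) pixel value.
#' @param saturation_level pixel value at or above which the scanner is
#'   saturated (default 65535 for 16-bit scans).
#' @return an object of class `film_dose_map`: `dose` matrix (cGy), `flags`
#'   matrix (0 ok, 1 netOD out of range, 2 saturated) and counts
#'   `n_out_of_range`, `n_saturated`.
#' @export
film_to_dose <- function(pixel_values, calibration, pv_unexposed,
                         pv_background = 0, saturation_level = 65535) {
  stopifnot(inherits(calibration, "film_calibration"))
  netod <- compute_netOD(pixel_values, pv_unexposed, pv_background)
  flags <- array(0L, dim = if (is.null(dim(netod))) length(netod) else dim(netod))
  oor <- netod > calibration$netod_range[2] + 1e-12
  sat <- pixel_values >= saturation_level
  flags[oor] <- 1L
  flags[sat] <- 2L
  dose <- predict(calibration, netod)
  dose[oor] <- NA_real_
  structure(list(dose = dose, flags = flags,
                 n_out_of_range = sum(oor), n_saturated = sum(sat)),
            class = "film_dose_map")
}

#' Map a film-plane dose map into TG-43 polar coordinates
#'
#' The film lies in a plane parallel to the tube axis at perpendicular
#' distance d (`offset_cm`) from it; a pixel at in-plane coordinates (u, v)
#' (u along the tube axis) sits at polar coordinates
#' `r = sqrt(u^2 + v^2 + d^2)`, `theta = arccos(u / r)`. A sample is
#' measurable only when `theta >= theta_min` (film directional dependence at
#' shallow polar angles) and `r sin(theta) >= d` (the geometric reach of an
#' off-axis plane; on the plane itself `r sin(theta) = sqrt(v^2 + d^2)`, so
#' this holds by construction but is asserted explicitly). Other samples are
#' masked, never dropped.
#'
#' @param map a `film_plane_map` (from [sample_film_plane()]) or a list with
#'   `u_cm`, `v_cm`, `dose` and `offset_cm`.
#' @param theta_min_deg minimum measurable polar angle, degrees (default 20).
#' @return a [polar_dose_samples] data.frame with `phi_deg` and validity
#'   mask.
#' @export
map_film_plane_to_polar <- function(map, theta_min_deg = 20) {
  stopifnot(!is.null(map$u_cm), !is.null(map$v_cm), !is.null(map$dose))
  d <- map$offset_cm
  if (is.null(d) || d <= 0) stop("plane offset must be positive")
  u <- rep(map$u_cm, times = length(map$v_cm))
  v <- rep(map$v_cm, each = length(map$u_cm))
  r <- sqrt(u^2 + v^2 + d^2)
  theta <- acos(pmin(pmax(u / r, -1), 1)) * 180 / pi
  phi <- atan2(d, v) * 180 / pi
  valid <- theta >= theta_min_deg & r * sinpi(theta / 180) >= d - 1e-9
  polar_dose_samples(r, theta, as.vector(map$dose), valid = valid,
                     phi_deg = phi)
}

#' Read one channel of a scanned film TIFF
#'
#' Film scans are 16-bit-per-channel RGB TIFF; pixel values are returned on
#' the native integer scale (0..65535).
#'
#' @param path TIFF file path.
#' @param channel color channel to extract.
#' @return integer pixel-value matrix.
#' @export
read_film_tiff <- function(path, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  img <- tiff::readTIFF(path, as.is = TRUE)
  # some TIFF encodings come back as 0-1 doubles; put them on the 16-bit scale
  if (max(img) <= 1 && any(img != round(img))) img <- round(img * 65535)
  if (length(dim(img)) == 3L)
    img <- img[, , match(channel, c("red", "green", "blue"))]
  img
}

#' Write a single- or three-channel 16-bit film TIFF
#'
#' Used to build synthetic film fixtures; values are clamped to 0..65535.
#'
#' @param pixel_values matrix (grey) or 3-D array (RGB) of pixel values on
#'   the 16-bit scale.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(pixel_values, path) {
  pv <- pmin(pmax(round(pixel_values), 0), 65535)
  tiff::writeTIFF(pv / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}
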