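#' Point-source geometry function G_P(r)
#'
#' The miniature tube is treated as a virtual point source, so the TG-43
#' geometry function is 1/r^2; the line-source variant is deliberately not
#' offered.
#'
#' @param r radial distance in cm; must be positive.
#' @return 1 / r^2 (cm^-2).
#' @export
geometry_function_point <- function(r) {
  if (any(r <= 0)) stop("r must be positive")
  1 / r^2
}

#' Polar dose samples
#'
#' Tabulated dose-rate samples on a polar (r, theta) lattice around the
#' source, the common currency between grid extraction, film mapping and the
#' TG-43 parameter computations. Reference convention: r0 = 1 cm,
#' theta0 = 90 degrees.
#'
#' @param r_cm radial distance, cm (> 0).
#' @param theta_deg polar angle from the tube axis, degrees, in \[0, 180\].
#' @param dose dose rate, cGy h^-1 uA^-1.
#' @param valid logical measurability flag (default `TRUE`).
#' @param phi_deg optional azimuthal angle of the sample, degrees.
#' @return a data.frame of class `polar_dose_samples`.
#' @export
polar_dose_samples <- function(r_cm, theta_deg, dose, valid = TRUE,
                               phi_deg = NULL) {
  if (any(r_cm <= 0)) stop("r must be positive")
  if (any(theta_deg < 0 | theta_deg > 180))
    stop("theta must be within [0, 180] degrees")
  df <- data.frame(r_cm = r_cm, theta_deg = theta_deg, dose = dose,
                   valid = rep_len(valid, length(r_cm)))
  if (!is.null(phi_deg)) df$phi_deg <- phi_deg
  class(df) <- c("polar_dose_samples", "data.frame")
  df
}

#' Extract polar dose samples from a dose grid
#'
#' For each requested (r, theta) pair the dose is averaged azimuthally and
#' over a narrow polar bin (2 degrees wide by default, mirroring voxel-ring
#' averaging) using trilinear interpolation.
#'
#' @param grid a [dose_grid].
#' @param radii radial distances, cm.
#' @param theta_deg polar angles, degrees.
#' @param theta_halfwidth_deg polar half-width of the averaging bin.
#' @param phi_step_deg azimuthal sampling step.
#' @return a [polar_dose_samples] data.frame over the full (r, theta) cross.
#' @export
extract_polar_samples <- function(grid, radii, theta_deg = seq(0, 90, by = 10),
                                  theta_halfwidth_deg = 1, phi_step_deg = 5) {
  stopifnot(inherits(grid, "dose_grid"))
  phis <- seq(0, 360 - phi_step_deg, by = phi_step_deg) * pi / 180
  out <- expand.grid(r_cm = radii, theta_deg = theta_deg,
                     KEEP.OUT.ATTRS = FALSE)
  out$dose <- mapply(function(r, th) {
    sub <- unique(pmin(pmax(th + c(-1, 0, 1) * theta_halfwidth_deg, 0), 180))
    pts <- do.call(rbind, lapply(sub * pi / 180, function(t) {
      if (sin(t) < 1e-12)  # ring degenerates to a single on-axis point
        matrix(c(0, 0, r * cos(t)), ncol = 3)
      else
        cbind(r * sin(t) * cos(phis), r * sin(t) * sin(phis), r * cos(t))
    }))
    mean(dose_at(grid, pts))
  }, out$r_cm, out$theta_deg)
  polar_dose_samples(out$r_cm, out$theta_deg, out$dose)
}

#' Dose-rate constant
#'
#' In the per-current convention used for electronic brachytherapy sources
#' the dose-rate constant is the reference-point dose rate per unit tube
#' current itself (cGy h^-1 uA^-1). The classical TG-43 convention divides
#' the reference dose rate by the air-kerma strength after unit
#' harmonization (cGy h^-1 over cGy cm^2 h^-1, giving cm^-2); both are
#' offered because the per-current form is the native one for a
#' current-controlled tube.
#'
#' @param reference_dose_rate dose rate at (r0 = 1 cm, theta0 = 90 deg);
#'   cGy h^-1 uA^-1 in per-current mode, cGy h^-1 in classical mode.
#' @param s_k air-kerma strength in Gy cm^2 min^-1 (classical mode only).
#' @param mode `"per_current"` (default) or `"classical"`.
#' @return the dose-rate constant (cGy h^-1 uA^-1, or cm^-2 in classical
#'   mode).
#' @export
dose_rate_constant <- function(reference_dose_rate, s_k = NULL,
                               mode = c("per_current", "classical")) {
  mode <- match.arg(mode)
  if (reference_dose_rate < 0) stop("reference dose rate must be >= 0")
  if (mode == "per_current") return(reference_dose_rate)
  if (is.null(s_k) || s_k <= 0)
    stop("classical mode needs a positive air-kerma strength")
  # 1 Gy cm^2 min^-1 = 100 cGy cm^2 min^-1 = 6000 cGy cm^2 h^-1
  reference_dose_rate / (s_k * 6000)
}

# interpolate the transverse dose at r0 (log-log, so that a pure
# inverse-square profile interpolates exactly)
transverse_reference_dose <- function(r, dose, r0) {
  hit <- which(abs(r - r0) < 1e-9)
  if (length(hit)) return(dose[hit[1]])
  if (r0 < min(r) || r0 > max(r))
    stop("no dose at r0 = ", r0, " and it is outside the sampled range")
  exp(stats::approx(log(r), log(dose), xout = log(r0))$y)
}

#' Radial dose function g(r)
#'
#' Transverse-plane dose falloff with the point-source geometric factor
#' removed: `g(r) = D(r, theta0) / D(r0, theta0) * (r / r0)^2`, normalized so
#' that `g(r0) = 1` exactly. Accepts a [depth_dose_curve] or a
#' [polar_dose_samples] table (its valid theta0 entries are used).
#'
#' @param x transverse doses: a [depth_dose_curve] or [polar_dose_samples].
#' @param r0 reference radial distance, cm (default 1).
#' @param theta0_deg transverse reference angle used when `x` is a polar
#'   sample table.
#' @return a data.frame of class `g_table` with columns `r_cm`, `g` and
#'   attribute `r0`.
#' @export
radial_dose_function <- function(x, r0 = 1, theta0_deg = 90) {
  if (inherits(x, "depth_dose_curve")) {
    r <- x$r_cm; dose <- x$dose
  } else if (inherits(x, "polar_dose_samples")) {
    sub <- x[x$valid & abs(x$theta_deg - theta0_deg) < 1e-9, ]
    if (!nrow(sub)) stop("no valid transverse (theta0) samples")
    sub <- sub[order(sub$r_cm), ]
    r <- sub$r_cm; dose <- sub$dose
  } else stop("x must be a depth_dose_curve or polar_dose_samples")
  if (any(dose <= 0)) stop("doses must be positive")
  d0 <- transverse_reference_dose(r, dose, r0)
  if (d0 <= 0) stop("zero dose at the reference distance")
  g <- dose / d0 * (r / r0)^2
  g[abs(r - r0) < 1e-9] <- 1  # exact at the normalization point
  structure(data.frame(r_cm = r, g = g), r0 = r0,
            class = c("g_table", "data.frame"))
}

#' Anisotropy function F(r, theta)
#'
#' With the theta-independent point-source geometry function the anisotropy
#' function reduces to `F(r, theta) = D(r, theta) / D(r, theta0)`, normalized
#' per radius to the transverse plane; `F(r, theta0) = 1` exactly. Radii
#' without a valid transverse reference are masked entirely (with a warning)
#' rather than silently filled.
#'
#' @param samples a [polar_dose_samples] data.frame.
#' @param theta0_deg transverse reference angle, degrees (default 90).
#' @return a data.frame of class `f_table` with columns `r_cm`, `theta_deg`,
#'   `F`, `valid`.
#' @export
anisotropy_function <- function(samples, theta0_deg = 90) {
  stopifnot(inherits(samples, "polar_dose_samples"))
  rs <- sort(unique(samples$r_cm))
  out <- NULL
  masked <- numeric(0)
  for (r in rs) {
    rows <- samples[abs(samples$r_cm - r) < 1e-9, ]
    ref <- rows[abs(rows$theta_deg - theta0_deg) < 1e-9 & rows$valid, ]
    if (!nrow(ref) || ref$dose[1] <= 0) {
      masked <- c(masked, r)
      out <- rbind(out, data.frame(r_cm = r, theta_deg = rows$theta_deg,
                                   F = NA_real_, valid = FALSE))
      next
    }
    Fv <- rows$dose / ref$dose[1]
    Fv[abs(rows$theta_deg - theta0_deg) < 1e-9] <- 1
    out <- rbind(out, data.frame(r_cm = r, theta_deg = rows$theta_deg,
                                 F = Fv, valid = rows$valid))
  }
  if (length(masked))
    warning("no valid transverse reference at r = ",
            paste(masked, collapse = ", "), " cm; those rows are masked")
  out$F[!out$valid] <- NA_real_
  structure(out[order(out$r_cm, out$theta_deg), ],
            theta0 = theta0_deg, class = c("f_table", "data.frame"))
}

#' Azimuthal dose ratios
#'
#' Ratios of the dose around the tube's long axis, normalized to the
#' 0-degree direction.
#'
#' @param doses_by_phi data.frame with columns `phi_deg` and `dose`.
#' @return data.frame of class `azimuthal_ratios` with columns `phi_deg`,
#'   `ratio`; attributes `max_ratio` and `max_phi_deg` report the maximum
#'   (ties broken toward the smallest phi).
#' @export
azimuthal_ratios <- function(doses_by_phi) {
  stopifnot(is.data.frame(doses_by_phi),
            all(c("phi_deg", "dose") %in% names(doses_by_phi)))
  df <- doses_by_phi[order(doses_by_phi$phi_deg), ]
  if (anyDuplicated(df$phi_deg)) stop("duplicate phi entries")
  if (any(df$dose <= 0)) stop("doses must be positive")
  i0 <- which(abs(df$phi_deg) < 1e-9)
  if (!length(i0)) stop("a dose at phi = 0 degrees is required")
  ratio <- df$dose / df$dose[i0]
  imax <- which.max(ratio)  # which.max returns the first (smallest phi) tie
  structure(data.frame(phi_deg = df$phi_deg, ratio = ratio),
            max_ratio = ratio[imax], max_phi_deg = df$phi_deg[imax],
            class = c("azimuthal_ratios", "data.frame"))
}

#' Compare two parameter tables point by point
#'
#' Computes per-point ratios or differences between two tables sharing an
#' identical point set (keyed by `r_cm`, and `theta_deg` when present;
#' validity masks are intersected first), plus the summary statistics used
#' for table comparisons: mean, sample SD (n - 1), and the maximum absolute
#' value with its location (ties broken toward smaller r, then smaller
#' theta).
#'
#' @param a,b data.frames with key columns (`r_cm`\[, `theta_deg`\]), a value
#'   column (the last non-key, non-`valid` column), and optionally `valid`.
#' @param mode `"ratio"` or `"difference"` (a/b or a - b).
#' @return an object of class `table_comparison`: list with `mode`, `points`
#'   (keys + `value`), `mean`, `sd`, `max_abs`, `argmax` (a one-row
#'   data.frame), `n`.
#' @export
compare_tables <- function(a, b, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  keyed <- function(d) {
    keys <- intersect(c("r_cm", "theta_deg"), names(d))
    if (!length(keys)) stop("tables need an r_cm (and optionally theta_deg) key")
    val <- setdiff(names(d), c(keys, "valid"))
    if (length(val) != 1L) stop("tables must carry exactly one value column")
    d <- as.data.frame(d)
    if ("valid" %in% names(d)) d <- d[d$valid, ]
    d <- d[do.call(order, d[keys]), c(keys, val)]
    names(d)[ncol(d)] <- "value"
    d
  }
  ka <- keyed(a); kb <- keyed(b)
  keys <- intersect(c("r_cm", "theta_deg"), names(ka))
  if (!identical(keys, intersect(c("r_cm", "theta_deg"), names(kb))))
    stop("tables are keyed differently")
  tag <- function(d) do.call(paste, c(lapply(d[keys], function(v) round(v, 6)),
                                      sep = "|"))
  ta <- tag(ka); tb <- tag(kb)
  common <- intersect(ta, tb)  # validity masks intersected
  if (!length(common)) stop("tables do not share an identical point set")
  ka <- ka[match(common, ta), ]; kb <- kb[match(common, tb), ]
  value <- switch(mode, ratio = ka$value / kb$value,
                  difference = ka$value - kb$value)
  pts <- cbind(ka[keys], value = value)
  pts <- pts[do.call(order, pts[keys]), ]
  value <- pts$value
  imax <- which.max(abs(value))  # rows are sorted by r then theta: first tie wins
  structure(list(mode = mode, points = pts,
                 mean = mean(value), sd = stats::sd(value),
                 max_abs = abs(value[imax]), argmax = pts[imax, , drop = FALSE],
                 n = length(value)),
            class = "table_comparison")
}

#' @export
print.table_comparison <- function(x, ...) {
  cat("<table_comparison> mode = ", x$mode, ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  mean = %.4f, sd = %.4f, max |value| = %.4f at %s\n",
              x$mean, x$sd, x$max_abs,
              paste(names(x$argmax)[-ncol(x$argmax)], "=",
                    unlist(x$argmax[-ncol(x$argmax)]), collapse = ", ")))
  invisible(x)
}
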