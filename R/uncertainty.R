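#' Quadrature sum of uncertainty components
#'
#' `sqrt(sum(v^2))`, the standard combination of independent uncertainty
#' components. Percentages in, percentages out.
#'
#' @param values non-negative component values, percent.
#' @return combined value, percent.
#' @export
quadrature_sum <- function(values) {
  if (any(values < 0)) stop("uncertainty components must be non-negative")
  sqrt(sum(values^2))
}

#' Build an uncertainty component
#'
#' @param name component label.
#' @param value_percent component value in percent (>= 0).
#' @param type `"A"` (statistically evaluated) or `"B"` (systematic /
#'   literature-sourced).
#' @param source free-text provenance.
#' @return one-row data.frame.
#' @export
uncertainty_component <- function(name, value_percent, type = c("A", "B"),
                                  source = "") {
  type <- match.arg(type)
  if (value_percent < 0) stop("component value must be non-negative")
  data.frame(name = name, value_percent = value_percent, type = type,
             source = source)
}

#' Combine typed components into an uncertainty budget
#'
#' Components are summed in quadrature within each type, then the total is
#' the quadrature of the two sums: `total = sqrt(A^2 + B^2)`.
#'
#' @param components data.frame with columns `name`, `value_percent`, `type`
#'   (every row typed `"A"` or `"B"`), optionally `source`.
#' @return an object of class `uncertainty_budget`: the components plus
#'   `quadrature_sum_A`, `quadrature_sum_B` and `total` (percent).
#' @export
combine_budget <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("name", "value_percent", "type") %in% names(components)))
  if (any(is.na(components$type)) || !all(components$type %in% c("A", "B")))
    stop("every component must be typed 'A' or 'B'")
  if (any(components$value_percent < 0))
    stop("component values must be non-negative")
  qa <- quadrature_sum(components$value_percent[components$type == "A"])
  qb <- quadrature_sum(components$value_percent[components$type == "B"])
  structure(list(components = components, quadrature_sum_A = qa,
                 quadrature_sum_B = qb, total = sqrt(qa^2 + qb^2)),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("<uncertainty_budget>\n")
  cmp <- x$components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-45s %6.2f%%  (Type %s)\n", cmp$name[i],
                cmp$value_percent[i], cmp$type[i]))
  cat(sprintf("  %-45s %6.2f%%\n", "Quadrature sum, Type A", x$quadrature_sum_A))
  cat(sprintf("  %-45s %6.2f%%\n", "Quadrature sum, Type B", x$quadrature_sum_B))
  cat(sprintf("  %-45s %6.2f%%\n", "Total (quadrature of A and B)", x$total))
  invisible(x)
}

#' Default packaged measurement uncertainty budget
#'
#' The film-measurement budget shipped with the package: repeated-reading
#' Type A component plus the systematic Type B components (film calibration,
#' film response at kilovoltage energies, medium conversion factor, setup
#' geometry). Literature-sourced values are data, not computation.
#'
#' @return an `uncertainty_budget`.
#' @export
default_budget <- function() {
  combine_budget(load_fixtures(verify_checksums = FALSE)$table4)
}

#' Geometric (voxel-alignment) uncertainty of a scoring region
#'
#' Uniform-distribution approximation of the dose spread across the voxels
#' of a scoring region: `100 * (max - min) / (2 * mean * sqrt(3))` percent.
#' Pronounced near the source where the dose gradient across a region is
#' steep.
#'
#' @param region_doses dose values of the voxels in the region (non-empty,
#'   positive mean).
#' @return uncertainty, percent.
#' @export
mc_geometric_uncertainty <- function(region_doses) {
  region_doses <- region_doses[!is.na(region_doses)]
  if (!length(region_doses)) stop("empty scoring region")
  m <- mean(region_doses)
  if (m <= 0) stop("region mean dose must be positive")
  100 * (max(region_doses) - min(region_doses)) / (2 * m * sqrt(3))
}

#' Dose-weighted mean statistical uncertainty
#'
#' Average of per-voxel relative errors weighted by the voxel doses:
#' `sum(e_i D_i) / sum(D_i)`.
#'
#' @param relative_errors per-voxel relative errors (percent or fraction;
#'   returned on the same scale).
#' @param doses per-voxel doses (non-negative, positive sum).
#' @return dose-weighted mean relative error.
#' @export
mc_statistical_uncertainty <- function(relative_errors, doses) {
  if (length(relative_errors) != length(doses))
    stop("relative_errors and doses must have equal length")
  if (any(doses < 0)) stop("doses must be non-negative")
  s <- sum(doses)
  if (s <= 0) stop("total dose must be positive")
  sum(relative_errors * doses) / s
}

#' Transverse scoring-region doses at a given radius
#'
#' Collects all voxels whose centres lie within a +/- half-voxel radial band
#' around `r` on the transverse ring (|z| within half a voxel), the region
#' definition used for the per-radius Monte Carlo uncertainty estimators.
#'
#' @param grid a [dose_grid].
#' @param r_cm ring radius, cm.
#' @return numeric vector of voxel doses in the region.
#' @export
transverse_ring_doses <- function(grid, r_cm) {
  stopifnot(inherits(grid, "dose_grid"))
  co <- grid_coords(grid)
  half <- grid$voxel_mm / 20  # half a voxel, in cm
  kz <- which(abs(co$z) <= half + 1e-12)
  rad <- sqrt(outer(co$x^2, co$y^2, "+"))
  sel <- abs(rad - r_cm) <= half + 1e-12
  vals <- grid$values[, , kz, drop = FALSE]
  out <- as.vector(vapply(seq_along(kz), function(i) vals[, , i][sel],
                          numeric(sum(sel))))
  out[!is.na(out)]
}
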