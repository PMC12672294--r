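# frozen md5 sums of the packaged reference tables (set once at packaging
# time; load_fixtures() refuses silently altered fixtures)
.fixture_md5 <- c(
  table1_radial_dose.csv   = "4540b2d6eae7a6e4e6e9caf8127deefa",
  table1_xr_detector.csv   = "e7a22629fba1a8c94befa0b4a882e45b",
  table2_anisotropy.csv    = "2c33f7ff2ec5fefa783def2fd4a47c9c",
  table2_printed_stats.csv = "bce4beea5a1a272eba75a8f3fdbd7e8a",
  table3_azimuthal.csv     = "999caebdd4bcc17393bd4fba00a09f84",
  table4_uncertainty.csv   = "bbd6bebeef77630b1d573afe22640bd6",
  text_summary_stats.csv   = "3af8b2ae8a86917a629222243ea7e8c7")

#' Load the packaged reference tables
#'
#' Reads the transcribed published reference tables shipped with the
#' package: the radial-dose function table in both media and both derivation
#' routes (Monte Carlo and film) with its comparison columns, the
#' XR-multidetector cross-check, the anisotropy-function blocks with their
#' validity masks (film cells exist only where the off-axis film plane can
#' reach, r sin(theta) >= 1 cm and theta >= 20 degrees), the azimuthal
#' ratios, the uncertainty-budget components, and the printed summary
#' statistics. Files are checksum-verified at load; transcription notes on
#' internal inconsistencies live in `FIXTURE_NOTES` next to the CSVs.
#'
#' @param verify_checksums refuse fixtures whose md5 differs from the frozen
#'   packaging-time value (default `TRUE`).
#' @return a list of class `fixture_tables` with elements `table1`,
#'   `table1_xr`, `table2`, `table2_printed_stats`, `table3`, `table4`,
#'   `text_stats`.
#' @export
load_fixtures <- function(verify_checksums = TRUE) {
  dir <- system.file("extdata", package = "mxt43")
  files <- names(.fixture_md5)
  paths <- file.path(dir, files)
  if (any(!file.exists(paths))) stop("packaged fixture tables are missing")
  if (verify_checksums) {
    sums <- tools::md5sum(paths)
    bad <- files[sums != .fixture_md5]
    if (length(bad)) stop("fixture checksum mismatch: ",
                          paste(bad, collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(dir, f))
  structure(list(table1 = rd("table1_radial_dose.csv"),
                 table1_xr = rd("table1_xr_detector.csv"),
                 table2 = rd("table2_anisotropy.csv"),
                 table2_printed_stats = rd("table2_printed_stats.csv"),
                 table3 = rd("table3_azimuthal.csv"),
                 table4 = rd("table4_uncertainty.csv"),
                 text_stats = rd("text_summary_stats.csv")),
            class = "fixture_tables")
}

stat_of <- function(fx, name) {
  fx$text_stats$value[match(name, fx$text_stats$stat)]
}

#' Recompute the published summary statistics from the packaged tables
#'
#' Every summary statistic quoted alongside the reference tables is
#' recomputed here from the table cells themselves and compared against the
#' printed value at its printed precision: the mean/SD of the water/ABS
#' radial-dose ratio, the signed means of the Monte Carlo minus film
#' differences in both media, the per-radius differences and their maximum,
#' the XR-multidetector cross-check differences, the extrema of the
#' film/Monte-Carlo anisotropy ratio block, the azimuthal maximum, and the
#' quadrature sums of the uncertainty budget. Three statistics are known
#' not to reproduce from the printed cells and are reported as failures by
#' design (see `FIXTURE_NOTES`): the grand total uncertainty (printed with
#' an unidentifiable extra contribution beyond the strict quadrature), the
#' SD of the water/ABS ratio column (printed 0.10, recomputes to 0.108
#' under any SD convention), and the SD of the ABS difference column
#' (printed 0.05 in the table, 0.06 in the text, recomputes to 0.056).
#'
#' @param fixtures a [load_fixtures()] result.
#' @return data.frame of class `regression_report` with columns `stat`,
#'   `computed`, `printed`, `pass` (agreement at the printed precision).
#' @export
regression_report <- function(fixtures = load_fixtures()) {
  fx <- fixtures
  t1 <- fx$table1
  gw <- data.frame(r_cm = t1$r_cm, g = t1$g_water_mc)
  ga <- data.frame(r_cm = t1$r_cm, g = t1$g_abs_mc)
  ratio <- compare_tables(gw, ga, "ratio")
  dif_a <- compare_tables(ga, data.frame(r_cm = t1$r_cm, g = t1$g_abs_ebt),
                          "difference")
  dif_w <- compare_tables(gw, data.frame(r_cm = t1$r_cm, g = t1$g_water_ebt),
                          "difference")
  # the printed difference columns exclude the r0 row (blank in print)
  not_r0 <- function(cmp) {
    keep <- abs(cmp$points$r_cm - 1) > 1e-9
    v <- cmp$points$value[keep]
    list(mean = mean(v), sd = stats::sd(v),
         max = max(abs(v)), argmax = cmp$points$r_cm[keep][which.max(abs(v))])
  }
  da <- not_r0(dif_a); dw <- not_r0(dif_w)
  at_r <- function(cmp, r) cmp$points$value[match(r, cmp$points$r_cm)]

  xr <- fx$table1_xr
  ebt_at <- t1$g_abs_ebt[match(xr$r_cm, t1$r_cm)]
  xr_diff <- xr$g_abs_xr - ebt_at

  az <- azimuthal_ratios(data.frame(phi_deg = fx$table3$phi_deg,
                                    dose = fx$table3$ratio))
  rat2 <- fx$table2[fx$table2$block == "ratio", ]
  imax2 <- which.max(rat2$value); imin2 <- which.min(rat2$value)

  t4 <- fx$table4
  qa <- quadrature_sum(t4$value_percent[t4$type == "A"])
  qb <- quadrature_sum(t4$value_percent[t4$type == "B"])
  bud <- combine_budget(t4)

  # per-angle means of the anisotropy blocks against the printed row stats
  t2s <- fx$table2_printed_stats
  row_mean <- mapply(function(bl, th) {
    mean(fx$table2$value[fx$table2$block == bl & fx$table2$theta_deg == th])
  }, t2s$block, t2s$theta_deg)

  chk <- function(stat, computed, printed, digits = 2)
    data.frame(stat = stat, computed = computed, printed = printed,
               pass = round(computed, digits) == printed)
  rep <- rbind(
    chk("mean water/ABS g(r) ratio (MC)", ratio$mean,
        stat_of(fx, "ratio_water_abs_g_mc_mean")),
    chk("SD water/ABS g(r) ratio (MC)", ratio$sd,
        stat_of(fx, "ratio_water_abs_g_mc_sd")),
    chk("signed mean water g(r) MC - film", dw$mean,
        stat_of(fx, "diff_water_g_mc_ebt_mean")),
    chk("SD water g(r) MC - film", dw$sd,
        stat_of(fx, "diff_water_g_mc_ebt_sd")),
    chk("mean ABS g(r) MC - film (printed column mean)", da$mean,
        stat_of(fx, "diff_abs_g_mc_ebt_mean_printed")),
    chk("SD ABS g(r) MC - film", da$sd,
        stat_of(fx, "diff_abs_g_mc_ebt_sd_printed")),
    chk("ABS g(r) MC - film at 2 cm", at_r(dif_a, 2.0), 0.09),
    chk("ABS g(r) MC - film at 3 cm", at_r(dif_a, 3.0), 0.10),
    chk("ABS g(r) MC - film at 4 cm", at_r(dif_a, 4.0), 0.11),
    chk("ABS g(r) MC - film at 5 cm", at_r(dif_a, 5.0), 0.10),
    chk("max |ABS g(r) MC - film|", da$max,
        stat_of(fx, "diff_abs_g_mc_ebt_max")),
    chk("argmax r of |ABS g(r) MC - film| (cm)", da$argmax,
        stat_of(fx, "diff_abs_g_mc_ebt_argmax_r_cm"), digits = 1),
    chk("XR - film g(r) at 2 cm", xr_diff[1], 0.03),
    chk("XR - film g(r) at 3 cm", xr_diff[2], -0.01),
    chk("XR - film g(r) at 4 cm", xr_diff[3], 0.02),
    chk("XR - film g(r) at 5 cm", xr_diff[4], 0.04),
    chk("max azimuthal ratio", attr(az, "max_ratio"),
        stat_of(fx, "azimuthal_max_ratio")),
    chk("argmax phi of azimuthal ratio (deg)", attr(az, "max_phi_deg"),
        stat_of(fx, "azimuthal_max_phi_deg"), digits = 0),
    chk("max F film/MC ratio", rat2$value[imax2], stat_of(fx, "f_ratio_max")),
    chk("argmax r of F ratio (cm)", rat2$r_cm[imax2],
        stat_of(fx, "f_ratio_max_r_cm"), digits = 1),
    chk("argmax theta of F ratio (deg)", rat2$theta_deg[imax2],
        stat_of(fx, "f_ratio_max_theta_deg"), digits = 0),
    chk("min F film/MC ratio", rat2$value[imin2], stat_of(fx, "f_ratio_min")),
    chk("Type A quadrature sum (%)", qa, stat_of(fx, "type_a_quadrature_pct")),
    chk("Type B quadrature sum (%)", qb, stat_of(fx, "type_b_quadrature_pct")),
    chk("total uncertainty, strict quadrature (%)", bud$total,
        stat_of(fx, "total_uncertainty_printed_pct")),
    data.frame(stat = sprintf("F %s-block mean at theta = %d deg",
                              t2s$block, t2s$theta_deg),
               computed = row_mean, printed = t2s$mean,
               pass = abs(row_mean - t2s$mean) <= 0.005 + 1e-9))
  rownames(rep) <- NULL
  class(rep) <- c("regression_report", "data.frame")
  rep
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report> ", sum(x$pass), "/", nrow(x),
      " statistics reproduce at printed precision\n", sep = "")
  bad <- x[!x$pass, ]
  if (nrow(bad)) {
    cat("mismatches:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s: computed %.4f vs printed %.4g\n",
                  bad$stat[i], bad$computed[i], bad$printed[i]))
  }
  invisible(x)
}
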