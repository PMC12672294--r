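Transcription notes for the packaged reference tables
=====================================================

Values are transcribed exactly as printed, including the source's internal
inconsistencies. Do not "fix" a cell: the regression report is built to
flag, not hide, the known discrepancies.

table1_radial_dose.csv
  - 22 radii, 1.0-5.0 cm. The comparison columns (water/ABS ratio, MC-film
    differences) are the printed ones; they equal the rounded per-row
    recomputation from the g columns.
  - The difference columns are blank at the 1.0 cm normalization row
    (recorded as NA); printed column means/SDs are over the other 21 radii.
  - Known inconsistencies: the ratio column's printed SD 0.10 recomputes to
    0.108 (sample or population convention); the ABS difference column's
    printed SD 0.05 recomputes to 0.056 (the accompanying text says 0.06,
    and says 0.06 for the mean where the table footer prints 0.07).
  - The source's abstract quotes water g(r) of 0.49/0.33/0.22/0.15 at
    2/3/4/5 cm; these match no column of the table and are NOT packaged.

table1_xr_detector.csv
  - XR multidetector g(r) in ABS at 2/3/4/5 cm (0.54/0.33/0.25/0.20).

table2_anisotropy.csv (long format: block, theta_deg, r_cm, value)
  - blocks: "ebt" = film-measured F(r,theta) after water conversion,
    "mc" = calculated F(r,theta) in water, "ratio" = ebt/mc.
  - The printed table's column alignment is ambiguous for the short rows
    (theta = 20-50 deg): rows were right-anchored so that each row's first
    populated radius satisfies the film-plane reach constraint
    r*sin(theta) >= 1 cm (film 1 cm below the source). This choice also
    reproduces the quoted extrema locations: maximum ratio 1.26 at
    (r = 4.2 cm, theta = 50 deg), minimum 0.84 at (r = 3.6 cm, 20 deg).
  - The "mc" block has no mask (all 18 radii populated for 0-80 deg).

table2_printed_stats.csv
  - The per-row Mean/SD values exactly as printed next to each block row.

table3_azimuthal.csv
  - Azimuthal ratios normalized to 0 deg; maximum 1.06 at 150 deg.

table4_uncertainty.csv
  - Film-measurement budget components. Strict quadrature of the printed
    components gives Type A 0.04%, Type B 12.02%, total 12.0204%; the
    source prints a total of 12.06%, whose extra contribution is not
    identifiable from the printed components. The package computes the
    strict quadrature and reports the discrepancy.

text_summary_stats.csv
  - Summary statistics quoted in the source's prose, at printed precision,
    used by the regression report. lambda_abs * cf_at_1cm (1104.28 * 1.23 =
    1358.3) does not equal the quoted lambda_water 1344.14; the implied
    conversion factor is 1.21719, i.e. the printed CF at 1 cm is rounded
    inconsistently with the printed dose-rate-constant pair.
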