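# Published summary tables from the two-season (2021-2022) drip-fertigated
# sunflower trial in the Hexi Oasis (Northwest China) that this package's
# verification mode reproduces. Raw plot data were not published; these
# treatment-level summaries are the inputs for coefficient-driven analysis
# and the defaults of the synthetic generator.

#' Published logistic growth parameters per treatment and season
#'
#' The fitted logistic parameters (k kg/ha, a, b 1/day) and their derived
#' rapid-growth characteristics as printed in the trial's growth-analysis
#' table, one row per year x treatment cell.
#'
#' @return data.frame: year, treatment, k, a, b, r2, t1, t2, tmax, delta_t,
#'   vmax.
#' @export
reference_growth_params <- function() {
  txt <- "year,treatment,k,a,b,r2,t1,t2,tmax,delta_t,vmax
2021,W1N1,17398.01,204.06,0.078,0.996,51.30,85.07,68.18,33.77,339.26
2021,W1N2,19048.33,190.89,0.077,0.997,51.10,85.31,68.20,34.21,366.68
2021,W1N3,19478.71,151.80,0.077,0.997,48.12,82.33,65.23,34.21,374.97
2021,W2N1,21040.56,132.60,0.075,0.998,47.60,82.72,65.16,35.12,394.51
2021,W2N2,24582.67,106.24,0.073,0.999,45.87,81.95,63.91,36.08,448.63
2021,W2N3,25419.80,79.21,0.069,0.998,44.28,82.45,63.36,38.17,438.49
2021,W3N1,22607.74,91.64,0.070,0.995,45.73,83.36,64.54,37.63,395.64
2021,W3N2,25622.80,71.90,0.069,0.998,42.71,80.88,61.80,38.17,441.99
2021,W3N3,26809.49,70.54,0.069,0.998,42.60,80.77,61.68,38.17,462.46
2022,W1N1,17049.45,157.56,0.077,0.996,48.61,82.82,65.71,34.21,328.20
2022,W1N2,20259.61,146.96,0.077,0.997,47.70,81.91,64.81,34.21,390.00
2022,W1N3,19329.24,128.91,0.074,0.993,47.87,83.46,65.66,35.59,357.59
2022,W2N1,21019.91,113.64,0.073,0.992,46.79,82.88,64.84,36.08,383.61
2022,W2N2,24625.74,113.07,0.073,0.996,46.73,82.81,64.77,36.08,449.42
2022,W2N3,25073.63,110.70,0.074,0.996,45.81,81.40,63.61,35.59,463.86
2022,W3N1,22549.49,114.82,0.073,0.994,46.94,83.02,64.98,36.08,411.53
2022,W3N2,25230.61,98.41,0.073,0.996,44.82,80.91,62.87,36.08,460.46
2022,W3N3,25948.89,93.08,0.075,0.996,42.89,78.01,60.45,35.12,486.54"
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  df$year <- as.character(df$year)
  df
}

#' Published response-surface regression coefficients per season
#'
#' Coefficients of y = y0 + a x1 + b x2 + c x1 x2 + d x1^2 + e x2^2
#' (x1 = ET mm, x2 = N kg/ha) for yield (kg/ha), WUE (kg/m3) and NPFP
#' (kg/kg), with the printed R2 and the printed location/value of each
#' response maximum. Coefficients are printed to 2-3 significant figures;
#' analyses derived from them inherit that rounding.
#'
#' @return data.frame: year, response, y0, a, b, c, d, e, r2, max_value,
#'   n_at_max, et_at_max.
#' @export
reference_surface_coefficients <- function() {
  df <- data.frame(
    year = rep(c("2021", "2022"), each = 3),
    response = rep(c("yield", "wue", "npfp"), 2),
    y0 = c(-1.072e4, -1.082, -17.083, -2.661e4, -6.741, -113.438),
    a = c(70.917, 0.013, 0.433, 177.137, 0.049, 1.009),
    b = c(30.557, 0.010, -0.220, 10.162, 0.004, -0.228),
    c = c(0.018, 4.953e-6, -1.3e-6, 0.088, 2.636e-5, -2.735e-5),
    d = c(-0.100, -2.321e-5, -5.47e-4, -0.280, -8.484e-5, -1.457e-3),
    e = c(-0.097, -2.974e-5, 3.10e-4, -0.097, -3.129e-5, 2.35e-4),
    r2 = c(0.966, 0.982, 0.999, 0.992, 0.983, 0.999),
    max_value = c(5422.27, 1.63, 40.70, 5390.37, 1.62, 38.48),
    n_at_max = c(191.02, 183.67, 120.00, 210.61, 198.37, 120.00),
    et_at_max = c(371.99, 290.63, 382.84, 348.46, 321.64, 348.46))
  df
}

#' Published water consumption and productivity indices per treatment
#'
#' Treatment-cell means and standard deviations (n = 3 replicates) of
#' seasonal ET (mm), WUE (kg/m3), IWUE (kg/m3) and NPFP (kg/kg).
#'
#' @return data.frame: year, treatment, water_level, n_level, and
#'   mean/sd pairs for et, wue, iwue, npfp.
#' @export
reference_indices_table <- function() {
  txt <- "year,treatment,et_mean,et_sd,wue_mean,wue_sd,iwue_mean,iwue_sd,npfp_mean,npfp_sd
2021,W1N1,271.65,18.91,1.51,0.04,2.49,0.26,34.07,1.10
2021,W1N2,274.11,16.40,1.62,0.05,2.69,0.13,24.62,0.39
2021,W1N3,280.25,10.12,1.51,0.06,2.54,0.18,17.72,0.53
2021,W2N1,324.60,5.84,1.43,0.07,2.19,0.20,38.78,1.15
2021,W2N2,330.81,8.96,1.60,0.08,2.46,0.16,29.40,0.60
2021,W2N3,336.15,12.04,1.51,0.08,2.34,0.15,21.17,0.47
2021,W3N1,392.14,13.72,1.25,0.06,1.79,0.11,40.79,0.59
2021,W3N2,398.61,11.96,1.33,0.05,1.94,0.16,29.53,1.24
2021,W3N3,404.53,18.09,1.26,0.03,1.84,0.05,21.28,0.44
2022,W1N1,274.18,14.98,1.34,0.05,2.96,0.12,30.62,0.52
2022,W1N2,280.62,8.84,1.47,0.05,3.15,0.10,22.86,0.71
2022,W1N3,285.97,5.71,1.41,0.04,2.99,0.15,16.80,0.30
2022,W2N1,308.93,11.13,1.41,0.03,2.41,0.11,36.30,0.56
2022,W2N2,315.29,8.96,1.62,0.01,2.70,0.08,28.42,0.91
2022,W2N3,322.85,12.55,1.57,0.07,2.63,0.13,21.15,0.16
2022,W3N1,347.07,9.35,1.33,0.05,1.85,0.07,38.55,1.15
2022,W3N2,358.63,16.55,1.47,0.06,1.99,0.05,29.15,0.33
2022,W3N3,375.29,13.01,1.38,0.02,1.87,0.10,21.51,0.89"
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  df$year <- as.character(df$year)
  df$water_level <- substr(df$treatment, 1, 2)
  df$n_level <- substr(df$treatment, 3, 4)
  df
}

#' Published per-season recommended intervals and season rainfall
#'
#' The reported acceptable ET and N intervals per season (95%/95%/75%
#' thresholds for yield/WUE/NPFP) and the growing-season rainfall totals.
#'
#' @return list with `intervals` (data.frame: year, et_lo, et_hi, n_lo,
#'   n_hi) and `rainfall_mm` (named vector).
#' @export
reference_optimum_intervals <- function() {
  list(
    intervals = data.frame(
      year = c("2021", "2022"),
      et_lo = c(334.3, 319.9), et_hi = c(348.7, 349.3),
      n_lo = c(160.9, 158.1), n_hi = c(175.3, 185.1)),
    rainfall_mm = c("2021" = 164.4, "2022" = 136.3))
}
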