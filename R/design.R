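# Trial design: treatment catalog and validation for the 3x3 factorial layout.

WATER_LEVELS <- c("W1", "W2", "W3")
N_LEVELS <- c("N1", "N2", "N3")
STAGE_LABELS <- c("S", "B", "F", "M")

#' Treatment catalog for a 3 x 3 water-nitrogen fertigation trial
#'
#' Builds the trial design object used throughout the package: three
#' irrigation levels defined as soil-water bands (fractions of field water
#' capacity, F_C) and three nitrogen rates with fixed split fractions across
#' the sowing, budding and flowering stages. Defaults reproduce the
#' two-season Hexi Oasis sunflower trial design: W1 55-65% F_C, W2 65-75%
#' F_C, W3 75-85% F_C; N totals 120/180/240 kg/ha split 40/30/30%; three
#' replicates; 27.2 m2 plots.
#'
#' @param water_bands named list of length-2 numeric vectors, lower/upper
#'   soil-water bounds as fractions of field capacity, one per water level.
#' @param n_totals named numeric vector of total N rates (kg/ha), strictly
#'   increasing across levels.
#' @param splits numeric vector of N split fractions (sowing, budding,
#'   flowering); must sum to 1.
#' @param replicates number of replicate plots per treatment cell.
#' @param plot_area_cm2 area of a single plot in cm2.
#' @param seasons character vector of season (year) labels.
#' @return An object of class `trial_design`.
#' @examples
#' design <- treatment_catalog()
#' design$n_totals[["N2"]]        # 180
#' n_split_schedule(design)["N3", "sowing"]  # 96
#' @export
treatment_catalog <- function(water_bands = list(W1 = c(0.55, 0.65),
                                                 W2 = c(0.65, 0.75),
                                                 W3 = c(0.75, 0.85)),
                              n_totals = c(N1 = 120, N2 = 180, N3 = 240),
                              splits = c(sowing = 0.4, budding = 0.3,
                                         flowering = 0.3),
                              replicates = 3,
                              plot_area_cm2 = 272000,
                              seasons = c("2021", "2022")) {
  design <- structure(
    list(water_bands = water_bands, n_totals = n_totals, splits = splits,
         replicates = as.integer(replicates), plot_area_cm2 = plot_area_cm2,
         seasons = as.character(seasons)),
    class = "trial_design")
  validate_trial_design(design)
  design
}

#' Validate a trial design
#'
#' Checks the design invariants: split fractions sum to 1 (within 1e-9),
#' each water band satisfies 0 < lower < upper <= 1, N totals are strictly
#' increasing, and replicates are positive.
#'
#' @param design a `trial_design` object.
#' @return The design, invisibly; errors on violation.
#' @export
validate_trial_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  if (abs(sum(design$splits) - 1) > 1e-9)
    stop("N split fractions must sum to 1 (got ", sum(design$splits), ")")
  for (w in names(design$water_bands)) {
    band <- design$water_bands[[w]]
    if (length(band) != 2 || !(band[1] > 0 && band[1] < band[2] && band[2] <= 1))
      stop("water band for ", w, " must satisfy 0 < lower < upper <= 1")
  }
  if (any(diff(design$n_totals) <= 0))
    stop("N totals must be strictly increasing across levels")
  if (design$replicates < 1) stop("replicates must be positive")
  if (design$plot_area_cm2 <= 0) stop("plot area must be positive")
  invisible(design)
}

#' Per-stage nitrogen application schedule
#'
#' Expands the design's N totals and split fractions into the per-stage
#' application amounts (kg/ha), one row per N level.
#'
#' @param design a `trial_design` object.
#' @return Numeric matrix with one row per N level and one column per split
#'   stage, plus a `total` column.
#' @export
n_split_schedule <- function(design) {
  validate_trial_design(design)
  m <- outer(design$n_totals, design$splits)
  dimnames(m) <- list(names(design$n_totals), names(design$splits))
  cbind(m, total = design$n_totals)
}

#' Treatment cell labels of a design
#'
#' @param design a `trial_design` object.
#' @return Character vector like `"W1N1"`, water level varying slowest.
#' @export
treatment_cells <- function(design = treatment_catalog()) {
  as.vector(t(outer(names(design$water_bands), names(design$n_totals),
                    paste0)))
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Water-nitrogen factorial trial design\n")
  cat("  water levels: ",
      paste(sprintf("%s [%g-%g%% F_C]", names(x$water_bands),
                    100 * vapply(x$water_bands, `[`, 0, 1),
                    100 * vapply(x$water_bands, `[`, 0, 2)),
            collapse = ", "), "\n", sep = "")
  cat("  N rates (kg/ha): ",
      paste(sprintf("%s=%g", names(x$n_totals), x$n_totals), collapse = ", "),
      "; splits ", paste(sprintf("%s %g%%", names(x$splits), 100 * x$splits),
                         collapse = ", "), "\n", sep = "")
  cat("  replicates: ", x$replicates, "; plot area: ", x$plot_area_cm2,
      " cm2; seasons: ", paste(x$seasons, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.check_level <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad))
    stop("invalid ", what, " label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(TRUE)
}
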