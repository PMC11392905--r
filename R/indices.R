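# Water-balance ET and productivity indices, treatment aggregation and
# percent-change contrasts.

#' Seasonal water consumption from the field water balance
#'
#' ET = P + U + I + dW - D - R (all mm). dW is the change in soil water
#' storage between planting and harvest, positive when the profile dries
#' (storage at planting minus storage at harvest), so consuming stored water
#' increases ET. In trials with deep groundwater and no runoff or deep
#' drainage, U, D and R are zero.
#'
#' @param P rainfall (mm).
#' @param I irrigation (mm).
#' @param delta_w soil water storage change, planting minus harvest (mm).
#' @param U groundwater recharge (mm).
#' @param D deep drainage (mm).
#' @param R surface runoff (mm).
#' @return Water consumption ET (mm).
#' @export
water_consumption <- function(P, I, delta_w, U = 0, D = 0, R = 0) {
  if (any(P < 0) || any(I < 0)) stop("rainfall and irrigation must be >= 0")
  et <- P + U + I + delta_w - D - R
  if (any(et <= 0))
    stop("computed ET <= 0 mm: physically implausible season water balance")
  et
}

#' Populate ET and productivity indices on plot records
#'
#' Adds the derived columns: et_mm from the water balance, WUE = GY/(10 ET)
#' kg/m3, IWUE = GY/(10 I) kg/m3 and NPFP = GY/N_T kg/kg. The factor 10
#' converts mm of water over one hectare to m3 per are so that kg/ha over mm
#' becomes kg/m3.
#'
#' @param plots a `plots`-schema data.frame (see [load_records()]).
#' @return The data.frame with et_mm, wue, iwue, npfp columns appended.
#' @export
compute_indices <- function(plots) {
  plots <- .validate_plots(plots)
  plots$et_mm <- water_consumption(plots$rainfall_mm, plots$irrigation_mm,
                                   plots$delta_storage_mm,
                                   plots$groundwater_mm, plots$drainage_mm,
                                   plots$runoff_mm)
  if (any(plots$irrigation_mm == 0))
    stop("zero divisor in field 'irrigation_mm': IWUE undefined")
  if (any(plots$n_total_kg_ha == 0))
    stop("zero divisor in field 'n_total_kg_ha': NPFP undefined")
  plots$wue <- plots$grain_yield_kg_ha / (10 * plots$et_mm)
  plots$iwue <- plots$grain_yield_kg_ha / (10 * plots$irrigation_mm)
  plots$npfp <- plots$grain_yield_kg_ha / plots$n_total_kg_ha
  plots
}

#' Aggregate plot indices to treatment summaries
#'
#' Arithmetic mean and sample standard deviation per group and year for each
#' metric. Marginal groupings (`"water"`, `"nitrogen"`) average the
#' constituent plots directly; with a balanced design this equals the
#' unweighted average of the W x N cell means.
#'
#' @param indices output of [compute_indices()].
#' @param grouping `"cell"` (full W x N), `"water"`, or `"nitrogen"`.
#' @param metrics columns to summarize.
#' @return data.frame: year, level, metric, mean, sd, n.
#' @export
aggregate_indices <- function(indices,
                              grouping = c("cell", "water", "nitrogen"),
                              metrics = c("et_mm", "wue", "iwue", "npfp",
                                          "grain_yield_kg_ha")) {
  grouping <- match.arg(grouping)
  key <- switch(grouping,
                cell = paste0(indices$water_level, indices$n_level),
                water = indices$water_level,
                nitrogen = indices$n_level)
  out <- list()
  for (yr in unique(indices$year)) {
    for (lev in unique(key[indices$year == yr])) {
      sel <- indices$year == yr & key == lev
      if (!any(sel)) stop("empty group ", lev, " in year ", yr)
      for (m in metrics) {
        v <- indices[[m]][sel]
        out[[length(out) + 1L]] <- data.frame(
          year = yr, grouping = grouping, level = lev, metric = m,
          mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
          n = sum(sel))
      }
    }
  }
  do.call(rbind, out)
}

#' Percent change between two values
#'
#' 100 (other - reference) / denominator, where the denominator is chosen by
#' `convention`. Published treatment contrasts mix both baselines, so the
#' convention is always explicit.
#'
#' @param reference baseline value.
#' @param other comparison value.
#' @param convention `"relative_to_reference"` (denominator = reference) or
#'   `"relative_to_other"` (denominator = other).
#' @return Signed percent change.
#' @export
percent_change <- function(reference, other,
                           convention = c("relative_to_reference",
                                          "relative_to_other")) {
  convention <- match.arg(convention)
  den <- if (convention == "relative_to_reference") reference else other
  if (any(den == 0)) stop("zero denominator in percent change")
  100 * (other - reference) / den
}
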