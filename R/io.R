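# Delimited-text readers/writers for the three record kinds.
#
# All files are comma-separated UTF-8 with a mandatory header and "." as the
# decimal mark. Optional water-balance columns (groundwater_mm, drainage_mm,
# runoff_mm) default to 0 when absent; a missing delta_storage_mm is an error
# because it materially changes ET.

.SCHEMAS <- list(
  plots = list(
    required = c("plot_id", "year", "water_level", "n_level", "replicate",
                 "grain_yield_kg_ha", "irrigation_mm", "rainfall_mm",
                 "delta_storage_mm", "n_total_kg_ha"),
    optional = c("groundwater_mm", "drainage_mm", "runoff_mm")),
  dma = list(
    required = c("plot_id", "year", "water_level", "n_level", "replicate",
                 "t_days", "dma_kg_ha"),
    optional = character()),
  leaves = list(
    required = c("plot_id", "stage", "plant_idx", "leaf_idx",
                 "leaf_length_cm", "leaf_width_cm"),
    optional = character()))

.check_schema <- function(df, schema, path) {
  spec <- .SCHEMAS[[schema]]
  missing <- setdiff(spec$required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), " for schema '", schema, "'")
  invisible(TRUE)
}

.fail_row <- function(df, bad, field, why) {
  if (any(bad))
    stop("validation error: ", why, " in field '", field, "' for plot_id ",
         paste(unique(df$plot_id[bad]), collapse = ", "))
  invisible(TRUE)
}

.validate_plots <- function(df) {
  for (col in .SCHEMAS$plots$optional)
    if (is.null(df[[col]])) df[[col]] <- 0
  .check_level(df$water_level, WATER_LEVELS, "water_level")
  .check_level(df$n_level, N_LEVELS, "n_level")
  .fail_row(df, df$grain_yield_kg_ha < 0, "grain_yield_kg_ha", "negative yield")
  .fail_row(df, df$irrigation_mm < 0, "irrigation_mm", "negative irrigation")
  .fail_row(df, df$rainfall_mm < 0, "rainfall_mm", "negative rainfall")
  .fail_row(df, df$n_total_kg_ha <= 0, "n_total_kg_ha", "non-positive N rate")
  .fail_row(df, !is.finite(df$delta_storage_mm), "delta_storage_mm",
            "missing soil-water storage change")
  df$year <- as.character(df$year)
  df
}

.validate_dma <- function(df) {
  .check_level(df$water_level, WATER_LEVELS, "water_level")
  .check_level(df$n_level, N_LEVELS, "n_level")
  .fail_row(df, df$dma_kg_ha < 0, "dma_kg_ha", "negative dry matter")
  .fail_row(df, df$t_days < 0, "t_days", "negative time")
  key <- interaction(df$plot_id, df$year, drop = TRUE)
  for (k in levels(key)) {
    tt <- df$t_days[key == k]
    if (is.unsorted(tt, strictly = TRUE))
      stop("validation error: t_days must be strictly increasing ",
           "in field 't_days' for plot_id ", df$plot_id[key == k][1])
  }
  df$year <- as.character(df$year)
  df
}

.validate_leaves <- function(df) {
  .check_level(df$stage, STAGE_LABELS, "stage")
  .fail_row(df, df$leaf_length_cm <= 0, "leaf_length_cm",
            "non-positive leaf length")
  .fail_row(df, df$leaf_width_cm <= 0, "leaf_width_cm",
            "non-positive leaf width")
  df
}

#' Read trial records from a delimited-text file
#'
#' Parses one of the three CSV schemas used by the pipeline and enforces the
#' record invariants. Row order is preserved.
#'
#' Schemas (comma-separated, header mandatory):
#' * `plots`: plot_id, year, water_level, n_level, replicate,
#'   grain_yield_kg_ha, irrigation_mm, rainfall_mm, delta_storage_mm,
#'   \[groundwater_mm, drainage_mm, runoff_mm\], n_total_kg_ha
#' * `dma`: plot_id, year, water_level, n_level, replicate, t_days, dma_kg_ha
#'   (long format)
#' * `leaves`: plot_id, stage, plant_idx, leaf_idx, leaf_length_cm,
#'   leaf_width_cm
#'
#' @param path file to read.
#' @param schema one of `"plots"`, `"dma"`, `"leaves"`.
#' @return A validated data.frame of the corresponding record kind.
#' @export
load_records <- function(path, schema = c("plots", "dma", "leaves")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_schema(df, schema, path)
  switch(schema,
         plots = .validate_plots(df),
         dma = .validate_dma(df),
         leaves = .validate_leaves(df))
}

#' Write trial records to a delimited-text file
#'
#' Inverse of [load_records()]: validates, then writes comma-separated UTF-8
#' with a header; a write-then-read round trip is the identity.
#'
#' @param df a records data.frame.
#' @param path file to write.
#' @param schema one of `"plots"`, `"dma"`, `"leaves"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(df, path, schema = c("plots", "dma", "leaves")) {
  schema <- match.arg(schema)
  .check_schema(df, schema, path)
  df <- switch(schema,
               plots = .validate_plots(df),
               dma = .validate_dma(df),
               leaves = .validate_leaves(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
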