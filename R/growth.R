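# Leaf area index and dry-matter scaling.

#' Leaf area index from sampled leaf dimensions
#'
#' LAI = factor x NP x (mean per-plant sum of LL x LB over the sampled
#' plants) / A, where LL and LB are the maximum length and width (cm) of
#' each fully extended leaf, NP the total number of plants in the plot and A
#' the plot area (cm2). The product LL x LB times a crop-specific conversion
#' factor (0.6564 for sunflower) approximates one-sided leaf area. The sum
#' over the sampled plants is averaged per plant before scaling by NP, so
#' the estimate is the plot total leaf area per plot ground area
#' (dimensionless).
#'
#' @param leaves data.frame with columns `plant_idx`, `leaf_length_cm`,
#'   `leaf_width_cm` for the sampled plants of one plot/stage.
#' @param n_plants total number of plants in the plot (NP). See
#'   [default_plant_count()].
#' @param plot_area_cm2 plot area A in cm2.
#' @param factor leaf-area conversion factor (default 0.6564, sunflower).
#' @return list with `lai` and `n_leaves_total` (leaves measured).
#' @examples
#' one <- data.frame(plant_idx = 1, leaf_length_cm = 10, leaf_width_cm = 10)
#' leaf_area_index(one, n_plants = 1, plot_area_cm2 = 100)$lai  # 0.6564
#' @export
leaf_area_index <- function(leaves, n_plants, plot_area_cm2 = 272000,
                            factor = 0.6564) {
  if (plot_area_cm2 <= 0) stop("plot area must be positive")
  if (n_plants <= 0) stop("plant count must be positive")
  if (nrow(leaves) == 0)
    return(list(lai = 0, n_leaves_total = 0L))
  if (any(leaves$leaf_length_cm <= 0) || any(leaves$leaf_width_cm <= 0))
    stop("leaf dimensions must be positive")
  n_sampled <- length(unique(leaves$plant_idx))
  total_llb <- sum(leaves$leaf_length_cm * leaves$leaf_width_cm)
  list(lai = factor * n_plants * (total_llb / n_sampled) / plot_area_cm2,
       n_leaves_total = nrow(leaves))
}

#' Leaf area index for every plot/stage in a leaves table
#'
#' @param leaves a `leaves`-schema data.frame (see [load_records()]).
#' @param n_plants plants per plot, recycled over plots.
#' @param plot_area_cm2,factor as in [leaf_area_index()].
#' @return data.frame with plot_id, stage, lai, n_leaves_total.
#' @export
lai_by_plot <- function(leaves, n_plants = default_plant_count(),
                        plot_area_cm2 = 272000, factor = 0.6564) {
  groups <- unique(leaves[, c("plot_id", "stage")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- leaves[leaves$plot_id == groups$plot_id[i] &
                    leaves$stage == groups$stage[i], , drop = FALSE]
    res <- leaf_area_index(sub, n_plants, plot_area_cm2, factor)
    data.frame(plot_id = groups$plot_id[i], stage = groups$stage[i],
               lai = res$lai, n_leaves_total = res$n_leaves_total)
  })
  do.call(rbind, out)
}

#' Geometry-derived default plant count per plot
#'
#' The trial plots (3.4 m x 8 m) carry paired rows on mulch film: narrow row
#' spacing 50 cm, wide row spacing 80 cm (mean 65 cm) and in-row plant
#' spacing 45 cm. The default count is rows x plants-per-row from that
#' geometry; it is a documented convention, override with a counted value
#' when available.
#'
#' @param plot_width_m,plot_length_m plot dimensions (m).
#' @param mean_row_spacing_cm average of narrow and wide row spacing (cm).
#' @param plant_spacing_cm in-row plant spacing (cm).
#' @return integer plant count.
#' @export
default_plant_count <- function(plot_width_m = 3.4, plot_length_m = 8,
                                mean_row_spacing_cm = 65,
                                plant_spacing_cm = 45) {
  rows <- floor(100 * plot_width_m / mean_row_spacing_cm)
  per_row <- floor(100 * plot_length_m / plant_spacing_cm) + 1
  as.integer(rows * per_row)
}

#' Scale per-plant dry weight to area basis
#'
#' DMA (kg/ha) = per-plant dry weight (kg) x sowing density (plants/ha) x
#' seedling emergence rate.
#'
#' @param per_plant_kg mean aboveground dry weight per sampled plant (kg).
#' @param sowing_density plants sown per hectare.
#' @param emergence_rate fraction of sown plants that emerged, in (0, 1].
#' @return dry matter accumulation in kg/ha.
#' @export
scale_dma <- function(per_plant_kg, sowing_density, emergence_rate) {
  if (sowing_density <= 0) stop("sowing density must be positive")
  if (emergence_rate <= 0 || emergence_rate > 1)
    stop("emergence rate must be in (0, 1]")
  per_plant_kg * sowing_density * emergence_rate
}
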