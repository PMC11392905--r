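# Synthetic trial generator: complete factorial trials with the statistical
# structure the analysis assumes, plus exported ground truth for recovery
# tests. Study conditions (design, rainfall, growth-curve and surface
# parameters, noise levels) default to the reference trial's published
# summaries.

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the reference two-season trial: the 3 x 3 x 3 design of
#' [treatment_catalog()], season rainfall 164.4 / 136.3 mm, per-cell
#' logistic growth parameters and per-cell ET means from the published
#' summary tables, and per-year yield surfaces from the published yield
#' regressions. Noise defaults: multiplicative dry-matter CV 0.05, additive
#' yield sd 150 kg/ha, additive ET sd 5 mm.
#'
#' @param seed integer root seed; every stage draws from a sub-seed derived
#'   from it.
#' @param design a `trial_design`.
#' @param rainfall_mm named per-season rainfall totals (mm).
#' @param logistic_params data.frame year/treatment/k/a/b (defaults:
#'   [reference_growth_params()]).
#' @param yield_surfaces named list (year) of `quad_surface` for yield;
#'   defaults to the published yield coefficients with the published ET
#'   range as domain.
#' @param et_means data.frame year/treatment/et_mean (defaults:
#'   [reference_indices_table()]).
#' @param noise list with `dma_cv`, `yield_sd`, `et_sd`.
#' @param times dry-matter sampling times, days after emergence.
#' @param sowing_density plants/ha (default: plot geometry, 65 cm mean row
#'   spacing x 45 cm plant spacing).
#' @param emergence_rate seedling emergence fraction.
#' @param delta_w_mean,delta_w_sd soil-water storage change draw (mm),
#'   planting minus harvest.
#' @param lai_peak 3 x 3 matrix (water x N) of target leaf area index at
#'   flowering; stage multipliers `lai_stage` shape the trajectory.
#' @param lai_stage named multipliers for stages S, B, F, M.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             design = treatment_catalog(),
                             rainfall_mm = c("2021" = 164.4, "2022" = 136.3),
                             logistic_params = NULL,
                             yield_surfaces = NULL,
                             et_means = NULL,
                             noise = list(dma_cv = 0.05, yield_sd = 150,
                                          et_sd = 5),
                             times = seq(20, 140, by = 20),
                             sowing_density = 34188,
                             emergence_rate = 0.95,
                             delta_w_mean = 20, delta_w_sd = 5,
                             lai_peak = NULL,
                             lai_stage = c(S = 0.25, B = 0.7, F = 1,
                                           M = 0.8)) {
  validate_trial_design(design)
  if (is.null(logistic_params))
    logistic_params <- reference_growth_params()[, c("year", "treatment",
                                                     "k", "a", "b")]
  if (is.null(et_means)) {
    ref <- reference_indices_table()
    et_means <- ref[, c("year", "treatment", "et_mean")]
  }
  if (is.null(yield_surfaces)) {
    sc <- reference_surface_coefficients()
    yield_surfaces <- list()
    for (yr in unique(sc$year)) {
      row <- sc[sc$year == yr & sc$response == "yield", ]
      ets <- et_means$et_mean[et_means$year == yr]
      yield_surfaces[[yr]] <- quad_surface(
        c(y0 = row$y0, a = row$a, b = row$b, c = row$c, d = row$d,
          e = row$e),
        domain = list(x1 = range(ets), x2 = range(design$n_totals)),
        response = "yield", year = yr)
    }
  }
  if (is.null(lai_peak)) {
    lai_peak <- 3.4 * outer(c(0.66, 0.9, 1), c(0.85, 0.97, 1))
    dimnames(lai_peak) <- list(names(design$water_bands),
                               names(design$n_totals))
  }
  if (any(unlist(noise) < 0)) stop("noise sds must be >= 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  for (s in yield_surfaces) {
    p <- s$coefs
    if (!(p[["d"]] < 0 && 4 * p[["d"]] * p[["e"]] - p[["c"]]^2 > 0))
      stop("yield surface must be concave (d < 0 and 4de - c^2 > 0)")
  }
  structure(list(seed = as.integer(seed), design = design,
                 rainfall_mm = rainfall_mm,
                 logistic_params = logistic_params,
                 yield_surfaces = yield_surfaces, et_means = et_means,
                 noise = noise, times = times,
                 sowing_density = sowing_density,
                 emergence_rate = emergence_rate,
                 delta_w_mean = delta_w_mean, delta_w_sd = delta_w_sd,
                 lai_peak = lai_peak, lai_stage = lai_stage),
            class = "synthetic_config")
}

# Mean-corrected multiplicative lognormal noise: E[factor] = 1.
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a complete synthetic trial
#'
#' Produces the three record tables of the pipeline's CSV schemas plus a
#' ground-truth record holding every generating parameter and the exact
#' per-plot bookkeeping values (true ET, noiseless yield, growth-curve
#' parameters), so recovery can be tested against truth. A fixed seed gives
#' bit-identical output.
#'
#' Per plot: ET is drawn around the cell's mean; rainfall P is the season
#' total, the storage change dW is drawn, and irrigation is back-filled as
#' I = ET - P - dW so the water balance holds exactly. Yield is the year's
#' surface evaluated at (ET, N) plus additive noise, truncated at zero.
#' Dry-matter series follow the cell's logistic curve with mean-corrected
#' multiplicative lognormal noise. Leaf tables are constructed so the plot's
#' leaf area index equals the cell's target trajectory exactly.
#'
#' @param config a [synthetic_config()].
#' @param components which tables to generate (subset of `"plots"`,
#'   `"dma"`, `"leaves"`).
#' @return list with `plots`, `dma`, `leaves` data.frames (those requested)
#'   and `truth`.
#' @export
generate_trial <- function(config,
                           components = c("plots", "dma", "leaves")) {
  stopifnot(inherits(config, "synthetic_config"))
  components <- match.arg(components, several.ok = TRUE)
  design <- config$design
  cells <- expand.grid(water_level = names(design$water_bands),
                       n_level = names(design$n_totals),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$water_level, cells$n_level), ]
  years <- names(config$rainfall_mm)
  reps <- seq_len(design$replicates)

  plots <- list(); dma <- list(); leaf <- list(); truth_plots <- list()
  for (yr in years) {
    nz <- config$noise
    np <- nrow(cells) * length(reps)
    et_draw <- .with_seed(.sub_seed(config$seed, paste0("et-", yr)),
                          stats::rnorm(np, 0, nz$et_sd))
    dw_draw <- .with_seed(.sub_seed(config$seed, paste0("dw-", yr)),
                          stats::rnorm(np, config$delta_w_mean,
                                       config$delta_w_sd))
    gy_draw <- .with_seed(.sub_seed(config$seed, paste0("gy-", yr)),
                          stats::rnorm(np, 0, nz$yield_sd))
    dma_draw <- .with_seed(.sub_seed(config$seed, paste0("dma-", yr)),
                           .mult_noise(np * length(config$times), nz$dma_cv))
    i_plot <- 0L
    for (ci in seq_len(nrow(cells))) {
      w <- cells$water_level[ci]; nl <- cells$n_level[ci]
      cell <- paste0(w, nl)
      n_total <- design$n_totals[[nl]]
      et_mean <- config$et_means$et_mean[config$et_means$year == yr &
                                         config$et_means$treatment == cell]
      lp <- config$logistic_params[config$logistic_params$year == yr &
                                   config$logistic_params$treatment == cell, ]
      if (length(et_mean) != 1 || nrow(lp) != 1)
        stop("config lacks parameters for cell ", cell, " in ", yr)
      for (r in reps) {
        i_plot <- i_plot + 1L
        plot_id <- sprintf("P%s-%s-R%d", yr, cell, r)
        et <- et_mean + et_draw[i_plot]
        P <- unname(config$rainfall_mm[[yr]])
        dw <- dw_draw[i_plot]
        irr <- et - P - dw
        if (irr < 5) { irr <- 5; dw <- et - P - irr }
        gy_true <- predict(config$yield_surfaces[[yr]], et, n_total)
        gy <- max(0, gy_true + gy_draw[i_plot])
        plots[[length(plots) + 1L]] <- data.frame(
          plot_id = plot_id, year = yr, water_level = w, n_level = nl,
          replicate = r, grain_yield_kg_ha = gy, irrigation_mm = irr,
          rainfall_mm = P, delta_storage_mm = dw, groundwater_mm = 0,
          drainage_mm = 0, runoff_mm = 0, n_total_kg_ha = n_total)
        truth_plots[[length(truth_plots) + 1L]] <- data.frame(
          plot_id = plot_id, year = yr, treatment = cell, replicate = r,
          et_true = et, yield_true = gy_true, k = lp$k, a = lp$a, b = lp$b)
        if ("dma" %in% components) {
          nt <- length(config$times)
          fac <- dma_draw[((i_plot - 1L) * nt + 1L):(i_plot * nt)]
          dma[[length(dma) + 1L]] <- data.frame(
            plot_id = plot_id, year = yr, water_level = w, n_level = nl,
            replicate = r, t_days = config$times,
            dma_kg_ha = logistic_value(config$times, lp$k, lp$a, lp$b) * fac)
        }
        if ("leaves" %in% components && r == 1L) {
          leaf[[length(leaf) + 1L]] <-
            .make_leaves(plot_id, config, w, nl)
        }
      }
    }
  }
  out <- list(truth = list(config = config,
                           plots = do.call(rbind, truth_plots)))
  if ("plots" %in% components) out$plots <- do.call(rbind, plots)
  if ("dma" %in% components) out$dma <- do.call(rbind, dma)
  if ("leaves" %in% components) out$leaves <- do.call(rbind, leaf)
  out
}

# Leaf table for one plot: 5 sampled plants x 20 leaves, 2:1 length:width,
# relative sizes drawn then rescaled so the plot LAI equals the target
# trajectory exactly at every stage.
.make_leaves <- function(plot_id, config, w, nl) {
  n_plants_tot <- default_plant_count()
  area <- config$design$plot_area_cm2
  n_sampled <- 5L; n_leaves <- 20L
  rows <- list()
  for (stage in names(config$lai_stage)) {
    target <- config$lai_peak[w, nl] * config$lai_stage[[stage]]
    rel <- .with_seed(.sub_seed(config$seed,
                                paste0("leaf-", plot_id, "-", stage)),
                      .mult_noise(n_sampled * n_leaves, 0.3))
    # total LL*LB over sampled plants required for the exact target LAI
    total_llb <- target * area * n_sampled / (0.6564 * n_plants_tot)
    s <- rel / sum(rel) * total_llb
    lb <- sqrt(s / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = plot_id, stage = stage,
      plant_idx = rep(seq_len(n_sampled), each = n_leaves),
      leaf_idx = rep(seq_len(n_leaves), n_sampled),
      leaf_length_cm = 2 * lb, leaf_width_cm = lb)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic trial with all treatment effects removed
#'
#' Same structure and noise as [generate_trial()], but every cell shares one
#' per-year ET mean, one yield mean and one growth curve (the across-cell
#' averages of the configured parameters). Used for type-I-error
#' calibration of the ANOVA stage.
#'
#' @inheritParams generate_trial
#' @return As [generate_trial()].
#' @export
generate_null_trial <- function(config,
                                components = c("plots", "dma", "leaves")) {
  stopifnot(inherits(config, "synthetic_config"))
  flat <- config
  for (yr in names(config$rainfall_mm)) {
    sel <- flat$et_means$year == yr
    flat$et_means$et_mean[sel] <- mean(flat$et_means$et_mean[sel])
    lsel <- flat$logistic_params$year == yr
    for (pcol in c("k", "a", "b"))
      flat$logistic_params[[pcol]][lsel] <-
        mean(flat$logistic_params[[pcol]][lsel])
    # flat yield: every cell gets the mean of the configured surface over
    # the cells, via a constant surface
    yields <- predict(config$yield_surfaces[[yr]],
                      config$et_means$et_mean[sel],
                      rep(config$design$n_totals,
                          times = length(config$design$water_bands)))
    s <- config$yield_surfaces[[yr]]
    s$coefs <- c(y0 = mean(yields), a = 0, b = 0, c = 0, d = 0, e = 0)
    flat$yield_surfaces[[yr]] <- s
  }
  flat$lai_peak[] <- mean(flat$lai_peak)
  # bypass the concavity validation: constant surfaces are intentional here
  generate_trial(flat, components)
}

#' Write a generated trial to a directory
#'
#' Writes the CSV schemas of [load_records()] plus `ground_truth.json` with
#' every generating parameter.
#'
#' @param trial output of [generate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(trial$plots))
    write_records(trial$plots, file.path(dir, "plots.csv"), "plots")
  if (!is.null(trial$dma))
    write_records(trial$dma, file.path(dir, "dma.csv"), "dma")
  if (!is.null(trial$leaves))
    write_records(trial$leaves, file.path(dir, "leaves.csv"), "leaves")
  truth <- trial$truth
  truth$config$design <- unclass(truth$config$design)
  truth$config$yield_surfaces <-
    lapply(truth$config$yield_surfaces, function(s)
      list(coefs = as.list(s$coefs), domain = s$domain, year = s$year))
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
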