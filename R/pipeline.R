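# End-to-end pipeline: load or simulate, indices, growth fits, ANOVA +
# Duncan letters, response surfaces, optima, acceptability regions and
# year-combined intervals, with every artifact written as delimited text.

#' Validated run configuration
#'
#' @param out_dir directory for artifacts.
#' @param seed integer seed (used by simulation and any stochastic stage).
#' @param simulate if `TRUE` generate the input trial; otherwise `input`
#'   paths are required.
#' @param input named list of file paths (`plots`, `dma`, `leaves`) when
#'   not simulating.
#' @param thresholds named acceptability fractions per response, each in
#'   (0, 1).
#' @param grid_n region grid cells per axis.
#' @param n_domain N domain box (kg/ha) for surfaces and regions.
#' @param et_domain optional ET domain box (mm); default is the observed
#'   per-year ET range.
#' @param sim_config optional [synthetic_config()] overriding the default
#'   simulation conditions.
#' @param verbose print stage logs.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE, input = NULL,
                       thresholds = c(yield = 0.95, wue = 0.95, npfp = 0.75),
                       grid_n = 1000, n_domain = c(120, 240),
                       et_domain = NULL, sim_config = NULL, verbose = TRUE) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must be strictly between 0 and 1")
  if (!simulate) {
    if (is.null(input) || !all(c("plots", "dma") %in% names(input)))
      stop("when not simulating, input must name at least plots and dma files")
    for (p in unlist(input))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (grid_n < 2) stop("grid_n must be at least 2")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input = input,
                 thresholds = thresholds, grid_n = grid_n,
                 n_domain = n_domain, et_domain = et_domain,
                 sim_config = sim_config, verbose = verbose),
            class = "run_config")
}

.log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message("[aquanit] ", ...)

#' Run the full water-nitrogen analysis pipeline
#'
#' Stages, in order: load or simulate the trial; water-balance ET and
#' productivity indices with treatment summaries; leaf area index; logistic
#' growth fits per treatment cell; two-way ANOVA with Duncan letters per
#' year and metric; per-year quadratic response surfaces on cell means;
#' stationary and box-constrained optima; per-year acceptability regions at
#' the configured thresholds; year-combined recommended intervals. All
#' artifacts are written under `config$out_dir` as CSV plus a plain-text
#' report; the run is deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, the full result bundle (tables, surfaces, regions,
#'   combined intervals).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)

  if (config$simulate) {
    .log(config, "stage data: simulating trial (seed ", config$seed, ")")
    sim_cfg <- config$sim_config
    if (is.null(sim_cfg)) sim_cfg <- synthetic_config(seed = config$seed)
    trial <- generate_trial(sim_cfg)
    write_trial(trial, art("simulated_input"))
  } else {
    .log(config, "stage data: loading ", config$input$plots)
    trial <- list(plots = load_records(config$input$plots, "plots"),
                  dma = load_records(config$input$dma, "dma"))
    if (!is.null(config$input$leaves))
      trial$leaves <- load_records(config$input$leaves, "leaves")
  }

  .log(config, "stage indices: water balance + WUE/IWUE/NPFP")
  indices <- compute_indices(trial$plots)
  utils::write.csv(indices, art("indices.csv"), row.names = FALSE)
  summaries <- rbind(aggregate_indices(indices, "cell"),
                     aggregate_indices(indices, "water"),
                     aggregate_indices(indices, "nitrogen"))
  utils::write.csv(summaries, art("summaries.csv"), row.names = FALSE)

  lai <- NULL
  if (!is.null(trial$leaves)) {
    .log(config, "stage lai: leaf area index per plot/stage")
    lai <- lai_by_plot(trial$leaves)
    utils::write.csv(lai, art("lai.csv"), row.names = FALSE)
  }

  .log(config, "stage growth: logistic fits per treatment cell")
  fits <- fit_growth_curves(trial$dma, by = "cell", seed = config$seed)
  utils::write.csv(fits, art("growth_fits.csv"), row.names = FALSE)

  .log(config, "stage anova: two-way ANOVA + Duncan letters")
  anova_rows <- list(); letter_rows <- list()
  metrics <- c(grain_yield_kg_ha = "yield", et_mm = "et", wue = "wue",
               npfp = "npfp")
  for (yr in unique(indices$year)) {
    sub <- indices[indices$year == yr, ]
    for (m in names(metrics)) {
      at <- two_way_anova(sub, m)
      anova_rows[[length(anova_rows) + 1L]] <-
        cbind(year = yr, metric = metrics[[m]], as.data.frame(at))
      cell_means <- tapply(sub[[m]], paste0(sub$water_level, sub$n_level),
                           mean)
      dg <- duncan_letters(cell_means, attr(at, "ms_error"),
                           attr(at, "df_error"),
                           n = length(unique(sub$replicate)))
      letter_rows[[length(letter_rows) + 1L]] <-
        cbind(year = yr, metric = metrics[[m]], as.data.frame(dg))
    }
  }
  utils::write.csv(do.call(rbind, anova_rows), art("anova.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, letter_rows), art("letters.csv"),
                   row.names = FALSE)

  .log(config, "stage surfaces: quadratic response surfaces on cell means")
  surfaces <- fit_year_surfaces(indices, n_domain = config$n_domain)
  if (!is.null(config$et_domain))
    for (yr in names(surfaces))
      for (r in names(surfaces[[yr]]))
        surfaces[[yr]][[r]]$domain$x1 <- range(config$et_domain)
  surf_rows <- list(); opt_rows <- list()
  for (yr in names(surfaces)) {
    for (r in names(surfaces[[yr]])) {
      s <- surfaces[[yr]][[r]]
      surf_rows[[length(surf_rows) + 1L]] <- data.frame(
        year = yr, response = r, t(s$coefs), r2 = s$r2, n_obs = s$n_obs)
      opt <- constrained_max(s)
      sp <- stationary_point(s)
      opt_rows[[length(opt_rows) + 1L]] <- data.frame(
        year = yr, response = r, et_at_max = opt$x1, n_at_max = opt$x2,
        max_value = opt$value, location = opt$location,
        stationary_kind = sp$kind)
    }
  }
  utils::write.csv(do.call(rbind, surf_rows), art("surfaces.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, opt_rows), art("optima.csv"),
                   row.names = FALSE)

  .log(config, "stage regions: acceptability intersection + projection")
  regions <- list(); interval_rows <- list()
  for (yr in names(surfaces)) {
    reg <- acceptability_region(surfaces[[yr]], config$thresholds,
                                config$grid_n)
    regions[[yr]] <- reg
    if (!reg$empty) {
      interval_rows[[length(interval_rows) + 1L]] <- data.frame(
        year = yr, axis = c("et", "n"),
        lower = c(reg$et_interval[1], reg$n_interval[1]),
        upper = c(reg$et_interval[2], reg$n_interval[2]),
        contiguous = unname(reg$contiguous))
    }
    utils::write.csv(reg$intersection * 1,
                     art(sprintf("region_mask_%s.csv", yr)),
                     row.names = FALSE)
  }
  combined <- NULL
  if (length(regions) >= 2 && !any(vapply(regions, `[[`, TRUE, "empty"))) {
    combined <- Reduce(combine_years, regions)
    if (!is.null(combined$et_interval))
      interval_rows[[length(interval_rows) + 1L]] <- data.frame(
        year = "combined", axis = "et", lower = combined$et_interval[1],
        upper = combined$et_interval[2], contiguous = NA)
    if (!is.null(combined$n_interval))
      interval_rows[[length(interval_rows) + 1L]] <- data.frame(
        year = "combined", axis = "n", lower = combined$n_interval[1],
        upper = combined$n_interval[2], contiguous = NA)
  }
  intervals <- do.call(rbind, interval_rows)
  utils::write.csv(intervals, art("intervals.csv"), row.names = FALSE)

  .report(config, intervals, art("report.txt"))
  .log(config, "done: artifacts in ", config$out_dir)
  invisible(list(trial = trial, indices = indices, summaries = summaries,
                 lai = lai, growth_fits = fits,
                 anova = do.call(rbind, anova_rows),
                 letters = do.call(rbind, letter_rows),
                 surfaces = surfaces, optima = do.call(rbind, opt_rows),
                 regions = regions, combined = combined,
                 intervals = intervals))
}

.report <- function(config, intervals, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "Water-nitrogen multi-objective optimization report",
    sprintf("seed: %d; grid: %d x %d; N domain: [%g, %g] kg/ha",
            config$seed, config$grid_n, config$grid_n,
            config$n_domain[1], config$n_domain[2]),
    sprintf("thresholds: %s",
            paste(sprintf("%s >= %g%% of box max", names(config$thresholds),
                          100 * config$thresholds), collapse = ", ")),
    ""), con)
  if (is.null(intervals) || nrow(intervals) == 0) {
    writeLines("no non-empty acceptability region found", con)
  } else {
    for (i in seq_len(nrow(intervals))) {
      unit <- if (intervals$axis[i] == "et") "mm" else "kg/ha"
      writeLines(sprintf("%-9s %-3s [%.1f, %.1f] %s%s",
                         intervals$year[i], intervals$axis[i],
                         intervals$lower[i], intervals$upper[i], unit,
                         ifelse(isFALSE(intervals$contiguous[i]),
                                " (gapped)", "")), con)
    }
  }
  invisible(path)
}

#' Coefficient-driven verification of the published analysis
#'
#' Re-derives, from the published summary tables carried by the package,
#' every closed-form quantity of the reference trial: the rapid-growth
#' characteristic parameters from the printed logistic (k, a, b); the
#' stationary points and box-constrained optima of the printed response
#' surfaces (ET domain = the year's observed cell-mean ET range, N domain
#' \[120, 240\] kg/ha); the per-year acceptability regions at the given
#' thresholds; and the year-combined intervals from the published per-year
#' intervals.
#'
#' @param thresholds acceptability fractions per response.
#' @param grid_n region grid cells per axis.
#' @param out_dir optional directory; when given, tables are written as CSV.
#' @return list with `characteristics`, `optima`, `regions`,
#'   `combined_regions` (from re-derived regions) and `combined_published`
#'   (intersection of the published per-year intervals).
#' @export
verify_reported <- function(thresholds = c(yield = 0.95, wue = 0.95,
                                           npfp = 0.75),
                            grid_n = 1000, out_dir = NULL) {
  gp <- reference_growth_params()
  ch <- do.call(rbind, lapply(seq_len(nrow(gp)), function(i) {
    p <- characteristic_params(gp$k[i], gp$a[i], gp$b[i])
    data.frame(year = gp$year[i], treatment = gp$treatment[i],
               t1 = p$t1, t2 = p$t2, tmax = p$tmax, delta_t = p$delta_t,
               vmax = p$vmax)
  }))

  sc <- reference_surface_coefficients()
  idx <- reference_indices_table()
  surfaces <- list(); opt_rows <- list()
  for (yr in unique(sc$year)) {
    ets <- idx$et_mean[idx$year == yr]
    domain <- list(x1 = range(ets), x2 = c(120, 240))
    surfaces[[yr]] <- list()
    for (r in c("yield", "wue", "npfp")) {
      row <- sc[sc$year == yr & sc$response == r, ]
      s <- quad_surface(c(y0 = row$y0, a = row$a, b = row$b, c = row$c,
                          d = row$d, e = row$e),
                        domain, response = r, year = yr, r2 = row$r2)
      surfaces[[yr]][[r]] <- s
      opt <- constrained_max(s)
      sp <- stationary_point(s)
      opt_rows[[length(opt_rows) + 1L]] <- data.frame(
        year = yr, response = r, et_at_max = opt$x1, n_at_max = opt$x2,
        max_value = opt$value, location = opt$location,
        stationary_et = sp$x1, stationary_n = sp$x2,
        stationary_kind = sp$kind)
    }
  }
  optima <- do.call(rbind, opt_rows)

  regions <- lapply(surfaces, acceptability_region, thresholds = thresholds,
                    grid_n = grid_n)
  combined_regions <-
    if (!any(vapply(regions, `[[`, TRUE, "empty")))
      Reduce(combine_years, regions) else NULL

  pub <- reference_optimum_intervals()$intervals
  pub_regions <- lapply(seq_len(nrow(pub)), function(i)
    list(et_interval = c(pub$et_lo[i], pub$et_hi[i]),
         n_interval = c(pub$n_lo[i], pub$n_hi[i])))
  combined_published <- Reduce(combine_years, pub_regions)

  out <- list(characteristics = ch, optima = optima, regions = regions,
              combined_regions = combined_regions,
              combined_published = combined_published)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ch, file.path(out_dir, "characteristics.csv"),
                     row.names = FALSE)
    utils::write.csv(optima, file.path(out_dir, "optima.csv"),
                     row.names = FALSE)
  }
  out
}
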