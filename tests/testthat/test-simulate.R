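test_that("a fixed seed gives bit-identical trials", {
  a <- generate_trial(synthetic_config(seed = 42))
  b <- generate_trial(synthetic_config(seed = 42))
  expect_identical(a$plots, b$plots)
  expect_identical(a$dma, b$dma)
  expect_identical(a$leaves, b$leaves)
  c <- generate_trial(synthetic_config(seed = 43))
  expect_false(identical(a$plots$grain_yield_kg_ha,
                         c$plots$grain_yield_kg_ha))
})

test_that("config invariants are validated", {
  expect_error(synthetic_config(noise = list(dma_cv = -0.1, yield_sd = 150,
                                             et_sd = 5)), "noise")
  expect_error(synthetic_config(times = c(20, 10, 40)), "increasing")
  sc <- reference_surface_coefficients()
  row <- sc[sc$year == "2021" & sc$response == "npfp", ]  # saddle
  bad <- quad_surface(c(y0 = row$y0, a = row$a, b = row$b, c = row$c,
                        d = row$d, e = row$e),
                      domain = list(x1 = c(270, 405), x2 = c(120, 240)))
  expect_error(synthetic_config(yield_surfaces = list("2021" = bad,
                                                      "2022" = bad)),
               "concave")
})

test_that("generator bookkeeping satisfies the water balance exactly", {
  trial <- generate_trial(synthetic_config(seed = 6), components = "plots")
  idx <- compute_indices(trial$plots)
  m <- merge(idx, trial$truth$plots, by = "plot_id")
  expect_equal(m$et_mm, m$et_true, tolerance = 1e-12)
  expect_equal(m$wue * 10 * m$et_mm, m$grain_yield_kg_ha, tolerance = 1e-12)
})

test_that("noise-free trials return the generating parameters exactly", {
  trial <- generate_trial(noiseless_config(seed = 10))
  idx <- compute_indices(trial$plots)
  cfg <- noiseless_config(seed = 10)
  for (yr in c("2021", "2022")) {
    s <- fit_year_surfaces(idx)[[yr]]$yield
    expect_equal(s$coefs, cfg$yield_surfaces[[yr]]$coefs, tolerance = 1e-8)
    expect_equal(s$r2, 1, tolerance = 1e-10)
  }
  sub <- trial$dma[trial$dma$plot_id == "P2022-W3N3-R2", ]
  f <- fit_logistic(sub$t_days, sub$dma_kg_ha)
  truth <- trial$truth$plots[trial$truth$plots$plot_id == "P2022-W3N3-R2", ]
  expect_equal(f$k, truth$k, tolerance = 1e-8)
  expect_equal(f$a, truth$a, tolerance = 1e-8)
  expect_equal(f$b, truth$b, tolerance = 1e-8)
})

test_that("default conditions reproduce the expected analysis regime", {
  trial <- generate_trial(synthetic_config(seed = 1))
  idx <- compute_indices(trial$plots)
  surfaces <- fit_year_surfaces(idx)
  for (yr in names(surfaces)) {
    expect_gt(surfaces[[yr]]$yield$r2, 0.95)
    reg <- acceptability_region(
      list(yield = surfaces[[yr]]$yield), grid_n = 200,
      thresholds = c(yield = 0.95))
    expect_false(reg$empty)
  }
})

test_that("null trials remove treatment structure but keep noise", {
  cfg <- synthetic_config(seed = 3, rainfall_mm = c("2021" = 164.4))
  null <- generate_null_trial(cfg, components = "plots")
  cells <- tapply(null$plots$grain_yield_kg_ha,
                  paste0(null$plots$water_level, null$plots$n_level), mean)
  # cell means scatter around one level with sd ~ yield_sd/sqrt(3)
  expect_lt(diff(range(cells)), 6 * cfg$noise$yield_sd / sqrt(3))
  expect_gt(sd(null$plots$grain_yield_kg_ha), 0)
  # zero-noise null: no variation at all -> ANOVA finds nothing
  null0 <- generate_null_trial(
    noiseless_config(seed = 3, rainfall_mm = c("2021" = 164.4)),
    components = "plots")
  at <- two_way_anova(null0$plots, "grain_yield_kg_ha")
  expect_equal(at$ss[at$effect %in% c("W", "N", "W:N")], rep(0, 3),
               tolerance = 1e-12)
  expect_true(all(at$code[at$effect %in% c("W", "N", "W:N")] == "ns"))
})

test_that("more yield noise lowers the median fitted R2", {
  r2_at <- function(sd) {
    median(vapply(1:5, function(s) {
      cfg <- synthetic_config(seed = s,
                              noise = list(dma_cv = 0.05, yield_sd = sd,
                                           et_sd = 5))
      idx <- compute_indices(generate_trial(cfg, components = "plots")$plots)
      fit_year_surfaces(idx)[["2021"]]$yield$r2
    }, 0))
  }
  expect_gt(r2_at(50), r2_at(600))
})

test_that("written trials carry a complete machine-readable ground truth", {
  dir <- withr::local_tempdir()
  trial <- generate_trial(synthetic_config(seed = 2))
  write_trial(trial, dir)
  expect_true(all(file.exists(file.path(dir, c("plots.csv", "dma.csv",
                                               "leaves.csv",
                                               "ground_truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 2)
  expect_equal(truth$config$noise$yield_sd, 150)
  expect_equal(truth$plots$et_true, trial$truth$plots$et_true)
})
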