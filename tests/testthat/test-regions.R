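test_that("acceptability masks are nested in the threshold", {
  s <- paraboloid_surface()
  g <- surface_grid(s$domain, 300)
  m95 <- acceptability_mask(s, 0.95, g)
  m75 <- acceptability_mask(s, 0.75, g)
  expect_true(all(m75[m95]))      # mask(0.95) subset of mask(0.75)
  expect_gt(sum(m75), sum(m95))
  # threshold -> 1 shrinks the mask to the neighbourhood of the argmax
  tight <- acceptability_mask(s, 0.999, g)
  expect_gte(sum(tight), 1)
  expect_lt(sum(tight), sum(m95) / 20)
  sp <- stationary_point(s)
  oracle <- ellipse_oracle(s, 0.999)
  hits <- which(tight, arr.ind = TRUE)
  expect_true(all(abs(g$x1[hits[, 1]] - sp$x1) <=
                    oracle$half[1] + g$step[["x1"]]))
  expect_true(all(abs(g$x2[hits[, 2]] - sp$x2) <=
                    oracle$half[2] + g$step[["x2"]]))
  expect_error(acceptability_mask(s, 1.2, g), "between 0 and 1")
})

test_that("threshold regions of a concave surface match the analytic ellipse", {
  s <- paraboloid_surface(center = c(240, 170), value = 120)
  g <- surface_grid(s$domain, 900)
  for (frac in c(0.95, 0.85)) {
    m <- acceptability_mask(s, frac, g)
    reg <- intersect_regions(list(yield = m))
    oracle <- ellipse_oracle(s, frac)
    expect_equal(reg$et_interval,
                 oracle$center[1] + c(-1, 1) * oracle$half[1],
                 tolerance = 2 * g$step[["x1"]] / oracle$half[1])
    expect_equal(reg$n_interval,
                 oracle$center[2] + c(-1, 1) * oracle$half[2],
                 tolerance = 2 * g$step[["x2"]] / oracle$half[2])
    area <- sum(m) * prod(g$step)
    expect_equal(area, oracle$area, tolerance = 0.01)
    expect_true(all(reg$contiguous))
  }
})

test_that("mask intersection is commutative and associative", {
  s1 <- paraboloid_surface(center = c(240, 170))
  s2 <- paraboloid_surface(center = c(260, 150), d = -0.01, e = -0.02)
  s3 <- paraboloid_surface(center = c(220, 190), d = -0.03, e = -0.008)
  g <- surface_grid(s1$domain, 250)
  m <- lapply(list(s1, s2, s3), acceptability_mask, threshold = 0.8,
              grid = g)
  ab <- intersect_regions(m[c(1, 2)])$intersection
  ba <- intersect_regions(m[c(2, 1)])$intersection
  expect_identical(ab, ba)
  abc <- intersect_regions(m)$intersection
  expect_identical(abc, ab & m[[3]])
  reg <- intersect_regions(m)
  expect_true(all(reg$intersection[reg$intersection] &
                    m[[1]][reg$intersection]))
})

test_that("nested masks intersect to the smallest, with its bounding ranges", {
  s <- paraboloid_surface()
  g <- surface_grid(s$domain, 400)
  masks <- list(a = acceptability_mask(s, 0.7, g),
                b = acceptability_mask(s, 0.8, g),
                c = acceptability_mask(s, 0.95, g))
  reg <- intersect_regions(masks)
  expect_equal(reg$intersection, masks$c, ignore_attr = TRUE)
  small <- intersect_regions(masks["c"])
  expect_equal(reg$et_interval, small$et_interval)
  expect_equal(reg$n_interval, small$n_interval)
})

test_that("empty intersections are flagged, not errored", {
  s1 <- paraboloid_surface(center = c(150, 100))
  s2 <- paraboloid_surface(center = c(380, 280))
  g <- surface_grid(s1$domain, 200)
  reg <- intersect_regions(list(a = acceptability_mask(s1, 0.99, g),
                                b = acceptability_mask(s2, 0.99, g)))
  expect_true(reg$empty)
  expect_null(reg$et_interval)
  expect_error(combine_years(reg, reg), "empty region")
})

test_that("published per-year intervals combine to the headline optimum", {
  a <- list(et_interval = c(334.3, 348.7), n_interval = c(160.9, 175.3))
  b <- list(et_interval = c(319.9, 349.3), n_interval = c(158.1, 185.1))
  comb <- combine_years(a, b)
  expect_equal(comb$et_interval, c(334.3, 348.7))
  expect_equal(comb$n_interval, c(160.9, 175.3))
  expect_false(any(comb$empty))
  same <- combine_years(a, a)
  expect_equal(same$et_interval, a$et_interval)
  disjoint <- combine_years(a, list(et_interval = c(400, 410),
                                    n_interval = c(160, 170)))
  expect_true(disjoint$empty[["et"]])
  expect_null(disjoint$et_interval)
})

test_that("halving the grid step moves endpoints by at most one old step", {
  surfaces <- list(yield = paraboloid_surface(center = c(240, 170)),
                   wue = paraboloid_surface(center = c(230, 180),
                                            d = -0.015, e = -0.012),
                   npfp = paraboloid_surface(center = c(200, 140),
                                             d = -0.01, e = -0.02))
  coarse <- acceptability_region(surfaces, grid_n = 250)
  fine <- acceptability_region(surfaces, grid_n = 500)
  old_step <- coarse$grid$step
  expect_lte(max(abs(coarse$et_interval - fine$et_interval)),
             old_step[["x1"]] + 1e-9)
  expect_lte(max(abs(coarse$n_interval - fine$n_interval)),
             old_step[["x2"]] + 1e-9)
})

test_that("the region reports which response blocks each endpoint", {
  surfaces <- list(yield = paraboloid_surface(center = c(240, 170)),
                   wue = paraboloid_surface(center = c(250, 175),
                                            d = -0.015, e = -0.012))
  reg <- acceptability_region(surfaces,
                              thresholds = c(yield = 0.9, wue = 0.9),
                              grid_n = 300)
  expect_false(reg$empty)
  expect_true(all(lengths(reg$active_constraints) >= 1))
})
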