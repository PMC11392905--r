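test_that("noiseless quadratic data are recovered exactly", {
  truth <- c(y0 = -10000, a = 70, b = 30, c = 0.02, d = -0.1, e = -0.09)
  g <- expand.grid(x1 = c(280, 330, 395), x2 = c(120, 180, 240))
  y <- truth[["y0"]] + truth[["a"]] * g$x1 + truth[["b"]] * g$x2 +
    truth[["c"]] * g$x1 * g$x2 + truth[["d"]] * g$x1^2 +
    truth[["e"]] * g$x2^2
  s <- fit_surface(g$x1, g$x2, y)
  expect_equal(s$coefs, truth, tolerance = 1e-8)
  expect_equal(s$r2, 1, tolerance = 1e-10)
})

test_that("constant response gives zero non-intercept coefficients", {
  g <- expand.grid(x1 = c(280, 330, 395), x2 = c(120, 180, 240))
  s <- fit_surface(g$x1, g$x2, rep(5, 9))
  expect_equal(unname(s$coefs[c("a", "b", "c", "d", "e")]), rep(0, 5),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  g <- expand.grid(x1 = c(280, 330, 395), x2 = c(120, 180, 240))
  expect_error(fit_surface(g$x1, rep(c(120, 180), length.out = 9), g$x1),
               "at least 3 distinct")
  # x2 identical to x1: interaction and squares collapse
  expect_error(fit_surface(g$x1, g$x1, g$x1), "collinear")
  x1 <- c(100, 200, 300, 100, 200, 300)
  expect_error(fit_surface(x1, 2 * x1, rnorm(6)), "collinear")
})

test_that("stationary point solves the gradient system", {
  s <- paraboloid_surface(center = c(0, 0), value = 50,
                          domain = list(x1 = c(-10, 10), x2 = c(-10, 10)))
  sp <- stationary_point(s)
  expect_equal(c(sp$x1, sp$x2), c(0, 0), tolerance = 1e-12)
  expect_equal(sp$kind, "maximum")
  set.seed(31)
  for (i in 1:10) {
    s <- paraboloid_surface(center = runif(2, 120, 280), value = 100,
                            d = -runif(1, 0.005, 0.05),
                            e = -runif(1, 0.005, 0.05),
                            c = runif(1, -0.004, 0.004))
    sp <- stationary_point(s)
    p <- s$coefs
    # gradient components vanish at the stationary point
    expect_equal(p[["a"]] + p[["c"]] * sp$x2 + 2 * p[["d"]] * sp$x1, 0,
                 tolerance = 1e-9)
    expect_equal(p[["b"]] + p[["c"]] * sp$x1 + 2 * p[["e"]] * sp$x2, 0,
                 tolerance = 1e-9)
  }
})

test_that("box-constrained maximization matches a dense grid search", {
  set.seed(7)
  domain <- list(x1 = c(100, 400), x2 = c(120, 240))
  for (i in 1:20) {
    coefs <- c(y0 = runif(1, -50, 50), a = runif(1, -1, 1),
               b = runif(1, -1, 1), c = runif(1, -0.01, 0.01),
               d = runif(1, -0.003, 0.001), e = runif(1, -0.003, 0.001))
    s <- quad_surface(coefs, domain)
    opt <- constrained_max(s)
    g1 <- seq(domain$x1[1], domain$x1[2], length.out = 800)
    g2 <- seq(domain$x2[1], domain$x2[2], length.out = 800)
    vals <- outer(g1, g2, function(a, b) predict(s, a, b))
    top <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    step <- c(g1[2] - g1[1], g2[2] - g2[1])
    expect_gte(opt$value, max(vals) - 1e-9 * max(1, abs(max(vals))))
    expect_lte(abs(opt$x1 - g1[top[1]]), step[1] + 1e-9)
    expect_lte(abs(opt$x2 - g2[top[2]]), step[2] + 1e-9)
  }
})

test_that("interior maxima agree between stationary and constrained analyses", {
  s <- paraboloid_surface()
  sp <- stationary_point(s)
  opt <- constrained_max(s, grid_check = TRUE)
  expect_equal(opt$location, "interior")
  expect_equal(c(opt$x1, opt$x2, opt$value), c(sp$x1, sp$x2, sp$value))
})

test_that("the optimum dominates every design point of a generated trial", {
  idx <- compute_indices(generate_trial(synthetic_config(seed = 12),
                                        components = "plots")$plots)
  surfaces <- fit_year_surfaces(idx)
  for (yr in names(surfaces)) {
    s <- surfaces[[yr]]$yield
    sub <- idx[idx$year == yr, ]
    opt <- constrained_max(s)
    expect_true(all(opt$value + 1e-9 >=
                      predict(s, sub$et_mm, sub$n_total_kg_ha)))
  }
})

test_that("fitting is equivariant under affine rescaling of the response", {
  g <- expand.grid(x1 = c(280, 310, 340, 395), x2 = c(120, 180, 240))
  set.seed(5)
  y <- 4000 + 3 * g$x1 - 2 * g$x2 + rnorm(12, 0, 10)
  s1 <- fit_surface(g$x1, g$x2, y)
  s2 <- fit_surface(g$x1, g$x2, 2.5 * y + 7)
  expect_equal(s2$r2, s1$r2, tolerance = 1e-10)
  scaled <- 2.5 * s1$coefs
  scaled[["y0"]] <- scaled[["y0"]] + 7
  expect_equal(s2$coefs, scaled, tolerance = 1e-8)
})

test_that("a saddle surface maximizes on the low-N boundary", {
  sc <- reference_surface_coefficients()
  row <- sc[sc$year == "2021" & sc$response == "npfp", ]
  s <- quad_surface(c(y0 = row$y0, a = row$a, b = row$b, c = row$c,
                      d = row$d, e = row$e),
                    domain = list(x1 = c(271.65, 404.53), x2 = c(120, 240)),
                    response = "npfp")
  expect_equal(stationary_point(s)$kind, "saddle")
  opt <- constrained_max(s, grid_check = TRUE)
  expect_equal(opt$x2, 120)
  expect_equal(opt$location, "edge")
})
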