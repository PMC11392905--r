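# Shared fixtures, all built in code.

# Noise-free generator configuration (same design/parameters as defaults).
noiseless_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed,
                   noise = list(dma_cv = 0, yield_sd = 0, et_sd = 0), ...)
}

# A concave quadratic surface with a prescribed interior maximum, built
# from the center so threshold sets are exact ellipses.
paraboloid_surface <- function(center = c(250, 180), value = 100,
                               d = -0.02, e = -0.01, c = 0.005,
                               domain = list(x1 = c(100, 400),
                                             x2 = c(60, 300))) {
  a <- -2 * d * center[1] - c * center[2]
  b <- -2 * e * center[2] - c * center[1]
  y0 <- value - (a * center[1] + b * center[2] + c * prod(center) +
                   d * center[1]^2 + e * center[2]^2)
  quad_surface(c(y0 = y0, a = a, b = b, c = c, d = d, e = e), domain,
               response = "yield")
}

# Closed-form projection half-widths and area of the ellipse
# {f >= frac * fmax} for a concave quadratic with interior maximum.
ellipse_oracle <- function(surface, frac) {
  sp <- stationary_point(surface)
  H <- matrix(c(2 * surface$coefs[["d"]], surface$coefs[["c"]],
                surface$coefs[["c"]], 2 * surface$coefs[["e"]]), 2, 2)
  r2 <- 2 * (1 - frac) * sp$value
  Hi <- solve(-H)
  list(center = c(sp$x1, sp$x2),
       half = c(sqrt(r2 * Hi[1, 1]), sqrt(r2 * Hi[2, 2])),
       area = pi * r2 / sqrt(det(-H)))
}

# Balanced factorial observations with prescribed effects.
factorial_data <- function(w_eff = c(0, 0, 0), n_eff = c(0, 0, 0),
                           mu = 100, sd = 1, reps = 3, seed = 1) {
  grid <- expand.grid(water_level = c("W1", "W2", "W3"),
                      n_level = c("N1", "N2", "N3"),
                      replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  set.seed(seed)
  grid$value <- mu + w_eff[match(grid$water_level, c("W1", "W2", "W3"))] +
    n_eff[match(grid$n_level, c("N1", "N2", "N3"))] +
    rnorm(nrow(grid), 0, sd)
  grid
}
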