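# Quadratic response surface in (water consumption, nitrogen rate):
# y = y0 + a x1 + b x2 + c x1 x2 + d x1^2 + e x2^2, fitted by ordinary
# least squares, with stationary-point and box-constrained maximization.

#' Construct a quadratic response surface
#'
#' Builds a `quad_surface` from known coefficients, e.g. published
#' regression tables, bypassing fitting (verification mode). The surface is
#' y = y0 + a x1 + b x2 + c x1 x2 + d x1^2 + e x2^2 with x1 = ET (mm) and
#' x2 = N rate (kg/ha).
#'
#' @param coefs named numeric vector with y0, a, b, c, d, e.
#' @param domain list with numeric `x1` and `x2` ranges (the box over which
#'   optimization and region analysis operate).
#' @param response response name, e.g. `"yield"`, `"wue"`, `"npfp"`.
#' @param year optional season label.
#' @param r2 coefficient of determination, if known.
#' @param n_obs number of observations behind the fit, if known.
#' @return An object of class `quad_surface`.
#' @export
quad_surface <- function(coefs, domain, response = "yield", year = NA,
                         r2 = NA_real_, n_obs = NA_integer_) {
  need <- c("y0", "a", "b", "c", "d", "e")
  if (!all(need %in% names(coefs)))
    stop("coefs must contain ", paste(need, collapse = ", "))
  coefs <- coefs[need]
  if (!is.list(domain) || !all(c("x1", "x2") %in% names(domain)) ||
      diff(range(domain$x1)) <= 0 || diff(range(domain$x2)) <= 0)
    stop("domain must be a list with non-empty numeric ranges x1 and x2")
  structure(list(coefs = coefs,
                 domain = list(x1 = range(domain$x1), x2 = range(domain$x2)),
                 response = response, year = year, r2 = r2,
                 n_obs = n_obs),
            class = "quad_surface")
}

#' Evaluate a quadratic surface
#'
#' @param object a `quad_surface`.
#' @param x1,x2 coordinates (recycled).
#' @param ... unused.
#' @return Surface values.
#' @export
predict.quad_surface <- function(object, x1, x2, ...) {
  p <- object$coefs
  p[["y0"]] + p[["a"]] * x1 + p[["b"]] * x2 + p[["c"]] * x1 * x2 +
    p[["d"]] * x1^2 + p[["e"]] * x2^2
}

#' @export
print.quad_surface <- function(x, ...) {
  p <- x$coefs
  cat(sprintf("Quadratic surface (%s%s): y = %.4g %+.4g x1 %+.4g x2 %+.4g x1.x2 %+.4g x1^2 %+.4g x2^2\n",
              x$response, if (is.na(x$year)) "" else paste0(", ", x$year),
              p[["y0"]], p[["a"]], p[["b"]], p[["c"]], p[["d"]], p[["e"]]))
  cat(sprintf("  domain: ET [%g, %g] mm, N [%g, %g] kg/ha; R2 = %s; n = %s\n",
              x$domain$x1[1], x$domain$x1[2], x$domain$x2[1], x$domain$x2[2],
              format(x$r2), format(x$n_obs)))
  invisible(x)
}

#' Fit a quadratic response surface by ordinary least squares
#'
#' Regresses y on \[1, x1, x2, x1 x2, x1^2, x2^2\]. Requires at least six
#' observations spanning at least three distinct values on each axis.
#'
#' @param x1 water consumption ET (mm).
#' @param x2 nitrogen rate (kg/ha).
#' @param y response values.
#' @param domain optional box; defaults to the observed x1 range and the
#'   design N range \[120, 240\] (see Details).
#' @param response,year labels stored on the surface.
#' @details The default N domain is the design range \[120, 240\] kg/ha
#'   rather than the observed range, because treatment N rates are exactly
#'   the design values; the ET domain defaults to the observed range per
#'   year. Both can be overridden.
#' @return A `quad_surface` with r2 and n_obs populated.
#' @export
fit_surface <- function(x1, x2, y, domain = NULL, response = "yield",
                        year = NA) {
  if (length(unique(x1)) < 3 || length(unique(x2)) < 3)
    stop("need at least 3 distinct values of each of x1 and x2")
  if (length(y) < 6) stop("need at least 6 observations")
  X <- cbind(x1 = x1, x2 = x2, x1x2 = x1 * x2, x1sq = x1^2, x2sq = x2^2)
  fit <- stats::lm(y ~ x1 + x2 + x1x2 + x1sq + x2sq, data = data.frame(y, X))
  cf <- coef(fit)
  if (any(is.na(cf))) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design: collinear term(s) ",
         paste(bad, collapse = ", "))
  }
  names(cf) <- c("y0", "a", "b", "c", "d", "e")
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  if (is.null(domain)) domain <- list(x1 = range(x1), x2 = c(120, 240))
  quad_surface(cf, domain, response = response, year = year,
               r2 = if (sst > 0) 1 - sse / sst else 1,
               n_obs = length(y))
}

#' Fit the per-year response surfaces from treatment cell means
#'
#' Convenience wrapper: aggregates plot indices to the 9 W x N cell means
#' (the summary-table structure) and fits one surface per year for each
#' requested response.
#'
#' @param indices output of [compute_indices()].
#' @param responses named character vector mapping surface names to index
#'   columns.
#' @param level `"cell"` fits on the 9 cell means (default), `"plot"` on
#'   individual plots.
#' @param n_domain N domain box passed to every surface.
#' @return Named list (year) of named lists (response) of `quad_surface`.
#' @export
fit_year_surfaces <- function(indices,
                              responses = c(yield = "grain_yield_kg_ha",
                                            wue = "wue", npfp = "npfp"),
                              level = c("cell", "plot"),
                              n_domain = c(120, 240)) {
  level <- match.arg(level)
  out <- list()
  for (yr in unique(indices$year)) {
    sub <- indices[indices$year == yr, ]
    if (level == "cell") {
      agg <- stats::aggregate(
        sub[, unname(c("et_mm", responses))],
        by = list(water_level = sub$water_level, n_level = sub$n_level),
        FUN = mean)
      x1 <- agg$et_mm
      x2v <- stats::aggregate(sub$n_total_kg_ha,
                              by = list(water_level = sub$water_level,
                                        n_level = sub$n_level),
                              FUN = mean)$x
      dat <- agg
    } else {
      x1 <- sub$et_mm
      x2v <- sub$n_total_kg_ha
      dat <- sub
    }
    out[[yr]] <- lapply(setNames(names(responses), names(responses)),
                        function(r) {
      fit_surface(x1, x2v, dat[[responses[[r]]]],
                  domain = list(x1 = range(x1), x2 = n_domain),
                  response = r, year = yr)
    })
  }
  out
}

# Hessian of the quadratic: [[2d, c], [c, 2e]].
.surface_hessian <- function(surface) {
  p <- surface$coefs
  matrix(c(2 * p[["d"]], p[["c"]], p[["c"]], 2 * p[["e"]]), 2, 2)
}

#' Stationary point of a quadratic surface
#'
#' Solves the gradient system: x1* = (c b - 2 e a)/(4 d e - c^2),
#' x2* = (c a - 2 d b)/(4 d e - c^2), and classifies it from the Hessian
#' (`"maximum"`, `"minimum"`, `"saddle"`); a singular Hessian yields kind
#' `"degenerate"` with no coordinates.
#'
#' @param surface a `quad_surface`.
#' @return list with x1, x2, value, kind, and `inside` (whether the point
#'   lies in the domain box).
#' @export
stationary_point <- function(surface) {
  p <- surface$coefs
  den <- 4 * p[["d"]] * p[["e"]] - p[["c"]]^2
  if (abs(den) < .Machine$double.eps * max(1, abs(p[["d"]] * p[["e"]])))
    return(list(x1 = NA_real_, x2 = NA_real_, value = NA_real_,
                kind = "degenerate", inside = FALSE))
  x1 <- (p[["c"]] * p[["b"]] - 2 * p[["e"]] * p[["a"]]) / den
  x2 <- (p[["c"]] * p[["a"]] - 2 * p[["d"]] * p[["b"]]) / den
  kind <- if (den > 0 && p[["d"]] < 0) "maximum"
          else if (den > 0) "minimum" else "saddle"
  inside <- x1 >= surface$domain$x1[1] && x1 <= surface$domain$x1[2] &&
    x2 >= surface$domain$x2[1] && x2 <= surface$domain$x2[2]
  list(x1 = x1, x2 = x2, value = predict(surface, x1, x2), kind = kind,
       inside = inside)
}

# Maximize the 1-D quadratic restriction of the surface along one box edge.
.edge_max <- function(surface, axis, fixed) {
  p <- surface$coefs
  if (axis == "x1") {
    rng <- surface$domain$x1
    # y(x1) = (d) x1^2 + (a + c fixed) x1 + const
    qa <- p[["d"]]; qb <- p[["a"]] + p[["c"]] * fixed
    cand <- rng
    if (qa < 0) cand <- c(cand, min(max(-qb / (2 * qa), rng[1]), rng[2]))
    vals <- predict(surface, cand, fixed)
    i <- which.max(vals)
    list(x1 = cand[i], x2 = fixed, value = vals[i])
  } else {
    rng <- surface$domain$x2
    qa <- p[["e"]]; qb <- p[["b"]] + p[["c"]] * fixed
    cand <- rng
    if (qa < 0) cand <- c(cand, min(max(-qb / (2 * qa), rng[1]), rng[2]))
    vals <- predict(surface, fixed, cand)
    i <- which.max(vals)
    list(x1 = fixed, x2 = cand[i], value = vals[i])
  }
}

#' Box-constrained maximum of a quadratic surface
#'
#' Returns the interior stationary point when it is a maximum inside the
#' domain box; otherwise maximizes the 1-D quadratic restriction along each
#' of the four edges (vertex-or-endpoint logic, corners included) and takes
#' the argmax. Optionally cross-checks against a dense grid evaluation.
#'
#' @param surface a `quad_surface`.
#' @param grid_check if `TRUE`, verify the result against an `n_grid` x
#'   `n_grid` evaluation (error if the grid beats the analytic optimum by
#'   more than one grid cell's worth of surface change).
#' @param n_grid grid resolution for the cross-check.
#' @return An object of class `surface_optimum`: x1, x2, value, and
#'   `location` (`"interior"`, `"edge"` or `"corner"`).
#' @export
constrained_max <- function(surface, grid_check = FALSE, n_grid = 200) {
  sp <- stationary_point(surface)
  if (sp$kind == "maximum" && sp$inside) {
    out <- list(x1 = sp$x1, x2 = sp$x2, value = sp$value,
                location = "interior")
  } else {
    cands <- list(
      .edge_max(surface, "x1", surface$domain$x2[1]),
      .edge_max(surface, "x1", surface$domain$x2[2]),
      .edge_max(surface, "x2", surface$domain$x1[1]),
      .edge_max(surface, "x2", surface$domain$x1[2]))
    best <- cands[[which.max(vapply(cands, `[[`, 0, "value"))]]
    on_x1_end <- best$x1 %in% surface$domain$x1
    on_x2_end <- best$x2 %in% surface$domain$x2
    best$location <- if (on_x1_end && on_x2_end) "corner" else "edge"
    out <- best
  }
  if (grid_check) {
    g1 <- seq(surface$domain$x1[1], surface$domain$x1[2], length.out = n_grid)
    g2 <- seq(surface$domain$x2[1], surface$domain$x2[2], length.out = n_grid)
    vals <- outer(g1, g2, function(a, b) predict(surface, a, b))
    gmax <- max(vals)
    if (gmax > out$value + 1e-8 * max(1, abs(out$value)))
      stop("grid cross-check found a larger value than the analytic optimum")
  }
  structure(out, class = "surface_optimum")
}

#' @export
print.surface_optimum <- function(x, ...) {
  cat(sprintf("Surface maximum (%s): %.4f at ET = %.2f mm, N = %.2f kg/ha\n",
              x$location, x$value, x$x1, x$x2))
  invisible(x)
}
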