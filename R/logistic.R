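# Logistic dry-matter accumulation model and its rapid-growth
# characteristic parameters.
#
# y(t) = k / (1 + a exp(-b t)); the second derivative has extrema at
# t1 = ln(a/(2+sqrt(3)))/b and t2 = ln(a/(2-sqrt(3)))/b, bracketing the
# inflection tmax = ln(a)/b. [t1, t2] is the rapid-growth period, its
# duration dt = ln(7+4 sqrt(3))/b depends on b alone, and the peak
# accumulation rate is vmax = k b / 4.

#' Logistic growth curve value
#'
#' @param t days after seedling emergence.
#' @param k asymptotic dry matter accumulation (kg/ha).
#' @param a dimensionless shape parameter.
#' @param b rate parameter (1/day).
#' @return Dry matter accumulation at `t` (kg/ha).
#' @export
logistic_value <- function(t, k, a, b) {
  .check_kab(k, a, b)
  k / (1 + a * exp(-b * t))
}

#' Logistic growth curve accumulation rate (first derivative)
#'
#' @inheritParams logistic_value
#' @return Accumulation rate at `t` (kg/ha/day).
#' @export
logistic_rate <- function(t, k, a, b) {
  .check_kab(k, a, b)
  u <- a * exp(-b * t)
  k * b * u / (1 + u)^2
}

.check_kab <- function(k, a, b) {
  if (any(k <= 0) || any(a <= 0) || any(b <= 0))
    stop("logistic parameters k, a, b must all be positive")
  invisible(TRUE)
}

#' Rapid-growth characteristic parameters of a logistic curve
#'
#' Closed forms: vmax = k b / 4; tmax = ln(a)/b; t1 = ln(a/(2+sqrt(3)))/b;
#' t2 = ln(a/(2-sqrt(3)))/b; delta_t = t2 - t1 = ln(7+4 sqrt(3))/b. t1 is
#' negative when a < 2 + sqrt(3) (rapid growth begins before emergence);
#' this is allowed and flagged.
#'
#' @inheritParams logistic_value
#' @return list with vmax, tmax, t1, t2, delta_t and `t1_negative` flag.
#' @examples
#' p <- characteristic_params(17398.01, 204.06, 0.078)
#' round(p$tmax, 2)  # 68.18
#' @export
characteristic_params <- function(k, a, b) {
  .check_kab(k, a, b)
  s3 <- sqrt(3)
  t1 <- log(a / (2 + s3)) / b
  t2 <- log(a / (2 - s3)) / b
  list(vmax = k * b / 4, tmax = log(a) / b, t1 = t1, t2 = t2,
       delta_t = t2 - t1, t1_negative = t1 < 0)
}

#' Fit the logistic growth model to a dry-matter series
#'
#' Nonlinear least squares on y ~ k/(1 + a exp(-b t)) with a log
#' parameterization that keeps k, a, b positive (Levenberg-Marquardt via
#' minpack.lm). Starting values: k0 = 1.05 max(y), and (a0, b0) from
#' ordinary least squares on ln(k0/y - 1) vs t; up to `max_restarts`
#' seeded jittered restarts on failure.
#'
#' @param t days after emergence (>= 5 points, strictly increasing).
#' @param y dry matter accumulation (kg/ha), non-negative; at least one
#'   point must lie past the empirical inflection (y > max(y)/2).
#' @param init optional named list/vector with starting `k`, `a`, `b`.
#' @param max_restarts jittered restarts tried after a failed fit.
#' @param seed integer seed for the restart jitter.
#' @return An object of class `logistic_fit`: estimates k, a, b, r2, the
#'   characteristic parameters of [characteristic_params()], `n_points` and
#'   a `converged` flag.
#' @export
fit_logistic <- function(t, y, init = NULL, max_restarts = 5, seed = 1L) {
  if (length(t) != length(y)) stop("t and y lengths differ")
  if (length(t) < 5) stop("need at least 5 time points to fit")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (any(y < 0)) stop("dry matter values must be non-negative")
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("degenerate series: no variation in y")
  if (sum(y > max(y) / 2) < 1)
    stop("no point past the empirical inflection (y > max(y)/2)")

  if (is.null(init)) {
    k0 <- 1.05 * max(y)
    pos <- y > 0 & y < k0
    z <- log(k0 / y[pos] - 1)
    ols <- stats::lm(z ~ t[pos])
    b0 <- max(-coef(ols)[[2]], 1e-4)
    a0 <- max(exp(coef(ols)[[1]]), 1e-4)
    init <- c(k = k0, a = a0, b = b0)
  } else {
    init <- c(k = init[["k"]], a = init[["a"]], b = init[["b"]])
  }

  dat <- data.frame(t = t, y = y)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(lk) / (1 + exp(la) * exp(-exp(lb) * t)),
        data = dat,
        start = list(lk = log(start[["k"]]), la = log(start[["a"]]),
                     lb = log(start[["b"]])),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) e)
  }

  fit <- try_fit(init)
  restarts_used <- 0L
  if (inherits(fit, "error") && max_restarts > 0) {
    for (i in seq_len(max_restarts)) {
      jitter <- .with_seed(seed + i, exp(stats::rnorm(3, 0, 0.3)))
      fit2 <- try_fit(init * jitter)
      restarts_used <- i
      if (!inherits(fit2, "error")) { fit <- fit2; break }
    }
  }
  if (inherits(fit, "error"))
    stop("logistic fit did not converge after ", max_restarts,
         " restarts: ", conditionMessage(fit),
         " (best starting values k=", signif(init[["k"]], 6),
         ", a=", signif(init[["a"]], 6), ", b=", signif(init[["b"]], 6), ")")

  est <- exp(coef(fit))
  names(est) <- c("k", "a", "b")
  resid <- y - logistic_value(t, est[["k"]], est[["a"]], est[["b"]])
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  ch <- characteristic_params(est[["k"]], est[["a"]], est[["b"]])
  structure(
    c(list(k = est[["k"]], a = est[["a"]], b = est[["b"]],
           r2 = 1 - sse / sst, sse = sse, n_points = length(t),
           converged = fit$convInfo$isConv %||% TRUE,
           restarts_used = restarts_used,
           fitted = y - resid, residuals = resid, t = t, y = y),
      ch),
    class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit (n = %d, R2 = %.4f)\n", x$n_points, x$r2))
  cat(sprintf("  k = %.2f kg/ha, a = %.2f, b = %.4f /day\n", x$k, x$a, x$b))
  cat(sprintf("  rapid growth: t1 = %.2f, t2 = %.2f d (dt = %.2f d)\n",
              x$t1, x$t2, x$delta_t))
  cat(sprintf("  vmax = %.2f kg/ha/day at tmax = %.2f d\n", x$vmax, x$tmax))
  invisible(x)
}

#' Fit logistic growth curves for every treatment cell (or plot)
#'
#' With `by = "cell"` the replicate series of each year x treatment cell are
#' averaged at each sampling time before fitting (the summary-table
#' convention); with `by = "plot"` each plot's series is fitted separately.
#'
#' @param dma a `dma`-schema data.frame (see [load_records()]).
#' @param by `"cell"` or `"plot"`.
#' @param ... passed to [fit_logistic()].
#' @return data.frame with year, water_level, n_level (and plot_id for
#'   `by = "plot"`), k, a, b, r2, t1, t2, tmax, delta_t, vmax, converged.
#' @export
fit_growth_curves <- function(dma, by = c("cell", "plot"), ...) {
  by <- match.arg(by)
  if (by == "cell") {
    agg <- stats::aggregate(
      dma_kg_ha ~ year + water_level + n_level + t_days, data = dma,
      FUN = mean)
    keys <- unique(agg[, c("year", "water_level", "n_level")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- merge(keys[i, , drop = FALSE], agg)
      sub <- sub[order(sub$t_days), ]
      f <- fit_logistic(sub$t_days, sub$dma_kg_ha, ...)
      cbind(keys[i, , drop = FALSE], .fit_row(f))
    })
  } else {
    keys <- unique(dma[, c("plot_id", "year", "water_level", "n_level")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- merge(keys[i, , drop = FALSE], dma)
      sub <- sub[order(sub$t_days), ]
      f <- fit_logistic(sub$t_days, sub$dma_kg_ha, ...)
      cbind(keys[i, , drop = FALSE], .fit_row(f))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.fit_row <- function(f) {
  data.frame(k = f$k, a = f$a, b = f$b, r2 = f$r2, t1 = f$t1, t2 = f$t2,
             tmax = f$tmax, delta_t = f$delta_t, vmax = f$vmax,
             converged = f$converged)
}
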