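# Two-factor ANOVA with a replication block and Duncan's multiple range
# test for treatment-letter displays.

#' Two-way ANOVA for a balanced water x nitrogen trial
#'
#' Fixed-effects decomposition with a replication block term:
#' value ~ replicate + W + N + W:N, all F tests against the error mean
#' square. The layout must be balanced (every W x N x replicate combination
#' observed once). Replication enters as a fixed block; with balanced data
#' the W, N and W x N tests coincide with those from a model treating
#' replication as random.
#'
#' @param df data.frame with columns `water_level`, `n_level`, `replicate`
#'   and the response column.
#' @param response name of the response column.
#' @return An object of class `anova_table`: data.frame with effect, df,
#'   ss, ms, F, p and a significance code (`**` p < 0.01, `*` p < 0.05,
#'   `ns`).
#' @export
two_way_anova <- function(df, response = "value") {
  need <- c("water_level", "n_level", "replicate", response)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  tab <- table(df$water_level, df$n_level, df$replicate)
  if (length(unique(as.vector(tab))) != 1 || any(tab != 1))
    stop("unbalanced layout: every W x N x replicate cell must be observed once")
  d <- data.frame(W = factor(df$water_level), N = factor(df$n_level),
                  R = factor(df$replicate), y = df[[response]])
  fit <- stats::aov(y ~ R + W + N + W:N, data = d)
  a <- summary(fit)[[1]]
  eff <- trimws(rownames(a))
  map <- c(R = "replication", W = "W", N = "N", `W:N` = "W:N",
           Residuals = "error")
  out <- data.frame(
    effect = unname(map[eff]),
    df = a$Df, ss = a$`Sum Sq`, ms = a$`Mean Sq`,
    F = a$`F value`, p = a$`Pr(>F)`)
  # an undefined F (zero error and effect SS) is reported as ns, not as
  # evidence of an effect
  out$code <- ifelse(out$effect == "error", "",
                     ifelse(is.na(out$p), "ns",
                            ifelse(out$p < 0.01, "**",
                                   ifelse(out$p < 0.05, "*", "ns"))))
  structure(out, class = c("anova_table", "data.frame"),
            ms_error = out$ms[out$effect == "error"],
            df_error = out$df[out$effect == "error"])
}

#' @export
print.anova_table <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$ss <- signif(y$ss, 6); y$ms <- signif(y$ms, 6)
  y$F <- signif(y$F, 4); y$p <- signif(y$p, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

# Duncan's protection level for a span of p means.
.duncan_alpha <- function(alpha, p) 1 - (1 - alpha)^(p - 1)

# Critical range for a span of p ordered means.
.duncan_range <- function(p, ms_error, df_error, n, alpha) {
  q <- stats::qtukey(1 - .duncan_alpha(alpha, p), p, df_error)
  q * sqrt(ms_error / n)
}

#' Duncan's multiple range test with letter display
#'
#' Means are sorted in descending order; the critical range for a span of p
#' means uses the studentized-range quantile at Duncan's protection level
#' alpha_p = 1 - (1 - alpha)^(p - 1), computed numerically from the
#' studentized-range distribution. Two means differ significantly when their
#' gap exceeds the critical range of the interval spanning them; letters
#' mark the maximal homogeneous intervals, `a` for the group containing the
#' highest mean.
#'
#' @param means named numeric vector of treatment means.
#' @param ms_error error mean square from the ANOVA.
#' @param df_error error degrees of freedom (>= 1).
#' @param n number of observations behind each mean.
#' @param alpha significance level.
#' @return An object of class `duncan_groups`: data.frame (treatment, mean,
#'   letters) in descending mean order, with the critical ranges attached.
#' @export
duncan_letters <- function(means, ms_error, df_error, n, alpha = 0.05) {
  if (length(means) < 2) stop("need at least 2 means")
  if (is.null(names(means)) || anyDuplicated(names(means)))
    stop("means must have unique names")
  if (ms_error <= 0) stop("ms_error must be positive")
  if (df_error < 1) stop("df_error must be at least 1")
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  crit <- vapply(2:k, .duncan_range, 0, ms_error = ms_error,
                 df_error = df_error, n = n, alpha = alpha)
  names(crit) <- paste0("span", 2:k)
  # Homogeneous interval [i, j]: the extreme gap is below the critical
  # range for its span (spans of 1 are trivially homogeneous). Under the
  # step-down protection rule, a pair is not significantly different iff
  # some homogeneous interval covers it, so each letter marks the widest
  # homogeneous interval per starting mean (homogeneity is not monotone in
  # the span: gap and critical range both grow, so scan all extensions).
  homog <- function(i, j)
    i == j || (m[i] - m[j]) < crit[[paste0("span", j - i + 1)]]
  intervals <- list()
  for (i in seq_len(k)) {
    j <- max(which(vapply(i:k, function(j2) homog(i, j2), logical(1)))) +
      i - 1L
    covered <- length(intervals) &&
      intervals[[length(intervals)]][2] >= j
    if (!covered) intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  letters_by_trt <- rep("", k)
  for (g in seq_along(intervals)) {
    span <- intervals[[g]]
    idx <- span[1]:span[2]
    letters_by_trt[idx] <- paste0(letters_by_trt[idx], letters[g])
  }
  out <- data.frame(treatment = names(m), mean = unname(m),
                    letters = letters_by_trt)
  structure(out, class = c("duncan_groups", "data.frame"),
            alpha = alpha, ms_error = ms_error, df_error = df_error,
            critical_ranges = crit)
}

#' @export
print.duncan_groups <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  print(y, row.names = FALSE)
  cat(sprintf("Duncan's multiple range test, alpha = %g (MSe = %.4g, df = %d)\n",
              attr(x, "alpha"), attr(x, "ms_error"), attr(x, "df_error")))
  invisible(x)
}
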