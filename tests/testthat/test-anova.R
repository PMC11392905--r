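test_that("ANOVA sums of squares match a hand decomposition", {
  # 2 x 2 x 2 balanced layout computed by hand from the marginal means
  df <- data.frame(
    water_level = rep(c("W1", "W2"), each = 4),
    n_level = rep(rep(c("N1", "N2"), each = 2), 2),
    replicate = rep(1:2, 4),
    value = c(10, 12, 20, 22, 30, 32, 44, 46))
  at <- two_way_anova(df)
  grand <- mean(df$value)
  ss_w <- 4 * sum((tapply(df$value, df$water_level, mean) - grand)^2)
  ss_n <- 4 * sum((tapply(df$value, df$n_level, mean) - grand)^2)
  ss_r <- 4 * sum((tapply(df$value, df$replicate, mean) - grand)^2)
  cellm <- tapply(df$value, paste(df$water_level, df$n_level), mean)
  ss_cells <- 2 * sum((cellm - grand)^2)
  ss_wn <- ss_cells - ss_w - ss_n
  ss_tot <- sum((df$value - grand)^2)
  expect_equal(at$ss[at$effect == "W"], ss_w)
  expect_equal(at$ss[at$effect == "N"], ss_n)
  expect_equal(at$ss[at$effect == "replication"], ss_r)
  expect_equal(at$ss[at$effect == "W:N"], ss_wn)
  expect_equal(sum(at$ss), ss_tot, tolerance = 1e-6)
  expect_equal(sum(at$df), nrow(df) - 1)
})

test_that("strong water effect and null nitrogen effect are coded correctly", {
  df <- factorial_data(w_eff = c(0, 10, 20), n_eff = c(0, 0, 0),
                       sd = 1, seed = 3)
  at <- two_way_anova(df)
  expect_equal(at$code[at$effect == "W"], "**")
  expect_equal(at$code[at$effect == "N"], "ns")
})

test_that("constant observations give zero SS and no significance", {
  df <- factorial_data(sd = 0, seed = 1)
  df$value <- 5
  at <- two_way_anova(df)
  expect_equal(at$ss[at$effect != "error"], rep(0, 4), tolerance = 1e-20)
  expect_true(all(at$code[at$effect %in% c("W", "N", "W:N")] == "ns"))
})

test_that("unbalanced layouts are rejected", {
  df <- factorial_data(seed = 2)
  expect_error(two_way_anova(df[-1, ]), "unbalanced")
})

test_that("adding a constant changes no F statistic and no letters", {
  df <- factorial_data(w_eff = c(0, 3, 6), n_eff = c(0, 1, 2), sd = 1.5,
                       seed = 8)
  at1 <- two_way_anova(df)
  df2 <- df
  df2$value <- df2$value + 1000
  at2 <- two_way_anova(df2)
  expect_equal(at1$F, at2$F)
  expect_equal(at1$p, at2$p)
  means1 <- tapply(df$value, paste0(df$water_level, df$n_level), mean)
  dg1 <- duncan_letters(means1, attr(at1, "ms_error"),
                        attr(at1, "df_error"), n = 3)
  dg2 <- duncan_letters(means1 + 1000, attr(at2, "ms_error"),
                        attr(at2, "df_error"), n = 3)
  expect_equal(dg1$letters, dg2$letters)
})

test_that("Duncan letters separate distant means and merge identical ones", {
  far <- c(A = 100, B = 10)
  dg <- duncan_letters(far, ms_error = 1, df_error = 16, n = 3)
  expect_equal(dg$letters, c("a", "b"))
  expect_equal(dg$treatment, c("A", "B"))  # descending order, a = highest
  same <- c(A = 10, B = 10, C = 10)
  dg2 <- duncan_letters(same, ms_error = 1, df_error = 16, n = 3)
  expect_equal(dg2$letters, c("a", "a", "a"))
  expect_error(duncan_letters(far, ms_error = 0, df_error = 16, n = 3),
               "positive")
  expect_error(duncan_letters(far, ms_error = 1, df_error = 0, n = 3),
               "df_error")
})

test_that("letter sharing equals the exhaustive step-down range oracle", {
  set.seed(17)
  for (trial in 1:10) {
    k <- 9
    means <- setNames(sort(rnorm(k, 100, 4), decreasing = TRUE),
                      paste0("T", 1:k))
    ms_error <- runif(1, 0.5, 6)
    df_error <- 16
    dg <- duncan_letters(means, ms_error, df_error, n = 3)
    crit <- function(p)
      qtukey(1 - (1 - (1 - 0.05)^(p - 1)), p, df_error) * sqrt(ms_error / 3)
    # oracle: (i, j) not significantly different iff some interval
    # [p, q] covering it has extreme gap below its span's critical range
    m <- sort(means, decreasing = TRUE)
    ns_oracle <- function(i, j) {
      for (p in 1:i) for (q in j:k)
        if (p != q && (m[p] - m[q]) < crit(q - p + 1)) return(TRUE)
      i == j
    }
    share <- function(i, j) {
      li <- strsplit(dg$letters[i], "")[[1]]
      lj <- strsplit(dg$letters[j], "")[[1]]
      length(intersect(li, lj)) > 0
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      expect_equal(share(i, j), ns_oracle(i, j),
                   info = sprintf("trial %d pair (%d,%d)", trial, i, j))
  }
})
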