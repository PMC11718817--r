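test_that("grubbs screening removes only a verified extreme value", {
  # zero variance: flagged, nothing removed
  flat <- grubbs_test(c(1, 1, 1, 1))
  expect_true(flat$zero_variance)
  expect_length(flat$removed, 0)

  # symmetric n = 3: G = 1 stays below the critical value ~1.1543
  sym <- grubbs_test(c(-1, 0, 1))
  orc <- oracle_grubbs(c(-1, 0, 1))
  expect_equal(sym$g[1], orc$g, tolerance = 1e-9)
  expect_equal(sym$critical[1], orc$critical, tolerance = 1e-9)
  expect_equal(orc$critical, 1.1543, tolerance = 1e-4)
  expect_length(sym$removed, 0)   # G = 1 < 1.1543

  # a clear outlier is removed, and it is the most extreme value
  x <- c(8.1, 8.2, 7.9, 8.0, 14.0)
  gt <- grubbs_test(x)
  orc2 <- oracle_grubbs(x)
  expect_gt(orc2$g, orc2$critical)
  expect_equal(gt$removed, 14.0)
  expect_equal(gt$g[1], orc2$g, tolerance = 1e-9)

  # symmetric two-extreme data: never more than one removal per pass
  two_ext <- grubbs_test(c(-10, 0, 0, 0, 10))
  expect_lte(length(two_ext$removed), 1)

  expect_error(grubbs_test(c(1, 2)),
               class = "spheromotion_validation_error")
  expect_equal(nrow(glance(gt)), 1)
  expect_equal(glance(gt)$n_removed, 1L)
})

test_that("welch test matches an independent implementation to 1e-9", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  w <- welch_t_test(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(w$statistic, orc$t, tolerance = 1e-9)
  expect_equal(w$df, orc$df, tolerance = 1e-9)
  expect_equal(w$p_value, orc$p, tolerance = 1e-9)

  # identical samples: t = 0, p = 1 (non-zero spread within each sample)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry under swapping
  swap <- welch_t_test(b, a)
  expect_equal(swap$statistic, -w$statistic)
  expect_equal(swap$p_value, w$p_value)

  # equal variances and sizes: Welch equals Student
  set.seed(91)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  y <- (y - mean(y)) / stats::sd(y) * stats::sd(x) + mean(y)
  expect_equal(welch_t_test(x, y)$statistic,
               welch_t_test(x, y, var_equal = TRUE)$statistic,
               tolerance = 1e-9)

  expect_error(welch_t_test(1, c(1, 2)),
               class = "spheromotion_validation_error")
  td <- tidy(w)
  expect_equal(td$estimate, mean(a) - mean(b))
})

test_that("one-way ANOVA with Tukey HSD behaves under label changes and nulls", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  same <- anova_tukey(g)
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(all(tidy(same)$adj_p_value == 1))

  set.seed(101)
  g2 <- list(a = stats::rnorm(8), b = stats::rnorm(8, 1),
             c = stats::rnorm(8, 2))
  fit <- anova_tukey(g2)
  perm <- anova_tukey(g2[c("c", "a", "b")])
  expect_equal(glance(perm)$f_statistic, glance(fit)$f_statistic)
  expect_equal(glance(perm)$p_value, glance(fit)$p_value)
  pair_key <- function(x) {
    sorted <- t(apply(tidy(x)[, c("group_1", "group_2")], 1, sort))
    o <- order(sorted[, 1], sorted[, 2])
    list(pairs = sorted[o, ], diff = abs(tidy(x)$diff)[o],
         p = tidy(x)$adj_p_value[o])
  }
  expect_equal(pair_key(perm)$p, pair_key(fit)$p, tolerance = 1e-12)
  expect_equal(pair_key(perm)$diff, pair_key(fit)$diff, tolerance = 1e-12)

  # Tukey-adjusted p >= unadjusted pairwise p (same pooled variance)
  df_w <- fit$df[2]
  mse <- sum(vapply(g2, function(v) sum((v - mean(v))^2), numeric(1))) / df_w
  for (k in seq_len(nrow(fit$pairwise))) {
    d <- abs(fit$pairwise$diff[k])
    se <- sqrt(mse * (1 / 8 + 1 / 8))
    p_unadj <- 2 * stats::pt(-d / se, df_w)
    expect_gte(fit$pairwise$adj_p_value[k] + 1e-12, p_unadj)
  }

  expect_error(anova_tukey(list(a = 1:3, b = 1:3)),
               class = "spheromotion_validation_error")
  expect_error(anova_tukey(list(a = 1:3, b = 1:3, c = 5)),
               class = "spheromotion_validation_error")

  # data-frame interface agrees with the list interface
  df <- tibble::tibble(value = unlist(g2),
                       group = rep(names(g2), times = lengths(g2)))
  expect_equal(anova_tukey(df)$f_statistic, fit$f_statistic)
})

test_that("star labels follow the thresholds and are monotone in p", {
  expect_equal(stars(0.03), "*")
  expect_equal(stars(0.05), "*")        # p <= 0.05 earns a star
  expect_equal(stars(0.5), "ns")
  expect_equal(stars(0.009), "**")
  expect_equal(stars(0.0005), "***")
  expect_equal(stars(0.001), "**")      # strict < for the upper tiers

  p_grid <- sort(stats::runif(100))
  ranks <- c("***" = 3, "**" = 2, "*" = 1, ns = 0)[stars(p_grid)]
  expect_true(all(diff(unname(ranks)) <= 0))
  expect_error(stars(1.2), class = "spheromotion_validation_error")
})
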