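#' Grubbs test for a single outlier
#'
#' Two-sided single-outlier Grubbs screening at level `alpha`:
#' `G = max |x_i - mean| / sd` compared against the t-quantile critical
#' value `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. At most one value — the most extreme
#' deviation from the mean — is removed per pass. An `iterative` mode
#' repeats the pass on the reduced sample until no outlier is found; it is
#' off by default, matching single-outlier screening of replicate sets.
#'
#' @param values numeric sample, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @param iterative repeat passes until no removal.
#' @return an object of class `"grubbs_test"`: a list with `values`,
#'   `kept`, `removed` (possibly empty), per-pass `g` and `critical`
#'   statistics, `alpha` and a `zero_variance` flag (zero-variance input
#'   removes nothing).
#' @examples
#' grubbs_test(c(8.1, 8.2, 7.9, 8.0, 14.0))
#' @export
grubbs_test <- function(values, alpha = 0.05, iterative = FALSE) {
  x <- as.numeric(values)
  if (length(x) < 3 || anyNA(x)) {
    abort("Grubbs test needs at least 3 non-missing values.",
          class = "spheromotion_validation_error")
  }
  removed <- numeric(0)
  g_all <- numeric(0)
  crit_all <- numeric(0)
  zero_var <- FALSE
  repeat {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) {
      zero_var <- TRUE
      break
    }
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    g_all <- c(g_all, g)
    crit_all <- c(crit_all, crit)
    if (g > crit) {
      drop_i <- which.max(dev)
      removed <- c(removed, x[drop_i])
      x <- x[-drop_i]
      if (!iterative || length(x) < 3) break
    } else {
      break
    }
  }
  structure(list(values = as.numeric(values), kept = x, removed = removed,
                 g = g_all, critical = crit_all, alpha = alpha,
                 zero_variance = zero_var, iterative = iterative),
            class = "grubbs_test")
}

#' @export
print.grubbs_test <- function(x, ...) {
  cat(sprintf("Grubbs outlier test (alpha = %g)\n", x$alpha))
  if (x$zero_variance) {
    cat("  zero variance: no outlier assessed\n")
  } else if (length(x$removed) == 0) {
    cat(sprintf("  no outlier (G = %.4f, critical = %.4f, n = %d)\n",
                x$g[1], x$critical[1], length(x$values)))
  } else {
    cat(sprintf("  removed: %s\n", paste(format(x$removed), collapse = ", ")))
  }
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unpaired two-tailed comparison of two independent samples with Welch's
#' unequal-variance correction and Welch-Satterthwaite degrees of freedom
#' (the conservative default; set `var_equal = TRUE` for Student's t).
#' Backed by [stats::t.test()].
#'
#' @param a,b numeric samples, each `n >= 2` with finite variance.
#' @param var_equal use the pooled-variance Student's t instead.
#' @return an object of class `"welch_t"` wrapping the `htest` result,
#'   with a `stars` significance label.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    abort("Both samples need at least 2 non-missing values.",
          class = "spheromotion_validation_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    abort("Both samples have zero variance; the t statistic is undefined.",
          class = "spheromotion_validation_error")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(ht$estimate[1] - ht$estimate[2]),
                 mean_a = unname(ht$estimate[1]),
                 mean_b = unname(ht$estimate[2]),
                 method = if (var_equal) "student" else "welch",
                 stars = stars(ht$p.value),
                 htest = ht),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4f, df = %.2f, p = %.4g (%s)\n",
              if (x$method == "welch") "Welch" else "Student",
              x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD
#'
#' Ordinary one-way ANOVA across three or more groups followed by Tukey's
#' multiple-comparison procedure in which each group is compared to every
#' other group (adjusted p-values from the studentized-range distribution).
#' Backed by [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param data a data frame, or a named list of numeric samples.
#' @param value,group column names (as strings) when `data` is a data
#'   frame.
#' @return an object of class `"anova_tukey"`: `f_statistic`, `df`,
#'   `p_value`, `stars`, and `pairwise` — a tibble of group pairs with mean
#'   differences, confidence bounds and adjusted p-values.
#' @export
anova_tukey <- function(data, value = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data)) || any(names(data) == "")) {
      abort("A list input must be fully named (one name per group).",
            class = "spheromotion_validation_error")
    }
    data <- purrr::imap_dfr(data, ~ tibble(value = as.numeric(.x),
                                           group = .y))
    value <- "value"; group <- "group"
  }
  df <- tibble(value = as.numeric(data[[value]]),
               group = as.character(data[[group]]))
  sizes <- table(df$group)
  if (length(sizes) < 3) {
    abort("At least 3 groups are required.",
          class = "spheromotion_validation_error")
  }
  if (any(sizes < 2)) {
    abort(sprintf("Every group needs n >= 2 (offending: %s).",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  # all groups identical: zero between- and within-group variance
  if (!is.finite(fstat)) {
    fstat <- 0
    pval <- 1
  }
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- tibble(
    group_1 = purrr::map_chr(pairs, 1),
    group_2 = purrr::map_chr(pairs, 2),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    adj_p_value = ifelse(is.finite(tk[, "p adj"]), tk[, "p adj"], 1),
    stars = stars(ifelse(is.finite(tk[, "p adj"]), tk[, "p adj"], 1)))
  structure(list(f_statistic = fstat,
                 df = unname(an[["Df"]]),
                 p_value = pval,
                 stars = stars(pval),
                 pairwise = pairwise,
                 n_groups = length(sizes),
                 n = nrow(df)),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g (%s)\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$stars))
  cat(sprintf("Tukey HSD over %d pairwise comparisons\n", nrow(x$pairwise)))
  invisible(x)
}

#' Significance-star labels
#'
#' Maps p-values to the star convention `* p <= 0.05`, `** p < 0.01`,
#' `*** p < 0.001`, `ns` otherwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of labels.
#' @examples
#' stars(c(0.03, 0.5, 0.0005))
#' @export
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].", class = "spheromotion_validation_error")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns")
}
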