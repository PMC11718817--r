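#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for the statistical-layer objects
#'
#' Broom-style one-row-per-term (`tidy()`) and one-row-per-model
#' (`glance()`) summaries for [grubbs_test()], [welch_t_test()] and
#' [anova_tukey()] results.
#'
#' @param x a fitted test object.
#' @param ... unused.
#' @return a tibble.
#' @name spheromotion-tidiers
NULL

#' @rdname spheromotion-tidiers
#' @method tidy grubbs_test
#' @export
tidy.grubbs_test <- function(x, ...) {
  if (x$zero_variance && length(x$g) == 0) {
    return(tibble(pass = integer(), g = numeric(), critical = numeric(),
                  removed = numeric()))
  }
  tibble(
    pass = seq_along(x$g),
    g = x$g,
    critical = x$critical,
    removed = c(x$removed, rep(NA_real_, length(x$g) - length(x$removed))))
}

#' @rdname spheromotion-tidiers
#' @method glance grubbs_test
#' @export
glance.grubbs_test <- function(x, ...) {
  tibble(n = length(x$values), n_removed = length(x$removed),
         alpha = x$alpha, zero_variance = x$zero_variance)
}

#' @rdname spheromotion-tidiers
#' @method tidy welch_t
#' @export
tidy.welch_t <- function(x, ...) {
  tibble(estimate = x$estimate, mean_a = x$mean_a, mean_b = x$mean_b,
         statistic = x$statistic, df = x$df, p_value = x$p_value,
         stars = x$stars, method = x$method)
}

#' @rdname spheromotion-tidiers
#' @method glance welch_t
#' @export
glance.welch_t <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         stars = x$stars)
}

#' @rdname spheromotion-tidiers
#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) {
  x$pairwise
}

#' @rdname spheromotion-tidiers
#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_between = x$df[1],
         df_within = x$df[2], p_value = x$p_value, stars = x$stars,
         n_groups = x$n_groups, n = x$n)
}
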