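#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col geom_errorbar labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a density curve
#'
#' @param object a `"density_curve"` from [arrest_density()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot density_curve
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$density)) +
    geom_line(linewidth = 0.8, colour = "#2166ac") +
    labs(x = attr(object, "metric"), y = "density",
         subtitle = sprintf("bandwidth = %.3g", attr(object, "bandwidth"))) +
    theme_minimal()
}

#' Instantaneous-velocity traces with the arrest threshold
#'
#' Velocity-versus-time traces for a handful of tracks with the arrest
#' threshold drawn as a dashed red line, the standard display of
#' alternating high- and low-velocity phases.
#'
#' @param timeline a [pause_timeline()] tibble.
#' @param max_tracks number of tracks to facet (first by id).
#' @return a ggplot.
#' @export
plot_pause_timeline <- function(timeline, max_tracks = 6) {
  keep <- utils::head(sort(unique(timeline$track_id)), max_tracks)
  dat <- dplyr::filter(timeline, .data$track_id %in% keep)
  ggplot(dat, aes(x = .data$t, y = .data$velocity)) +
    geom_line(colour = "grey30") +
    geom_point(aes(colour = .data$below_threshold), size = 0.8) +
    geom_hline(yintercept = timeline$threshold[1], linetype = "dashed",
               colour = "red") +
    facet_wrap(~track_id) +
    labs(x = "time (min)", y = "instantaneous velocity (um/min)",
         colour = "arrested") +
    theme_minimal()
}

#' Bar plot of cohort means with SD error bars
#'
#' @param summary a [cohort_summary()] tibble.
#' @param metric which metric row to plot.
#' @param group column used for the x axis.
#' @return a ggplot.
#' @export
plot_cohort_summary <- function(summary, metric = "average_speed",
                                group = "genotype") {
  dat <- dplyr::filter(summary, .data$metric == !!metric)
  ggplot(dat, aes(x = .data[[group]], y = .data$mean)) +
    geom_col(fill = "grey70", colour = "grey30") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    labs(x = group, y = metric) +
    theme_minimal()
}
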