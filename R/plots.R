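#' Plot methods for styledyn objects
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a `dmm_trajectory` shows the evolution of a parameter family across
#' clusters; a `trend_ssm` shows the observed series with the smoothed
#' level; a `style_experiment` shows estimated, actual and forecast mixture
#' probabilities around the referential year.
#'
#' @param object Object to plot.
#' @param family Parameter family for trajectories: `"pi"` or `"alpha"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name styledyn_plots
NULL

#' @rdname styledyn_plots
#' @export
autoplot.dmm_trajectory <- function(object, family = c("pi", "alpha"), ...) {
  family <- match.arg(family)
  df <- tidy(object) %>%
    mutate(cluster = factor(.data$cluster),
           value = if (family == "pi") .data$pi else .data$alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year",
                  y = if (family == "pi") "mixture probability" else "concentration") +
    ggplot2::theme_minimal()
}

#' @rdname styledyn_plots
#' @export
autoplot.trend_ssm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$level), colour = "steelblue") +
    ggplot2::labs(x = "time", y = "series / smoothed level") +
    ggplot2::theme_minimal()
}

#' @rdname styledyn_plots
#' @export
autoplot.style_experiment <- function(object, family = c("pi", "alpha"), ...) {
  family <- match.arg(family)
  pick <- function(traj, which) {
    tidy(traj) %>%
      mutate(series = which, cluster = factor(.data$cluster),
             value = if (family == "pi") .data$pi else .data$alpha)
  }
  df <- dplyr::bind_rows(pick(object$trajectory, "estimated"),
                         pick(object$actual, "actual"),
                         pick(object$forecast, "forecast"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$cluster,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$manifest$t0, colour = "grey50",
                        linetype = 3) +
    ggplot2::labs(x = "year",
                  y = if (family == "pi") "mixture probability" else "concentration") +
    ggplot2::theme_minimal()
}

#' Plot a time-constant selection curve
#'
#' Displays the next-year mean log-likelihood as a function of the decay
#' time constant, as returned by [select_time_constant()], with the
#' maximizing value marked.
#'
#' @param curve Tibble from [select_time_constant()].
#' @return A ggplot object.
#' @export
plot_tau_curve <- function(curve) {
  best <- attr(curve, "best")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$tau, y = .data$mean_loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "time constant (years)", y = "next-year mean log-likelihood") +
    ggplot2::theme_minimal()
}
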