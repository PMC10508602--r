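#' Plot the running RED share of one trajectory
#'
#' @param object An `urn_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.urn_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = seq_len(nrow(df)) - 1,
                                   y = .data$share_red)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = df$share_red[1], linetype = "dashed") +
    ggplot2::labs(x = "decision index", y = "running RED share",
                  title = sprintf("ps = %g, pc = %g, delta1 = %g",
                                  object$params$ps, object$params$pc,
                                  object$params$delta1)) +
    ggplot2::ylim(0, 1)
}

#' Histogram of final RED shares across an ensemble
#'
#' @param object An `urn_ensemble`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.urn_ensemble <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$shares, ggplot2::aes(x = .data$red)) +
    ggplot2::geom_histogram(bins = bins, fill = "firebrick",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$shares$red),
                        linetype = "dashed") +
    ggplot2::labs(x = "final RED share", y = "runs") +
    ggplot2::xlim(-0.02, 1.02)
}

#' Heatmap of a sweep statistic over the (ps, pc) grid
#'
#' @param object An `urn_sweep`.
#' @param statistic Column to fill by; defaults to the statistic the sweep
#'   was run for (mean RED share, `U`, or mean `G`).
#' @param ... Unused.
#' @return A ggplot, faceted by start condition (and `delta1` when several
#'   values were swept).
#' @export
autoplot.urn_sweep <- function(object, statistic = NULL, ...) {
  statistic <- statistic %||% attr(object, "statistic") %||% "mean_red"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$ps, y = .data$pc,
                                    fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = statistic) +
    ggplot2::labs(x = "social influence ps", y = "conformity pc")
  if (length(unique(object$delta1)) > 1L)
    p + ggplot2::facet_grid(delta1 ~ start)
  else p + ggplot2::facet_wrap(~start)
}

#' Analytic-vs-simulated market share comparison plot
#'
#' @param object An `urn_comparison`.
#' @param ... Unused.
#' @return A ggplot: analytic curve, simulated means with 3 SE error bars.
#' @export
autoplot.urn_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta1)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytic,
                                    colour = "analytic")) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$simulated,
      ymin = .data$simulated - 3 * .data$se,
      ymax = .data$simulated + 3 * .data$se,
      colour = "simulated")) +
    ggplot2::labs(x = "delta1", y = "final RED share", colour = NULL)
}

#' Unpredictability through diffusion time
#'
#' @param object An `urn_time_u` tibble from
#'   [time_resolved_unpredictability()].
#' @param ... Unused.
#' @return A ggplot of `U` against the decision index.
#' @export
autoplot.urn_time_u <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "decision index", y = "overall unpredictability U")
}
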