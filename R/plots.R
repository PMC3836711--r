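#' Ratio-vs-position track with copy-state calls and breakpoint
#'
#' Plots normalized (129+BAC)/CAST dosage ratios along the chromosome, one
#' point per SNP colored by copy-state call, with horizontal guides at the
#' noise-free expectations (1, 2, 3) and, optionally, the inferred
#' breakpoint interval shaded.
#'
#' @param calls Tibble from [call_copy_state()] with `pos`, `ratio`,
#'   `state`; an `sd` column adds error bars.
#' @param breakpoint Optional `breakpoint_interval` to overlay.
#' @return A ggplot object.
#' @export
plot_ratio_track <- function(calls, breakpoint = NULL) {
  check_columns(calls, c("pos", "ratio", "state"), "copy-state calls")
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$pos, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = c(1, 2, 3), linetype = "dotted",
                        colour = "grey60")
  if (!is.null(breakpoint)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = breakpoint$last_present_pos,
      xmax = breakpoint$first_absent_pos, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "red"
    )
  }
  if ("sd" %in% names(calls)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ratio - .data$sd,
                   ymax = .data$ratio + .data$sd),
      width = 0, colour = "grey40"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 2) +
    ggplot2::labs(x = "position (bp)", y = "(129+BAC)/CAST ratio",
                  colour = "copy state") +
    ggplot2::theme_minimal()
}

#' Cumulative frequency curves of normalized probe distances
#'
#' One curve per group, showing the proportion of nuclei in which the two
#' probes are closer than a given (area-normalized) distance. Curves can be
#' truncated to the closest fraction of observations for display;
#' truncation never affects test statistics, which are computed on full
#' samples.
#'
#' @param pairs Probe-pair tibble with a distance column and a grouping
#'   column.
#' @param group Column (string) identifying the curves, e.g. `"pair_class"`.
#' @param value Distance column to plot (default `"norm_distance"`).
#' @param display_fraction Fraction of closest observations to display
#'   (default 0.7).
#' @return A ggplot object.
#' @export
plot_cumulative_frequency <- function(pairs, group = "pair_class",
                                      value = "norm_distance",
                                      display_fraction = 0.7) {
  check_columns(pairs, c(group, value), "probe-pair table")
  curves <- pairs %>%
    group_by(.data[[group]]) %>%
    reframe(cumulative_frequency(.data[[value]], display_fraction))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$distance, y = .data$cum_prop,
                                       colour = .data[[group]])) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = if (value == "norm_distance") {
        expression("normalized distance (" * mu * "m/" * mu * m^2 * ")")
      } else {
        expression("distance (" * mu * "m)")
      },
      y = "cumulative proportion of nuclei"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn ks_two_sample Overlay the two empirical cumulative curves
#'   being compared, annotated with D and p.
#' @param object An `xci_ks` object.
#' @method autoplot xci_ks
#' @export
autoplot.xci_ks <- function(object, ...) {
  df <- bind_rows(
    cumulative_frequency(object$sample_x) %>% mutate(sample = "x"),
    cumulative_frequency(object$sample_y) %>% mutate(sample = "y")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$cum_prop,
                                   colour = .data$sample)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      subtitle = sprintf("KS D = %.3f, p = %.3g (%s)",
                         object$statistic, object$p.value, object$method),
      x = "value", y = "cumulative proportion"
    ) +
    ggplot2::theme_minimal()
}
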