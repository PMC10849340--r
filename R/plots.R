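# ggplot2 display methods for the main result types

#' Plot a population trajectory
#'
#' Abundances (log scale) and the mutant fraction over time.
#'
#' @param object A `population_trajectory` tibble.
#' @param what `"fraction"` (default) or `"abundance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_trajectory <- function(object, what = c("fraction", "abundance"), ...) {
  what <- match.arg(what)
  if (what == "fraction") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$f)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (h)", y = "Mutant (rho0) fraction") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_classic()
  } else {
    long <- tidyr::pivot_longer(object, c("p_wt", "p_mut"),
                                names_to = "state", values_to = "abundance")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$abundance,
                                       colour = .data$state)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Time (h)", y = "Abundance (cells)", colour = NULL) +
      ggplot2::theme_classic()
  }
}

#' Plot a parameter sweep of the mutant fraction
#'
#' One curve per value of the varied parameter.
#'
#' @param sweep Output of [sweep_fraction_grid()].
#' @return A ggplot object.
#' @export
plot_fraction_sweep <- function(sweep) {
  check_columns(sweep, c("value", "time_h", "f"), "sweep")
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$time_h, y = .data$f,
                                      colour = factor(.data$value),
                                      group = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Mutant (rho0) fraction",
                  colour = "value") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
}

#' @rdname fit_exponential_rate
#' @param object A `growth_fit` object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$data
  df$od_adj <- df$od600 - object$blank
  idx <- object$window[1]:object$window[2]
  fitline <- tibble(
    time_min = df$time_min[idx],
    od = exp(object$intercept + object$rate * df$time_min[idx] / 60) + object$blank
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min / 60, y = .data$od600)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = fitline,
                       ggplot2::aes(x = .data$time_min / 60, y = .data$od),
                       colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "OD600",
                  title = sprintf("rate = %.3f /h, R^2 = %.4f",
                                  object$rate, object$r_squared)) +
    ggplot2::theme_classic()
}

#' @rdname estimate_loss_rate
#' @param object A `loss_rate_fit` object.
#' @export
autoplot.loss_rate_fit <- function(object, ...) {
  series <- object$series
  series$fraction <- series$n_petite / series$n_total
  tgrid <- seq(min(series$time_h), max(series$time_h), length.out = 100)
  curve <- tibble(
    time_h = tgrid,
    fraction = loss_model_fraction(tgrid, object$r_hat, object$f0_hat,
                                   object$g_wt, object$g_mut)
  )
  sumtab <- dplyr::summarise(
    dplyr::group_by(series, .data$time_h),
    wmean = sum(.data$n_petite) / sum(.data$n_total), .groups = "drop"
  )
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_h, y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_point(data = sumtab, ggplot2::aes(y = .data$wmean),
                        size = 3, shape = 21, fill = "black") +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(
      x = "Time (h)", y = "Petite fraction",
      title = sprintf("r = %.3f /h [%.3f, %.3f]",
                      object$r_hat, object$ci_lower, object$ci_upper)
    ) +
    ggplot2::theme_classic()
}

#' Rank-ordered plot of screen rank metrics
#'
#' Genes ordered by rank metric along the x axis; significant genes (BH
#' adjusted p below the given FDR) highlighted in magenta.
#'
#' @param results An `enrichment_result` tibble from [run_contrast()].
#' @param fdr Highlight threshold on `p_adj`.
#' @return A ggplot object.
#' @export
plot_rank_metric <- function(results, fdr = 0.05) {
  check_columns(results, c("gene_id", "rank_metric", "p_adj"), "results")
  ord <- results[order(-results$rank_metric, results$gene_id), ]
  ord$rank <- seq_len(nrow(ord))
  ord$signif <- ord$p_adj < fdr
  ggplot2::ggplot(ord, ggplot2::aes(x = .data$rank, y = .data$rank_metric,
                                    colour = .data$signif)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "magenta"),
                                 guide = "none") +
    ggplot2::labs(x = "Gene rank", y = "Rank metric (sign x -log10 p)") +
    ggplot2::theme_classic()
}

#' Plot petite-fraction summaries over time
#'
#' Per-replicate fractions as open circles, population-weighted means as
#' filled circles with unweighted SEM error bars.
#'
#' @param series Petite time series tibble.
#' @return A ggplot object.
#' @export
plot_petite_fractions <- function(series) {
  summ <- petite_fraction_summary(series)
  series$fraction <- series$n_petite / series$n_total
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_h, y = .data$weighted_mean,
                                     colour = .data$genotype)) +
    ggplot2::geom_point(data = dplyr::mutate(series, fraction = .data$n_petite / .data$n_total),
                        ggplot2::aes(y = .data$fraction), shape = 1, alpha = 0.6) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$weighted_mean - .data$sem,
                                        ymax = .data$weighted_mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "Time (h)", y = "Petite fraction", colour = NULL) +
    ggplot2::theme_classic()
}
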