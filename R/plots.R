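#' Plot a posterior introgression track
#'
#' @param track [posterior_tracks()] output.
#' @param threshold Optional horizontal reference line (default 0.5).
#' @return A ggplot.
#' @export
plot_posterior_track <- function(track, threshold = 0.5) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(track)[, c("start_bp", "p_any", "p_het", "p_hom")],
    cols = c("p_any", "p_het", "p_hom"),
    names_to = "component", values_to = "posterior")
  ggplot2::ggplot(df, ggplot2::aes(.data$start_bp / 1e3, .data$posterior,
                                   colour = .data$component)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(
      x = "position (kb)", y = "posterior probability",
      title = paste(attr(track, "band"), "introgression in",
                    attr(track, "individual"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.posterior_track <- function(object, ...)
  plot_posterior_track(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a basewise ROC curve
#'
#' @param roc [roc_curve()] output (optionally several curves row-bound with
#'   a `label` column).
#' @return A ggplot.
#' @export
plot_roc <- function(roc) {
  p <- ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr))
  if ("label" %in% names(roc))
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$label))
  else p <- p + ggplot2::geom_path()
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate (basewise)",
                  y = "true positive rate (basewise)") +
    ggplot2::theme_minimal()
}

#' Plot called vs true region length distributions
#'
#' @param ld [length_distribution()] output.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2e3,
                                   y = .data$count, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "region length (kb)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot chain diagnostics
#'
#' Log-likelihood and per-band migrant column counts per iteration.
#'
#' @param chain An `arg_chain`.
#' @return A ggplot.
#' @export
plot_chain <- function(chain) {
  df <- tidyr::pivot_longer(chain$stats, cols = -"iteration",
                            names_to = "stat", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arg_chain <- function(object, ...) plot_chain(object, ...)
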