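#' Plot a posterior summary
#'
#' Point-interval plot of the fixed-effect posterior means with 95%
#' credible intervals.
#'
#' @param object A `phylo_fit` or `pooled_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylo_fit <- function(object, ...) {
  tab <- tidy(object) |> dplyr::filter(.data$type == "fixed")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term,
                                                       .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Posterior mean (95% CI)", y = NULL,
                  title = "Fixed effects on the log citation rate")
}

#' @rdname autoplot.phylo_fit
#' @export
autoplot.pooled_posterior <- autoplot.phylo_fit

#' Plot the h-index distribution
#'
#' Histogram of per-species h on the log10(h + 1) display scale,
#' emphasizing the right-skew (point mass at 0, thin upper tail).
#'
#' @param indices Tibble from [compute_indices()] (or any table with `h`).
#' @return A ggplot object.
#' @export
plot_h_distribution <- function(indices) {
  stopifnot("h" %in% names(indices))
  ggplot2::ggplot(indices, ggplot2::aes(x = log_h_transform(.data$h))) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = expression(log[10](h + 1)), y = "Species",
                  title = "Species h-index distribution")
}

#' Trace plot of posterior draws
#'
#' @param fit A `phylo_fit`.
#' @param pars Columns to show (default: variances and H2 if present).
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "phylo_fit"))
  if (is.null(pars)) {
    pars <- intersect(c("sigma2_phylo", "sigma2_overdisp", "h2"),
                      names(fit$draws))
  }
  long <- fit$draws |>
    dplyr::select(dplyr::all_of(c("draw", pars))) |>
    tidyr::pivot_longer(-"draw", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Stored draw", y = NULL)
}
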