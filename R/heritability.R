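#' Phylogenetic heritability on the latent scale
#'
#' For a log-link Poisson model the latent-scale variance explained by
#' phylogeny is
#' `H2 = sigma2_phylo / (sigma2_phylo + sigma2_overdisp + ln(1 + 1/mean_h))`,
#' where the log term is the distribution-specific observation-level
#' variance of the Poisson on the log scale; `mean_h` is the arithmetic
#' mean of the counts actually modeled. H2 is the count-model analogue of
#' Pagel's lambda and falls in [0, 1).
#'
#' @param samples A `phylo_fit`, a `pooled_posterior`, or a data frame of
#'   draws with columns `sigma2_phylo` and `sigma2_overdisp`.
#' @param mean_h Mean of the modeled counts (> 0); taken from the fit
#'   metadata when `samples` is a `phylo_fit`.
#' @return A list of class `h2_summary` with `draws` (numeric vector),
#'   `mean`, and `ci` (central 95% interval).
#' @export
phylo_heritability <- function(samples, mean_h = NULL) {
  if (inherits(samples, "phylo_fit")) {
    if (is.null(mean_h)) mean_h <- samples$meta$mean_h
    samples <- samples$draws
  } else if (inherits(samples, "pooled_posterior")) {
    if (is.null(mean_h)) mean_h <- samples$mean_h
    samples <- samples$draws
  }
  if (is.null(mean_h) || !is.numeric(mean_h) || mean_h <= 0) {
    abort("`mean_h` must be a positive number.")
  }
  draws <- h2_from_draws(samples$sigma2_phylo, samples$sigma2_overdisp,
                         mean_h)
  structure(list(draws = draws, mean = mean(draws),
                 ci = unname(quantile(draws, c(0.025, 0.975))),
                 mean_h = mean_h),
            class = "h2_summary")
}

h2_from_draws <- function(s2p, s2e, mean_h) {
  s2p / (s2p + s2e + log(1 + 1 / mean_h))
}

#' @export
print.h2_summary <- function(x, ...) {
  cat(sprintf("Phylogenetic heritability H2: %.3f (95%% CI %.3f, %.3f)\n",
              x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}
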