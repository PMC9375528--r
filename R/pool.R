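#' Pool posterior draws across imputation and tree runs
#'
#' Concatenates the last `retain_last` retained draws of each run, tagging
#' every draw with its (tree id, imputation id) provenance. Pooling draws
#' (rather than Rubin's rules on point estimates) propagates both
#' imputation and phylogenetic uncertainty into one posterior; the
#' survey-scale protocol retains the last 100 of 1,000 stored draws from
#' each of 500 runs, giving 50,000 pooled draws.
#'
#' @param runs List of `phylo_fit` objects sharing design columns.
#' @param retain_last Number of final draws kept per run (default: all).
#' @return An object of class `pooled_posterior`: list with `draws`
#'   (tibble with provenance columns), `terms`, `mean_h` (average of the
#'   per-run modeled means).
#' @export
pool_runs <- function(runs, retain_last = NULL) {
  if (inherits(runs, "phylo_fit")) runs <- list(runs)
  if (length(runs) == 0) abort("`runs` must contain at least one fit.")
  terms <- runs[[1]]$terms
  for (r in runs) {
    if (!identical(r$terms, terms)) {
      abort("Runs have mismatched design columns; cannot pool.")
    }
  }
  draws <- purrr::map_dfr(runs, function(r) {
    d <- r$draws
    if (!is.null(retain_last)) {
      if (retain_last > nrow(d)) {
        abort(sprintf("Run has only %d draws; cannot retain %d.",
                      nrow(d), retain_last))
      }
      d <- tail(d, retain_last)
    }
    d
  })
  structure(list(draws = draws, terms = terms,
                 mean_h = mean(vapply(runs, function(r) r$meta$mean_h,
                                      numeric(1))),
                 n_runs = length(runs)),
            class = "pooled_posterior")
}

#' @export
print.pooled_posterior <- function(x, ...) {
  cat(sprintf("<pooled_posterior: %d draws from %d runs>\n",
              nrow(x$draws), x$n_runs))
  print(tidy(x))
  invisible(x)
}

# one summary row; draws are sorted first so the result is invariant (to
# the bit) under permutation of the pooled runs
summary_row <- function(v, term, type) {
  v <- sort(v)
  tibble(term = term, type = type, estimate = mean(v),
         conf.low = unname(quantile(v, 0.025)),
         conf.high = unname(quantile(v, 0.975)))
}

posterior_summary_table <- function(draws, terms) {
  out <- dplyr::bind_rows(
    purrr::map_dfr(terms, function(tm) summary_row(draws[[tm]], tm, "fixed")),
    summary_row(draws$sigma2_phylo, "Phylogeny", "random"),
    summary_row(draws$sigma2_overdisp, "Nonphylogeny", "random"))
  if ("h2" %in% names(draws)) {
    out <- dplyr::bind_rows(out, summary_row(
      draws$h2, "Phylogenetic heritability (H2)", "derived"))
  }
  out
}

#' @rdname tidy.phylo_fit
#' @export
tidy.pooled_posterior <- function(x, ...) {
  posterior_summary_table(x$draws, x$terms)
}

#' Tidy posterior summaries
#'
#' `tidy()` returns one row per model term (fixed effects, the two
#' variance components, and the derived H2) with posterior mean and
#' central 95% credible interval; `glance()` returns a one-row overview.
#'
#' @param x A `phylo_fit` or `pooled_posterior`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phylo_fit <- function(x, ...) {
  posterior_summary_table(x$draws, x$terms)
}

#' @rdname tidy.phylo_fit
#' @export
glance.phylo_fit <- function(x, ...) {
  tibble(n = x$meta$n, n_draws = nrow(x$draws),
         iterations = x$meta$iterations, burnin = x$meta$burnin,
         thin = x$meta$thin, mean_h = x$meta$mean_h,
         acc_beta = unname(x$meta$acceptance["beta"]),
         acc_u = unname(x$meta$acceptance["u"]),
         acc_e = unname(x$meta$acceptance["e"]),
         h2 = if ("h2" %in% names(x$draws)) mean(x$draws$h2) else NA_real_)
}

#' @rdname tidy.phylo_fit
#' @export
glance.pooled_posterior <- function(x, ...) {
  tibble(n_runs = x$n_runs, n_draws = nrow(x$draws), mean_h = x$mean_h,
         h2 = if ("h2" %in% names(x$draws)) mean(x$draws$h2) else NA_real_)
}

#' Human-readable posterior report
#'
#' Formats the pooled (or single-run) posterior as the standard summary
#' layout: fixed effects, random effects (variance components), and
#' phylogenetic heritability, each with posterior mean and 95% credible
#' interval. Row order is fixed: design-column order, then Phylogeny,
#' Nonphylogeny, H2.
#'
#' @param pooled A `pooled_posterior` or `phylo_fit`.
#' @param path Optional CSV path to write the table to.
#' @return The summary tibble, invisibly if `path` is given.
#' @export
report_posterior <- function(pooled, path = NULL) {
  if (nrow(if (inherits(pooled, "phylo_fit")) pooled$draws
           else pooled$draws) == 0) {
    abort("Empty posterior: nothing to report.")
  }
  tab <- tidy(pooled)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
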