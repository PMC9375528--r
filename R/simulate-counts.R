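#' Ground truth for a latent-count simulation
#'
#' Parameters of the generative model
#' `h_i ~ Poisson(exp(x_i' beta + a_i + e_i))` with phylogenetic effects
#' `a ~ MVN(0, sigma2_phylo * A)` and i.i.d. overdispersion
#' `e_i ~ N(0, sigma2_overdisp)`; kept alongside simulated data so recovery
#' tests can compare estimates to truth.
#'
#' @param beta Named or unnamed numeric vector of fixed effects on the
#'   log-rate scale, ordered as the design columns of [build_design()].
#' @param sigma2_phylo Variance of the phylogenetic effects (>= 0).
#' @param sigma2_overdisp Variance of the overdispersion effects (>= 0).
#' @param seed Integer seed.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(beta, sigma2_phylo = 1, sigma2_overdisp = 0.5,
                             seed = 1) {
  if (!is.numeric(beta) || length(beta) < 1) abort("`beta` must be numeric.")
  if (sigma2_phylo < 0 || sigma2_overdisp < 0) {
    abort("Variances must be non-negative.")
  }
  structure(list(beta = beta, sigma2_phylo = sigma2_phylo,
                 sigma2_overdisp = sigma2_overdisp,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate citation counts under the phylogenetic Poisson mixed model
#'
#' Draws `a ~ MVN(0, sigma2_phylo * A)` on the tree, i.i.d. overdispersion
#' `e`, and counts `h_i ~ Poisson(exp(eta_i))` with
#' `eta = X beta + a + e`. The design matrix comes from [build_design()]
#' unless supplied; `beta` may also be a single intercept for an
#' intercept-only model.
#'
#' @param tree A `phylo` covering all trait rows.
#' @param traits Complete trait tibble (ignored if `design` given).
#' @param truth A [simulation_truth()].
#' @param design Optional `design_matrix` (or numeric matrix) overriding
#'   the trait-derived design; use a one-column matrix of ones (or
#'   `length(beta) == 1` with `traits = NULL`) for intercept-only.
#' @param variant Design variant when building from traits.
#' @return A tibble with `binomial`, `h`, `a`, `e`, `eta`, carrying the
#'   truth and design as attributes `truth` and `design`.
#' @export
simulate_latent_counts <- function(tree, traits = NULL, truth,
                                   design = NULL, variant = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(truth, "simulation_truth"))
  n <- length(tree$tip.label)
  if (is.null(design)) {
    if (is.null(traits)) {
      if (length(truth$beta) != 1) {
        abort("Without traits or design, `beta` must be a single intercept.")
      }
      X <- matrix(1, n, 1, dimnames = list(tree$tip.label, "(Intercept)"))
      species <- tree$tip.label
    } else {
      dm <- build_design(traits, variant = variant)
      X <- dm$X
      species <- dm$species
    }
  } else {
    X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
    species <- rownames(X)
    if (is.null(species)) species <- tree$tip.label[seq_len(nrow(X))]
  }
  if (ncol(X) != length(truth$beta)) {
    abort(sprintf("`beta` has length %d but the design has %d columns.",
                  length(truth$beta), ncol(X)))
  }
  L <- if (truth$sigma2_phylo > 0) {
    chol_pivot(phylo_correlation(tree, species)$A)
  } else {
    NULL   # A is irrelevant when the phylogenetic variance is zero
  }
  with_seed(truth$seed, {
    a <- if (is.null(L)) rep(0, length(species)) else
      sqrt(truth$sigma2_phylo) * drop(L %*% rnorm(length(species)))
    e <- rnorm(length(species), 0, sqrt(truth$sigma2_overdisp))
    eta <- drop(X %*% truth$beta) + a + e
    h <- rpois(length(species), exp(eta))
    out <- tibble(binomial = species, h = h, a = a, e = e, eta = eta)
    attr(out, "truth") <- truth
    attr(out, "design") <- X
    out
  })
}
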