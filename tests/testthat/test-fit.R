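test_that("with variances pinned to zero the posterior matches the IRLS
           oracle", {
  set.seed(61)
  n <- 300
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  rownames(X) <- synthetic_binomials(n)
  y <- rpois(n, exp(0.8 + 0.4 * X[, 2] - 0.3 * X[, 3]))
  cfg <- chain_config(iterations = 12000, burnin = 4000, thin = 8,
                      fix_sigma2_phylo = 0, fix_sigma2_overdisp = 0)
  A <- diag(n); dimnames(A) <- list(rownames(X), rownames(X))
  fit <- fit_phylo_poisson(y, X, A, cfg, seed = 62)
  mle <- coef(glm(y ~ X[, 2] + X[, 3], family = poisson()))
  post <- colMeans(fit$draws[, colnames(X)])
  expect_lt(max(abs(post - mle)), 0.05)
  # no heritability draws without sampled variances on a zero-variance fit
  expect_true(all(fit$draws$sigma2_phylo == 0))
})

test_that("a prior-only chain reproduces the variance prior quantiles", {
  n <- 40
  X <- matrix(1, n, 1, dimnames = list(synthetic_binomials(n),
                                       "(Intercept)"))
  A <- diag(n); dimnames(A) <- list(rownames(X), rownames(X))
  cfg <- chain_config(iterations = 30000, burnin = 5000, thin = 5,
                      ig_shape = 5, ig_rate = 5, use_likelihood = FALSE,
                      init_sigma2 = 1)
  fit <- fit_phylo_poisson(rpois(n, 1), X, A, cfg, seed = 63)
  # inverse-gamma(5, 5): mean 5/4, quantiles via 1/qgamma
  qs <- c(0.25, 0.5, 0.75)
  theo <- 1 / stats::qgamma(rev(qs), shape = 5, rate = 5)
  emp_e <- unname(quantile(fit$draws$sigma2_overdisp, qs))
  emp_p <- unname(quantile(fit$draws$sigma2_phylo, qs))
  expect_equal(emp_e, theo, tolerance = 0.1)
  expect_equal(emp_p, theo, tolerance = 0.1)
  expect_lt(abs(mean(fit$draws$sigma2_overdisp) - 5 / 4), 0.1)
})

test_that("the sampler is reproducible from its seed and tags provenance", {
  tr <- simulate_tree(50, seed = 64)
  truth <- simulation_truth(beta = 1, sigma2_phylo = 0.5,
                            sigma2_overdisp = 0.3, seed = 65)
  sim <- simulate_latent_counts(tr, truth = truth)
  X <- matrix(1, 50, 1, dimnames = list(tr$tip.label, "(Intercept)"))
  cfg <- chain_config(iterations = 2000, burnin = 500, thin = 3)
  f1 <- fit_phylo_poisson(sim$h, X, tr, cfg, seed = 66, tree_id = 4,
                          imputation_id = 9)
  f2 <- fit_phylo_poisson(sim$h, X, tr, cfg, seed = 66, tree_id = 4,
                          imputation_id = 9)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), (2000 - 500) %/% 3)
  expect_true(all(f1$draws$tree_id == 4L))
  expect_true(all(f1$draws$imputation_id == 9L))
  expect_true(all(f1$draws$sigma2_phylo > 0))
  expect_true(all(f1$draws$h2 > 0 & f1$draws$h2 < 1))
  # acceptance diagnostics land near the adaptation targets
  expect_gt(f1$meta$acceptance["u"], 0.2)
  expect_lt(f1$meta$acceptance["u"], 0.7)
  td <- tidy(f1)
  expect_identical(td$term[1], "(Intercept)")
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("input contracts: misaligned rows, bad counts, bad config", {
  X <- cbind(`(Intercept)` = rep(1, 10))
  expect_error(fit_phylo_poisson(rep(1, 9), X, diag(10)), "rows differ")
  expect_error(fit_phylo_poisson(c(rep(1, 9), -2), X, diag(10)),
               "non-negative")
  expect_error(fit_phylo_poisson(c(rep(1, 9), 0.5), X, diag(10)),
               "non-negative integers")
  expect_error(chain_config(iterations = 100, burnin = 200), "below")
})
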