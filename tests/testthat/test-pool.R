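make_run <- function(seed, n_draws = 120, terms = c("(Intercept)", "x1")) {
  set.seed(seed)
  d <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n_draws * length(terms)), n_draws)), terms))
  d$sigma2_phylo <- stats::rgamma(n_draws, 2)
  d$sigma2_overdisp <- stats::rgamma(n_draws, 2)
  d$h2 <- d$sigma2_phylo / (d$sigma2_phylo + d$sigma2_overdisp + 0.5)
  fake_fit(d, terms, mean_h = 2, tree_id = seed %% 7,
           imputation_id = seed %% 3)
}

test_that("pooled draw counts follow the retain-last arithmetic", {
  runs <- lapply(1:10, make_run)
  pooled <- pool_runs(runs, retain_last = 100)
  expect_equal(nrow(pooled$draws), 1000)
  # survey-scale protocol: 500 runs x last 100 of 1000 = 50,000 draws
  big <- lapply(1:500, function(i) make_run(i, n_draws = 1000))
  expect_equal(nrow(pool_runs(big, retain_last = 100)$draws), 50000)
})

test_that("single-run pooling with the full chain is the identity", {
  r <- make_run(5)
  pooled <- pool_runs(list(r))
  expect_equal(tidy(pooled), tidy(r))
  expect_equal(pooled$mean_h, r$meta$mean_h)
})

test_that("summaries are invariant under run permutation", {
  runs <- lapply(1:6, make_run)
  s1 <- tidy(pool_runs(runs, retain_last = 50))
  s2 <- tidy(pool_runs(rev(runs), retain_last = 50))
  expect_identical(s1, s2)
})

test_that("pooling refuses mismatched designs and oversized retention", {
  r1 <- make_run(1)
  r2 <- make_run(2, terms = c("(Intercept)", "zz"))
  expect_error(pool_runs(list(r1, r2)), "mismatched")
  expect_error(pool_runs(list(r1), retain_last = 1e6), "retain")
  expect_error(pool_runs(list()), "at least one")
})

test_that("the posterior report has the documented fixed layout", {
  runs <- lapply(1:4, make_run)
  pooled <- pool_runs(runs, retain_last = 60)
  tab <- report_posterior(pooled)
  expect_identical(tab$term,
                   c("(Intercept)", "x1", "Phylogeny", "Nonphylogeny",
                     "Phylogenetic heritability (H2)"))
  expect_identical(tab$type,
                   c("fixed", "fixed", "random", "random", "derived"))
  # constant draws collapse the interval onto the mean
  cd <- tibble::tibble(`(Intercept)` = rep(2, 40),
                       sigma2_phylo = 1, sigma2_overdisp = 1, h2 = 0.4)
  cfit <- fake_fit(cd, "(Intercept)")
  tc <- tidy(cfit)
  expect_equal(tc$conf.low, tc$estimate)
  expect_equal(tc$conf.high, tc$estimate)
  # standard-normal draws give the Gaussian 95% interval within MC error
  set.seed(81)
  nd <- tibble::tibble(`(Intercept)` = rnorm(40000),
                       sigma2_phylo = 1, sigma2_overdisp = 1)
  nfit <- fake_fit(nd, "(Intercept)")
  tn <- tidy(nfit)[1, ]
  expect_equal(tn$conf.low, -1.96, tolerance = 0.03)
  expect_equal(tn$conf.high, 1.96, tolerance = 0.03)
  # CSV export is byte-stable
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  report_posterior(pooled, p1); report_posterior(pooled, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(report_posterior(fake_fit(cd[0, ], "(Intercept)")), "Empty")
})
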