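make_missing_traits <- function(n = 400, rate = 0.2, seed = 41) {
  tr <- simulate_tree(n, seed = seed)
  tt <- simulate_traits(tr, seed = seed + 1)
  truth <- simulation_truth(
    beta = c(-1, 0.1, 0.02, -0.5, 0.1, 0.3, -0.2, 0.5),
    sigma2_phylo = 1, sigma2_overdisp = 0.5, seed = seed + 2)
  tt$h <- simulate_latent_counts(tr, tt, truth)$h
  list(complete = tt,
       missing = inject_missingness(tt, c(body_mass_g = rate,
                                          latitude_deg = rate,
                                          iucn_status = rate / 2),
                                    "MCAR", seed = seed + 3))
}

test_that("a complete table yields m identical copies", {
  tt <- make_missing_traits(100)$complete
  imp <- impute_traits(tt, m = 3, seed = 1)
  expect_length(imp$tables, 3)
  for (tab in imp$tables) expect_identical(tab, tt)
  expect_equal(nrow(imp$diagnostics), 0)
})

test_that("PMM imputations stay in the observed donor support and never
           alter observed cells", {
  dat <- make_missing_traits(400)
  imp <- impute_traits(dat$missing, m = 5, seed = 2)
  for (tab in imp$tables) {
    expect_false(anyNA(tab))
    for (v in c("body_mass_g", "latitude_deg")) {
      mis <- is.na(dat$missing[[v]])
      obs_support <- dat$missing[[v]][!mis]
      expect_true(all(tab[[v]][mis] %in% obs_support))
      # observed cells bitwise unchanged
      expect_identical(tab[[v]][!mis], dat$missing[[v]][!mis])
    }
    mis <- is.na(dat$missing$iucn_status)
    expect_true(all(as.character(tab$iucn_status[mis]) %in% iucn_levels()))
    expect_true(is.ordered(tab$iucn_status))
  }
  expect_identical(imp$diagnostics$variable,
                   c("body_mass_g", "latitude_deg", "iucn_status"))
})

test_that("imputation preserves a known linear dependence (MCAR oracle)", {
  set.seed(43)
  n <- 600
  x <- rnorm(n)
  y <- 2 + 1.5 * x + rnorm(n, 0, 0.5)
  tab <- tibble::tibble(binomial = synthetic_binomials(n), x = x, y = y)
  full_fit <- lm(y ~ x, data = tab)
  tab$y[sample(n, 0.2 * n)] <- NA
  imp <- impute_traits(tab, m = 10, seed = 3)
  slopes <- vapply(imp$tables,
                   function(tt) coef(lm(tt$y ~ tt$x))[2], numeric(1))
  expect_lt(abs(mean(slopes) - coef(full_fit)[2]),
            3 * summary(full_fit)$coefficients[2, 2])
  # multiple imputation is non-degenerate: between-imputation variance > 0
  means <- vapply(imp$tables, function(tt) mean(tt$y), numeric(1))
  expect_gt(var(means), 0)
})

test_that("imputation streams are reproducible and errors are explicit", {
  dat <- make_missing_traits(120)
  i1 <- impute_traits(dat$missing, m = 2, seed = 7)
  i2 <- impute_traits(dat$missing, m = 2, seed = 7)
  expect_identical(i1$tables, i2$tables)
  bad <- dat$missing
  bad$body_mass_g <- NA_real_
  expect_error(impute_traits(bad), "fully missing")
  expect_error(impute_traits(dat$missing, m = 0), "integer")
})
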