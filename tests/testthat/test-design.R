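test_that("orthogonal contrasts for six balanced levels are the classic
           linear pattern", {
  scores <- rep(1:6, each = 10)
  P <- orthogonal_poly(scores, 2)
  lin <- c(-5, -3, -1, 1, 3, 5)
  target <- lin[scores] / sqrt(sum((lin[scores])^2))
  expect_equal(unname(P[, 1]), target, tolerance = 1e-10)
  # orthogonality to the constant and to each other; unit length
  expect_lt(abs(sum(P[, 1])), 1e-8)
  expect_lt(abs(sum(P[, 2])), 1e-8)
  expect_lt(abs(sum(P[, 1] * P[, 2])), 1e-8)
  expect_equal(colSums(P^2), c(poly1 = 1, poly2 = 1))
  # agreement with the standard orthogonal-polynomial basis
  ref <- unclass(stats::poly(scores, 2))
  expect_equal(abs(unname(P)), abs(unname(ref[, 1:2])), tolerance = 1e-8)
  expect_error(orthogonal_poly(rep(1:2, 5), 2), "distinct")
})

test_that("build_design assembles the documented columns", {
  tr <- simulate_tree(80, seed = 51)
  tt <- simulate_traits(tr, seed = 52)
  tt$latitude_deg[1] <- -30
  tt$search_interest[2] <- 0
  dm <- build_design(tt, variant = 1)
  expect_identical(colnames(dm$X),
                   c("(Intercept)", "log10_body_mass", "abs_latitude",
                     "iucn_poly1", "iucn_poly2", "human_use",
                     "domestication", "log10_search"))
  expect_equal(unname(dm$X[1, "abs_latitude"]), 30)
  expect_equal(unname(dm$X[2, "log10_search"]), 0)
  expect_equal(unname(dm$X[, "log10_body_mass"]), log10(tt$body_mass_g))
  # IUCN polys orthogonal to the intercept on the fitted sample
  expect_lt(abs(sum(dm$X[, "iucn_poly1"])), 1e-8)
  expect_lt(abs(sum(dm$X[, "iucn_poly1"] * dm$X[, "iucn_poly2"])), 1e-8)

  dm2 <- build_design(dplyr::filter(tt, domestication == "wild"),
                      variant = 2)
  expect_false("domestication" %in% colnames(dm2$X))
})

test_that("design construction enforces its contracts", {
  tr <- simulate_tree(30, seed = 53)
  tt <- simulate_traits(tr, trait_config(
    domestication_probs = c(0.3, 0.3, 0.4)), seed = 54)
  expect_error(build_design(tt, variant = 2), "wild species only")
  tt2 <- tt
  tt2$body_mass_g[3] <- NA
  expect_error(build_design(tt2), "impute first")
  expect_error(build_design(tt[, -2]), "missing columns")
})

test_that("VIF matches the closed form and flags exact collinearity", {
  # mutually orthogonal (and centred) columns: all VIFs exactly 1
  set.seed(55)
  M <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, 2:4]
  colnames(M) <- c("a", "b", "c")
  expect_equal(vif(M)$vif, rep(1, 3), tolerance = 1e-10)

  # two columns with sample correlation exactly 0.6 -> VIF 1.5625 each
  q <- qr.Q(qr(cbind(1, matrix(rnorm(400), 100, 4))))[, 2:5]
  x1 <- q[, 1]
  x2 <- 0.6 * q[, 1] + sqrt(1 - 0.36) * q[, 2]
  X <- cbind(x1 = x1, x2 = x2, x3 = q[, 3], x4 = q[, 4])
  v <- vif(X)
  expect_equal(v$vif[v$term %in% c("x1", "x2")], rep(1.5625, 2),
               tolerance = 1e-10)
  expect_equal(v$vif[v$term %in% c("x3", "x4")], rep(1, 2),
               tolerance = 1e-10)

  # duplicated column -> infinite VIF, not an exception
  D <- cbind(x1 = x1, x2 = x1, x3 = q[, 3])
  expect_true(all(is.infinite(vif(D)$vif[1:2])))
})

test_that("VIFs on simulated trait designs sit in the low-collinearity
           range seen in practice", {
  tr <- simulate_tree(500, seed = 56)
  tt <- simulate_traits(tr, seed = 57)
  v <- vif(build_design(tt))
  expect_true(all(v$vif >= 1))
  expect_true(all(v$vif < 3))
})
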