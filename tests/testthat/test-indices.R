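test_that("h-index matches known values and the brute-force oracle", {
  expect_identical(h_index(integer(0)), 0L)
  expect_identical(h_index(c(25, 8, 5, 3, 3)), 3L)
  expect_identical(h_index(c(3, 3, 3)), 3L)
  expect_identical(h_index(c(1, 1, 1, 1)), 1L)
  expect_error(h_index(c(3, -1)), "non-negative")

  set.seed(101)
  for (i in 1:2000) {
    p <- random_profile()
    expect_identical(h_index(p), as.integer(h_brute(p)))
  }
})

test_that("indices are invariant to record order and monotone", {
  set.seed(202)
  for (i in 1:200) {
    p <- random_profile()
    if (length(p) < 2) next
    perm <- sample(p)
    yrs <- sample(2000:2020, length(p), replace = TRUE)
    expect_identical(h_index(p), h_index(perm))
    expect_identical(i10_index(p), i10_index(perm))
    # adding a record never decreases h, h5, i10
    p2 <- c(p, sample(0:50, 1))
    expect_gte(h_index(p2), h_index(p))
    expect_gte(i10_index(p2), i10_index(p))
    expect_gte(h5_index(c(p, 30), c(yrs, 2020), 2020),
               h5_index(p, yrs, 2020))
    # adding citations to one record never decreases h
    p3 <- p
    j <- sample(length(p3), 1)
    p3[j] <- p3[j] + 5
    expect_gte(h_index(p3), h_index(p))
    # bound: h <= min(#records, max citation count)
    expect_lte(h_index(p), min(length(p), max(p)))
  }
})

test_that("m-index divides h by years since first publication, clamped", {
  cites <- rep(10, 15)
  yrs <- c(2010, rep(2015, 14))
  expect_equal(m_index(cites, yrs, 2020), h_index(cites) / 10)
  # first publication in the census year: denominator clamps to 1
  expect_equal(m_index(cites, rep(2020, 15), 2020), h_index(cites))
  expect_equal(m_index(integer(0), integer(0), 2020), 0)
  expect_error(m_index(cites, yrs, 2005), "precedes")
})

test_that("h5 restricts to the five calendar years ending at census", {
  cites <- c(20, 15, 12, 9, 3)
  yrs <- c(2010, 2011, 2018, 2019, 2020)
  # only the 2016-2020 records count
  expect_identical(h5_index(cites, yrs, 2020), h_index(c(12, 9, 3)))
  # all records older than 5 years -> 0
  expect_identical(h5_index(cites, rep(2000, 5), 2020), 0L)
  # all within the window -> equals the full h
  expect_identical(h5_index(cites, rep(2019, 5), 2020), h_index(cites))
  # boundary: census_year - 4 is inside, census_year - 5 is not
  expect_identical(h5_index(c(5, 5), c(2016, 2015), 2020), h_index(5))
})

test_that("i10 counts records with at least ten citations", {
  expect_identical(i10_index(integer(0)), 0L)
  expect_identical(i10_index(c(10, 9, 11)), 2L)
  set.seed(303)
  for (i in 1:200) {
    p <- random_profile()
    expect_identical(i10_index(p), as.integer(i10_brute(p)))
  }
})

test_that("log h transform maps 0, 9, 99 to 0, 1, 2", {
  expect_equal(log_h_transform(c(0, 9, 99)), c(0, 1, 2))
  expect_error(log_h_transform(-1), "non-negative")
})

test_that("compute_indices summarizes a record table per species", {
  rec <- tibble::tibble(
    species = rep(c("Aops alba", "Bops nigra"), c(5, 2)),
    year = c(2010, 2015, 2018, 2019, 2020, 2019, 2020),
    citations = c(25, 8, 5, 3, 3, 10, 9))
  idx <- compute_indices(rec, census_year = 2020)
  expect_equal(nrow(idx), 2)
  a <- idx[idx$species == "Aops alba", ]
  expect_identical(a$h, 3L)
  expect_equal(a$m, 3 / 10)
  expect_identical(a$h5, h_index(c(5, 3, 3)))
  expect_identical(a$i10, 1L)
  b <- idx[idx$species == "Bops nigra", ]
  expect_identical(b$h, 2L)
  expect_identical(b$i10, 1L)
  expect_equal(b$log_h, log10(3))
})
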