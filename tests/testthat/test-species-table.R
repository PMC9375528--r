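test_that("duplicates merge, synonyms remap, subspecies drop", {
  rec <- tibble::tibble(
    binomial = c("Mus musculus", "Mus musculus", "Mus domesticus",
                 "Rattus norvegicus", "Canis lupus familiaris"),
    body_mass_g = c(20, NA, 21, 300, 1e4))
  syn <- tibble::tibble(synonym = "Mus domesticus",
                        accepted = "Mus musculus")
  out <- suppressWarnings(resolve_and_dedupe(rec, syn))
  expect_identical(sort(out$binomial),
                   c("Mus musculus", "Rattus norvegicus"))
  # first-seen wins: the original 20 g record is kept
  expect_equal(out$body_mass_g[out$binomial == "Mus musculus"], 20)
  conf <- attr(out, "conflicts")
  expect_equal(nrow(conf), 1)
  expect_equal(conf$field, "body_mass_g")
})

test_that("resolution is order-invariant and idempotent", {
  set.seed(31)
  rec <- tibble::tibble(
    binomial = sample(rep(synthetic_binomials(30), 2)),
    h = sample(0:50, 60, replace = TRUE))
  out1 <- suppressWarnings(resolve_and_dedupe(rec))
  out2 <- suppressWarnings(resolve_and_dedupe(rec[sample(nrow(rec)), ]))
  expect_identical(out1$binomial, out2$binomial)
  again <- suppressWarnings(resolve_and_dedupe(out1))
  strip <- function(x) { attr(x, "conflicts") <- NULL; x }
  expect_identical(strip(again), strip(out1))
  # acyclic requirement on the synonym table
  bad <- tibble::tibble(synonym = c("A a", "B b"), accepted = c("B b", "C c"))
  expect_error(resolve_and_dedupe(rec, bad), "accepted names only")
})

test_that("search queries are deterministic, quoted and parseable", {
  expect_identical(build_search_query("Mus musculus"),
                   'TITLE-ABS-KEY("Mus musculus")')
  q1 <- build_search_query("Mus musculus", "Mus domesticus")
  expect_identical(q1, 'TITLE-ABS-KEY("Mus musculus" OR "Mus domesticus")')
  syns <- paste("Genus", letters[1:5])
  qk <- build_search_query("Zeta zeta", syns)
  expect_equal(lengths(regmatches(qk, gregexpr(" OR ", qk))), 5)
  names_back <- regmatches(qk, gregexpr('"[^"]+"', qk))[[1]]
  expect_identical(gsub('"', "", names_back),
                   c("Zeta zeta", sort(syns)))
  expect_error(build_search_query(""), "non-empty")
})

test_that("orders condense to the five major clades; unknown orders error", {
  expect_identical(map_order_to_clade("Proboscidea"), "Afrotheria")
  expect_identical(map_order_to_clade("Rodentia"), "Euarchontoglires")
  expect_identical(map_order_to_clade("Chiroptera"), "Laurasiatheria")
  expect_identical(map_order_to_clade("Pilosa"), "Xenarthra")
  expect_identical(map_order_to_clade("Monotremata"),
                   "Marsupials and Monotremes")
  expect_length(unique(map_order_to_clade(
    c("Proboscidea", "Pilosa", "Rodentia", "Carnivora", "Didelphimorphia"))),
    5)
  expect_error(map_order_to_clade("Dinosauria"), "Unknown taxonomic order")
})
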