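# Independent brute-force oracles used across the suite. These stay
# deliberately naive and separate from the package implementations.

# h-index by scanning every candidate n
h_brute <- function(citations) {
  best <- 0L
  for (k in seq_len(length(citations))) {
    if (sum(citations >= k) >= k) best <- k
  }
  best
}

# i10 by explicit count
i10_brute <- function(citations) sum(citations >= 10)

# random citation profile generator (discretized log-normal tail)
random_profile <- function(max_papers = 40) {
  n <- sample.int(max_papers + 1, 1) - 1L
  if (n == 0) return(integer(0))
  as.integer(floor(stats::rlnorm(n, meanlog = 1.2, sdlog = 1.3)))
}

# shared root-to-MRCA path length for a pair of tips, via ape::mrca and
# node depths (independent route from vcv.phylo)
shared_path_brute <- function(tree, i, j) {
  depths <- ape::node.depth.edgelength(tree)
  if (i == j) return(depths[i])
  m <- ape::mrca(tree)[tree$tip.label[i], tree$tip.label[j]]
  depths[m]
}

# star tree with unit branch lengths and synthetic tip names
star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- taxabias::synthetic_binomials(n)
  tr
}

# scalar H2 evaluation (thin shim over the package internal)
h2_draw_one <- function(s2p, s2e, mean_h) {
  taxabias:::h2_from_draws(s2p, s2e, mean_h)
}

# a minimal phylo_fit-shaped object for pooling tests (no MCMC involved)
fake_fit <- function(draws_tbl, terms, mean_h = 1, tree_id = 1L,
                     imputation_id = 1L) {
  draws_tbl$tree_id <- as.integer(tree_id)
  draws_tbl$imputation_id <- as.integer(imputation_id)
  draws_tbl$draw <- seq_len(nrow(draws_tbl))
  structure(list(draws = draws_tbl, terms = terms,
                 meta = list(mean_h = mean_h, n = 1L,
                             iterations = nrow(draws_tbl), burnin = 0L,
                             thin = 1L,
                             acceptance = c(beta = NA, u = NA, e = NA))),
            class = "phylo_fit")
}
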