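#' Deterministic synthetic binomial names
#'
#' Builds `n` unique pseudo-Latin binomials ("Genus species", genus
#' capitalized) from a fixed syllable inventory. The mapping from index to
#' name is deterministic and involves no random numbers, so tip labels are
#' stable across seeds and runs.
#'
#' @param n Number of names.
#' @return Character vector of length `n`.
#' @export
#' @examples
#' synthetic_binomials(3)
synthetic_binomials <- function(n) {
  n <- check_scalar_count(n, "n", min = 1L)
  gen_syl <- c("vul", "mur", "cer", "fel", "lup", "sor", "tal", "ursa",
               "dasy", "pter", "rhin", "lem", "mac", "pan", "equ", "bov")
  sp_syl <- c("alba", "nigra", "rufa", "minor", "major", "montana", "silva",
              "arctica", "australis", "borealis", "velox", "gracilis",
              "robusta", "pictus", "vulgaris", "rarus")
  ng <- length(gen_syl)
  ns <- length(sp_syl)
  idx <- seq_len(n) - 1L
  genus <- gen_syl[(idx %/% ns) %% ng + 1L]
  genus <- paste0(toupper(substr(genus, 1, 1)), substr(genus, 2, nchar(genus)),
                  "ops", ifelse(idx >= ng * ns, idx %/% (ng * ns), ""))
  species <- sp_syl[idx %% ns + 1L]
  paste(genus, species)
}

#' Simulate an ultrametric pure-birth (Yule) phylogeny
#'
#' Wraps a constant-rate pure-birth simulation and relabels the tips with
#' unique synthetic binomials. All tips are equidistant from the root;
#' identical `(n_tips, birth_rate, seed)` give a byte-identical Newick
#' string.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate (> 0).
#' @param seed Integer seed.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- simulate_tree(10, birth_rate = 1, seed = 1)
#' ape::is.ultrametric(tr)
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  n_tips <- check_scalar_count(n_tips, "n_tips", min = 2L)
  if (!is.numeric(birth_rate) || length(birth_rate) != 1 || birth_rate <= 0) {
    abort("`birth_rate` must be a single positive number.")
  }
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- synthetic_binomials(n_tips)
  tree
}

#' Write one or more trees to a Newick file
#'
#' @param trees A `phylo` or `multiPhylo` object (or list of `phylo`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read trees from a (possibly multi-tree) Newick file
#'
#' @param path Newick file, one tree per line.
#' @return A list of `phylo` objects.
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  tr <- unclass(tr)
  # Newick encodes spaces in tip labels as underscores; undo that
  lapply(tr, function(t) {
    t$tip.label <- gsub("_", " ", t$tip.label)
    t
  })
}
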