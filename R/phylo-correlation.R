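#' Tree-derived species correlation matrix
#'
#' Computes the phylogenetic covariance C (C_ij = branch length shared on
#' the root-to-tip paths of i and j, i.e. root-to-MRCA path length) and
#' standardizes it to a correlation matrix A with unit diagonal,
#' `A_ij = C_ij / sqrt(C_ii * C_jj)`. Under Brownian motion A is the
#' expected correlation of a trait across species; for an ultrametric tree
#' all entries lie in [0, 1].
#'
#' @param tree A `phylo` with branch lengths.
#' @param species Optional character vector selecting and ordering species;
#'   defaults to all tips in tree order.
#' @return A list of class `phylo_correlation` with elements `A` (matrix,
#'   dimnames = species) and `tip_order`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' phylo_correlation(tr)$A
phylo_correlation <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("`tree` must have non-negative branch lengths.")
  }
  if (is.null(species)) species <- tree$tip.label
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Species missing from tree: ",
                 paste(missing, collapse = ", ")))
  }
  C <- ape::vcv.phylo(tree)[species, species, drop = FALSE]
  d <- sqrt(diag(C))
  if (any(d <= 0)) {
    abort("Zero root-to-tip depth: correlation undefined for some tips.")
  }
  A <- C / tcrossprod(d)
  diag(A) <- 1
  structure(list(A = A, tip_order = species), class = "phylo_correlation")
}

# Lower Cholesky factor of A, with up to 3 rounds of 1e-8 diagonal jitter
# before giving up (numerically indefinite A after that is an error).
chol_pivot <- function(A) {
  for (k in 0:3) {
    Aj <- A + diag(k * 1e-8, nrow(A))
    L <- tryCatch(t(chol(Aj)), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  abort(paste0("Phylogenetic correlation matrix is not positive definite ",
               "after 3 jitter attempts (min eigenvalue ",
               format(min(eigen(A, symmetric = TRUE,
                                only.values = TRUE)$values)), ")."))
}
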