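#' Orthogonal polynomial contrasts for an ordinal predictor
#'
#' Gram–Schmidt orthogonalization of the powers `scores^1 .. scores^degree`
#' against the constant column, each column normalized to unit length on
#' the fitted sample. For six balanced, equally spaced levels the linear
#' column is proportional to (-5, -3, -1, 1, 3, 5).
#'
#' @param scores Numeric codes of the ordinal variable (one per row of the
#'   fitted sample).
#' @param degree Polynomial degree (columns returned).
#' @return A matrix with `degree` columns named `poly1`, `poly2`, ...
#' @export
#' @examples
#' orthogonal_poly(rep(1:6, each = 2), 2)
orthogonal_poly <- function(scores, degree = 2) {
  degree <- check_scalar_count(degree, "degree", min = 1L)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite numeric codes.")
  }
  if (length(unique(scores)) < degree + 1) {
    abort(sprintf(
      "Need at least %d distinct score values for degree %d contrasts.",
      degree + 1, degree))
  }
  n <- length(scores)
  basis <- cbind(rep(1, n), outer(scores, seq_len(degree), `^`))
  qr_b <- qr(basis)
  Q <- qr.Q(qr_b)[, -1, drop = FALSE]
  # fix signs so the top-degree coefficient is positive (deterministic)
  R <- qr.R(qr_b)
  sgn <- sign(diag(R)[-1])
  sgn[sgn == 0] <- 1
  out <- sweep(Q, 2, sgn, `*`)
  colnames(out) <- paste0("poly", seq_len(degree))
  out
}

#' Build the fixed-effect design matrix for the citation-rate model
#'
#' Assembles, from a complete trait table, the columns of the two model
#' variants: intercept, log10 body mass, absolute latitude, first- and
#' second-degree orthogonal-polynomial contrasts of IUCN status (scored
#' 1..6 from Least Concern to Extinct in the Wild), human use (0/1),
#' domestication score (wild = 0, partially = 1, domesticated = 2; variant
#' 1 only) and log10(search interest + 1).
#'
#' Variant 2 is the wild-only model: it drops the domestication column and
#' requires the input to contain only wild species (filter rows first).
#'
#' @param traits Complete trait tibble (no missing cells) with the columns
#'   produced by [simulate_traits()].
#' @param variant 1 (with domestication) or 2 (wild-only).
#' @param domestication_scores Named numeric scores for the three levels.
#' @return A list of class `design_matrix` with elements `X` (numeric
#'   matrix, first column `(Intercept)`), `species`, `variant`.
#' @export
build_design <- function(traits, variant = 1,
                         domestication_scores = c(
                           "wild" = 0, "partially domesticated" = 1,
                           "domesticated" = 2)) {
  stopifnot(is.data.frame(traits))
  needed <- c("binomial", "body_mass_g", "latitude_deg", "iucn_status",
              "human_use", "domestication", "search_interest")
  miss_col <- setdiff(needed, names(traits))
  if (length(miss_col) > 0) {
    abort(paste0("Trait table is missing columns: ",
                 paste(miss_col, collapse = ", ")))
  }
  if (anyNA(traits[needed])) {
    abort("Trait table has missing cells: impute first (see impute_traits()).")
  }
  if (!variant %in% c(1, 2)) abort("`variant` must be 1 or 2.")
  if (variant == 2 && any(traits$domestication != "wild")) {
    abort(paste0("Variant 2 models wild species only: remove domesticated ",
                 "and partially domesticated rows before building."))
  }
  iucn_score <- as.integer(factor(as.character(traits$iucn_status),
                                  levels = iucn_levels()))
  if (anyNA(iucn_score)) abort("Unrecognized IUCN status level.")
  ip <- orthogonal_poly(iucn_score, 2)
  X <- cbind(
    `(Intercept)` = 1,
    log10_body_mass = log10(traits$body_mass_g),
    abs_latitude = abs(traits$latitude_deg),
    iucn_poly1 = ip[, 1],
    iucn_poly2 = ip[, 2],
    human_use = as.numeric(traits$human_use)
  )
  if (variant == 1) {
    dom <- domestication_scores[as.character(traits$domestication)]
    if (anyNA(dom)) abort("Unrecognized domestication level.")
    X <- cbind(X, domestication = unname(dom))
  }
  X <- cbind(X, log10_search = log10(traits$search_interest + 1))
  rownames(X) <- traits$binomial
  structure(list(X = X, species = traits$binomial, variant = variant),
            class = "design_matrix")
}

#' Variance inflation factors of a design matrix
#'
#' Regresses each non-intercept column on all the others (intercept
#' included) and reports `VIF_j = 1 / (1 - R^2_j)`. Exactly collinear
#' columns get `Inf` rather than an error.
#'
#' @param design A `design_matrix` from [build_design()], or a numeric
#'   matrix whose first column may be an intercept.
#' @return A tibble with columns `term` and `vif`.
#' @export
vif <- function(design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  is_int <- apply(X, 2, function(col) all(col == col[1]))
  terms <- colnames(X)[!is_int]
  if (length(terms) < 2) {
    abort("Need at least two non-intercept columns for VIF.")
  }
  Xn <- X[, !is_int, drop = FALSE]
  out <- vapply(seq_along(terms), function(j) {
    y <- Xn[, j]
    others <- Xn[, -j, drop = FALSE]
    fit <- lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = terms, vif = out)
}
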