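#' Derive a reproducible child seed from a master seed
#'
#' Stage and run seeds throughout the package are split off a single master
#' seed by hashing the master seed together with a character label, so that
#' each (stage, tree, imputation) combination gets its own independent stream
#' and results do not depend on execution order.
#'
#' @param seed Master integer seed.
#' @param ... Character or integer labels identifying the stream (e.g.
#'   `"impute"`, tree id, imputation id).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "fit", 3, 1)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = "/"),
                  character(1))
  key <- paste(c(format(seed, scientific = FALSE), parts), collapse = "|")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1; all
  # intermediates stay below 2^53 so double arithmetic is exact
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, making every simulator a pure function of its inputs.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# shared argument checks ------------------------------------------------

check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be probabilities in [0, 1].", name))
  }
  x
}
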