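#' Inject missingness into a trait table
#'
#' Blanks cells of the incomplete variables (by default body mass,
#' latitude and IUCN status — the variables imputed downstream) either
#' completely at random (MCAR) or at random conditional on the always
#' observed h and human-use columns (MAR). Observed cells are untouched;
#' the realized missing fraction of each variable matches its target rate
#' in expectation (the MAR logistic intercept is calibrated so the mean
#' missingness probability equals the rate).
#'
#' @param traits Complete trait tibble; for MAR it must also carry `h` and
#'   `human_use`.
#' @param rates Named numeric vector of per-variable missingness
#'   probabilities, e.g. `c(body_mass_g = 0.2)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed Integer seed.
#' @param mar_slope Log-odds slope on the scaled MAR predictor.
#' @return The tibble with `NA` in removed cells.
#' @export
inject_missingness <- function(traits, rates, mechanism = c("MCAR", "MAR"),
                               seed = 1, mar_slope = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.data.frame(traits))
  check_probability(rates, "rates")
  if (is.null(names(rates)) || !all(names(rates) %in% names(traits))) {
    abort("`rates` must be named by columns of `traits`.")
  }
  n <- nrow(traits)
  out <- as_tibble(traits)
  with_seed(seed, {
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r == 0) next
      if (mechanism == "MCAR" || r == 1) {
        drop_it <- runif(n) < r
      } else {
        if (!all(c("h", "human_use") %in% names(traits))) {
          abort("MAR mechanism needs observed `h` and `human_use` columns.")
        }
        z <- scale(log1p(traits$h))[, 1] + 0.5 * (traits$human_use - 0.5)
        s <- mar_slope * z
        # calibrate the intercept so mean missingness equals the target rate
        alpha <- uniroot(function(a) mean(plogis(a + s)) - r,
                         interval = c(-40, 40))$root
        drop_it <- runif(n) < plogis(alpha + s)
      }
      out[[v]][drop_it] <- NA
    }
  })
  out
}

#' Missingness mask of a trait table
#'
#' @param traits Trait tibble possibly containing `NA` cells.
#' @return Logical tibble of the same shape (`TRUE` = missing).
#' @export
missingness_mask <- function(traits) {
  as_tibble(lapply(traits, is.na))
}
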