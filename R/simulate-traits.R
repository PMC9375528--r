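#' Configuration for the synthetic trait generator
#'
#' Bundles the marginal distributions of the six predictor surrogates used
#' throughout the package: log10 body mass (normal), signed median latitude
#' (uniform within bounds, the model later takes the absolute value), IUCN
#' Red List status (categorical over the six modelled levels), documented
#' human use (Bernoulli), domestication level (categorical: domesticated /
#' partially domesticated / wild) and a zero-inflated search-interest index.
#'
#' Defaults are desk-scale stand-ins for real mammalian trait tables: body
#' mass centred on ~250 g with 1.2 decades of spread, latitudes over the
#' whole globe, IUCN frequencies dominated by Least Concern, rare
#' domestication, and a search-interest index that is 0 for most species.
#'
#' @param body_mass_log10_mean,body_mass_log10_sd Mean and SD of log10 body
#'   mass in grams.
#' @param latitude_bounds Two non-negative degrees `c(lo, hi)` bounding the
#'   absolute latitude; the sign is random.
#' @param iucn_probs Probabilities over the 6 IUCN levels (sum to 1).
#' @param human_use_prob Probability that a species has a documented use.
#' @param domestication_probs Probabilities over
#'   (domesticated, partially domesticated, wild); sum to 1.
#' @param search_zero_prob Zero-inflation probability of the search index.
#' @param search_scale Scale (mean) of the exponential positive part.
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(body_mass_log10_mean = 2.4,
                         body_mass_log10_sd = 1.2,
                         latitude_bounds = c(0, 90),
                         iucn_probs = c(0.66, 0.07, 0.11, 0.105, 0.045, 0.01),
                         human_use_prob = 0.19,
                         domestication_probs = c(0.002, 0.018, 0.98),
                         search_zero_prob = 0.8,
                         search_scale = 20) {
  check_probability(iucn_probs, "iucn_probs")
  check_probability(domestication_probs, "domestication_probs")
  check_probability(human_use_prob, "human_use_prob")
  check_probability(search_zero_prob, "search_zero_prob")
  if (length(iucn_probs) != 6 || abs(sum(iucn_probs) - 1) > 1e-12) {
    abort("`iucn_probs` must have 6 levels summing to 1.")
  }
  if (length(domestication_probs) != 3 ||
      abs(sum(domestication_probs) - 1) > 1e-12) {
    abort("`domestication_probs` must have 3 levels summing to 1.")
  }
  if (length(latitude_bounds) != 2 || any(latitude_bounds < 0) ||
      any(latitude_bounds > 90) || latitude_bounds[1] > latitude_bounds[2]) {
    abort("`latitude_bounds` must be 0 <= lo <= hi <= 90.")
  }
  if (search_scale <= 0) abort("`search_scale` must be positive.")
  structure(
    list(body_mass_log10_mean = body_mass_log10_mean,
         body_mass_log10_sd = body_mass_log10_sd,
         latitude_bounds = latitude_bounds,
         iucn_probs = iucn_probs,
         human_use_prob = human_use_prob,
         domestication_probs = domestication_probs,
         search_zero_prob = search_zero_prob,
         search_scale = search_scale),
    class = "trait_config")
}

#' IUCN Red List levels modelled (ordered, least to most threatened)
#' @export
iucn_levels <- function() {
  c("Least Concern", "Near Threatened", "Vulnerable",
    "Endangered", "Critically Endangered", "Extinct in the Wild")
}

#' Domestication levels
#' @export
domestication_levels <- function() {
  c("domesticated", "partially domesticated", "wild")
}

#' Simulate a complete species trait table
#'
#' Draws one row per tip of `tree` from the marginals in `config`. All
#' cells are complete; missingness is injected separately with
#' [inject_missingness()]. Latitude is stored signed; models downstream use
#' its absolute value.
#'
#' @param tree A `phylo` whose tip labels name the species.
#' @param config A [trait_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `binomial`, `body_mass_g`, `latitude_deg`,
#'   `iucn_status`, `human_use`, `domestication`, `search_interest`.
#' @export
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' simulate_traits(tr, trait_config(), seed = 2)
simulate_traits <- function(tree, config = trait_config(), seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "trait_config"))
  n <- length(tree$tip.label)
  with_seed(seed, {
    lat_abs <- runif(n, config$latitude_bounds[1], config$latitude_bounds[2])
    lat_sign <- sample(c(-1, 1), n, replace = TRUE)
    search <- ifelse(runif(n) < config$search_zero_prob, 0,
                     stats::rexp(n, rate = 1 / config$search_scale))
    tibble(
      binomial = tree$tip.label,
      body_mass_g = 10 ^ rnorm(n, config$body_mass_log10_mean,
                               config$body_mass_log10_sd),
      latitude_deg = lat_abs * lat_sign,
      iucn_status = factor(
        sample(iucn_levels(), n, replace = TRUE, prob = config$iucn_probs),
        levels = iucn_levels(), ordered = TRUE),
      human_use = rbinom(n, 1, config$human_use_prob),
      domestication = factor(
        sample(domestication_levels(), n, replace = TRUE,
               prob = config$domestication_probs),
        levels = domestication_levels()),
      search_interest = search
    )
  })
}
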