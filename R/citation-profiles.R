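#' Construct a citation profile with a prescribed h-index
#'
#' Constructive inverse of the h-index: emits `target_h` "core" papers each
#' cited at least `target_h` times and `n_extra_papers` papers cited at
#' most `target_h` times, so that the profile's computed h-index equals
#' `target_h` exactly (no (h+1)-th paper can reach h+1 citations). Years
#' are drawn uniformly in `year_window`.
#'
#' @param target_h Desired h-index (>= 0).
#' @param n_extra_papers Papers below the core (>= 0).
#' @param seed Integer seed.
#' @param year_window Two calendar years bounding publication dates.
#' @param species Species label attached to the records.
#' @return A tibble of records with columns `species`, `year`, `citations`;
#'   zero rows when `target_h = 0` and `n_extra_papers = 0`.
#' @export
#' @examples
#' pr <- synthesize_citation_profile(7, n_extra_papers = 5, seed = 1)
#' h_index(pr$citations)  # 7
synthesize_citation_profile <- function(target_h, n_extra_papers = 0,
                                        seed = 1,
                                        year_window = c(2000, 2020),
                                        species = "Synthetica exempli") {
  target_h <- check_scalar_count(target_h, "target_h")
  n_extra_papers <- check_scalar_count(n_extra_papers, "n_extra_papers")
  n <- target_h + n_extra_papers
  if (n == 0) {
    return(tibble(species = character(), year = integer(),
                  citations = integer()))
  }
  with_seed(seed, {
    core <- if (target_h > 0) target_h + rpois(target_h, 2) else integer()
    extra <- if (n_extra_papers > 0) {
      as.integer(floor(runif(n_extra_papers, 0, target_h + 1)))
    } else integer()
    extra <- pmin(extra, target_h)  # never push an extra above the core bar
    tibble(
      species = species,
      year = as.integer(floor(runif(n, year_window[1], year_window[2] + 1))),
      citations = as.integer(c(core, extra))
    )
  })
}

#' Simulate full citation-record tables for a set of species
#'
#' Turns per-species target h values (e.g. from
#' [simulate_latent_counts()]) into record-level tables via
#' [synthesize_citation_profile()], with a discretized log-normal number
#' of extra low-cited papers. This is a testing device for the record
#' pipeline; the science models h directly.
#'
#' @param h Named integer vector (names = species) or tibble with
#'   `binomial` and `h`.
#' @param seed Integer seed.
#' @param extra_meanlog,extra_sdlog Log-normal parameters for the extra
#'   paper counts.
#' @param year_window Two calendar years bounding publication dates.
#' @return A tibble of records (`species`, `year`, `citations`).
#' @export
simulate_citation_records <- function(h, seed = 1, extra_meanlog = 1,
                                      extra_sdlog = 1,
                                      year_window = c(2000, 2020)) {
  if (is.data.frame(h)) h <- setNames(h$h, h$binomial)
  species <- names(h)
  if (is.null(species)) abort("`h` must be named by species.")
  purrr::map2_dfr(species, as.integer(h), function(sp, hv) {
    s <- derive_seed(seed, "records", sp)
    n_extra <- with_seed(derive_seed(s, "extra"),
                         as.integer(round(stats::rlnorm(1, extra_meanlog,
                                                        extra_sdlog))))
    synthesize_citation_profile(hv, n_extra_papers = n_extra, seed = s,
                                year_window = year_window, species = sp)
  })
}

#' Write citation records as JSON-lines
#'
#' One JSON object per line: `{"species": ..., "year": ..., "citations": ...}`.
#'
#' @param records Record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_citation_records <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(records) > 0) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(species = records$species[i],
                            year = records$year[i],
                            citations = records$citations[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read citation records from JSON-lines
#'
#' @param path JSON-lines file written by [write_citation_records()].
#' @return A record tibble (`species`, `year`, `citations`).
#' @export
read_citation_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(species = character(), year = integer(),
                  citations = integer()))
  }
  purrr::map_dfr(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(species = x$species, year = as.integer(x$year),
           citations = as.integer(x$citations))
  })
}
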