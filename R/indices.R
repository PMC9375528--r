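#' Species h-index
#'
#' The h-index of a set of publications is the largest number n such that
#' at least n of them have been cited at least n times each. Applied per
#' species, it summarizes both how much a species has been studied and how
#' influential that work is. An empty profile has h = 0; the result does
#' not depend on record order.
#'
#' @param citations Non-negative integer citation counts, one per
#'   publication. May be empty.
#' @return A single non-negative integer.
#' @export
#' @examples
#' h_index(c(25, 8, 5, 3, 3))  # 3
h_index <- function(citations) {
  if (length(citations) == 0) return(0L)
  if (any(!is.finite(citations)) || any(citations < 0)) {
    abort("`citations` must be non-negative counts.")
  }
  cs <- sort(as.numeric(citations), decreasing = TRUE)
  as.integer(max(0L, which(cs >= seq_along(cs)), 0L))
}

#' m-index: h-index per year of research history
#'
#' h divided by the number of calendar years since the species' first
#' publication, with the denominator clamped at 1 so a first publication in
#' the census year gives m = h.
#'
#' @param citations Citation counts per publication.
#' @param years Publication calendar years (same length).
#' @param census_year Year at which the index is taken.
#' @return A single non-negative number.
#' @export
m_index <- function(citations, years, census_year) {
  if (length(citations) == 0) return(0)
  stopifnot(length(citations) == length(years))
  first <- min(years)
  if (census_year < first) {
    abort("`census_year` precedes the first publication year.")
  }
  h_index(citations) / max(1, census_year - first)
}

#' h5 index: h-index over the past five calendar years
#'
#' The h-index restricted to publications whose year lies in the window
#' `[census_year - 4, census_year]` (five calendar years inclusive).
#'
#' @inheritParams m_index
#' @return A single non-negative integer.
#' @export
h5_index <- function(citations, years, census_year) {
  if (length(citations) == 0) return(0L)
  stopifnot(length(citations) == length(years))
  keep <- years >= census_year - 4 & years <= census_year
  h_index(citations[keep])
}

#' i10 index: publications with at least ten citations
#'
#' @param citations Citation counts per publication.
#' @return A single non-negative integer.
#' @export
i10_index <- function(citations) {
  if (length(citations) == 0) return(0L)
  if (any(!is.finite(citations)) || any(citations < 0)) {
    abort("`citations` must be non-negative counts.")
  }
  sum(citations >= 10)
}

#' Display transform log10(h + 1)
#'
#' The right-skewed h distribution (most species near 0, a thin tail of
#' heavily studied species) is shown on a log10(h + 1) scale; modeling uses
#' the raw counts.
#'
#' @param h Non-negative integer h-index values.
#' @return log10(h + 1).
#' @export
#' @examples
#' log_h_transform(c(0, 9, 99))  # 0, 1, 2
log_h_transform <- function(h) {
  if (any(!is.finite(h)) || any(h < 0)) abort("`h` must be non-negative.")
  log10(h + 1)
}

#' Compute all citation indices per species
#'
#' Takes a long table of per-publication citation records and returns one
#' row of indices per species.
#'
#' @param records Data frame with columns `species`, `year`, `citations`.
#' @param census_year Census year for m and h5 (default: max year present,
#'   or the current year for an empty table).
#' @return A tibble with columns `species`, `n_pubs`, `h`, `m`, `h5`,
#'   `i10`, `log_h`, `census_year`.
#' @export
compute_indices <- function(records, census_year = NULL) {
  stopifnot(is.data.frame(records),
            all(c("species", "year", "citations") %in% names(records)))
  if (is.null(census_year)) {
    census_year <- if (nrow(records) > 0) max(records$year)
                   else as.integer(format(Sys.Date(), "%Y"))
  }
  records |>
    dplyr::group_by(species = .data$species) |>
    dplyr::summarise(
      n_pubs = dplyr::n(),
      h = h_index(.data$citations),
      m = m_index(.data$citations, .data$year, census_year),
      h5 = h5_index(.data$citations, .data$year, census_year),
      i10 = i10_index(.data$citations),
      .groups = "drop") |>
    dplyr::mutate(log_h = log_h_transform(.data$h),
                  census_year = census_year)
}
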