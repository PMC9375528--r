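#' Resolve synonyms and deduplicate a species table
#'
#' Maps each record's binomial through a synonym table to its accepted
#' name, drops subspecies (names with three or more tokens), and merges
#' duplicate records under one accepted name. On conflicting trait values
#' the first-seen (in input order) record wins and the conflict is
#' reported via a `conflicts` attribute and a warning.
#'
#' @param records Data frame with a `binomial` column plus any trait
#'   columns.
#' @param synonym_table Data frame with columns `synonym`, `accepted`
#'   (accepted names map to themselves implicitly).
#' @return A tibble with one row per accepted binomial, sorted by name;
#'   attribute `conflicts` lists merged fields that disagreed.
#' @export
resolve_and_dedupe <- function(records, synonym_table = NULL) {
  stopifnot(is.data.frame(records), "binomial" %in% names(records))
  records <- as_tibble(records)
  # subspecies (3+ tokens) are out of scope
  tokens <- lengths(strsplit(trimws(records$binomial), "\\s+"))
  records <- records[tokens == 2, , drop = FALSE]
  accepted <- records$binomial
  if (!is.null(synonym_table) && nrow(synonym_table) > 0) {
    stopifnot(all(c("synonym", "accepted") %in% names(synonym_table)))
    if (any(synonym_table$accepted %in% synonym_table$synonym)) {
      abort("`synonym_table` must map synonyms to accepted names only.")
    }
    idx <- match(accepted, synonym_table$synonym)
    accepted <- ifelse(is.na(idx), accepted, synonym_table$accepted[idx])
  }
  records$binomial <- accepted
  trait_cols <- setdiff(names(records), "binomial")
  conflicts <- list()
  merged <- records |>
    dplyr::group_by(.data$binomial) |>
    dplyr::group_map(function(grp, key) {
      row <- grp[1, , drop = FALSE]
      for (col in trait_cols) {
        vals <- grp[[col]][!is.na(grp[[col]])]
        if (length(vals) > 0) {
          if (is.na(row[[col]])) row[[col]] <- vals[1]
          if (length(unique(vals)) > 1) {
            conflicts[[length(conflicts) + 1]] <<-
              tibble(binomial = key$binomial, field = col,
                     kept = as.character(row[[col]]),
                     dropped = paste(unique(as.character(vals[vals != vals[1]])),
                                     collapse = "; "))
          }
        }
      }
      dplyr::bind_cols(key, row[, trait_cols, drop = FALSE])
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$binomial)
  conflicts <- if (length(conflicts)) dplyr::bind_rows(conflicts) else
    tibble(binomial = character(), field = character(),
           kept = character(), dropped = character())
  if (nrow(conflicts) > 0) {
    warn(sprintf("%d trait conflicts resolved first-seen-wins; see attr(x, 'conflicts').",
                 nrow(conflicts)))
  }
  attr(merged, "conflicts") <- conflicts
  merged
}

#' Build a literature-database Boolean search query
#'
#' Produces the deterministic title/abstract/keyword query string for one
#' species: the accepted binomial first, then its synonyms in lexical
#' order, each quoted and joined with OR.
#'
#' @param accepted Accepted binomial name.
#' @param synonyms Character vector of synonymous binomials (may be empty).
#' @return A single query string, e.g.
#'   `TITLE-ABS-KEY("Mus musculus" OR "Mus domesticus")`.
#' @export
#' @examples
#' build_search_query("Mus musculus", c("Mus domesticus"))
build_search_query <- function(accepted, synonyms = character()) {
  if (!is.character(accepted) || length(accepted) != 1 ||
      !nzchar(trimws(accepted))) {
    abort("`accepted` must be a non-empty binomial name.")
  }
  synonyms <- synonyms[nzchar(trimws(synonyms))]
  names_all <- c(accepted, sort(unique(setdiff(synonyms, accepted))))
  paste0("TITLE-ABS-KEY(",
         paste(sprintf('"%s"', names_all), collapse = " OR "), ")")
}

# The 30 extant mammalian orders condensed into 5 major clades.
order_clade_table <- function() {
  tibble::tribble(
    ~order, ~clade,
    "Afrosoricida", "Afrotheria",
    "Macroscelidea", "Afrotheria",
    "Tubulidentata", "Afrotheria",
    "Hyracoidea", "Afrotheria",
    "Proboscidea", "Afrotheria",
    "Sirenia", "Afrotheria",
    "Cingulata", "Xenarthra",
    "Pilosa", "Xenarthra",
    "Scandentia", "Euarchontoglires",
    "Dermoptera", "Euarchontoglires",
    "Primates", "Euarchontoglires",
    "Lagomorpha", "Euarchontoglires",
    "Rodentia", "Euarchontoglires",
    "Eulipotyphla", "Laurasiatheria",
    "Chiroptera", "Laurasiatheria",
    "Pholidota", "Laurasiatheria",
    "Carnivora", "Laurasiatheria",
    "Perissodactyla", "Laurasiatheria",
    "Artiodactyla", "Laurasiatheria",
    "Cetacea", "Laurasiatheria",
    "Monotremata", "Marsupials and Monotremes",
    "Didelphimorphia", "Marsupials and Monotremes",
    "Paucituberculata", "Marsupials and Monotremes",
    "Microbiotheria", "Marsupials and Monotremes",
    "Dasyuromorphia", "Marsupials and Monotremes",
    "Peramelemorphia", "Marsupials and Monotremes",
    "Notoryctemorphia", "Marsupials and Monotremes",
    "Diprotodontia", "Marsupials and Monotremes",
    "Cetartiodactyla", "Laurasiatheria",
    "Soricomorpha", "Laurasiatheria"
  )
}

#' Condense a taxonomic order to one of five major mammalian clades
#'
#' Lookup over the 30 mammalian orders into Afrotheria, Xenarthra,
#' Euarchontoglires, Laurasiatheria, or Marsupials and Monotremes. Unknown
#' orders raise an error rather than guessing.
#'
#' @param order Character vector of order names.
#' @return Character vector of clade names.
#' @export
#' @examples
#' map_order_to_clade(c("Rodentia", "Chiroptera"))
map_order_to_clade <- function(order) {
  tab <- order_clade_table()
  idx <- match(order, tab$order)
  if (anyNA(idx)) {
    abort(paste0("Unknown taxonomic order(s): ",
                 paste(unique(order[is.na(idx)]), collapse = ", ")))
  }
  tab$clade[idx]
}
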