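#' Write a trait table to CSV
#'
#' One row per species; missing cells are written as empty fields, so the
#' missingness mask survives the round trip.
#'
#' @param traits Trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Restores the factor columns (IUCN status ordered over its six levels,
#' domestication over its three) and treats empty fields as missing.
#'
#' @param path CSV written by [write_trait_table()].
#' @return A trait tibble.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  out <- as_tibble(df)
  if ("iucn_status" %in% names(out)) {
    out$iucn_status <- factor(out$iucn_status, levels = iucn_levels(),
                              ordered = TRUE)
  }
  if ("domestication" %in% names(out)) {
    out$domestication <- factor(out$domestication,
                                levels = domestication_levels())
  }
  out
}
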