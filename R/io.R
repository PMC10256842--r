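# TSV interchange for the tabular inputs and outputs.

#' Read or write abundance tables and pocket fingerprints as TSV
#'
#' Abundance tables round-trip directly. Pocket fingerprints are stored as
#' `protein, pocket, size, bits` with the sorted bit indices space-separated
#' in one column; reading restores the list-column of integer bit sets.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return a tibble; writers invisibly return `path`.
#' @export
write_abundance_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname write_abundance_tsv
#' @export
write_pockets_tsv <- function(x, path) {
  flat <- x |>
    dplyr::mutate(bits = purrr::map_chr(.data$bits, function(b) paste(sort(b), collapse = " ")))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_pockets_tsv <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE)
  flat |>
    dplyr::mutate(bits = purrr::map(
      strsplit(as.character(.data$bits), " "),
      function(b) as.integer(b)
    ))
}
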