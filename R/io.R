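#' Read and write pipeline tables
#'
#' Plate tables are TSV with columns `plate`, `row`, `col`, `size`,
#' `fluor_low`, `fluor_high`, `saturated_high`; layout tables are TSV with
#' `plate`, `row`, `col`, `orf`, `role` (and `group`); flow-event tables are
#' CSV with `well`, `day`, `event_id`, `mng`, `mcherry`. Missing values are
#' written as empty fields. Writers produce a canonical representation so that
#' `write(read(x))` round-trips byte-identically.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return Readers return a data frame; writers return `path` invisibly.
#' @name aid_io
NULL

read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname aid_io
#' @export
read_plate <- function(path) read_tsv_table(path)

#' @rdname aid_io
#' @export
write_plate <- function(x, path) write_tsv_table(x, path)

#' @rdname aid_io
#' @export
read_layout <- function(path) read_tsv_table(path)

#' @rdname aid_io
#' @export
write_layout <- function(x, path) write_tsv_table(x, path)

#' @rdname aid_io
#' @export
read_events <- function(path) {
  utils::read.csv(path, header = TRUE, na.strings = "",
                  stringsAsFactors = FALSE)
}

#' @rdname aid_io
#' @export
write_events <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a YAML analysis configuration
#'
#' @param path Path to a YAML file of named parameters.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
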