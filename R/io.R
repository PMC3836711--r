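# Tabular I/O. All tables are UTF-8 TSV with mandatory headers and '.' for
# missing values; readers validate the schema and report the offending file
# and column.

xci_schemas <- list(
  markers = c("snp_id", "chrom", "pos", "allele_129", "allele_cast",
              "panel_role"),
  peaks = c("snp_id", "sample_id", "template", "replicate", "height_129",
            "height_cast"),
  cells = c("nucleus_id", "line_id", "assay", "category", "included"),
  geometry = c("nucleus_id", "z_index", "polygon_area"),
  coordinates = c("nucleus_id", "locus", "x", "y", "z")
)

read_xci_table <- function(path, schema) {
  if (!file.exists(path)) stop_data("input file not found: %s", path)
  df <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(xci_schemas[[schema]], names(df))
  if (length(missing) > 0L) {
    stop_data("%s: missing required column(s): %s",
              path, paste(missing, collapse = ", "))
  }
  df
}

write_xci_table <- function(df, path) {
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

#' Read and write the pipeline's tab-separated tables
#'
#' Each reader validates its schema (header names) and fails with the file
#' and missing column named; each writer emits UTF-8 TSV with `.` for
#' missing values. Writers and readers round-trip with value equality.
#'
#' Schemas: markers (`snp_id`, `chrom`, `pos`, `allele_129`, `allele_cast`,
#' `panel_role`); peaks (`snp_id`, `sample_id`, `template`, `replicate`,
#' `height_129`, `height_cast`); cells (`nucleus_id`, `line_id`, `assay`,
#' `category`, `included`); geometry (`nucleus_id`, `z_index`,
#' `polygon_area`); coordinates (`nucleus_id`, `locus`, `x`, `y`, `z`).
#'
#' @param path File path.
#' @param df Tibble to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name xci_io
NULL

#' @rdname xci_io
#' @export
read_markers <- function(path) read_xci_table(path, "markers")

#' @rdname xci_io
#' @export
read_peaks <- function(path) read_xci_table(path, "peaks")

#' @rdname xci_io
#' @export
read_cells <- function(path) read_xci_table(path, "cells")

#' @rdname xci_io
#' @export
read_geometry <- function(path) read_xci_table(path, "geometry")

#' @rdname xci_io
#' @export
read_coordinates <- function(path) read_xci_table(path, "coordinates")

#' @rdname xci_io
#' @export
write_markers <- function(df, path) {
  check_columns(df, xci_schemas$markers, "markers table")
  write_xci_table(df, path)
}

#' @rdname xci_io
#' @export
write_peaks <- function(df, path) {
  check_columns(df, xci_schemas$peaks, "peaks table")
  write_xci_table(df, path)
}

#' @rdname xci_io
#' @export
write_cells <- function(df, path) {
  check_columns(df, xci_schemas$cells, "cells table")
  write_xci_table(df, path)
}

#' @rdname xci_io
#' @export
write_geometry <- function(df, path) {
  check_columns(df, xci_schemas$geometry, "geometry table")
  write_xci_table(df, path)
}

#' @rdname xci_io
#' @export
write_coordinates <- function(df, path) {
  check_columns(df, xci_schemas$coordinates, "coordinates table")
  write_xci_table(df, path)
}
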