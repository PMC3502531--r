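# Well identifiers and plate geometry.
#
# Wells are identified by a row letter (A..H for 96-well, A..P for
# 384-well plates) and a 1-based column number, rendered without zero
# padding ("A1", "P24").  Parsing is case-insensitive and tolerates zero
# padding ("a01" -> "A1") so that matrix-derived IDs match annotation
# files from other software.

#' Plate dimensions for a well format
#'
#' @param format Plate format, `96` (8 x 12) or `384` (16 x 24).
#' @return Integer vector `c(n_rows, n_cols)`.
#' @export
#' @examples
#' plate_dims(384)
plate_dims <- function(format) {
  switch(as.character(format),
    "96" = c(8L, 12L),
    "384" = c(16L, 24L),
    abort_screen("invalid_format",
      paste0("Plate format must be 96 or 384, got ", format))
  )
}

#' Render well names from row/column indices
#'
#' @param row Integer row index (1 = A).
#' @param col Integer column index (1-based).
#' @return Character vector like `"A1"`, `"P24"`.
#' @export
well_name <- function(row, col) {
  paste0(LETTERS[row], col)
}

#' Parse well identifiers
#'
#' Accepts `"A1"`, `"a01"`, `"P24"` etc.; normalises case and strips zero
#' padding.  Errors with code `bad_well_id` on malformed tokens or wells
#' outside the plate format.
#'
#' @param x Character vector of well identifiers.
#' @param format Plate format (96 or 384) used to bound-check.
#' @return Tibble with columns `well` (normalised name), `row`, `col`.
#' @export
#' @examples
#' parse_wells(c("a01", "P24"))
parse_wells <- function(x, format = 384) {
  dims <- plate_dims(format)
  m <- stringr::str_match(toupper(stringr::str_trim(x)), "^([A-Z])0*([0-9]+)$")
  bad <- is.na(m[, 1])
  row <- match(m[, 2], LETTERS)
  col <- suppressWarnings(as.integer(m[, 3]))
  bad <- bad | is.na(row) | is.na(col) | row > dims[1] | col < 1 | col > dims[2]
  if (any(bad)) {
    abort_screen("bad_well_id",
      paste0("Unparseable or out-of-format well ID(s): ",
             paste(unique(x[bad]), collapse = ", ")),
      context = paste0("format ", format))
  }
  tibble::tibble(well = well_name(row, col), row = row, col = col)
}

#' Normalise well identifiers to canonical form
#'
#' @inheritParams parse_wells
#' @return Character vector of canonical well names.
#' @export
normalize_wells <- function(x, format = 384) {
  parse_wells(x, format)$well
}

#' All wells of a plate format in row-major order
#'
#' Row-major means A1, A2, ..., A24, B1, ... — the reading order of the
#' plate matrix files.
#'
#' @param format Plate format (96 or 384).
#' @return Tibble with columns `well`, `row`, `col`, one row per well.
#' @export
all_wells <- function(format = 384) {
  dims <- plate_dims(format)
  grid <- tidyr::expand_grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  tibble::tibble(well = well_name(grid$row, grid$col), row = grid$row, col = grid$col)
}
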