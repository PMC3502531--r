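# Readers for the plate-matrix, plate-ID, annotation and protocol files.
#
# Plate data arrive as one file per plate holding a 16x24 (384-well) or
# 8x12 (96-well) numeric grid after a fixed number of header lines.
# Delimiter is sniffed from the extension: .csv is comma-separated,
# .tsv/.txt (and anything else) tab-separated.  The literal token "NaN"
# (case-insensitive) marks wells excluded from all statistics.

file_delim <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

split_fields <- function(lines, delim) {
  strsplit(lines, delim, fixed = TRUE)
}

#' Read a plate matrix file
#'
#' @param path Path to a tsv/txt (tab) or csv (comma) file containing a
#'   format-shaped numeric grid after `n_header_lines` header lines.
#' @param format Plate format, 96 or 384.
#' @param n_header_lines Number of header lines to skip (identical for
#'   every data file of a screen).
#' @param plate_id Plate identifier; defaults to the file name stem.
#' @return Tibble with columns `plate_id`, `well`, `row`, `col`, `raw`
#'   (numeric, `NA` where missing) and `missing` (logical).
#' @export
read_plate_matrix <- function(path, format = 384, n_header_lines = 0,
                              plate_id = NULL) {
  if (!file.exists(path)) {
    abort_screen("file_not_found", paste0("Plate data file not found: ", path))
  }
  dims <- plate_dims(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > n_header_lines &
                     !nzchar(trimws(lines)))]  # drop blank body lines
  n_body <- length(lines) - n_header_lines
  if (n_body <= 0) {
    abort_screen("header_mismatch",
      paste0("File has ", length(lines), " line(s); expected ",
             n_header_lines, " header line(s) plus a ", dims[1], "-row matrix"),
      context = path)
  }
  if (n_body != dims[1]) {
    abort_screen("dimension_mismatch",
      paste0("File has ", n_body, " matrix rows; expected ", dims[1]),
      context = path)
  }
  body <- lines[(n_header_lines + 1):(n_header_lines + dims[1])]
  rows <- split_fields(body, file_delim(path))
  ncols <- lengths(rows)
  if (any(ncols != dims[2])) {
    bad <- which(ncols != dims[2])[1]
    abort_screen("dimension_mismatch",
      paste0("Matrix row ", bad, " has ", ncols[bad], " columns; expected ",
             dims[2]),
      context = path)
  }
  tokens <- trimws(unlist(rows))  # row-major
  is_nan <- toupper(tokens) == "NAN"
  values <- suppressWarnings(as.numeric(tokens))
  bad <- !is_nan & is.na(values)
  if (any(bad)) {
    i <- which(bad)[1]
    abort_screen("non_numeric_cell",
      paste0("Non-numeric cell '", tokens[i], "' at row ",
             ((i - 1) %/% dims[2]) + 1, ", column ", ((i - 1) %% dims[2]) + 1),
      context = path)
  }
  values[is_nan] <- NA_real_
  grid <- all_wells(format)
  tibble::tibble(
    plate_id = plate_id %||% tools::file_path_sans_ext(basename(path)),
    well = grid$well, row = grid$row, col = grid$col,
    raw = values, missing = is_nan
  )
}

#' Read a plate-ID list file
#'
#' Two columns after one header line: assay plate ID, RNAi source plate
#' ID, in run order (replicate grouping depends on the order).  Empty
#' cells are replaced with the sentinel `"no plateID"`.
#'
#' @param path Path to a tab- or comma-separated file.
#' @return Tibble with columns `assay_plate_id`, `source_plate_id`.
#' @export
read_plate_id_file <- function(path) {
  if (!file.exists(path)) {
    abort_screen("file_not_found", paste0("Plate-ID file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) {
    abort_screen("missing_column", "Plate-ID file is empty", context = path)
  }
  rows <- split_fields(lines[-1], file_delim(path))
  # a trailing empty field (e.g. "P3<TAB>") is an empty plate ID, not a
  # missing column
  rows <- lapply(rows, function(r) c(r, "", "")[1:2])
  header <- split_fields(lines[1], file_delim(path))[[1]]
  if (length(header) < 2) {
    abort_screen("missing_column",
      "Plate-ID file must have two columns (assay plate ID, source plate ID)",
      context = path)
  }
  fill_empty <- function(x) {
    x <- trimws(x)
    ifelse(nzchar(x), x, "no plateID")
  }
  out <- tibble::tibble(
    assay_plate_id = fill_empty(vapply(rows, `[`, "", 1)),
    source_plate_id = fill_empty(vapply(rows, `[`, "", 2))
  )
  dup <- out$assay_plate_id[duplicated(out$assay_plate_id)]
  if (length(dup)) {
    abort_screen("duplicate_plate_id",
      paste0("Duplicated assay plate ID(s): ",
             paste(unique(dup), collapse = ", ")),
      context = path)
  }
  out
}

#' Read an RNAi annotation file
#'
#' First two columns are the RNAi source plate ID and the well ID; any
#' further columns are retained verbatim, in order.  One header line.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param format Plate format used to validate well IDs.
#' @return Tibble with columns `source_plate_id`, `well` and the extra
#'   annotation columns (named from the header).
#' @export
read_annotation_file <- function(path, format = 384) {
  if (!file.exists(path)) {
    abort_screen("file_not_found", paste0("Annotation file not found: ", path))
  }
  delim <- file_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) {
    abort_screen("missing_column", "Annotation file is empty", context = path)
  }
  header <- split_fields(lines[1], delim)[[1]]
  if (length(header) < 2) {
    abort_screen("missing_column",
      "Annotation file needs at least source plate ID and well ID columns",
      context = path)
  }
  rows <- split_fields(lines[-1], delim)
  if (length(rows) && any(lengths(rows) < 2)) {
    abort_screen("missing_column",
      "Annotation row(s) with fewer than two columns", context = path)
  }
  pad <- function(x, n) c(x, rep("", n - length(x)))[seq_len(n)]
  mat <- do.call(rbind, lapply(rows, pad, n = length(header)))
  out <- tibble::tibble(
    source_plate_id = trimws(mat[, 1]),
    well = normalize_wells(mat[, 2], format)
  )
  if (length(header) > 2) {
    extra <- tibble::as_tibble(as.data.frame(mat[, -(1:2), drop = FALSE],
                                             stringsAsFactors = FALSE),
                               .name_repair = "minimal")
    names(extra) <- make.unique(trimws(header[-(1:2)]))
    out <- dplyr::bind_cols(out, extra)
  }
  dup <- duplicated(out[, c("source_plate_id", "well")])
  if (any(dup)) {
    key <- paste0(out$source_plate_id[dup], ":", out$well[dup])
    abort_screen("duplicate_annotation",
      paste0("Duplicated annotation entries: ",
             paste(unique(key), collapse = ", ")),
      context = path)
  }
  out
}

#' Match assay plate IDs to data files
#'
#' With a plate-ID list, each ID must match exactly one file name;
#' an exact match of the file name stem is preferred, otherwise a unique
#' substring match (IDs are claimed longest-first so that `P10` does not
#' collide with `P1`).  Without a list, files are taken in lexicographic
#' order and plate IDs are the file name stems.
#'
#' @param directory Directory holding one data file per plate.
#' @param plate_ids Optional character vector of assay plate IDs.
#' @return Tibble with columns `plate_id`, `path`, ordered like
#'   `plate_ids` (or lexicographically when absent).
#' @export
discover_data_files <- function(directory, plate_ids = NULL) {
  if (!dir.exists(directory)) {
    abort_screen("directory_not_found",
      paste0("Data file directory not found: ", directory))
  }
  files <- sort(list.files(directory,
                           pattern = "\\.(tsv|txt|csv)$", ignore.case = TRUE))
  if (!length(files)) {
    abort_screen("directory_empty",
      paste0("No plate data files (tsv/txt/csv) in ", directory))
  }
  if (is.null(plate_ids)) {
    return(tibble::tibble(
      plate_id = tools::file_path_sans_ext(files),
      path = file.path(directory, files)))
  }
  stems <- tools::file_path_sans_ext(files)
  assigned <- setNames(rep(NA_character_, length(plate_ids)), plate_ids)
  claimed <- logical(length(files))
  for (id in plate_ids[order(-nchar(plate_ids))]) {
    hit <- which(!claimed & stems == id)
    if (length(hit) == 0) {
      hit <- which(!claimed & grepl(id, files, fixed = TRUE))
    }
    if (length(hit) == 0) {
      abort_screen("plate_id_unmatched",
        paste0("Assay plate ID '", id, "' matches no data file"),
        context = directory)
    }
    if (length(hit) > 1) {
      abort_screen("plate_id_ambiguous",
        paste0("Assay plate ID '", id, "' matches several files: ",
               paste(files[hit], collapse = ", ")),
        context = directory)
    }
    claimed[hit] <- TRUE
    assigned[id] <- files[hit]
  }
  tibble::tibble(plate_id = plate_ids,
                 path = file.path(directory, unname(assigned[plate_ids])))
}

#' Read every plate of a screen
#'
#' @param files Tibble from [discover_data_files()] (columns `plate_id`,
#'   `path`).
#' @inheritParams read_plate_matrix
#' @return Long tibble of all plates (one row per well per plate).
#' @export
read_screen_data <- function(files, format = 384, n_header_lines = 0) {
  purrr::pmap(files, function(plate_id, path) {
    read_plate_matrix(path, format = format,
                      n_header_lines = n_header_lines, plate_id = plate_id)
  }) |>
    dplyr::bind_rows()
}
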