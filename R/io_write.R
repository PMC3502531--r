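# Tab-delimited result tables and the run folder.
#
# Numeric score/summary fields are serialised with 6 significant digits
# (stable golden files across platforms); raw compiled values keep full
# precision.  The run folder name is "<name>_<date-time>" and is never
# overwritten: a clash gets a counter suffix.  Tables are written into a
# temporary folder and renamed into place on success, so an aborted run
# leaves no half-written output folder.

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
}

write_tsv_plain <- function(df, path, numeric_digits = 6) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- fmt_num(out[[col]], numeric_digits)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Create a run output folder
#'
#' @param output_dir Parent directory.
#' @param name Folder base name, at most 25 characters; the folder is
#'   suffixed with the current date and time (and a counter if needed)
#'   so that reruns never overwrite earlier results.
#' @return The created folder path.
#' @export
create_run_folder <- function(output_dir, name) {
  if (nchar(name) > 25) {
    abort_screen("output_name_too_long",
      paste0("Output folder name has ", nchar(name),
             " characters; the maximum is 25"))
  }
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort_screen("unwritable_output",
      paste0("Cannot create output directory ", output_dir))
  }
  stamp <- format(Sys.time(), "%Y%m%d-%H%M%S")
  base <- file.path(output_dir, paste0(name, "_", stamp))
  path <- base
  i <- 0
  while (dir.exists(path)) {
    i <- i + 1
    path <- paste0(base, "-", i)
  }
  if (!dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
    abort_screen("unwritable_output", paste0("Cannot create ", path))
  }
  path
}

#' Write the tabular outputs of a screen analysis
#'
#' Writes the standard result tables into `dir`:
#' `Raw_data_compiled.tsv` (all plates in long form; missing wells with
#' empty value fields), `QC_summary.tsv` (both knockout stages),
#' `Scores_all_wells.tsv` (grouped by well type),
#' `Hits.tsv`, `Effect_class_counts.tsv` (SSMD-family methods) and
#' `Annotated_hits.tsv` (when annotations were mapped).
#'
#' @param result A `screen_result` (from [analyze_screen()]).
#' @param dir Output folder.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(df, file, digits = 6) {
    path <- file.path(dir, file)
    write_tsv_plain(df, path, digits)
    written <<- c(written, path)
  }

  raw <- result$data |>
    dplyr::transmute(assay_plate_id = .data$plate_id, well = .data$well,
                     raw_value = ifelse(.data$missing, NA_real_, .data$raw))
  put(raw, "Raw_data_compiled.tsv", digits = 10)

  if (!is.null(result$qc)) {
    put(result$qc, "QC_summary.tsv")
  }

  type_order <- c("sample", "negative_control", POSITIVE_SETS)
  scores <- result$scores |>
    dplyr::arrange(match(.data$well_type, type_order),
                   .data$assay_plate_id, .data$row, .data$col) |>
    dplyr::select(-dplyr::any_of(c("row", "col", "negative_reference")))
  put(scores, "Scores_all_wells.tsv")

  hits <- result$hits |>
    dplyr::select(-dplyr::any_of(c("row", "col", "negative_reference")))
  put(hits, "Hits.tsv")

  if (!is.null(result$effect_counts)) {
    put(result$effect_counts, "Effect_class_counts.tsv")
  }
  if (!is.null(result$annotated_hits)) {
    ann <- result$annotated_hits |>
      dplyr::select(-dplyr::any_of(c("row", "col", "negative_reference")))
    put(ann, "Annotated_hits.tsv")
  }
  invisible(written)
}
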