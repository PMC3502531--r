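# Classed conditions used on every abort path.  Each failure mode has a
# stable code so that callers (and the command-line driver) can react to
# categories rather than message text.

.validation_catalog <- tibble::tribble(
  ~code,                      ~family,      ~description,
  "file_not_found",           "io",         "A referenced input file does not exist",
  "directory_not_found",      "io",         "The data file directory does not exist",
  "directory_empty",          "io",         "The data file directory contains no plate data files",
  "unwritable_output",        "io",         "The output directory cannot be written to",
  "dimension_mismatch",       "format",     "A plate matrix does not have the row/column count of the declared plate format",
  "header_mismatch",          "format",     "A data file has fewer lines than the declared number of header lines plus the plate grid",
  "non_numeric_cell",         "format",     "A plate matrix cell is neither numeric nor the NaN missing-value marker",
  "missing_column",           "format",     "A list file has fewer columns than required",
  "bad_well_id",              "format",     "A well identifier cannot be parsed or lies outside the plate format",
  "duplicate_plate_id",       "design",     "The plate-ID list contains a duplicated assay plate ID",
  "duplicate_annotation",     "design",     "The annotation table repeats a (source plate, well) pair",
  "plate_id_unmatched",       "design",     "An assay plate ID matches no file in the data directory",
  "plate_id_ambiguous",       "design",     "An assay plate ID matches more than one file in the data directory",
  "replicate_count_mismatch", "design",     "The number of assay plates is not a multiple of the replicate count",
  "replicate_source_mismatch","design",     "A replicate group spans more than one RNAi source plate",
  "insufficient_replicates",  "design",     "Replicate scoring requires at least 3 replicates",
  "invalid_method",           "design",     "Unknown scoring method, or method not permitted for the screen mode",
  "invalid_transform",        "design",     "Unknown data transformation",
  "invalid_cutoff",           "design",     "Hit-selection cutoff out of range for the chosen method",
  "invalid_format",           "design",     "Plate format must be 96 or 384",
  "invalid_knockout",         "design",     "Outlier-knockout parameters out of range",
  "role_conflict",            "config",     "A well is assigned to more than one role (other than the negative-control/negative-reference pairing)",
  "missing_negative_reference","config",    "Scoring requires a non-empty negative-reference well set",
  "missing_negative_control", "config",     "Plate QC requires negative-control wells",
  "missing_positive_control", "config",     "Plate QC requires at least one positive-control well set",
  "missing_percent_activity_high","config", "Percent-activity scoring requires a designated high-signal positive-control set",
  "annotation_file_missing",  "config",     "Hit annotation was requested but no annotation file was given",
  "plate_id_file_missing",    "config",     "Replicate screens and hit annotation require a plate-ID file",
  "protocol_field_missing",   "config",     "A required protocol field is absent",
  "output_name_too_long",     "config",     "Output folder name exceeds 25 characters",
  "degenerate_reference",     "numeric",    "Negative-reference spread (SD or MAD) is zero on a plate",
  "degenerate_normalization", "numeric",    "Percent-activity high and low signals have equal means",
  "transform_degenerate",     "numeric",    "A plate has no positive values under a log transform",
  "unsupported_method",       "numeric",    "Operation not defined for the chosen scoring method",
  "broken_figure_link",       "io",         "A figure referenced by the report manifest is missing"
)

#' Catalog of validation error codes
#'
#' Every abort path in the package raises a classed condition carrying one
#' of these codes (condition class `ssmdscreen_<code>`).  The pipeline
#' validator ([validate_protocol()]) reports problems using the same codes,
#' so operator errors can be pinpointed before any computation starts.
#'
#' @return A tibble with columns `code`, `family`
#'   (`io`/`format`/`design`/`config`/`numeric`) and `description`.
#' @export
#' @examples
#' validation_codes()
validation_codes <- function() {
  .validation_catalog
}

# Raise a classed error. `context` is free-form (file/plate/well) and is
# appended to the message.
abort_screen <- function(code, message, context = NULL, call = rlang::caller_env()) {
  stopifnot(code %in% .validation_catalog$code)
  if (!is.null(context)) {
    message <- paste0(message, " [", paste(context, collapse = ", "), "]")
  }
  rlang::abort(
    message,
    class = c(paste0("ssmdscreen_", code), "ssmdscreen_error"),
    code = code,
    context = context,
    call = call
  )
}

# One validation finding (not raised); used by validate_protocol() which
# returns ALL problems rather than stopping at the first.
validation_issue <- function(code, message, context = NA_character_) {
  stopifnot(code %in% .validation_catalog$code)
  tibble::tibble(code = code, message = message, context = context)
}

no_issues <- function() {
  tibble::tibble(code = character(), message = character(), context = character())
}
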