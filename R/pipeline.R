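# Protocol files and the end-to-end pipeline.
#
# A protocol is a YAML file (or equivalent named list) recording every
# analysis choice, so a setup can be saved, shared and re-run:
#
#   data_dir: plates/            # one matrix file per plate
#   n_header_lines: 2
#   format: 384
#   mode: single_copy            # or replicates (+ n_replicates)
#   method: robust_ssmd
#   transform: log2
#   cutoff: 1.28
#   qc: true
#   knockout: {k: 2.0, f: 0.3}
#   roles:                       # wells not listed are samples
#     negative_control: [A1, B1, ...]
#     positive_1: [...]
#   negative_reference: samples  # or explicit well list
#   plate_id_file: plate_ids.tsv     # optional
#   annotation_file: annotations.tsv # optional
#   annotate: true
#   output_dir: results/
#   output_name: myscreen        # <= 25 characters
#   figures: true
#
# run_analysis() validates everything up front and aborts before any
# computation on the first problem; validate_protocol() returns the
# complete list of problems instead.

protocol_defaults <- list(
  n_header_lines = 0, format = 384, mode = "single_copy",
  transform = "raw", qc = TRUE, annotate = FALSE,
  negative_reference = "samples", output_name = "screen",
  figures = TRUE, figure_device = "jpeg",
  percent_activity_direction = "above"
)

#' Read a protocol file
#'
#' @param path YAML protocol file.
#' @return Named list of protocol fields (defaults filled in).
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    abort_screen("file_not_found", paste0("Protocol file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  utils::modifyList(protocol_defaults, raw)
}

#' Write a protocol file
#'
#' @param protocol Named list of protocol fields.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(protocol, path)
  invisible(path)
}

as_protocol <- function(protocol) {
  if (is.character(protocol) && length(protocol) == 1) {
    read_protocol(protocol)
  } else {
    utils::modifyList(protocol_defaults, protocol)
  }
}

protocol_config <- function(p) {
  plate_config(format = p$format,
               roles = lapply(p$roles %||% list(), unlist),
               negative_reference =
                 if (identical(p$negative_reference, "samples")) "samples"
                 else unlist(p$negative_reference))
}

protocol_design <- function(p, plate_pairs = NULL) {
  screen_design(
    method = p$method, cutoff = p$cutoff, mode = p$mode,
    n_replicates = p$n_replicates, transform = p$transform,
    knockout = if (!is.null(p$knockout)) {
      knockout_params(p$knockout$k, p$knockout$f)
    },
    plate_pairs = plate_pairs,
    percent_activity_high = p$percent_activity_high,
    percent_activity_direction = p$percent_activity_direction %||% "above")
}

#' Validate a protocol
#'
#' Checks the protocol and every referenced file for the problems the
#' pipeline would abort on, and returns them all (not just the first)
#' so an operator can fix a setup in one pass.  An empty result means
#' the protocol is runnable.
#'
#' @param protocol Protocol file path or named list.
#' @return Tibble with columns `code`, `message`, `context`; zero rows
#'   when the protocol is valid.  Codes are from [validation_codes()].
#' @export
validate_protocol <- function(protocol) {
  issues <- no_issues()
  note <- function(cnd) {
    issues <<- dplyr::bind_rows(issues, validation_issue(
      cnd$code %||% "protocol_field_missing", conditionMessage(cnd)))
  }
  catching <- function(expr) {
    tryCatch(expr, ssmdscreen_error = function(cnd) {
      note(cnd)
      NULL
    })
  }
  p <- catching(as_protocol(protocol))
  if (is.null(p)) {
    return(issues)
  }

  for (field in c("data_dir", "method", "cutoff")) {
    if (is.null(p[[field]])) {
      issues <- dplyr::bind_rows(issues, validation_issue(
        "protocol_field_missing",
        paste0("Required protocol field missing: ", field), field))
    }
  }
  if (nrow(issues)) {
    return(issues)
  }

  config <- catching(protocol_config(p))
  pairs <- NULL
  if (!is.null(p$plate_id_file)) {
    pairs <- catching(read_plate_id_file(p$plate_id_file))
  } else if (identical(p$mode, "replicates")) {
    issues <- dplyr::bind_rows(issues, validation_issue(
      "plate_id_file_missing",
      "Replicated screens require a plate-ID file"))
  }
  design <- catching(protocol_design(p, pairs))
  if (identical(p$mode, "replicates") && !is.null(pairs) &&
      !is.null(p$n_replicates) && p$n_replicates >= 2) {
    catching(replicate_groups(pairs, p$n_replicates))
  }

  files <- catching(discover_data_files(p$data_dir, pairs$assay_plate_id))
  if (!is.null(files) && nrow(files)) {
    # probe the first data file for shape problems shared by all files
    catching(read_plate_matrix(files$path[1], p$format, p$n_header_lines,
                               files$plate_id[1]))
  }

  if (!is.null(config)) {
    if (!is.null(design)) {
      catching(check_config_for_scoring(config))
    }
    if (isTRUE(p$qc)) {
      catching(check_config_for_qc(config))
    }
  }
  if (isTRUE(p$annotate)) {
    if (is.null(p$annotation_file)) {
      issues <- dplyr::bind_rows(issues, validation_issue(
        "annotation_file_missing",
        "Hit annotation requested but no annotation file given"))
    } else {
      catching(read_annotation_file(p$annotation_file, p$format))
    }
    if (is.null(p$plate_id_file)) {
      issues <- dplyr::bind_rows(issues, validation_issue(
        "plate_id_file_missing",
        "Hit annotation requires a plate-ID file"))
    }
  }
  if (!is.null(p$output_name) && nchar(p$output_name) > 25) {
    issues <- dplyr::bind_rows(issues, validation_issue(
      "output_name_too_long",
      paste0("Output folder name has ", nchar(p$output_name),
             " characters; the maximum is 25"), p$output_name))
  }
  dplyr::distinct(issues)
}

#' Analyse a screen held in memory
#'
#' The computational core of the pipeline: transform, QC (+ optional
#' knockout), scoring, hit selection, effect-class tally, hit-frequency
#' and per-plate hit counts, and optional annotation.  No files are
#' read or written.
#'
#' @param data Long well table (`plate_id`, `well`, `row`, `col`, `raw`,
#'   `missing`).
#' @param config [plate_config()].
#' @param design [screen_design()].
#' @param qc Whether to compute plate quality metrics (requires negative
#'   and positive controls).
#' @param annotations Optional annotation table for hit mapping.
#' @return A list of class `screen_result` with elements `data` (with
#'   transformed `value`), `config`, `design`, `qc`, `negref`, `scores`,
#'   `hits`, `hit_freq`, `hit_counts`, `effect_counts`,
#'   `annotated_hits`, `heatmap_bounds`.
#' @export
analyze_screen <- function(data, config, design, qc = TRUE,
                           annotations = NULL) {
  check_config_for_scoring(config)
  data <- transform_values(data, design$transform)
  qc_tab <- NULL
  if (qc) {
    check_config_for_qc(config)
    qc_tab <- plate_qc(data, config, design$knockout)
  }
  scores <- score_wells(data, config, design)
  scores <- classify_hits(scores, design)
  hits <- dplyr::filter(scores, .data$hit_category != "non_hit")
  n_units <- if (design$mode == "replicates") {
    dplyr::n_distinct(scores$group)
  } else {
    dplyr::n_distinct(data$plate_id)
  }
  freq <- hit_frequency(hits, n_units, config_format(config))
  counts <- hit_counts_per_plate(hits, unique(scores$assay_plate_id))
  effect_counts <- if (design$method %in% c("ssmd", "robust_ssmd",
                                            "ssmd_umvue")) {
    tally_effect_classes(scores, design$method)
  }
  annotated <- if (!is.null(annotations)) annotate_hits(hits, annotations)
  structure(
    list(data = data, config = config, design = design,
         qc = qc_tab, scores = scores, hits = hits,
         hit_freq = freq, hit_counts = counts,
         effect_counts = effect_counts, annotated_hits = annotated,
         heatmap_bounds = rescaled_heatmap_bounds(data, config)),
    class = "screen_result")
}

#' Run a full analysis from a protocol
#'
#' Validates the protocol (aborting, with the offending error code,
#' before any computation if a problem is found), reads the plate data,
#' runs [analyze_screen()], and writes the result tables, figures and
#' HTML report into a freshly created run folder.  Outputs are staged
#' in a temporary folder and renamed into place, so a failed run leaves
#' no partial output folder.
#'
#' @param protocol Protocol file path or named list (see
#'   [read_protocol()]).
#' @param overrides Named list of protocol fields to override (e.g.
#'   `list(method = "zscore", cutoff = 2)`); flags take precedence over
#'   the protocol, which takes precedence over the defaults.
#' @return The `screen_result`, invisibly, with `$run_dir` set when
#'   outputs were written.
#' @export
run_analysis <- function(protocol, overrides = list()) {
  p <- as_protocol(protocol)
  if (length(overrides)) {
    p <- utils::modifyList(p, overrides)
  }
  issues <- validate_protocol(p)
  if (nrow(issues)) {
    abort_screen(issues$code[1],
      paste0("Protocol validation failed (", nrow(issues), " problem(s)); ",
             "first: ", issues$message[1]))
  }

  pairs <- if (!is.null(p$plate_id_file)) read_plate_id_file(p$plate_id_file)
  config <- protocol_config(p)
  design <- protocol_design(p, pairs)
  files <- discover_data_files(p$data_dir, pairs$assay_plate_id)
  data <- read_screen_data(files, p$format, p$n_header_lines)
  annotations <- if (isTRUE(p$annotate)) {
    read_annotation_file(p$annotation_file, p$format)
  }

  result <- analyze_screen(data, config, design, qc = isTRUE(p$qc),
                           annotations = annotations)

  if (!is.null(p$output_dir)) {
    staging <- tempfile("ssmdscreen_run_")
    dir.create(staging, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)
    write_outputs(result, staging)
    if (isTRUE(p$figures)) {
      write_figures(result, staging, device = p$figure_device %||% "jpeg")
      assemble_html(staging)
    }
    run_dir <- create_run_folder(p$output_dir, p$output_name)
    unlink(run_dir, recursive = TRUE)
    if (!file.rename(staging, run_dir)) {
      # staging may sit on another filesystem; fall back to copying
      dir.create(run_dir, showWarnings = FALSE)
      file.copy(list.files(staging, full.names = TRUE), run_dir,
                recursive = TRUE)
      unlink(staging, recursive = TRUE)
    }
    ok <- TRUE
    result$run_dir <- run_dir
  }
  invisible(result)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen analysis:", dplyr::n_distinct(x$data$plate_id), "plates,",
      x$design$method, "scoring at cutoff", x$design$cutoff, "\n")
  cat("  hits:", sum(x$hits$hit_category == "up"), "up,",
      sum(x$hits$hit_category == "down"), "down,",
      sum(x$hits$hit_category == "unclassified_hit"), "unclassified\n")
  if (!is.null(x$run_dir)) cat("  outputs:", x$run_dir, "\n")
  invisible(x)
}
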