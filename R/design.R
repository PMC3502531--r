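# Screen design: mode, scoring method, transform, cutoff, replicate
# structure and outlier-knockout parameters.

SINGLE_COPY_METHODS <- c("percent_activity", "zscore", "robust_zscore",
                         "ssmd", "robust_ssmd")
REPLICATE_METHODS <- c("ssmd_umvue", "t_test")
ALL_METHODS <- c(SINGLE_COPY_METHODS, REPLICATE_METHODS)
TRANSFORMS <- c("raw", "log2", "log10")

#' Control-outlier knockout parameters
#'
#' @param k Outlier threshold in SD units: a control well is a knockout
#'   candidate when it lies beyond mean +/- `k` SD of its control set.
#' @param f Maximum fraction of a control set that may be knocked out;
#'   the cap is `floor(f * n0)` wells, `n0` the initial set size.
#' @return A list of class `knockout_params`.
#' @export
#' @examples
#' knockout_params(k = 2, f = 0.3)
knockout_params <- function(k = 2, f = 0.3) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k <= 0) {
    abort_screen("invalid_knockout", "Knockout SD multiplier k must be > 0")
  }
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f <= 0 || f > 1) {
    abort_screen("invalid_knockout", "Knockout cap fraction f must be in (0, 1]")
  }
  structure(list(k = k, f = f), class = "knockout_params")
}

#' Describe a screen design
#'
#' Collects the analysis choices that apply screen-wide: single-copy
#' vs. replicated mode, scoring method, data transform, hit cutoff and
#' (optionally) knockout parameters and the assay-to-source plate pairing.
#'
#' Single-copy screens permit percent activity, z-score, robust z-score,
#' SSMD and robust SSMD; replicated screens (3 or more copies) permit the
#' UMVUE of SSMD and the paired t-test, for which the cutoff is the
#' maximum p-value.
#'
#' @param method Scoring method (see Details).
#' @param cutoff Hit-selection cutoff: a positive score threshold, or for
#'   `t_test` the maximum p-value, in (0, 1).
#' @param mode `"single_copy"` or `"replicates"`.
#' @param n_replicates Number of replicate plates per source plate
#'   (>= 3; replicated mode only).
#' @param transform `"raw"`, `"log2"` or `"log10"`.
#' @param knockout Optional [knockout_params()].
#' @param plate_pairs Tibble/data frame with columns `assay_plate_id`,
#'   `source_plate_id` in run order.  Required for replicated screens
#'   (replicate copies must be listed consecutively) and for annotation.
#' @param percent_activity_high For `percent_activity`: which positive
#'   control set supplies the high signal (`"positive_1"` ...).
#' @param percent_activity_direction For `percent_activity`: whether hits
#'   lie `"above"` or `"below"` the cutoff.
#' @return A list of class `screen_design`.
#' @export
#' @examples
#' screen_design("robust_ssmd", cutoff = 1.28, transform = "log2",
#'               knockout = knockout_params(2, 0.3))
screen_design <- function(method, cutoff,
                          mode = c("single_copy", "replicates"),
                          n_replicates = NULL,
                          transform = "raw",
                          knockout = NULL,
                          plate_pairs = NULL,
                          percent_activity_high = NULL,
                          percent_activity_direction = c("above", "below")) {
  mode <- rlang::arg_match(mode)
  if (!is.character(method) || length(method) != 1 ||
      !method %in% ALL_METHODS) {
    abort_screen("invalid_method",
      paste0("Unknown scoring method: ", paste(method, collapse = ", ")))
  }
  permitted <- if (mode == "single_copy") SINGLE_COPY_METHODS else REPLICATE_METHODS
  if (!method %in% permitted) {
    abort_screen("invalid_method",
      paste0("Method '", method, "' is not available in ", mode, " mode"))
  }
  if (!transform %in% TRANSFORMS) {
    abort_screen("invalid_transform",
      paste0("Unknown transform: ", transform))
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0) {
    abort_screen("invalid_cutoff", "Hit-selection cutoff must be > 0")
  }
  if (method == "t_test" && cutoff >= 1) {
    abort_screen("invalid_cutoff",
      "For the t-test the cutoff is a maximum p-value and must be in (0, 1)")
  }
  if (mode == "replicates") {
    if (is.null(n_replicates) || n_replicates < 3) {
      abort_screen("insufficient_replicates",
        "Replicate scoring requires n_replicates >= 3")
    }
    n_replicates <- as.integer(n_replicates)
    if (is.null(plate_pairs)) {
      abort_screen("plate_id_file_missing",
        "Replicated screens require a plate-ID list pairing assay and source plates")
    }
  }
  if (!is.null(plate_pairs)) {
    plate_pairs <- tibble::as_tibble(plate_pairs)
    stopifnot(all(c("assay_plate_id", "source_plate_id") %in% names(plate_pairs)))
  }
  if (method == "percent_activity") {
    percent_activity_direction <- rlang::arg_match(percent_activity_direction)
    if (is.null(percent_activity_high) ||
        !percent_activity_high %in% POSITIVE_SETS) {
      abort_screen("missing_percent_activity_high",
        "Percent activity requires a positive-control set as the high signal")
    }
  } else {
    percent_activity_direction <- NULL
  }
  if (!is.null(knockout) && !inherits(knockout, "knockout_params")) {
    knockout <- do.call(knockout_params, as.list(knockout))
  }
  structure(
    list(mode = mode, method = method, cutoff = cutoff,
         n_replicates = n_replicates, transform = transform,
         knockout = knockout, plate_pairs = plate_pairs,
         percent_activity_high = percent_activity_high,
         percent_activity_direction = percent_activity_direction),
    class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Screen design:", x$mode,
      if (x$mode == "replicates") paste0("(n = ", x$n_replicates, ")"), "\n")
  cat("  method:", x$method, " cutoff:", x$cutoff,
      " transform:", x$transform, "\n")
  if (!is.null(x$knockout)) {
    cat("  knockout: k =", x$knockout$k, ", f =", x$knockout$f, "\n")
  }
  invisible(x)
}

#' Group assay plates into replicate blocks
#'
#' Replicate copies must be listed consecutively in the plate-ID list;
#' the list is chunked into consecutive blocks of `n_replicates`, each of
#' which must reference a single source plate.
#'
#' @param plate_pairs Tibble with `assay_plate_id`, `source_plate_id` in
#'   run order.
#' @param n_replicates Replicates per group.
#' @return `plate_pairs` with an integer `group` column.
#' @export
replicate_groups <- function(plate_pairs, n_replicates) {
  plate_pairs <- tibble::as_tibble(plate_pairs)
  n <- nrow(plate_pairs)
  if (n %% n_replicates != 0) {
    abort_screen("replicate_count_mismatch",
      paste0(n, " assay plates cannot be grouped into replicates of ",
             n_replicates))
  }
  plate_pairs$group <- rep(seq_len(n / n_replicates), each = n_replicates)
  bad <- plate_pairs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_src = dplyr::n_distinct(.data$source_plate_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_src > 1)
  if (nrow(bad)) {
    abort_screen("replicate_source_mismatch",
      paste0("Replicate group(s) spanning several source plates: ",
             paste(bad$group, collapse = ", ")))
  }
  plate_pairs
}
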