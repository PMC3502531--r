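# broom-style accessors and autoplot methods for screen results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return The per-well score table (tibble), one row per scored well,
#'   with hit categories and effect classes.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  tibble::as_tibble(x$scores)
}

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A one-row tibble: plates, scored sample wells, method,
#'   cutoff, hit counts and the median after-knockout Z'-factor and
#'   QC SSMD of positive control 1 (NA when QC was off).
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  qc1 <- if (!is.null(x$qc)) {
    dplyr::filter(x$qc, .data$set == "positive_1",
                  .data$stage == "after_knockout")
  }
  tibble::tibble(
    n_plates = dplyr::n_distinct(x$data$plate_id),
    n_sample_wells = sum(x$scores$well_type == "sample"),
    method = x$design$method,
    cutoff = x$design$cutoff,
    n_hits_up = sum(x$hits$hit_category == "up"),
    n_hits_down = sum(x$hits$hit_category == "down"),
    n_hits_unclassified = sum(x$hits$hit_category == "unclassified_hit"),
    median_zprime = if (!is.null(qc1)) stats::median(qc1$zprime) else NA_real_,
    median_ssmd_qc = if (!is.null(qc1)) stats::median(qc1$ssmd_qc) else NA_real_
  )
}

#' Plot a screen result
#'
#' @param object A `screen_result`.
#' @param type One of `"scores"`, `"hit_counts"`, `"hit_frequency"`,
#'   `"qc"`, `"controls"`, `"series"`, `"heatmap"`, `"histogram"`.
#' @param plate Plate ID for the per-plate types (`heatmap`,
#'   `histogram`; defaults to the first plate).
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object,
                                   type = c("scores", "hit_counts",
                                            "hit_frequency", "qc",
                                            "controls", "series",
                                            "heatmap", "histogram"),
                                   plate = NULL, ...) {
  type <- rlang::arg_match(type)
  plate <- plate %||% object$data$plate_id[1]
  switch(type,
    scores = plot_score_scatter(object$scores, object$design, ...),
    hit_counts = plot_hit_counts(object$hit_counts),
    hit_frequency = plot_hit_frequency(object$hit_freq),
    qc = plot_qc_lines(object$qc, ...),
    controls = plot_control_lines(object$qc, ...),
    series = plot_plate_series(object$data, ...),
    heatmap = plot_plate_heatmap(object$data, plate, ...),
    histogram = plot_plate_histogram(object$data, plate, ...)
  )
}
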