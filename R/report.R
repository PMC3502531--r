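# Diagnostic figures and the HTML report.
#
# Every figure writer also dumps the plotted values as a .tsv next to
# the image, so figure content can be regression-tested on the data
# rather than on pixels.  The HTML assembly is a pure function of the
# run folder: re-running it on the same outputs yields identical HTML.

HIST_BINS <- 50  # identical across plates for comparability

plate_subset <- function(data, plate) {
  dplyr::filter(data, .data$plate_id == plate)
}

#' Histogram of one plate's signal distribution
#'
#' When a transform was applied, raw and transformed panels are shown
#' side by side, making the symmetrising effect of the log transform
#' visible on right-skewed (e.g. luminescence) readouts.
#'
#' @param data Long well table with `plate_id`, `raw`, `value`.
#' @param plate Plate ID.
#' @param transformed Whether to add the transformed-data panel.
#' @return A ggplot.
#' @export
plot_plate_histogram <- function(data, plate, transformed = TRUE) {
  pd <- plate_subset(data, plate)
  long <- tibble::tibble(panel = "raw", x = pd$raw[!pd$missing])
  if (transformed && !identical(pd$value, pd$raw)) {
    long <- dplyr::bind_rows(
      long, tibble::tibble(panel = "transformed", x = pd$value[!pd$missing]))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = HIST_BINS, fill = "grey35") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(title = paste0("Signal distribution, ", plate),
                  x = "signal", y = "wells")
}

#' Plate heat map
#'
#' With `bounds = NULL` the plate is coloured on its own range; with
#' screen-wide bounds (from [rescaled_heatmap_bounds()]) values are
#' clipped to the shared scale, which exposes systematic row/column or
#' edge patterns that per-plate scaling hides.  Missing wells are drawn
#' in a distinct colour.
#'
#' @param data Long well table.
#' @param plate Plate ID.
#' @param bounds Optional `c(low, high)` colour limits.
#' @return A ggplot.
#' @export
plot_plate_heatmap <- function(data, plate, bounds = NULL) {
  pd <- plate_subset(data, plate)
  pd$shown <- ifelse(pd$missing, NA_real_, pd$value)
  subtitle <- "original scale"
  if (!is.null(bounds)) {
    pd$shown <- clip_to_bounds(pd$shown, bounds)
    subtitle <- sprintf("rescaled to screen-wide [%.4g, %.4g]",
                        bounds[[1]], bounds[[2]])
  }
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$shown)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.1) +
    ggplot2::scale_y_reverse(breaks = unique(pd$row),
                             labels = LETTERS[unique(pd$row)]) +
    ggplot2::scale_fill_viridis_c(limits = bounds, na.value = "grey80") +
    ggplot2::labs(title = paste0("Plate heat map, ", plate),
                  subtitle = subtitle, x = "column", y = "row",
                  fill = "signal")
}

# well values of all plates concatenated in row-major ("row") or
# column-major ("column") order, with a running index
series_table <- function(data, by = c("row", "column")) {
  by <- rlang::arg_match(by)
  n_rows <- max(data$row)
  ordered <- if (by == "row") {
    dplyr::arrange(data, .data$plate_id, .data$row, .data$col)
  } else {
    # column-wise index of well (r, c) within a plate is (c-1)*n_rows + r
    dplyr::arrange(data, .data$plate_id, .data$col, .data$row)
  }
  dplyr::mutate(ordered, index = dplyr::row_number())
}

#' Plate-series plot
#'
#' All well values of the screen concatenated plate by plate, in
#' row-wise or column-wise order, with plate separators.  Row or column
#' systematic effects show up as periodic patterns.
#'
#' @param data Long well table.
#' @param by `"row"` or `"column"` traversal order.
#' @return A ggplot.
#' @export
plot_plate_series <- function(data, by = c("row", "column")) {
  by <- rlang::arg_match(by)
  st <- series_table(data, by)
  seps <- st |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(at = max(.data$index) + 0.5, .groups = "drop")
  ggplot2::ggplot(st, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = utils::head(seps$at, -1),
                        linetype = 3, colour = "grey50") +
    ggplot2::labs(title = paste0(by, "-wise plate series"),
                  x = "well index across plates", y = "signal")
}

#' Screen-wise control line plot
#'
#' Mean of each control set across plates, one line per set; the
#' separation between negative control and positive controls should be
#' consistent throughout the screen.
#'
#' @param qc QC table from [plate_qc()].
#' @param stage Knockout stage to plot.
#' @return A ggplot.
#' @export
plot_control_lines <- function(qc, stage = "after_knockout") {
  sd <- dplyr::filter(qc, .data$stage == !!stage)
  ggplot2::ggplot(sd, ggplot2::aes(x = .data$plate_id, y = .data$mean,
                                   colour = .data$set, group = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = paste0("Control means (", stage, ")"),
                  x = NULL, y = "mean signal") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Screen-wise quality-metric line plot
#'
#' One line per positive-control set, both knockout stages
#' distinguished.  Undefined metrics are gaps, not zeros.
#'
#' @param qc QC table from [plate_qc()].
#' @param metric `"ssmd_qc"`, `"zprime"` or `"signal_window"`.
#' @return A ggplot.
#' @export
plot_qc_lines <- function(qc, metric = c("ssmd_qc", "zprime",
                                         "signal_window")) {
  metric <- rlang::arg_match(metric)
  sd <- dplyr::filter(qc, .data$set %in% POSITIVE_SETS)
  ggplot2::ggplot(sd, ggplot2::aes(x = .data$plate_id,
                                   y = .data[[metric]],
                                   colour = .data$set,
                                   linetype = .data$stage,
                                   group = interaction(.data$set,
                                                       .data$stage))) +
    ggplot2::geom_line(na.rm = TRUE) + ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::labs(title = paste0("Plate quality: ", metric),
                  x = NULL, y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Score scatter plot with cutoff lines
#'
#' Sample-well scores in well order, with horizontal lines at the
#' cutoff: both signs for the two-sided score families, a single line
#' for percent activity, and for the t-test the p-values are drawn on a
#' -log10 scale with the line at `-log10(cutoff)`.
#'
#' @param scores `screen_scores` table.
#' @param design [screen_design()].
#' @param plate Optional plate ID (default: whole screen).
#' @return A ggplot.
#' @export
plot_score_scatter <- function(scores, design, plate = NULL) {
  sd <- dplyr::filter(scores, .data$well_type == "sample")
  if (!is.null(plate)) {
    sd <- dplyr::filter(sd, .data$assay_plate_id == plate)
  }
  scope <- plate %||% "screen"
  sd <- dplyr::mutate(sd, index = dplyr::row_number())
  if (design$method == "t_test") {
    sd$y <- -log10(sd$p_value)
    cuts <- -log10(design$cutoff)
    ylab <- "-log10(p)"
  } else {
    sd$y <- sd$score
    cuts <- if (design$method == "percent_activity") design$cutoff
            else c(-design$cutoff, design$cutoff)
    ylab <- paste0(design$method, " score")
  }
  ggplot2::ggplot(sd, ggplot2::aes(x = .data$index, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = cuts, colour = "red", linetype = 2) +
    ggplot2::labs(title = paste0("Scores, ", scope),
                  x = "sample well index", y = ylab)
}

#' Hit-frequency heat maps
#'
#' Per-well fraction of plates in which the well was a hit, separately
#' for signal-increasing and signal-decreasing hits.  Hotspots indicate
#' systematic errors.
#'
#' @param freq Table from [hit_frequency()].
#' @return A ggplot.
#' @export
plot_hit_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~direction, ncol = 1) +
    ggplot2::labs(title = "Hit frequency by well position",
                  x = "column", y = "row", fill = "frequency")
}

#' Hit counts per plate
#'
#' @param counts Table from [hit_counts_per_plate()].
#' @return A ggplot.
#' @export
plot_hit_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, -"assay_plate_id",
                              names_to = "direction", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assay_plate_id, y = .data$n,
                                     colour = .data$direction,
                                     group = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Hits per plate", x = NULL, y = "hits") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

save_figure <- function(plot, dump, path_stem, device = "jpeg") {
  img <- paste0(path_stem, if (device == "jpeg") ".jpg" else ".png")
  suppressMessages(ggplot2::ggsave(img, plot, width = 7, height = 4.5,
                                   dpi = 96, device = device))
  utils::write.table(dump, paste0(path_stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  basename(img)
}

#' Write all screen figures
#'
#' Produces the standard figure set: per-plate histograms and
#' original/rescaled heat maps; screen-wide row- and column-wise series
#' plots, control-mean and quality-metric lines, per-plate and
#' screen-wide score scatters, hit-frequency maps and per-plate hit
#' counts.  Each image is accompanied by a .tsv dump of its plotted
#' values and listed in `manifest.tsv` (section, label, file).
#'
#' @param result A `screen_result` (from [analyze_screen()]).
#' @param dir Directory for the `figures/` folder.
#' @param device `"jpeg"` (default) or `"png"`.
#' @return Invisibly, the manifest tibble.
#' @export
write_figures <- function(result, dir, device = c("jpeg", "png")) {
  device <- rlang::arg_match(device)
  figdir <- file.path(dir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  data <- result$data
  plates <- unique(data$plate_id)
  manifest <- list()
  add <- function(section, label, file) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(section = section, label = label, file = file)
  }

  transformed <- result$design$transform != "raw"
  for (p in plates) {
    pd <- plate_subset(data, p)
    f <- save_figure(plot_plate_histogram(data, p, transformed),
                     pd[, c("well", "raw", "value")],
                     file.path(figdir, paste0("qc_hist_", p)), device)
    add("Plate QC: distributions", paste0("Histogram ", p), f)
    f <- save_figure(plot_plate_heatmap(data, p),
                     pd[, c("well", "row", "col", "value")],
                     file.path(figdir, paste0("qc_heatmap_orig_", p)), device)
    add("Plate QC: heat maps", paste0("Heat map (original scale) ", p), f)
    dump <- pd[, c("well", "row", "col", "value")]
    dump$clipped <- clip_to_bounds(dump$value, result$heatmap_bounds)
    f <- save_figure(plot_plate_heatmap(data, p, result$heatmap_bounds),
                     dump,
                     file.path(figdir, paste0("qc_heatmap_rescaled_", p)),
                     device)
    add("Plate QC: heat maps", paste0("Heat map (rescaled) ", p), f)
  }
  for (by in c("row", "column")) {
    st <- series_table(data, by)
    f <- save_figure(plot_plate_series(data, by),
                     st[, c("index", "plate_id", "well", "value")],
                     file.path(figdir, paste0("qc_series_", by, "wise")),
                     device)
    add("Plate QC: series plots", paste0(by, "-wise series"), f)
  }
  if (!is.null(result$qc)) {
    f <- save_figure(plot_control_lines(result$qc), result$qc,
                     file.path(figdir, "qc_control_means"), device)
    add("Plate QC: metrics", "Control means", f)
    for (m in c("ssmd_qc", "zprime")) {
      f <- save_figure(plot_qc_lines(result$qc, m), result$qc,
                       file.path(figdir, paste0("qc_metric_", m)), device)
      add("Plate QC: metrics", paste0("Quality metric: ", m), f)
    }
  }
  score_dump <- result$scores[, c("assay_plate_id", "well", "score",
                                  "p_value")]
  f <- save_figure(plot_score_scatter(result$scores, result$design),
                   score_dump, file.path(figdir, "scores_screen"), device)
  add("Scoring", "Screen-wise scores", f)
  for (p in unique(result$scores$assay_plate_id)) {
    f <- save_figure(
      plot_score_scatter(result$scores, result$design, p),
      dplyr::filter(score_dump, .data$assay_plate_id == p),
      file.path(figdir, paste0("scores_plate_", p)), device)
    add("Scoring", paste0("Scores, plate ", p), f)
  }
  f <- save_figure(plot_hit_frequency(result$hit_freq), result$hit_freq,
                   file.path(figdir, "hits_frequency"), device)
  add("Hit selection", "Hit-frequency maps", f)
  f <- save_figure(plot_hit_counts(result$hit_counts), result$hit_counts,
                   file.path(figdir, "hits_counts"), device)
  add("Hit selection", "Hits per plate", f)

  manifest <- dplyr::bind_rows(manifest)
  utils::write.table(manifest, file.path(figdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Assemble the HTML report
#'
#' Builds `report.html` in a run folder from the figure manifest and the
#' tabular outputs, with sections ordered along the analysis workflow
#' (QC, scoring, hit selection, annotation).  The page references the
#' images by relative path; a manifest entry whose image file is missing
#' is an error.  Deterministic: identical inputs give identical HTML.
#'
#' @param run_dir Run folder containing `figures/manifest.tsv` and the
#'   result tables.
#' @return The path of `report.html`, invisibly.
#' @export
assemble_html <- function(run_dir) {
  manifest_path <- file.path(run_dir, "figures", "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort_screen("file_not_found",
      paste0("No figure manifest in ", run_dir))
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  missing <- !file.exists(file.path(run_dir, "figures", manifest$file))
  if (any(missing)) {
    abort_screen("broken_figure_link",
      paste0("Missing figure file(s): ",
             paste(manifest$file[missing], collapse = ", ")))
  }
  tables <- intersect(
    c("QC_summary.tsv", "Scores_all_wells.tsv", "Hits.tsv",
      "Annotated_hits.tsv", "Effect_class_counts.tsv",
      "Raw_data_compiled.tsv"),
    list.files(run_dir))
  lines <- c(
    "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    "<title>Screen analysis report</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
    "img{max-width:100%}</style></head><body>",
    "<h1>High-throughput screen analysis report</h1>",
    "<h2>Result tables</h2><ul>",
    sprintf("<li><a href='%s'>%s</a></li>", tables, html_escape(tables)),
    "</ul>")
  for (section in unique(manifest$section)) {
    lines <- c(lines, sprintf("<h2>%s</h2>", html_escape(section)))
    rows <- manifest[manifest$section == section, ]
    lines <- c(lines, sprintf(
      "<h3>%s</h3><img src='figures/%s' alt='%s'>",
      html_escape(rows$label), rows$file, html_escape(rows$label)))
  }
  lines <- c(lines, "</body></html>")
  out <- file.path(run_dir, "report.html")
  writeLines(lines, out)
  invisible(out)
}
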