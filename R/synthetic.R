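# Synthetic screen generator with known ground truth.
#
# Emulates a luminescence-readout siRNA screen: raw signals are
# log-normal (Gaussian on the log2 scale), so the raw histograms are
# right-skewed and the log2 transform visibly symmetrises them.  Control
# sets are shifted multiplicatively; hit wells are spiked at chosen true
# SSMD values on the log2 scale (shift = true_ssmd * sqrt(2) * sdlog2,
# the inversion of the single-copy SSMD formula); optional outliers are
# injected into control sets to exercise the knockout.  Generation is
# deterministic given the seed.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

default_spikes <- function(n_plates) {
  per_plate <- tibble::tibble(
    well = c("D5", "F12", "H18", "K8", "M20"),
    true_ssmd = c(3, 3, 3, -3, -3))
  tidyr::expand_grid(plate = seq_len(n_plates), per_plate)
}

#' Describe a synthetic screen
#'
#' The defaults reproduce the canonical demonstration screen: 12 plates,
#' 384-well standard layout (320 negative-reference samples, 16 negative
#' controls, 16 + 16 + 8 positive controls, 8 blanks), log-normal
#' baseline with `meanlog2 = 10`, `sdlog2 = 0.5`, positive-control
#' shifts of +3, +2 and -2 log2 units, and five spiked hits per plate
#' (three at true SSMD +3, two at -3).
#'
#' @param n_plates Number of assay plates.
#' @param config Plate configuration ([standard_384_config()] by
#'   default).
#' @param meanlog2,sdlog2 Mean and SD of the baseline signal on the log2
#'   scale.
#' @param control_shifts Named numeric vector of log2 shifts for the
#'   control sets (names among `negative_control`, `positive_1..3`).
#' @param spikes Tibble with columns `plate` (integer index, or `NA` for
#'   every plate), `well`, `true_ssmd`; `NULL` for none.  Spiked wells
#'   must be sample wells.
#' @param outliers Tibble with columns `set` (control set), `plate`,
#'   `z_offset` (offset in baseline-SD units, applied to one well of the
#'   set); `NULL` for none.
#' @param seed Integer seed; generation is reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_plates = 2, seed = 7)
synthetic_spec <- function(n_plates = 12,
                           config = standard_384_config(),
                           meanlog2 = 10, sdlog2 = 0.5,
                           control_shifts = c(positive_1 = 3,
                                              positive_2 = 2,
                                              positive_3 = -2),
                           spikes = default_spikes(n_plates),
                           outliers = NULL,
                           seed = 1) {
  stopifnot(n_plates >= 1, sdlog2 > 0)
  if (!is.null(spikes) && nrow(spikes)) {
    spikes <- tibble::as_tibble(spikes)
    spikes$well <- normalize_wells(spikes$well, config_format(config))
    bad <- config$role[match(spikes$well, config$well)] != "sample"
    if (any(bad)) {
      abort_screen("role_conflict",
        paste0("Spiked well(s) are not sample wells: ",
               paste(unique(spikes$well[bad]), collapse = ", ")))
    }
  }
  structure(
    list(n_plates = as.integer(n_plates), config = config,
         meanlog2 = meanlog2, sdlog2 = sdlog2,
         control_shifts = control_shifts,
         spikes = spikes, outliers = outliers, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Theoretical SSMD of a spiked well
#'
#' The single-copy SSMD of a well shifted by `shift` on the log scale
#' against a reference with log-scale SD `sdlog`: `shift / (sqrt(2) *
#' sdlog)`.  Used to place spikes in chosen effect-size classes.
#'
#' @param sdlog Log-scale SD of the baseline (> 0).
#' @param shift Log-scale shift added to the spiked well.
#' @return The true SSMD value.
#' @export
#' @examples
#' true_ssmd_spike(0.5, 3 * sqrt(2) * 0.5)  # 3
true_ssmd_spike <- function(sdlog, shift) {
  stopifnot(sdlog > 0)
  shift / (sqrt(2) * sdlog)
}

#' Simulate a screen in memory
#'
#' @param spec [synthetic_spec()].
#' @return List with `data` (long well table with `raw` and `missing`),
#'   `config`, `plate_pairs`, `annotations` (one gene ID per sample well
#'   per source plate), `ground_truth` (spiked wells with their true
#'   SSMD and effect class) and `injected_outliers` (the control wells
#'   that received an outlier offset).
#' @export
simulate_screen <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  config <- spec$config
  format <- config_format(config)
  n_wells <- nrow(config)
  plate_ids <- sprintf("Plate%02d", seq_len(spec$n_plates))
  source_ids <- sprintf("Source%02d", seq_len(spec$n_plates))

  outlier_log <- list()
  data <- local_seed(spec$seed, {
    purrr::map(seq_len(spec$n_plates), function(p) {
      log2v <- stats::rnorm(n_wells, spec$meanlog2, spec$sdlog2)
      for (set in names(spec$control_shifts)) {
        idx <- config$role == set
        log2v[idx] <- log2v[idx] + spec$control_shifts[[set]]
      }
      if (!is.null(spec$spikes) && nrow(spec$spikes)) {
        sp <- spec$spikes[is.na(spec$spikes$plate) | spec$spikes$plate == p, ]
        if (nrow(sp)) {
          idx <- match(sp$well, config$well)
          log2v[idx] <- log2v[idx] +
            sp$true_ssmd * sqrt(2) * spec$sdlog2
        }
      }
      if (!is.null(spec$outliers) && nrow(spec$outliers)) {
        ol <- spec$outliers[spec$outliers$plate == p, ]
        if (nrow(ol)) {
          for (i in seq_len(nrow(ol))) {
            set_wells <- which(config$role == ol$set[i])
            target <- sample(set_wells, 1)
            log2v[target] <- log2v[target] + ol$z_offset[i] * spec$sdlog2
            outlier_log[[length(outlier_log) + 1]] <<- tibble::tibble(
              plate_id = plate_ids[p], set = ol$set[i],
              well = config$well[target], z_offset = ol$z_offset[i])
          }
        }
      }
      blank <- config$role == "blank"
      tibble::tibble(
        plate_id = plate_ids[p],
        well = config$well, row = config$row, col = config$col,
        raw = ifelse(blank, NA_real_, 2^log2v),
        missing = blank)
    }) |>
      dplyr::bind_rows()
  })

  sample_wells <- config$well[config$role == "sample"]
  annotations <- tidyr::expand_grid(
    source_plate_id = source_ids,
    well = sample_wells) |>
    dplyr::arrange(.data$source_plate_id)
  annotations$gene_id <- sprintf("gene_%04d", seq_len(nrow(annotations)))

  gt_spikes <- if (!is.null(spec$spikes) && nrow(spec$spikes)) {
    spec$spikes |>
      dplyr::mutate(
        plate_id = ifelse(is.na(.data$plate), "all", plate_ids[.data$plate]),
        effect_class = classify_effect(.data$true_ssmd)) |>
      dplyr::select("plate_id", "well", "true_ssmd", "effect_class")
  } else {
    tibble::tibble(plate_id = character(), well = character(),
                   true_ssmd = numeric(), effect_class = character())
  }

  list(
    data = data,
    config = config,
    plate_pairs = tibble::tibble(assay_plate_id = plate_ids,
                                 source_plate_id = source_ids),
    annotations = annotations,
    ground_truth = gt_spikes,
    injected_outliers = if (length(outlier_log)) {
      dplyr::bind_rows(outlier_log)
    } else {
      tibble::tibble(plate_id = character(), set = character(),
                     well = character(), z_offset = numeric())
    },
    spec = spec
  )
}

#' Write a synthetic screen to disk
#'
#' Materialises [simulate_screen()] as the input files the readers
#' expect: one matrix file per plate (blank and missing wells written as
#' `NaN`), a plate-ID file, an annotation file and a
#' `ground_truth.tsv`.  Byte-identical for a given spec and seed.
#'
#' @param spec [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param delimiter `"tab"` (writes .tsv) or `"comma"` (writes .csv).
#' @param n_header_lines Number of header lines to prepend to each plate
#'   file.
#' @return Invisibly, the [simulate_screen()] result augmented with the
#'   file paths (`$files`).
#' @export
generate_screen <- function(spec, dir, delimiter = c("tab", "comma"),
                            n_header_lines = 2) {
  delimiter <- rlang::arg_match(delimiter)
  sim <- simulate_screen(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sep <- if (delimiter == "tab") "\t" else ","
  ext <- if (delimiter == "tab") "tsv" else "csv"
  dims <- plate_dims(config_format(spec$config))

  plate_files <- sim$data |>
    dplyr::group_split(.data$plate_id) |>
    purrr::map_chr(function(pd) {
      id <- pd$plate_id[1]
      path <- file.path(dir, paste0(id, ".", ext))
      vals <- ifelse(pd$missing | is.na(pd$raw), "NaN",
                     sprintf("%.10g", pd$raw))
      mat <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
      header <- sprintf("# synthetic plate %s (line %d of %d)",
                        id, seq_len(n_header_lines), n_header_lines)
      body <- apply(mat, 1, paste, collapse = sep)
      writeLines(c(utils::head(header, n_header_lines), body), path)
      path
    })

  plate_id_path <- file.path(dir, "plate_ids.tsv")
  writeLines(c("assay_plate_id\tsource_plate_id",
               paste(sim$plate_pairs$assay_plate_id,
                     sim$plate_pairs$source_plate_id, sep = "\t")),
             plate_id_path)

  ann_path <- file.path(dir, "annotations.tsv")
  writeLines(c("source_plate_id\twell\tgene_id",
               paste(sim$annotations$source_plate_id, sim$annotations$well,
                     sim$annotations$gene_id, sep = "\t")),
             ann_path)

  gt_path <- file.path(dir, "ground_truth.tsv")
  writeLines(c("plate_id\twell\ttrue_ssmd\teffect_class",
               paste(sim$ground_truth$plate_id, sim$ground_truth$well,
                     sprintf("%.10g", sim$ground_truth$true_ssmd),
                     sim$ground_truth$effect_class, sep = "\t")),
             gt_path)

  sim$files <- list(plates = plate_files, plate_ids = plate_id_path,
                    annotations = ann_path, ground_truth = gt_path,
                    dir = dir, n_header_lines = n_header_lines)
  invisible(sim)
}
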