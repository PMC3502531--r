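# Hit selection, hit categories, hit-frequency statistics and
# annotation joining.

#' Categorise scored wells as hits
#'
#' Cutoff comparisons are inclusive.  For the z/SSMD score families a
#' sample well is `up` when `score >= +cutoff` and `down` when
#' `score <= -cutoff`; percent activity is single-sided in the
#' user-chosen direction; the t-test flags `unclassified_hit` when
#' `p <= cutoff` (the test cannot tell signal-increasing from
#' signal-decreasing wells).  Control and blank wells, and wells with
#' undefined scores, are never hits.
#'
#' @param scores `screen_scores` table from [score_wells()].
#' @param design [screen_design()].
#' @return `scores` with a `hit_category` column (`up`, `down`,
#'   `unclassified_hit`, `non_hit`).
#' @export
classify_hits <- function(scores, design) {
  cutoff <- design$cutoff
  eligible <- scores$well_type == "sample" & is.finite(scores$score)
  cat <- rep("non_hit", nrow(scores))
  if (design$method == "t_test") {
    hit <- eligible & !is.na(scores$p_value) & scores$p_value <= cutoff
    cat[hit] <- "unclassified_hit"
  } else if (design$method == "percent_activity") {
    hit <- if (design$percent_activity_direction == "above") {
      eligible & scores$score >= cutoff
    } else {
      eligible & scores$score <= cutoff
    }
    cat[hit] <- ifelse(design$percent_activity_direction == "above",
                       "up", "down")
  } else {
    cat[eligible & scores$score >= cutoff] <- "up"
    cat[eligible & scores$score <= -cutoff] <- "down"
  }
  scores$hit_category <- cat
  scores
}

#' Select hit wells
#'
#' @inheritParams classify_hits
#' @return The hit rows of [classify_hits()] (category != `non_hit`).
#' @export
#' @examples
#' # see classify_hits() for the cutoff semantics
select_hits <- function(scores, design) {
  classify_hits(scores, design) |>
    dplyr::filter(.data$hit_category != "non_hit")
}

#' Per-well hit frequency across plates
#'
#' For each well position, the fraction of plates (or replicate groups)
#' in which that well was called a hit, separately for signal-increasing
#' and signal-decreasing hits.  Hotspots in these maps indicate
#' systematic errors, since true hits should be scattered randomly.
#'
#' @param hits Hit table from [select_hits()] (or a full
#'   [classify_hits()] table).
#' @param n_plates Number of plates (replicate groups) screened; the
#'   denominator for every well.
#' @param format Plate format (96 or 384).
#' @return Tibble with columns `direction` (`up`/`down`), `well`, `row`,
#'   `col`, `n_hit`, `frequency`, covering every well of the format.
#' @export
hit_frequency <- function(hits, n_plates, format = 384) {
  stopifnot(n_plates >= 1)
  grid <- all_wells(format)
  per_dir <- function(direction) {
    counts <- hits |>
      dplyr::filter(.data$hit_category == direction) |>
      dplyr::count(.data$well, name = "n_hit")
    grid |>
      dplyr::left_join(counts, by = "well") |>
      dplyr::mutate(direction = direction,
                    n_hit = dplyr::coalesce(.data$n_hit, 0L),
                    frequency = .data$n_hit / n_plates)
  }
  dplyr::bind_rows(per_dir("up"), per_dir("down")) |>
    dplyr::select("direction", "well", "row", "col", "n_hit", "frequency")
}

#' Hit counts per plate
#'
#' @param hits Hit table from [select_hits()].
#' @param plate_ids All assay plate IDs of the screen in run order
#'   (plates without hits are reported with zero counts).
#' @return Tibble with columns `assay_plate_id`, `n_up`, `n_down`,
#'   `n_unclassified`.
#' @export
hit_counts_per_plate <- function(hits, plate_ids) {
  counts <- hits |>
    dplyr::count(.data$assay_plate_id, .data$hit_category) |>
    tidyr::pivot_wider(names_from = "hit_category", values_from = "n",
                       values_fill = 0L)
  out <- tibble::tibble(assay_plate_id = plate_ids) |>
    dplyr::left_join(counts, by = "assay_plate_id")
  for (col in c("up", "down", "unclassified_hit")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]] <- dplyr::coalesce(out[[col]], 0L)
  }
  dplyr::transmute(out, assay_plate_id = .data$assay_plate_id,
                   n_up = .data$up, n_down = .data$down,
                   n_unclassified = .data$unclassified_hit)
}

#' Attach RNAi annotations to hit wells
#'
#' Left-joins the annotation table on (source plate ID, well).  Hits
#' whose source plate or well has no annotation row are retained with
#' empty annotation fields; a single warning reports how many were
#' unmatched (screens routinely have partial annotation).
#'
#' @param hits Hit table from [select_hits()] (carries
#'   `source_plate_id` from the plate-ID pairing; replicate copies of a
#'   source plate all map through the same annotations).
#' @param annotations Annotation table from [read_annotation_file()].
#' @return `hits` with the annotation columns appended.
#' @export
annotate_hits <- function(hits, annotations) {
  out <- dplyr::left_join(hits, annotations,
                          by = c("source_plate_id", "well"))
  ann_cols <- setdiff(names(annotations), c("source_plate_id", "well"))
  if (length(ann_cols)) {
    unmatched <- !stats::complete.cases(out[, ann_cols, drop = FALSE]) &
      apply(is.na(out[, ann_cols, drop = FALSE]), 1, all)
    if (any(unmatched)) {
      rlang::warn(paste0(sum(unmatched),
                         " hit(s) without a matching annotation entry"))
    }
  }
  out
}
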