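# The 21-bin SSMD effect-size scale.
#
# SSMD values are classified into signed strength bins (extremely weak to
# extremely strong, up- and down-regulated, plus "no effect" for exactly
# 0).  The bins partition the real line: on the up side each bin is
# [lower, upper) with the lower magnitude bound inclusive; the down side
# is the exact mirror, (-upper, -lower]; SSMD 0 is its own class, so the
# up-side "extremely weak" bin is open at 0.

.strengths <- c("extremely weak", "very weak", "weak", "fairly weak",
                "fairly moderate", "moderate", "fairly strong", "strong",
                "very strong", "extremely strong")
.thresholds <- c(0, 0.25, 0.5, 0.75, 1, 1.28, 1.645, 2, 3, 5, Inf)

#' The SSMD effect-size classification table
#'
#' All 21 classes in the conventional presentation order: up-regulated
#' from strongest to weakest, down-regulated from weakest to strongest,
#' then the zero class.
#'
#' @return Tibble with columns `type` (`up`/`down`/`zero`), `strength`,
#'   `label` (e.g. `"strong (up)"`), `lower`, `upper` (interval on the
#'   SSMD axis) and `bounds` (printable interval).
#' @export
#' @examples
#' effect_classes()
effect_classes <- function() {
  up <- tibble::tibble(
    type = "up",
    strength = rev(.strengths),
    lower = rev(.thresholds[1:10]),
    upper = rev(.thresholds[2:11])
  )
  up$bounds <- ifelse(
    is.infinite(up$upper), paste0("SSMD >= ", up$lower),
    ifelse(up$lower == 0, paste0(up$upper, " > SSMD > 0"),
           paste0(up$upper, " > SSMD >= ", up$lower)))
  down <- tibble::tibble(
    type = "down",
    strength = .strengths,
    lower = -.thresholds[2:11],
    upper = -.thresholds[1:10]
  )
  down$bounds <- ifelse(
    is.infinite(down$lower), paste0("SSMD <= ", down$upper),
    ifelse(down$upper == 0, paste0("0 > SSMD > ", down$lower),
           paste0(down$upper, " >= SSMD > ", down$lower)))
  zero <- tibble::tibble(type = "zero", strength = "no effect",
                         lower = 0, upper = 0, bounds = "SSMD = 0")
  out <- dplyr::bind_rows(up, down, zero)
  out$label <- ifelse(out$type == "zero", "no effect",
                      paste0(out$strength, " (", out$type, ")"))
  out[, c("type", "strength", "label", "lower", "upper", "bounds")]
}

#' Classify SSMD scores into effect-size classes
#'
#' Maps each finite SSMD value to the unique class of [effect_classes()]
#' containing it.  The classification is mirror-symmetric: on the up side
#' the lower magnitude bound is inclusive (`3 > SSMD >= 2` is "strong"),
#' on the down side the corresponding bound is `-2 >= SSMD > -3`; exactly
#' 0 is "no effect".
#'
#' @param ssmd Numeric vector of SSMD scores.
#' @param well Optional well IDs used in error messages.
#' @return Character vector of class labels (e.g. `"moderate (down)"`).
#' @export
#' @examples
#' classify_effect(c(2.1, 0, -1.4))
classify_effect <- function(ssmd, well = NULL) {
  bad <- !is.finite(ssmd)
  if (any(bad)) {
    where <- if (!is.null(well)) well[bad] else paste0("position ", which(bad))
    abort_screen("degenerate_reference",
      paste0("Non-finite SSMD score for well(s): ",
             paste(utils::head(where, 5), collapse = ", ")))
  }
  mag <- abs(ssmd)
  # bin index by magnitude; thresholds inclusive from below on the
  # magnitude scale, which yields [l, u) up and (-u, -l] down
  idx <- findInterval(mag, .thresholds[2:10]) + 1L
  out <- paste0(.strengths[idx],
                ifelse(ssmd > 0, " (up)", " (down)"))
  out[ssmd == 0] <- "no effect"
  out
}

#' Tally scored wells by effect-size class
#'
#' Counts the sample wells of a score table in each of the 21 effect
#' classes.  Only defined for the SSMD-family scoring methods.
#'
#' @param scores Score table (as from [score_wells()]) with columns
#'   `score`, `well_type` and (optionally) `effect_class`.
#' @param method Scoring method that produced the scores.
#' @return [effect_classes()] with a `count` column; counts sum to the
#'   number of scored sample wells.
#' @export
tally_effect_classes <- function(scores,
                                 method = attr(scores, "method") %||% "robust_ssmd") {
  if (!method %in% c("ssmd", "robust_ssmd", "ssmd_umvue")) {
    abort_screen("unsupported_method",
      paste0("Effect-size classification is defined for SSMD-family ",
             "methods only, not ", method))
  }
  samples <- dplyr::filter(scores, .data$well_type == "sample",
                           is.finite(.data$score))
  labels <- if (nrow(samples)) classify_effect(samples$score, samples$well) else character()
  tally <- dplyr::count(tibble::tibble(label = labels), .data$label,
                        name = "count")
  dplyr::left_join(effect_classes(), tally, by = "label") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Roll up effect-class counts by minimum strength
#'
#' Aggregates a per-class count table (as produced by
#' [tally_effect_classes()], or supplied externally) into the number of
#' up- and down-regulated wells whose effect is `at_least` a given
#' strength.
#'
#' @param counts Tibble with columns `type`, `strength` and `count`.
#' @param at_least Minimum strength to include (default `"moderate"`).
#' @return Tibble with columns `type` (`up`, `down`) and `count`.
#' @export
#' @examples
#' summarise_effect_counts(sirna_effect_counts())
summarise_effect_counts <- function(counts, at_least = "moderate") {
  rank <- match(counts$strength, .strengths)  # NA for "no effect"
  keep <- !is.na(rank) & rank >= match(at_least, .strengths) &
    counts$type %in% c("up", "down")
  counts[keep, ] |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$type))
}

#' Effect-class counts from a published 3840-gene siRNA screen
#'
#' Per-class well counts reported for a 12-plate, 384-well pooled mouse
#' siRNA screen (3840 genes, luminescence readout) analysed with robust
#' SSMD at cutoff 1.28 on log2 data.  Useful as a worked example for the
#' aggregation functions: the moderate-or-stronger roll-up gives 200
#' up-regulated and 150 down-regulated siRNAs.
#'
#' @return [effect_classes()] with a `count` column (21 rows).
#' @export
#' @examples
#' summarise_effect_counts(sirna_effect_counts())
sirna_effect_counts <- function() {
  counts <- c(
    # up, strongest to weakest
    2L, 15L, 39L, 34L, 110L, 169L, 235L, 338L, 417L, 561L,
    # down, weakest to strongest
    542L, 481L, 365L, 238L, 144L, 93L, 34L, 21L, 2L, 0L,
    # no effect
    0L
  )
  dplyr::mutate(effect_classes(), count = counts)
}
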