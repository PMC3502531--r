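# Data transformation and the scoring estimators.
#
# Single-copy scores compare each well with the plate's negative-reference
# distribution:
#   z        = (x - mean_N) / sd_N
#   robust z = (x - median_N) / MAD_N
#   SSMD     = (x - mean_N) / (sqrt(2) sd_N)        (= z / sqrt(2))
#   robust SSMD = (x - median_N) / (sqrt(2) MAD_N)
# where MAD carries the 1.4826 normal-consistency factor, so robust and
# classical scores agree on Gaussian data.  Percent activity normalises
# between the negative reference (low) and a designated positive control
# (high).  Replicated screens score the per-replicate differences
# d_j = x_j - median_N(plate j) with either the UMVUE of SSMD,
# c_n * dbar / s_d, or a paired two-sided t-test.

#' Transform signal values
#'
#' Applies the selected transform elementwise to the `raw` column,
#' writing a `value` column.  Under a log transform, nonpositive raw
#' values become missing, with a single warning carrying the count
#' (negative background-subtracted readouts are legitimate in screens);
#' a plate with no positive values at all is an error.
#'
#' @param data Long well table with columns `plate_id`, `raw`, `missing`.
#' @param transform `"raw"`, `"log2"` or `"log10"`.
#' @return `data` with columns `value` (transformed signal) and updated
#'   `missing`.
#' @export
transform_values <- function(data, transform = "raw") {
  if (!transform %in% TRANSFORMS) {
    abort_screen("invalid_transform", paste0("Unknown transform: ", transform))
  }
  if (transform == "raw") {
    data$value <- ifelse(data$missing, NA_real_, data$raw)
    return(data)
  }
  logf <- if (transform == "log2") log2 else log10
  nonpos <- !data$missing & !is.na(data$raw) & data$raw <= 0
  if (any(nonpos)) {
    rlang::warn(paste0(sum(nonpos), " nonpositive value(s) set to missing ",
                       "under ", transform, " transform"))
  }
  data$missing <- data$missing | nonpos
  data$value <- NA_real_
  ok <- !data$missing & !is.na(data$raw)
  data$value[ok] <- logf(data$raw[ok])
  dead <- data |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(all_missing = all(.data$missing), .groups = "drop") |>
    dplyr::filter(.data$all_missing)
  if (nrow(dead)) {
    abort_screen("transform_degenerate",
      paste0("Plate(s) with no positive values under ", transform, ": ",
             paste(dead$plate_id, collapse = ", ")))
  }
  data
}

#' Per-plate negative-reference statistics
#'
#' Mean, SD, median and MAD (scaled by 1.4826) of the negative-reference
#' wells of every plate, computed on the transformed values, excluding
#' missing wells.  A plate whose reference has zero SD or zero MAD
#' cannot support scoring and raises a `degenerate_reference` error.
#'
#' @param data Long well table with `plate_id`, `well`, `value`, `missing`.
#' @param config [plate_config()].
#' @return Tibble with columns `plate_id`, `n`, `mean`, `sd`, `median`,
#'   `mad`.
#' @export
negref_stats <- function(data, config) {
  check_config_for_scoring(config)
  nr_wells <- role_wells(config, "negative_reference")
  out <- data |>
    dplyr::filter(.data$well %in% nr_wells, !.data$missing,
                  is.finite(.data$value)) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      median = stats::median(.data$value),
      mad = stats::mad(.data$value),  # constant 1.4826
      .groups = "drop")
  thin <- out$n < 2
  if (any(thin)) {
    abort_screen("degenerate_reference",
      paste0("Fewer than 2 negative-reference values on plate(s): ",
             paste(out$plate_id[thin], collapse = ", ")))
  }
  degenerate <- out$sd == 0 | out$mad == 0
  if (any(degenerate)) {
    abort_screen("degenerate_reference",
      paste0("Zero negative-reference spread on plate(s): ",
             paste(out$plate_id[degenerate], collapse = ", ")))
  }
  out
}

#' Single-copy well scores
#'
#' @param x Numeric vector of (transformed) well values.
#' @param ref One row of [negref_stats()] (list or one-row data frame
#'   with `mean`, `sd`, `median`, `mad`).
#' @param method One of `"zscore"`, `"robust_zscore"`, `"ssmd"`,
#'   `"robust_ssmd"`.
#' @return Numeric vector of scores.
#' @export
#' @examples
#' ref <- list(mean = 3, sd = 1.5811388, median = 3, mad = 1.4826)
#' score_single(6, ref, "zscore")
score_single <- function(x, ref, method) {
  # the SSMD forms are computed as z / sqrt(2) so the documented
  # linearity between the two families holds to the last bit
  switch(method,
    zscore = (x - ref$mean) / ref$sd,
    robust_zscore = (x - ref$median) / ref$mad,
    ssmd = (x - ref$mean) / ref$sd / sqrt(2),
    robust_ssmd = (x - ref$median) / ref$mad / sqrt(2),
    abort_screen("unsupported_method",
      paste0("'", method, "' is not a single-copy score"))
  )
}

#' Normalised percent activity
#'
#' `100 (x - m_low) / (m_high - m_low)` with the negative reference as
#' the low signal and a designated positive-control set as the high
#' signal.
#'
#' @param x Numeric vector of (transformed) well values.
#' @param low_mean Negative-reference mean (low signal).
#' @param high_mean Positive-control mean (high signal).
#' @return Numeric vector of percent activities.
#' @export
#' @examples
#' percent_activity(60, low_mean = 10, high_mean = 110)
percent_activity <- function(x, low_mean, high_mean) {
  if (any(high_mean == low_mean)) {
    abort_screen("degenerate_normalization",
      "Percent activity undefined: high and low signal means are equal")
  }
  100 * (x - low_mean) / (high_mean - low_mean)
}

#' UMVUE correction factor for replicate SSMD
#'
#' `c_n = Gamma((n-1)/2) / Gamma((n-2)/2) * sqrt(2/(n-1))`, the factor
#' that makes `c_n * dbar / s_d` the uniformly minimum-variance unbiased
#' estimate of SSMD from `n` replicate differences.  Strictly between 0
#' and 1, increasing in `n`, tending to 1.
#'
#' @param n Integer vector of replicate counts (each >= 3).
#' @return Numeric vector of correction factors.
#' @export
#' @examples
#' umvue_factor(3)  # 1/sqrt(pi)
umvue_factor <- function(n) {
  if (any(!is.finite(n) | n < 3)) {
    abort_screen("insufficient_replicates",
      "The UMVUE factor requires at least 3 replicates")
  }
  exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2)) * sqrt(2 / (n - 1))
}

#' Score a well from replicate differences
#'
#' @param d Numeric vector of per-replicate differences
#'   `x_j - median_N(plate j)`.
#' @param method `"ssmd_umvue"` or `"t_test"`.
#' @return List with `score` and `p` (`NA` except for the t-test, which
#'   reports the two-sided p-value on `n - 1` degrees of freedom).
#'   Zero-variance differences yield `score = NA` (degenerate, reported
#'   but never a hit).
#' @export
#' @examples
#' score_replicates(c(1, 2, 3), "t_test")
score_replicates <- function(d, method = c("ssmd_umvue", "t_test")) {
  method <- rlang::arg_match(method)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) {
    abort_screen("insufficient_replicates",
      "Replicate scoring requires at least 3 non-missing replicate values")
  }
  s <- stats::sd(d)
  if (s == 0) {
    return(list(score = NA_real_, p = NA_real_))
  }
  if (method == "ssmd_umvue") {
    list(score = umvue_factor(n) * mean(d) / s, p = NA_real_)
  } else {
    t <- mean(d) / (s / sqrt(n))
    list(score = t, p = 2 * stats::pt(-abs(t), df = n - 1))
  }
}

# mean of the chosen high-signal control set per plate, after knockout
# when knockout is enabled (so percent activity uses the same cleaned
# controls as the QC report)
high_control_means <- function(data, config, design) {
  wells <- role_wells(config, design$percent_activity_high)
  if (!length(wells)) {
    abort_screen("missing_percent_activity_high",
      paste0("No wells assigned to ", design$percent_activity_high))
  }
  data |>
    dplyr::filter(.data$well %in% wells, !.data$missing,
                  is.finite(.data$value)) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(pd, key) {
      vals <- tibble::tibble(well = pd$well, value = pd$value)
      if (!is.null(design$knockout)) {
        vals <- knockout_outliers(vals, design$knockout)$kept
      }
      tibble::tibble(high_mean = mean(vals$value, na.rm = TRUE))
    }) |>
    dplyr::ungroup()
}

#' Score every well of a screen
#'
#' Applies the design's scoring method to all non-blank wells (controls
#' are scored too, for the by-well-type score report, but are never
#' hits).  Single-copy methods score each plate against its own
#' negative-reference statistics; replicated methods first chunk the
#' plate list into consecutive replicate groups and score the
#' per-replicate differences from each plate's reference median.
#'
#' @param data Long well table with `plate_id`, `well`, `row`, `col`,
#'   `raw`, `value`, `missing` (as produced by [read_screen_data()] +
#'   [transform_values()]).
#' @param config [plate_config()].
#' @param design [screen_design()].
#' @return Tibble of class `screen_scores`: `assay_plate_id`,
#'   `source_plate_id`, `well`, `row`, `col`, `well_type`,
#'   `negative_reference`, `raw`, `transformed`, `score`, `p_value`,
#'   `effect_class` (SSMD-family methods only), plus `group` and
#'   `n_replicates` in replicated mode.  Attribute `method` records the
#'   scoring method.
#' @export
score_wells <- function(data, config, design) {
  check_config_for_scoring(config)
  roles <- tibble::as_tibble(config)[, c("well", "role", "negative_reference")]
  data <- dplyr::left_join(data, roles, by = "well") |>
    dplyr::filter(.data$role != "blank")
  pairs <- design$plate_pairs
  if (is.null(pairs)) {
    pairs <- tibble::tibble(assay_plate_id = unique(data$plate_id),
                            source_plate_id = "no plateID")
  }
  ref <- negref_stats(data, config)

  if (design$mode == "single_copy") {
    scored <- dplyr::left_join(data, ref, by = "plate_id")
    if (design$method == "percent_activity") {
      high <- high_control_means(data, config, design)
      scored <- dplyr::left_join(scored, high, by = "plate_id")
      scored$score <- percent_activity(scored$value, scored$mean,
                                       scored$high_mean)
    } else {
      scored$score <- score_single(
        scored$value,
        list(mean = scored$mean, sd = scored$sd,
             median = scored$median, mad = scored$mad),
        design$method)
    }
    out <- scored |>
      dplyr::left_join(pairs, by = c(plate_id = "assay_plate_id")) |>
      dplyr::transmute(
        assay_plate_id = .data$plate_id,
        source_plate_id = dplyr::coalesce(.data$source_plate_id, "no plateID"),
        well = .data$well, row = .data$row, col = .data$col,
        well_type = .data$role,
        negative_reference = .data$negative_reference,
        raw = .data$raw, transformed = .data$value,
        score = .data$score, p_value = NA_real_)
  } else {
    groups <- replicate_groups(pairs, design$n_replicates)
    missing_plates <- setdiff(groups$assay_plate_id, unique(data$plate_id))
    if (length(missing_plates)) {
      abort_screen("plate_id_unmatched",
        paste0("Plate(s) in the plate-ID list without data: ",
               paste(missing_plates, collapse = ", ")))
    }
    med <- ref[, c("plate_id", "median")]
    d <- data |>
      dplyr::left_join(med, by = "plate_id") |>
      dplyr::mutate(diff = .data$value - .data$median) |>
      dplyr::inner_join(groups, by = c(plate_id = "assay_plate_id"))
    grouped <- d |>
      dplyr::group_by(.data$group, .data$source_plate_id, .data$well,
                      .data$row, .data$col, .data$role,
                      .data$negative_reference) |>
      dplyr::summarise(
        assay_plate_id = dplyr::first(.data$plate_id),
        raw = mean(.data$raw[!.data$missing]),
        transformed = mean(.data$value[is.finite(.data$value)]),
        n_eff = sum(is.finite(.data$diff)),
        d_mean = mean(.data$diff[is.finite(.data$diff)]),
        d_sd = stats::sd(.data$diff[is.finite(.data$diff)]),
        .groups = "drop")
    short <- grouped$n_eff < design$n_replicates & grouped$n_eff >= 3
    if (any(short)) {
      rlang::warn(paste0(sum(short), " well(s) scored on fewer than ",
                         design$n_replicates,
                         " replicates because of missing values"))
    }
    too_few <- grouped$n_eff < 3
    if (any(too_few)) {
      rlang::warn(paste0(sum(too_few), " well(s) with fewer than 3 ",
                         "non-missing replicates left unscored"))
    }
    ok <- !too_few & !is.na(grouped$d_sd) & grouped$d_sd > 0
    grouped$score <- NA_real_
    grouped$p_value <- NA_real_
    if (design$method == "ssmd_umvue") {
      grouped$score[ok] <- umvue_factor(grouped$n_eff[ok]) *
        grouped$d_mean[ok] / grouped$d_sd[ok]
    } else {
      t <- grouped$d_mean[ok] / (grouped$d_sd[ok] / sqrt(grouped$n_eff[ok]))
      grouped$score[ok] <- t
      grouped$p_value[ok] <- 2 * stats::pt(-abs(t), df = grouped$n_eff[ok] - 1)
    }
    out <- grouped |>
      dplyr::transmute(
        assay_plate_id = .data$assay_plate_id,
        source_plate_id = .data$source_plate_id,
        group = .data$group,
        n_replicates = .data$n_eff,
        well = .data$well, row = .data$row, col = .data$col,
        well_type = .data$role,
        negative_reference = .data$negative_reference,
        raw = .data$raw, transformed = .data$transformed,
        score = .data$score, p_value = .data$p_value) |>
      dplyr::arrange(.data$group, .data$row, .data$col)
  }

  if (design$method %in% c("ssmd", "robust_ssmd", "ssmd_umvue")) {
    finite <- is.finite(out$score)
    out$effect_class <- NA_character_
    out$effect_class[finite] <- classify_effect(out$score[finite])
  } else {
    out$effect_class <- NA_character_
  }
  attr(out, "method") <- design$method
  class(out) <- c("screen_scores", class(out))
  out
}
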