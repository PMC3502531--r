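# Plate quality control: control-set summaries, Z'-factor,
# method-of-moment SSMD, signal window, and the iterative control-outlier
# knockout.  All statistics use the sample SD (n - 1 denominator) and are
# computed on transformed data when a transform is selected.

summary_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- if (n) mean(values) else NA_real_
  s <- if (n >= 2) stats::sd(values) else NA_real_
  tibble::tibble(n = n, mean = m, sd = s,
                 cv = ifelse(is.na(m) | m == 0, NA_real_, s / m))
}

#' Z'-factor of a positive/negative control pair
#'
#' `Z' = 1 - 3 (s_p + s_n) / |m_p - m_n|`.  At most 1 (equal to 1 only
#' when both SDs vanish), unbounded below.  Undefined (NA) when the
#' control means coincide.
#'
#' @param pos_mean,pos_sd Mean and SD of the positive control set.
#' @param neg_mean,neg_sd Mean and SD of the negative control set.
#' @return Numeric vector of Z'-factors (NA where undefined).
#' @export
#' @examples
#' zprime(100, 5, 10, 5)  # 1 - 30/90
zprime <- function(pos_mean, pos_sd, neg_mean, neg_sd) {
  sep <- abs(pos_mean - neg_mean)
  ifelse(sep == 0, NA_real_, 1 - 3 * (pos_sd + neg_sd) / sep)
}

#' Method-of-moment SSMD of a control pair
#'
#' `(m_p - m_n) / sqrt(s_p^2 + s_n^2)`; signed like the mean difference.
#' Undefined (NA) when both SDs are zero.
#'
#' @inheritParams zprime
#' @return Numeric vector (NA where undefined).
#' @export
#' @examples
#' ssmd_qc(100, 5, 10, 5)  # 90 / sqrt(50)
ssmd_qc <- function(pos_mean, pos_sd, neg_mean, neg_sd) {
  pooled <- sqrt(pos_sd^2 + neg_sd^2)
  ifelse(pooled == 0, NA_real_, (pos_mean - neg_mean) / pooled)
}

#' Signal window of a control pair
#'
#' `(|m_p - m_n| - 3 (s_p + s_n)) / s_n`: the separation left between the
#' control bands after subtracting three SDs of each arm, in units of the
#' negative-control SD.  Negative values mean no usable window; undefined
#' (NA) when the negative-control SD is zero.
#'
#' @inheritParams zprime
#' @return Numeric vector (NA where undefined).
#' @export
#' @examples
#' signal_window(100, 5, 10, 5)  # (90 - 30)/5
signal_window <- function(pos_mean, pos_sd, neg_mean, neg_sd) {
  out <- (abs(pos_mean - neg_mean) - 3 * (pos_sd + neg_sd)) / neg_sd
  out[!is.finite(out)] <- NA_real_
  out
}

#' Iterative control-outlier knockout
#'
#' Repeatedly removes the most outlying value of a control set: at each
#' step the set mean and SD are recomputed on the current members, the
#' point with the largest absolute deviation from the mean is removed if
#' it lies beyond `k` SD, and the process stops when no point qualifies
#' or when `floor(f * n0)` removals have been made (`n0` the initial set
#' size), whichever comes first.  Ties on the deviation are broken toward
#' the earliest well in row-major order, so the procedure is
#' deterministic.
#'
#' @param values Tibble with columns `well` and `value` (row-major well
#'   order), or a plain numeric vector.
#' @param params [knockout_params()].
#' @return List with tibbles `kept` and `removed` (the latter in removal
#'   order).
#' @export
#' @examples
#' knockout_outliers(c(rep(10, 7), 30), knockout_params(k = 2, f = 0.3))
knockout_outliers <- function(values, params) {
  if (!inherits(params, "knockout_params")) {
    params <- do.call(knockout_params, as.list(params))
  }
  if (is.numeric(values)) {
    values <- tibble::tibble(well = as.character(seq_along(values)),
                             value = values)
  }
  values <- tibble::as_tibble(values)[, c("well", "value")]
  present <- values[is.finite(values$value), ]
  n0 <- nrow(present)
  cap <- floor(params$f * n0)
  cur <- present
  removed <- present[0, ]
  while (nrow(removed) < cap && nrow(cur) >= 2) {
    m <- mean(cur$value)
    s <- stats::sd(cur$value)
    if (!is.finite(s) || s == 0) break
    dev <- abs(cur$value - m)
    i <- which.max(dev)  # first maximum = earliest well on ties
    if (dev[i] > params$k * s) {
      removed <- dplyr::bind_rows(removed, cur[i, ])
      cur <- cur[-i, ]
    } else {
      break
    }
  }
  kept <- dplyr::bind_rows(cur, values[!is.finite(values$value), ])
  kept <- kept[order(match(kept$well, values$well)), ]
  list(kept = kept, removed = removed)
}

control_set_labels <- function(config) {
  sets <- c("negative_control",
            intersect(POSITIVE_SETS, unique(config$role)))
  c(sets, "negative_reference")
}

#' Per-plate quality control
#'
#' For every plate: control-set summaries (n, mean, SD, CV) for the
#' negative control, each positive-control set and the negative
#' reference, plus Z'-factor, method-of-moment SSMD and signal window for
#' each positive set against the negative control.  When knockout
#' parameters are given, the outlier knockout is applied to each control
#' set independently (never to the negative reference) and all metrics
#' are recomputed on the survivors; both stages are reported.
#'
#' @param data Long well table with columns `plate_id`, `well`, `value`
#'   (transformed signal) and `missing`.
#' @param config [plate_config()] with negative control and at least one
#'   positive-control set.
#' @param knockout Optional [knockout_params()].
#' @return Tibble of class `screen_qc` with one row per (plate, stage,
#'   control set): columns `plate_id`, `stage` (`before_knockout`,
#'   `after_knockout`), `set`, `n`, `mean`, `sd`, `cv`, `zprime`,
#'   `ssmd_qc`, `signal_window` (positive sets only) and
#'   `knocked_out_wells` (semicolon-joined).
#' @export
plate_qc <- function(data, config, knockout = NULL) {
  check_config_for_qc(config)
  sets <- control_set_labels(config)
  per_plate <- function(pd) {
    plate_vals <- function(wells) {
      v <- pd[match(wells, pd$well), ]
      v$value[v$missing] <- NA_real_
      v[, c("well", "value")]
    }
    stage_stats <- function(vals_by_set, stage, removed_by_set) {
      rows <- purrr::imap(vals_by_set, function(v, set) {
        st <- summary_stats(v$value)
        st$set <- set
        st$knocked_out_wells <-
          paste(removed_by_set[[set]] %||% character(), collapse = ";")
        st
      })
      out <- dplyr::bind_rows(rows)
      neg <- out[out$set == "negative_control", ]
      out$zprime <- NA_real_
      out$ssmd_qc <- NA_real_
      out$signal_window <- NA_real_
      pos_rows <- out$set %in% POSITIVE_SETS
      out$zprime[pos_rows] <- zprime(out$mean[pos_rows], out$sd[pos_rows],
                                     neg$mean, neg$sd)
      out$ssmd_qc[pos_rows] <- ssmd_qc(out$mean[pos_rows], out$sd[pos_rows],
                                       neg$mean, neg$sd)
      out$signal_window[pos_rows] <- signal_window(out$mean[pos_rows],
                                                   out$sd[pos_rows],
                                                   neg$mean, neg$sd)
      out$stage <- stage
      out
    }
    vals <- lapply(stats::setNames(sets, sets),
                   function(s) plate_vals(role_wells(config, s)))
    before <- stage_stats(vals, "before_knockout", list())
    if (is.null(knockout)) {
      after <- before
      after$stage <- "after_knockout"
    } else {
      ko_sets <- setdiff(sets, "negative_reference")
      removed <- list()
      vals_after <- vals
      for (s in ko_sets) {
        ko <- knockout_outliers(vals[[s]], knockout)
        vals_after[[s]] <- ko$kept
        removed[[s]] <- ko$removed$well
      }
      after <- stage_stats(vals_after, "after_knockout", removed)
    }
    dplyr::bind_rows(before, after)
  }
  out <- data |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(~ per_plate(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("plate_id", "stage", "set", "n", "mean", "sd", "cv",
                  "zprime", "ssmd_qc", "signal_window", "knocked_out_wells")
  class(out) <- c("screen_qc", class(out))
  out
}

#' Screen-wide bounds for rescaled heat maps
#'
#' Heat maps coloured on each plate's own min/max can hide systematic
#' errors in high-signal-window assays, so a second, rescaled map is
#' drawn with colour limits shared across the screen:
#' `low = min(negref means) - 2 * min(negref SDs)` and
#' `high = max(negref means) + 2 * max(negref SDs)`, the extrema taken
#' over plates.
#'
#' @param data Long well table with `plate_id`, `well`, `value`, `missing`.
#' @param config [plate_config()] with a non-empty negative-reference set.
#' @return Named numeric vector `c(low = , high = )`.
#' @export
rescaled_heatmap_bounds <- function(data, config) {
  nr_wells <- role_wells(config, "negative_reference")
  if (!length(nr_wells)) {
    abort_screen("missing_negative_reference",
      "Rescaled heat-map bounds require negative-reference wells")
  }
  stats <- data |>
    dplyr::filter(.data$well %in% nr_wells, !.data$missing,
                  is.finite(.data$value)) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  c(low = min(stats$mean) - 2 * min(stats$sd),
    high = max(stats$mean) + 2 * max(stats$sd))
}

#' Clip values to heat-map bounds
#'
#' @param x Numeric vector.
#' @param bounds `c(low, high)` as from [rescaled_heatmap_bounds()].
#' @return `x` clipped into `[low, high]`.
#' @export
clip_to_bounds <- function(x, bounds) {
  pmin(pmax(x, bounds[[1]]), bounds[[2]])
}
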