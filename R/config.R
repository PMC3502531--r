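# Plate configuration: the role of every well of the plate format.
#
# Roles: sample, negative_reference handling via a flag, negative_control,
# positive_1..positive_3, blank.  Every well carries exactly one role;
# in addition any sample or negative-control well may be flagged as a
# negative-reference well (the population supplying the scoring baseline).
# The dual designation negative_control + negative_reference is the only
# permitted overlap, used for focused/confirmatory libraries.

WELL_ROLES <- c("sample", "negative_control",
                "positive_1", "positive_2", "positive_3", "blank")
POSITIVE_SETS <- c("positive_1", "positive_2", "positive_3")

#' Build a plate configuration
#'
#' Assigns a role to every well of the chosen format.  Wells not listed in
#' `roles` are samples.  `negative_reference` names the wells whose
#' distribution supplies the scoring baseline: the default `"samples"`
#' flags every sample well (appropriate for unfocused libraries, where a
#' high hit rate is not expected); alternatively pass explicit well IDs
#' (which may be negative-control wells, for focused or confirmatory
#' screens).
#'
#' @param format Plate format, 96 or 384.
#' @param roles Named list mapping a role (`negative_control`,
#'   `positive_1`, `positive_2`, `positive_3`, `blank`) to a character
#'   vector of well IDs.
#' @param negative_reference `"samples"` or a character vector of well IDs.
#' @return A tibble of class `plate_config` with columns `well`, `row`,
#'   `col`, `role`, `negative_reference` (logical) and attribute `format`.
#' @export
#' @examples
#' cfg <- plate_config(96, roles = list(negative_control = c("A1", "B1")))
#' dplyr::count(cfg, role)
plate_config <- function(format = 384, roles = list(),
                         negative_reference = "samples") {
  dims <- plate_dims(format)
  if (length(roles)) {
    bad_roles <- setdiff(names(roles), setdiff(WELL_ROLES, "sample"))
    if (length(bad_roles)) {
      abort_screen("role_conflict",
        paste0("Unknown role(s): ", paste(bad_roles, collapse = ", ")))
    }
  }
  cfg <- all_wells(format)
  cfg$role <- "sample"
  assigned <- character(0)
  for (role in names(roles)) {
    wells <- normalize_wells(roles[[role]], format)
    dup <- intersect(wells, assigned)
    if (length(dup)) {
      abort_screen("role_conflict",
        paste0("Well(s) assigned to more than one role: ",
               paste(dup, collapse = ", ")))
    }
    assigned <- c(assigned, wells)
    cfg$role[match(wells, cfg$well)] <- role
  }

  if (identical(negative_reference, "samples")) {
    cfg$negative_reference <- cfg$role == "sample"
  } else {
    nr <- normalize_wells(negative_reference, format)
    cfg$negative_reference <- cfg$well %in% nr
    # dual designation is allowed only for sample and negative-control wells
    clash <- cfg$negative_reference &
      !cfg$role %in% c("sample", "negative_control")
    if (any(clash)) {
      abort_screen("role_conflict",
        paste0("Negative-reference flag on positive-control or blank well(s): ",
               paste(cfg$well[clash], collapse = ", ")))
    }
  }
  structure(cfg, format = as.integer(format),
            class = c("plate_config", class(cfg)))
}

#' @export
print.plate_config <- function(x, ...) {
  cat("Plate configuration (", attr(x, "format"), "-well)\n", sep = "")
  tally <- dplyr::count(tibble::as_tibble(x), .data$role)
  print(tally, ...)
  cat(sum(x$negative_reference), "negative-reference wells\n")
  invisible(x)
}

config_format <- function(config) {
  fmt <- attr(config, "format")
  if (is.null(fmt)) {
    # tolerate plain tibbles with the right columns
    fmt <- if (max(config$col) > 12 || max(config$row) > 8) 384L else 96L
  }
  fmt
}

# wells of a given control set (or negative reference) as a character vector
role_wells <- function(config, set) {
  if (set == "negative_reference") {
    config$well[config$negative_reference]
  } else {
    config$well[config$role == set]
  }
}

#' The standard 384-well screening layout
#'
#' The canonical layout used by the synthetic generator and the examples:
#' 320 sample wells (columns 3--22, all flagged negative reference), 16
#' negative-control wells (column 1), 16 + 16 wells of positive controls 1
#' and 2 (columns 2 and 23), 8 wells of positive control 3 (column 24,
#' rows A--H) and 8 blank wells (column 24, rows I--P).
#'
#' @return A `plate_config` for the 384-well format.
#' @export
#' @examples
#' standard_384_config()
standard_384_config <- function() {
  plate_config(
    format = 384,
    roles = list(
      negative_control = well_name(1:16, 1),
      positive_1 = well_name(1:16, 2),
      positive_2 = well_name(1:16, 23),
      positive_3 = well_name(1:8, 24),
      blank = well_name(9:16, 24)
    ),
    negative_reference = "samples"
  )
}

# Configuration checks shared by QC and scoring entry points.
check_config_for_scoring <- function(config) {
  if (!any(config$negative_reference)) {
    abort_screen("missing_negative_reference",
      "Scoring requires a non-empty negative-reference well set")
  }
  invisible(config)
}

check_config_for_qc <- function(config) {
  if (!any(config$role == "negative_control")) {
    abort_screen("missing_negative_control",
      "Plate QC requires negative-control wells")
  }
  if (!any(config$role %in% POSITIVE_SETS)) {
    abort_screen("missing_positive_control",
      "Plate QC requires at least one positive-control well set")
  }
  invisible(config)
}
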