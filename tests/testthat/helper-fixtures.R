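# Shared fixtures: tiny plates, configs and file writers, all built in
# code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

# a small 96-well config: 4 negative controls, 4 + 2 positive controls,
# 2 blanks, everything else sample (= negative reference)
tiny_config <- function() {
  plate_config(
    format = 96,
    roles = list(
      negative_control = c("A1", "B1", "C1", "D1"),
      positive_1 = c("E1", "F1", "G1", "H1"),
      positive_2 = c("A12", "B12"),
      blank = c("G12", "H12")
    )
  )
}

# long well table for one or more plates from a generator function
# value_fn(i, wells) -> numeric vector
make_data <- function(plate_ids, format = 96, value_fn = function(i, w) {
  seq_len(nrow(w)) + 100 * i
}) {
  wells <- all_wells(format)
  purrr::imap(plate_ids, function(id, i) {
    tibble::tibble(plate_id = id, well = wells$well, row = wells$row,
                   col = wells$col, raw = value_fn(i, wells),
                   missing = FALSE)
  }) |> dplyr::bind_rows()
}

# write a plate matrix file from a numeric matrix
write_plate_file <- function(mat, path, n_header_lines = 0, sep = "\t") {
  lines <- c(
    rep("header", n_header_lines),
    apply(mat, 1, paste, collapse = sep)
  )
  writeLines(lines, path)
  path
}

# matrix of the right shape filled with a constant (or given values)
grid_matrix <- function(format = 384, values = 1) {
  dims <- plate_dims(format)
  matrix(values, nrow = dims[1], ncol = dims[2])
}

# gaussian reference values used across scoring tests
ref_12345 <- function() {
  list(mean = 3, sd = stats::sd(1:5), median = 3, mad = stats::mad(1:5))
}

# single-plate synthetic spec with chosen spikes (robust-SSMD recovery
# fixtures); wells must be sample wells of the standard 384 layout
spiked_plate_spec <- function(seed, up = 8, down = 8, true_ssmd = 3) {
  samples <- standard_384_config()
  sample_wells <- samples$well[samples$role == "sample"]
  spikes <- tibble::tibble(
    plate = 1L,
    well = sample_wells[seq_len(up + down)],
    true_ssmd = c(rep(true_ssmd, up), rep(-true_ssmd, down)))
  synthetic_spec(n_plates = 1, spikes = spikes, seed = seed)
}

# robust-SSMD scores of all sample wells of a simulated screen
robust_ssmd_scores <- function(sim) {
  data <- transform_values(sim$data, "log2")
  ref <- negref_stats(data, sim$config)
  scored <- dplyr::left_join(data, ref, by = "plate_id")
  scored$score <- (scored$value - scored$median) / scored$mad / sqrt(2)
  roles <- tibble::as_tibble(sim$config)[, c("well", "role")]
  joined <- dplyr::left_join(scored, roles, by = "well")
  joined[joined$role == "sample", ]
}
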