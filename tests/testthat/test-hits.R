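# Hit selection, categories, frequency maps and annotation.

mk_scores <- function(scores, wells = NULL, type = "sample") {
  n <- length(scores)
  tibble::tibble(
    assay_plate_id = "P1", source_plate_id = "S1",
    well = wells %||% well_name(rep(1, n), seq_len(n)),
    row = 1, col = seq_len(n), well_type = type,
    raw = scores, transformed = scores, score = scores,
    p_value = NA_real_)
}

rz_design <- function(cutoff = 1.28) {
  screen_design("robust_ssmd", cutoff)
}

test_that("cutoffs are inclusive and two-sided for score families", {
  scores <- mk_scores(c(2.1, -1.5, 0.3, 1.28, -1.28))
  hits <- select_hits(scores, rz_design())
  expect_equal(hits$well[hits$hit_category == "up"], c("A1", "A4"))
  expect_equal(hits$well[hits$hit_category == "down"], c("A2", "A5"))
  full <- classify_hits(scores, rz_design())
  expect_equal(full$hit_category[full$well == "A3"], "non_hit")
  # up/down/non-hit partition the scored sample wells
  expect_setequal(full$hit_category, c("up", "down", "non_hit"))
})

test_that("control and blank wells are never hits", {
  scores <- dplyr::bind_rows(
    mk_scores(c(5, -5)),
    mk_scores(c(8, -8), wells = c("B1", "B2"), type = "negative_control"),
    mk_scores(6, wells = "C1", type = "positive_1"))
  hits <- select_hits(scores, rz_design())
  expect_equal(sort(hits$well), c("A1", "A2"))
})

test_that("t-test hits are unclassified and selected on p", {
  scores <- mk_scores(c(3.5, 1.2))
  scores$p_value <- c(0.04, 0.2)
  design <- screen_design("t_test", 0.05, mode = "replicates",
                          n_replicates = 3,
                          plate_pairs = tibble::tibble(
                            assay_plate_id = paste0("P", 1:3),
                            source_plate_id = "S1"))
  hits <- select_hits(scores, design)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$hit_category, "unclassified_hit")
})

test_that("percent-activity hits are single-sided", {
  design_above <- screen_design("percent_activity", 60,
                                percent_activity_high = "positive_1",
                                percent_activity_direction = "above")
  design_below <- screen_design("percent_activity", 30,
                                percent_activity_high = "positive_1",
                                percent_activity_direction = "below")
  scores <- mk_scores(c(75, 45, 10))
  expect_equal(select_hits(scores, design_above)$well, "A1")
  expect_equal(select_hits(scores, design_below)$well, "A3")
  expect_equal(select_hits(scores, design_above)$hit_category, "up")
  expect_equal(select_hits(scores, design_below)$hit_category, "down")
})

test_that("raising the cutoff never adds a hit", {
  set.seed(51)
  scores <- mk_scores(rnorm(200, 0, 2))
  cuts <- sort(runif(10, 0.2, 4))
  sizes <- vapply(cuts, function(ct) {
    nrow(select_hits(scores, rz_design(ct)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hits at cutoff 1.28 are at least fairly moderate", {
  set.seed(52)
  scores <- mk_scores(rnorm(500, 0, 1.5))
  hits <- select_hits(scores, rz_design(1.28))
  cls <- classify_effect(hits$score)
  strength <- sub(" \\((up|down)\\)", "", cls)
  weak <- c("extremely weak", "very weak", "weak", "fairly weak")
  expect_false(any(strength %in% weak))
  expect_false(any(cls == "no effect"))
})

test_that("hit frequencies count per well over all plates", {
  hits <- tibble::tibble(
    assay_plate_id = paste0("P", 1:6), well = "A1",
    hit_category = "up")
  freq <- hit_frequency(hits, n_plates = 12, format = 384)
  expect_equal(freq$frequency[freq$well == "A1" & freq$direction == "up"], 0.5)
  expect_equal(nrow(freq), 2L * 384L)
  # conservation: sum(freq) * n_plates = total hits per direction
  expect_equal(sum(freq$frequency[freq$direction == "up"]) * 12, 6)
  expect_equal(sum(freq$frequency[freq$direction == "down"]), 0)
  # no hits at all: all-zero maps
  none <- hit_frequency(hits[0, ], n_plates = 3, format = 96)
  expect_true(all(none$frequency == 0))
  # every well hit on every plate
  all_hits <- tidyr::expand_grid(assay_plate_id = paste0("P", 1:3),
                                 well = all_wells(96)$well) |>
    dplyr::mutate(hit_category = "down")
  f <- hit_frequency(all_hits, 3, 96)
  expect_true(all(f$frequency[f$direction == "down"] == 1))
})

test_that("per-plate hit counts include empty plates and conserve totals", {
  hits <- tibble::tibble(
    assay_plate_id = c("P1", "P1", "P2"),
    hit_category = c("up", "down", "up"))
  counts <- hit_counts_per_plate(hits, paste0("P", 1:3))
  expect_equal(counts$n_up, c(1L, 1L, 0L))
  expect_equal(counts$n_down, c(1L, 0L, 0L))
  expect_equal(sum(counts$n_up), sum(hits$hit_category == "up"))
})

test_that("spiked screens yield the designed per-plate hit counts", {
  spikes <- tidyr::expand_grid(
    plate = 1:4,
    tibble::tibble(well = c("D5", "F12", "H18"), true_ssmd = 6))
  sim <- simulate_screen(synthetic_spec(n_plates = 4, spikes = spikes,
                                        seed = 17))
  design <- screen_design("robust_ssmd", 3, transform = "log2",
                          plate_pairs = sim$plate_pairs)
  res <- analyze_screen(sim$data, sim$config, design, qc = FALSE)
  counts <- hit_counts_per_plate(res$hits, unique(sim$data$plate_id))
  expect_equal(counts$n_up, rep(3L, 4))
  expect_equal(sum(counts$n_down), 0L)
})

test_that("annotation joining keeps unmatched hits with a warning", {
  hits <- tibble::tibble(
    assay_plate_id = c("P1", "P2", "P3"),
    source_plate_id = c("S1", "S1", "no plateID"),
    well = c("A1", "A1", "B2"),
    score = c(2, 3, -2), hit_category = c("up", "up", "down"))
  ann <- tibble::tibble(source_plate_id = "S1", well = "A1",
                        gene = "Tp53")
  out <- NULL
  expect_warning(out <- annotate_hits(hits, ann), "without a matching")
  expect_equal(nrow(out), 3L)
  # replicate copies of one source plate all map through it
  expect_equal(out$gene[1:2], c("Tp53", "Tp53"))
  expect_true(is.na(out$gene[3]))
})

test_that("the null flag rate at cutoff 1.28 matches its theory value", {
  # under a Gaussian null the robust SSMD score is ~N(0, 1/2), so the
  # two-sided exceedance of 1.28 is 2*pnorm(-1.28*sqrt(2)) ~ 7%,
  # slightly deflated here by the spiked wells widening the MAD
  fpr <- vapply(1:60, function(seed) {
    spec <- spiked_plate_spec(seed, up = 8, down = 8, true_ssmd = 3)
    sc <- robust_ssmd_scores(simulate_screen(spec))
    null <- !sc$well %in% spec$spikes$well
    mean(abs(sc$score[null]) >= 1.28)
  }, numeric(1))
  expect_gt(mean(fpr), 0.03)
  expect_lt(mean(fpr), 0.10)
})
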