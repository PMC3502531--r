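# Plate quality metrics and the control-outlier knockout.

test_that("quality metrics match their closed forms", {
  expect_equal(zprime(100, 5, 10, 5), 1 - 30 / 90)
  expect_equal(ssmd_qc(100, 5, 10, 5), 90 / sqrt(50))
  expect_equal(signal_window(100, 5, 10, 5), 12)

  # perfect separation and undefined cases
  expect_equal(zprime(100, 0, 10, 0), 1)
  expect_true(is.na(zprime(50, 5, 50, 5)))
  expect_equal(ssmd_qc(50, 5, 50, 5), 0)
  expect_true(is.na(ssmd_qc(100, 0, 10, 0)))
  expect_true(is.na(signal_window(100, 5, 10, 0)))
  # swapping the arms negates the QC SSMD
  expect_equal(ssmd_qc(10, 5, 100, 5), -ssmd_qc(100, 5, 10, 5))
  # boundary: window exactly closed
  expect_equal(signal_window(40, 5, 10, 5), 0)
  # identical controls: negative window, no separation
  expect_lt(signal_window(10, 5, 10, 5), 0)
  # vectorised over positive sets
  expect_equal(signal_window(c(100, 40), c(5, 5), 10, 5), c(12, 0))
})

test_that("quality metrics are invariant under affine rescaling", {
  set.seed(21)
  for (i in 1:20) {
    mp <- runif(1, 50, 150); sp <- runif(1, 1, 10)
    mn <- runif(1, 0, 40); sn <- runif(1, 1, 10)
    a <- runif(1, 0.1, 5); b <- runif(1, -50, 50)
    expect_equal(zprime(a * mp + b, a * sp, a * mn + b, a * sn),
                 zprime(mp, sp, mn, sn))
    expect_equal(ssmd_qc(a * mp + b, a * sp, a * mn + b, a * sn),
                 ssmd_qc(mp, sp, mn, sn))
    expect_equal(signal_window(a * mp + b, a * sp, a * mn + b, a * sn),
                 signal_window(mp, sp, mn, sn))
  }
  expect_lte(zprime(100, 5, 10, 5), 1)
})

test_that("knockout removes the most extreme point first and stops", {
  # hand-computed: mean 12.5, sd sqrt(50); |30-12.5| = 17.5 > 2*7.071
  ko <- knockout_outliers(c(rep(10, 7), 30), knockout_params(2, 0.3))
  expect_equal(ko$removed$value, 30)
  expect_equal(nrow(ko$kept), 7L)

  # all equal: nothing to remove
  ko <- knockout_outliers(rep(5, 8), knockout_params(2, 0.3))
  expect_equal(nrow(ko$removed), 0L)

  # cap of zero binds before any removal
  ko <- knockout_outliers(c(rep(10, 7), 1e6), knockout_params(2, 0.05))
  expect_equal(nrow(ko$removed), 0L)

  # enormous k: nothing removed
  ko <- knockout_outliers(c(1, 2, 3, 50), knockout_params(1e9, 1))
  expect_equal(nrow(ko$removed), 0L)

  # f = 1 with one extreme among constants: exactly that point goes
  ko <- knockout_outliers(c(rep(2, 9), 40), knockout_params(2, 1))
  expect_equal(ko$removed$value, 40)

  # ties on the deviation: earliest well in input (row-major) order
  vals <- tibble::tibble(well = c("A1", "A2", "A3", "A4"),
                         value = c(0, 10, 10, 0))
  ko <- knockout_outliers(vals, knockout_params(0.5, 0.25))
  expect_equal(ko$removed$well, "A1")
})

test_that("knockout agrees with a brute-force oracle and obeys its cap", {
  brute_knockout <- function(vals, k, f) {
    removed <- integer(0)
    cap <- floor(f * length(vals))
    repeat {
      if (length(removed) >= cap) break
      left <- setdiff(seq_along(vals), removed)
      if (length(left) < 2) break
      m <- mean(vals[left])
      s <- stats::sd(vals[left])
      if (!is.finite(s) || s == 0) break
      devs <- abs(vals - m)
      devs[removed] <- -Inf
      cand <- which.max(devs)
      if (devs[cand] > k * s) removed <- c(removed, cand) else break
    }
    removed
  }
  set.seed(99)
  for (i in 1:2000) {
    n <- sample(3:8, 1)
    vals <- round(rnorm(n, 0, 1 + 4 * runif(1)), 2)
    k <- runif(1, 0.5, 3)
    f <- runif(1)
    ko <- knockout_outliers(vals, knockout_params(k, f))
    expect_identical(as.integer(ko$removed$well), brute_knockout(vals, k, f))
    # partition and cap invariants
    expect_lte(nrow(ko$removed), floor(f * n))
    expect_equal(sort(c(ko$kept$value, ko$removed$value)), sort(vals))
    expect_length(intersect(ko$kept$well, ko$removed$well), 0)
  }
})

test_that("plate_qc reports both stages with per-set metrics", {
  sim <- simulate_screen(synthetic_spec(n_plates = 2, seed = 8))
  data <- transform_values(sim$data, "log2")
  qc <- plate_qc(data, sim$config, knockout_params(2, 0.3))

  expect_equal(sort(unique(qc$stage)), c("after_knockout", "before_knockout"))
  one <- qc[qc$plate_id == "Plate01" & qc$stage == "before_knockout", ]
  # 5 control sets tracked; metric triple on each of the 3 positive sets
  expect_equal(nrow(one), 5L)
  pos <- one[grepl("^positive", one$set), ]
  expect_equal(nrow(pos), 3L)
  expect_true(all(is.finite(pos$zprime)))
  expect_true(all(is.finite(pos$ssmd_qc)))
  expect_true(all(is.finite(pos$signal_window)))
  # negative reference is summarised but never gets pair metrics
  nr <- one[one$set == "negative_reference", ]
  expect_equal(nr$n, 320L)
  expect_true(is.na(nr$zprime))

  # knockout cap: each control set keeps at least 70% of its wells
  after <- qc[qc$stage == "after_knockout" & qc$set != "negative_reference", ]
  before <- qc[qc$stage == "before_knockout" & qc$set != "negative_reference", ]
  expect_true(all(after$n >= ceiling(0.7 * before$n)))
  # the knocked-out wells are recorded
  n_ko <- lengths(strsplit(after$knocked_out_wells, ";"))
  n_ko[after$knocked_out_wells == ""] <- 0L
  expect_equal(before$n - after$n, n_ko)

  # without knockout the two stages coincide
  qc0 <- plate_qc(data, sim$config)
  b <- qc0[qc0$stage == "before_knockout", -2]
  a <- qc0[qc0$stage == "after_knockout", -2]
  expect_equal(as.data.frame(a), as.data.frame(b))

  expect_error(plate_qc(data, plate_config(384)),
               class = "ssmdscreen_missing_negative_control")
})

test_that("rescaled heat-map bounds follow the negative-reference extrema", {
  # two plates with negref means {100, 120} and SDs {10, 15}
  cfg <- plate_config(96)
  set.seed(4)
  mk <- function(id, mean, sd) {
    w <- all_wells(96)
    v <- scale(rnorm(96)) * sd + mean  # exact sample mean/sd
    tibble::tibble(plate_id = id, well = w$well, row = w$row, col = w$col,
                   value = as.numeric(v), missing = FALSE)
  }
  data <- dplyr::bind_rows(mk("p1", 100, 10), mk("p2", 120, 15))
  b <- rescaled_heatmap_bounds(data, cfg)
  expect_equal(unname(b), c(100 - 2 * 10, 120 + 2 * 15))

  # single plate collapses to mean +/- 2 SD
  b1 <- rescaled_heatmap_bounds(mk("p1", 50, 4), cfg)
  expect_equal(unname(b1), c(42, 58))

  # identical plates: same bounds as one plate
  b2 <- rescaled_heatmap_bounds(
    dplyr::bind_rows(mk("p1", 50, 4), dplyr::mutate(mk("p1", 50, 4),
                                                    plate_id = "p2")), cfg)
  expect_equal(b2, b1)

  empty_cfg <- plate_config(96, roles = list(), negative_reference = character())
  expect_error(rescaled_heatmap_bounds(data, empty_cfg),
               class = "ssmdscreen_missing_negative_reference")
})
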