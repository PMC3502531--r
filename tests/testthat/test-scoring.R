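# Transforms, negative-reference statistics and the scoring estimators.

test_that("transforms are elementwise and guard nonpositive values", {
  data <- tibble::tibble(plate_id = "p", well = c("A1", "A2", "A3"),
                         row = 1, col = 1:3,
                         raw = c(8, 1000, -5), missing = FALSE)
  out <- NULL
  expect_warning(out <- transform_values(data, "log2"), "nonpositive")
  expect_equal(out$value[1], 3)
  expect_true(out$missing[3])
  expect_true(is.na(out$value[3]))
  out10 <- NULL
  expect_warning(out10 <- transform_values(data, "log10"), "nonpositive")
  expect_equal(out10$value[2], 3)
  raw <- transform_values(data, "raw")
  expect_equal(raw$value, raw$raw)

  all_neg <- dplyr::mutate(data, raw = -abs(raw))
  expect_error(suppressWarnings(transform_values(all_neg, "log2")),
               class = "ssmdscreen_transform_degenerate")
  expect_error(transform_values(data, "ln"),
               class = "ssmdscreen_invalid_transform")
})

test_that("negative-reference statistics are computed per plate", {
  cfg <- plate_config(96)
  w <- all_wells(96)
  mk <- function(id, vals) {
    tibble::tibble(plate_id = id, well = w$well[seq_along(vals)],
                   row = 1, col = seq_along(vals),
                   value = vals, missing = FALSE)
  }
  st <- negref_stats(mk("p", 1:5), cfg)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sd(1:5))
  expect_equal(st$median, 3)
  expect_equal(st$mad, 1.4826)

  # robust statistics shrug off a gross outlier
  st2 <- negref_stats(mk("p", c(1, 2, 3, 4, 100)), cfg)
  expect_equal(st2$median, 3)
  expect_equal(st2$mad, 1.4826)
  expect_equal(st2$mean, 22)
  expect_equal(st2$sd, sd(c(1, 2, 3, 4, 100)))

  expect_error(negref_stats(mk("p", rep(7, 10)), cfg),
               class = "ssmdscreen_degenerate_reference")
})

test_that("single-copy scores match their definitions and the sqrt(2) link", {
  ref <- ref_12345()
  expect_equal(score_single(6, ref, "zscore"), 3 / sd(1:5))
  expect_equal(score_single(6, ref, "ssmd"),
               score_single(6, ref, "zscore") / sqrt(2))
  expect_equal(score_single(ref$mean, ref, "zscore"), 0)
  expect_equal(score_single(ref$mean, ref, "ssmd"), 0)

  ref2 <- list(mean = 22, sd = sd(c(1, 2, 3, 4, 100)), median = 3,
               mad = 1.4826)
  expect_equal(score_single(6, ref2, "robust_zscore"), 3 / 1.4826)
  expect_equal(score_single(6, ref2, "robust_ssmd"),
               3 / 1.4826 / sqrt(2))
  expect_error(score_single(6, ref, "t_test"),
               class = "ssmdscreen_unsupported_method")
})

test_that("the SSMD/z linearity holds on random plates", {
  set.seed(31)
  for (i in 1:5) {
    vals <- rlnorm(2000, 7, 0.6)
    ref <- list(mean = mean(vals[1:300]), sd = sd(vals[1:300]),
                median = median(vals[1:300]), mad = mad(vals[1:300]))
    expect_equal(score_single(vals, ref, "ssmd"),
                 score_single(vals, ref, "zscore") / sqrt(2))
    expect_equal(score_single(vals, ref, "robust_ssmd"),
                 score_single(vals, ref, "robust_zscore") / sqrt(2))
  }
})

test_that("single-copy scores are location-scale invariant", {
  set.seed(32)
  vals <- rnorm(50, 10, 2)
  refvals <- rnorm(200, 10, 2)
  mkref <- function(v) list(mean = mean(v), sd = sd(v),
                            median = median(v), mad = mad(v))
  a <- 2.7; b <- -13
  for (m in c("zscore", "robust_zscore", "ssmd", "robust_ssmd")) {
    expect_equal(score_single(a * vals + b, mkref(a * refvals + b), m),
                 score_single(vals, mkref(refvals), m))
  }
})

test_that("robust scores ignore a corrupted reference maximum", {
  base <- 1:9
  blown <- base
  blown[9] <- 9 * 1e6
  mkref <- function(v) list(mean = mean(v), sd = sd(v),
                            median = median(v), mad = mad(v))
  x <- c(2.5, 4.5, 7)
  expect_lt(max(abs(score_single(x, mkref(blown), "robust_zscore") -
                    score_single(x, mkref(base), "robust_zscore"))), 1e-12)
  expect_lt(max(abs(score_single(x, mkref(blown), "robust_ssmd") -
                    score_single(x, mkref(base), "robust_ssmd"))), 1e-12)
  expect_gt(max(abs(score_single(x, mkref(blown), "zscore") -
                    score_single(x, mkref(base), "zscore"))), 1)
})

test_that("percent activity normalises between reference and high control", {
  expect_equal(percent_activity(60, low_mean = 10, high_mean = 110), 50)
  expect_equal(percent_activity(10, 10, 110), 0)
  expect_equal(percent_activity(110, 10, 110), 100)
  expect_error(percent_activity(5, 10, 10),
               class = "ssmdscreen_degenerate_normalization")
})

test_that("the UMVUE factor matches its gamma closed form", {
  expect_equal(umvue_factor(3), 1 / sqrt(pi), tolerance = 1e-12)
  expect_equal(umvue_factor(4), gamma(1.5) / gamma(1) * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(umvue_factor(100), 1, tolerance = 0.01)
  # 0 < c_n < 1, strictly increasing, tending to 1
  cn <- umvue_factor(3:200)
  expect_true(all(cn > 0 & cn < 1))
  expect_true(all(diff(cn) > 0))
  expect_error(umvue_factor(2), class = "ssmdscreen_insufficient_replicates")
})

test_that("replicate scores match the t oracle and shrink the ratio", {
  d <- c(1, 2, 3)
  t <- score_replicates(d, "t_test")
  expect_equal(t$score, 2 / (1 / sqrt(3)))
  expect_equal(t$score, unname(t.test(d)$statistic))  # independent route
  expect_equal(t$p, t.test(d)$p.value)
  expect_equal(t$p, 0.0742, tolerance = 1e-3)

  s <- score_replicates(d, "ssmd_umvue")
  expect_equal(s$score, (1 / sqrt(pi)) * 2, tolerance = 1e-12)
  expect_true(is.na(s$p))

  z <- score_replicates(c(-1, 0, 1), "t_test")
  expect_equal(z$score, 0)
  expect_equal(z$p, 1)
  expect_equal(score_replicates(c(-1, 0, 1), "ssmd_umvue")$score, 0)

  # UMVUE shrinkage: strictly smaller magnitude than dbar/s
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    d <- rnorm(n, 1)
    got <- score_replicates(d, "ssmd_umvue")$score
    expect_lt(abs(got), abs(mean(d) / sd(d)) + 1e-15)
  }

  expect_equal(score_replicates(c(4, 4, 4), "t_test"),
               list(score = NA_real_, p = NA_real_))
  expect_error(score_replicates(c(1, 2), "t_test"),
               class = "ssmdscreen_insufficient_replicates")
})

test_that("score_wells drives the replicate pipeline end to end", {
  cfg <- standard_384_config()
  spec <- synthetic_spec(n_plates = 6, config = cfg, seed = 13,
                         spikes = tibble::tibble(plate = NA_integer_,
                                                 well = "H10",
                                                 true_ssmd = 4))
  sim <- simulate_screen(spec)
  # 6 plates as 2 groups of 3: rename sources so copies share one source
  pairs <- sim$plate_pairs
  pairs$source_plate_id <- rep(c("S1", "S2"), each = 3)
  design <- screen_design("ssmd_umvue", 1.28, mode = "replicates",
                          n_replicates = 3, transform = "log2",
                          plate_pairs = pairs)
  data <- transform_values(sim$data, "log2")
  scores <- score_wells(data, cfg, design)
  expect_equal(dplyr::n_distinct(scores$group), 2L)
  # one score per well per group, blanks excluded
  expect_equal(nrow(scores), 2L * 376L)
  expect_true(all(scores$n_replicates == 3))
  # the spiked well scores high in both groups
  spiked <- scores[scores$well == "H10", ]
  expect_true(all(spiked$score > 1.28))
  expect_true(all(!is.na(scores$effect_class[is.finite(scores$score)])))

  tdesign <- screen_design("t_test", 0.05, mode = "replicates",
                           n_replicates = 3, transform = "log2",
                           plate_pairs = pairs)
  tscores <- score_wells(data, cfg, tdesign)
  expect_true(all(tscores$p_value[is.finite(tscores$score)] >= 0 &
                  tscores$p_value[is.finite(tscores$score)] <= 1))
  expect_true(all(tscores$p_value[tscores$well == "H10"] < 0.05))

  # an odd plate count cannot be grouped
  expect_error(replicate_groups(pairs[1:5, ], 3),
               class = "ssmdscreen_replicate_count_mismatch")
  bad <- sim$plate_pairs  # six distinct sources
  expect_error(replicate_groups(bad, 3),
               class = "ssmdscreen_replicate_source_mismatch")
})
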