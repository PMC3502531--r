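# Figures and the HTML report.  Figure content is asserted on the
# plotted data (series tables, clipped matrices, dump files), not on
# rendered pixels.

small_result <- function(n_plates = 2, seed = 23) {
  sim <- simulate_screen(synthetic_spec(n_plates = n_plates, seed = seed))
  design <- screen_design("robust_ssmd", 1.28, transform = "log2",
                          knockout = knockout_params(2, 0.3),
                          plate_pairs = sim$plate_pairs)
  analyze_screen(sim$data, sim$config, design)
}

test_that("series plots traverse wells in the documented order", {
  res <- small_result()
  rw <- ssmdscreen:::series_table(res$data, "row")
  expect_equal(nrow(rw), 2L * 384L)
  # row-wise: A1..A24 then B1..
  expect_equal(rw$well[1:3], c("A1", "A2", "A3"))
  expect_equal(rw$well[25], "B1")
  cw <- ssmdscreen:::series_table(res$data, "column")
  # column-wise index of well (r, c) is (c-1)*n_rows + r
  expect_equal(cw$well[1:3], c("A1", "B1", "C1"))
  idx <- cw$index[cw$plate_id == "Plate01"]
  expect_equal(idx, (cw$col[1:384] - 1) * 16 + cw$row[1:384])
  # plates are consecutive segments
  expect_equal(cw$index[cw$plate_id == "Plate02"][1], 385L)
})

test_that("rescaled heat-map clipping is idempotent and order-preserving", {
  b <- c(80, 150)
  expect_equal(clip_to_bounds(200, b), 150)
  expect_equal(clip_to_bounds(40, b), 80)
  set.seed(61)
  x <- runif(500, 0, 250)
  once <- clip_to_bounds(x, b)
  expect_equal(clip_to_bounds(once, b), once)
  inside <- x[x > b[1] & x < b[2]]
  expect_equal(clip_to_bounds(inside, b), inside)
  # order preserved on unclipped values
  expect_equal(order(clip_to_bounds(inside, b)), order(inside))
})

test_that("plot builders return ggplot objects for every figure kind", {
  res <- small_result()
  expect_s3_class(plot_plate_histogram(res$data, "Plate01"), "ggplot")
  expect_s3_class(plot_plate_heatmap(res$data, "Plate01"), "ggplot")
  expect_s3_class(plot_plate_heatmap(res$data, "Plate01",
                                     res$heatmap_bounds), "ggplot")
  expect_s3_class(plot_plate_series(res$data, "column"), "ggplot")
  expect_s3_class(plot_control_lines(res$qc), "ggplot")
  expect_s3_class(plot_qc_lines(res$qc, "zprime"), "ggplot")
  expect_s3_class(plot_score_scatter(res$scores, res$design), "ggplot")
  expect_s3_class(plot_hit_frequency(res$hit_freq), "ggplot")
  expect_s3_class(plot_hit_counts(res$hit_counts), "ggplot")
  expect_s3_class(autoplot(res, "scores"), "ggplot")
  expect_s3_class(autoplot(res, "heatmap", plate = "Plate02"), "ggplot")
})

test_that("figures, dumps and the report are written and verified", {
  res <- small_result()
  dir <- withr::local_tempdir()
  write_outputs(res, dir)
  manifest <- write_figures(res, dir)
  figdir <- file.path(dir, "figures")
  expect_true(all(file.exists(file.path(figdir, manifest$file))))
  # every image has a tsv dump of its plotted values
  dumps <- sub("\\.jpg$", ".tsv", manifest$file)
  expect_true(all(file.exists(file.path(figdir, dumps))))
  # per-plate kinds appear once per plate (hist + 2 heat maps + scatter)
  expect_equal(sum(grepl("^qc_hist_", manifest$file)), 2L)
  expect_equal(sum(grepl("^qc_heatmap_", manifest$file)), 4L)
  expect_equal(sum(grepl("^scores_plate_", manifest$file)), 2L)

  # the rescaled dump really is clipped to the screen-wide bounds
  dump <- utils::read.delim(file.path(figdir,
                                      "qc_heatmap_rescaled_Plate01.tsv"))
  expect_true(all(dump$clipped >= res$heatmap_bounds[1] - 1e-9, na.rm = TRUE))
  expect_true(all(dump$clipped <= res$heatmap_bounds[2] + 1e-9, na.rm = TRUE))
  expect_equal(dump$clipped,
               unname(clip_to_bounds(dump$value, res$heatmap_bounds)))

  # report assembly is deterministic and checks its links
  html1 <- assemble_html(dir)
  first <- readLines(html1)
  html2 <- assemble_html(dir)
  expect_identical(readLines(html2), first)
  expect_gte(length(unique(manifest$section)), 4L)
  expect_true(any(grepl("scores_screen", first)))

  # a missing image breaks assembly
  file.remove(file.path(figdir, manifest$file[1]))
  expect_error(assemble_html(dir), class = "ssmdscreen_broken_figure_link")
})

test_that("t-test scatter uses the -log10 p scale", {
  sim <- simulate_screen(synthetic_spec(n_plates = 3, seed = 29))
  pairs <- sim$plate_pairs
  pairs$source_plate_id <- "S1"
  design <- screen_design("t_test", 0.05, mode = "replicates",
                          n_replicates = 3, transform = "log2",
                          plate_pairs = pairs)
  res <- analyze_screen(sim$data, sim$config, design, qc = FALSE)
  p <- plot_score_scatter(res$scores, design)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  hline <- built$data[[2]]
  expect_equal(hline$yintercept, -log10(0.05))
})
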