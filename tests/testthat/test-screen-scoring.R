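# Well aggregation, Z-scoring, QMS assembly and hit calling.

make_layout2 <- function(n_cond = 4, n_mock = 10, replicates = 2) {
  screen_layout(sprintf("c%02d", seq_len(n_cond)), n_mock = n_mock,
                replicates = replicates)
}

test_that("well summaries tally fractions that sum to one", {
  lay <- make_layout2()
  cells <- data.frame(well_id = rep(lay$well_id[1], 10),
                      class = "triangular", ratio = 0.3)
  s <- summarize_wells(cells, lay, min_cells = 5)
  expect_equal(as.numeric(s[1, paste0("p_", shape_classes())]),
               c(0, 0, 1, 0, 0))
  cells2 <- simulate_cell_table(lay, cells_per_well = 80, seed = 2)
  s2 <- summarize_wells(cells2, lay, min_cells = 5)
  sums <- rowSums(s2[, paste0("p_", shape_classes())])
  expect_equal(sums, rep(1, nrow(s2)), tolerance = 1e-9)
  expect_error(summarize_wells(data.frame(well_id = "nope",
                                          class = "fan", ratio = 0),
                               lay), "unknown well")
})

test_that("Z-scores standardise against mock wells", {
  lay <- make_layout2(n_cond = 10, n_mock = 40, replicates = 2)
  cells <- simulate_cell_table(lay, cells_per_well = 100, seed = 7)
  s <- summarize_wells(cells, lay, min_cells = 10)
  z <- zscore_vs_mock(normalize_per_plate(s))
  mock <- z$is_mock & !z$excluded
  for (m in paste0("z_", c(paste0("p_", shape_classes()),
                           "median_ratio"))) {
    expect_gt(mean(z[[m]][mock]), -0.1)
    expect_lt(mean(z[[m]][mock]), 0.1)
    expect_gt(sd(z[[m]][mock]), 0.9)
    expect_lt(sd(z[[m]][mock]), 1.1)
  }
  # exact arithmetic: value = mean + 2 sd -> Z = 2
  v <- s$median_ratio[s$is_mock & !s$excluded]
  s2 <- s
  i <- which(!s2$is_mock)[1]
  s2$median_ratio[i] <- mean(v) + 2 * sd(v)
  z2 <- zscore_vs_mock(s2)
  expect_equal(z2$z_median_ratio[i], 2, tolerance = 1e-9)
  # zero mock SD is an error naming the metric
  s3 <- s
  s3$median_ratio[s3$is_mock] <- 0.5
  expect_error(zscore_vs_mock(s3), "median_ratio")
})

test_that("QMS averaging over replicates behaves as a mean", {
  z <- data.frame(well_id = c("a", "b"), condition = "c1",
                  is_mock = FALSE, excluded = FALSE,
                  z_median_ratio = c(1, 3))
  q <- assemble_qms(z)
  expect_equal(q$z_median_ratio, 2)
  expect_equal(q$n_wells, 2L)
  # permuting rows leaves the QMS unchanged
  q2 <- assemble_qms(z[2:1, ])
  expect_equal(q2$z_median_ratio, q$z_median_ratio)
  # single replicate: QMS equals that well's Z
  q3 <- assemble_qms(z[1, ])
  expect_equal(q3$z_median_ratio, 1)
})

test_that("hit flags reproduce the siDOCK5 replicate worked example", {
  z <- data.frame(well_id = sprintf("w%d", 1:4), condition = "siDOCK5",
                  is_mock = FALSE, excluded = FALSE,
                  z_median_ratio = c(-1.73, -2.33, -2.77, -0.79))
  h <- call_hits(z)
  expect_identical(h$wells$yap_low, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(h$wells$yap_high, rep(FALSE, 4))
})

test_that("hit thresholds are inclusive and null Z yields no hits", {
  z <- data.frame(well_id = c("a", "b"), condition = c("c1", "c2"),
                  is_mock = FALSE, excluded = FALSE,
                  z_median_ratio = c(0, 1.5))
  h <- call_hits(z)
  expect_identical(h$wells$yap_high, c(FALSE, TRUE))
  expect_identical(h$wells$yap_low, c(FALSE, FALSE))
})

test_that("hit flags are invariant to affine rescaling of the metric", {
  lay <- make_layout2(n_cond = 6, n_mock = 12, replicates = 2)
  shifts <- setNames(c(-0.5, 0, 0, 0.5, 0, 0), unique(lay$condition[!lay$is_mock]))
  lay2 <- lay
  lay2$ratio_shift <- ifelse(lay$is_mock, 0, shifts[lay$condition])
  cells <- simulate_cell_table(lay2, cells_per_well = 150, seed = 3)
  s <- summarize_wells(cells, lay2, min_cells = 10)
  flags1 <- call_hits(zscore_vs_mock(s))$wells
  s2 <- s
  for (m in qms_cols <- "median_ratio") s2[[m]] <- 100 + 7 * s2[[m]]
  flags2 <- call_hits(zscore_vs_mock(s2))$wells
  expect_identical(flags1$yap_low, flags2$yap_low)
  expect_identical(flags1$yap_high, flags2$yap_high)
})

test_that("density columns are excluded from mock statistics and hits", {
  lay <- screen_layout(sprintf("c%d", 1:3), n_mock = 10, replicates = 2)
  # force two mock wells onto a density column
  lay$column[1:2] <- 1L
  cells <- simulate_cell_table(lay, cells_per_well = 100, seed = 5)
  # corrupt the excluded wells grossly; mock stats must not move
  cells$ratio[cells$well_id %in% lay$well_id[1:2]] <- 99
  s <- summarize_wells(cells, lay, min_cells = 10)
  expect_true(all(s$excluded[1:2]))
  z <- zscore_vs_mock(s)
  h <- call_hits(z)
  expect_false(any(h$wells$well_id %in% lay$well_id[1:2]))
  mock_z <- z$z_median_ratio[z$is_mock & !z$excluded]
  expect_lt(abs(mean(mock_z)), 0.1)
})
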