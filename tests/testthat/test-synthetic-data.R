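# Synthetic generators: ground truth must be exactly consistent with what
# is rendered, and everything must be a pure function of (parameters, seed).

test_that("degenerate mixture yields a single class and seeds give identical plates", {
  lay <- screen_layout("x", n_mock = 1, replicates = 1)[1, , drop = FALSE]
  lay[paste0("mix_", shape_classes())] <- as.list(c(0, 0, 1, 0, 0))
  spec <- plate_spec(lay, cells_per_field = 12, fields_per_well = 1,
                     image_size = 240, margin = 30, seed = 42)
  p1 <- generate_plate(spec)
  expect_true(all(p1$ground_truth$class == "triangular"))
  p2 <- generate_plate(spec)
  expect_identical(p1$fields[[1]]$images, p2$fields[[1]]$images)
  expect_identical(p1$ground_truth, p2$ground_truth)
  # count conservation: one ground-truth record per rendered cell
  expect_equal(nrow(p1$ground_truth), 12L)
})

test_that("plate spec rejects bad mixtures and overfull fields", {
  lay <- screen_layout("x", n_mock = 1, replicates = 1)[1, , drop = FALSE]
  bad <- lay
  bad[paste0("mix_", shape_classes())] <- as.list(c(0.5, 0.5, 0.5, 0, 0))
  expect_error(plate_spec(bad), "sum to 1")
  neg <- lay
  neg[paste0("mix_", shape_classes())] <-
    as.list(c(-0.2, 0.4, 0.4, 0.2, 0.2))
  expect_error(plate_spec(neg), "non-negative")
  expect_error(plate_spec(lay, cells_per_field = 500, image_size = 128),
               "too small")
})

test_that("class draws stay inside the multinomial 99% envelope", {
  # oracle: per-class 99% binomial envelope at n = 500, p = 0.2
  lo <- qbinom(0.005, 500, 0.2)
  hi <- qbinom(0.995, 500, 0.2)
  lay <- screen_layout("x", n_mock = 1, replicates = 1)[1, , drop = FALSE]
  lay[paste0("mix_", shape_classes())] <- as.list(rep(0.2, 5))
  cells <- simulate_cell_table(lay, cells_per_well = 500, seed = 9)
  counts <- table(factor(cells$class, shape_classes()))
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("noiseless adhesion traces are exactly log-linear and counts conserved", {
  tr <- generate_fa_traces(n_tracks = 50, k_a = 0.1, k_d = 0.05,
                           noise_sd = 0, seed = 4)
  expect_length(tr$tracks, 50L)
  expect_equal(nrow(tr$truth), 50L)
  t1 <- tr$tracks[[1]]
  peak <- tr$truth$peak_frame[1] + 1L
  asm <- seq_len(peak)
  slopes <- diff(log(t1$frames$intensity[asm])) /
    diff(t1$frames$t_min[asm])
  expect_equal(slopes, rep(0.1, length(slopes)), tolerance = 1e-12)
  # k_d = 0: intensity never decreases after the peak
  tr0 <- generate_fa_traces(n_tracks = 5, k_a = 0.2, k_d = 0,
                            noise_sd = 0, seed = 4)
  for (t in tr0$tracks) {
    pk <- which.max(t$frames$intensity)
    expect_true(all(diff(t$frames$intensity[pk:nrow(t$frames)]) >= 0))
  }
})

test_that("invasion stacks place blobs as requested", {
  st <- generate_invasion_stack(c(100, 0, 0), seed = 2)
  cs <- count_cells_per_plane(st)
  expect_equal(cs$planes$count[2:3], c(0L, 0L))
  expect_gt(cs$planes$count[1], 0L)
  expect_equal(st$depth_um, c(0, 30, 60))
})

test_that("abundance generator encodes its ground truth", {
  null_tab <- generate_abundance_table(n_proteins = 100, n_spiked = 10,
                                       delta_log2 = 0, seed = 1)
  expect_equal(sum(null_tab$truth$spiked), 0L)
  exact <- generate_abundance_table(n_proteins = 200, n_spiked = 20,
                                    delta_log2 = 1, noise_sd = 0,
                                    seed = 1)
  lr <- log2_ratio(log2(exact$abundance), exact$meta)
  expect_equal(unname(lr[exact$truth$spiked]), rep(1, 20),
               tolerance = 1e-12)
  expect_equal(unname(lr[!exact$truth$spiked]), rep(0, 180),
               tolerance = 1e-12)
  big <- generate_abundance_table(n_proteins = 2000, n_spiked = 100,
                                  seed = 3)
  expect_equal(nrow(big$abundance), 2000L)
  expect_equal(sum(big$truth$spiked), 100L)
})

test_that("wound assay ground truth matches its parameters", {
  all90 <- generate_wound_assay(n_cells = 50, polarity_bias = 1, seed = 5)
  expect_true(all(all90$cells$true_angle == 90))
  front <- generate_wound_assay(n_cells = 5, front_speed_um_h = 30,
                                hours = 10, seed = 5)$front
  expect_equal(front$position_um[front$time_h == 10] -
                 front$position_um[front$time_h == 0], 300)
  # polarity_bias 0: angle histogram compatible with uniform (chi-square)
  unif <- generate_wound_assay(n_cells = 10000, polarity_bias = 0,
                               seed = 6)
  ct <- table(cut(unif$cells$true_angle, seq(0, 180, by = 18)))
  expect_gt(suppressWarnings(chisq.test(ct)$p.value), 0.01)
  expect_error(generate_wound_assay(polarity_bias = 2), "polarity_bias")
})
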