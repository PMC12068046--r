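# Segmentation, subcellular regions, intensity measurement and features.

test_that("non-touching synthetic cells are segmented one-to-one", {
  lay <- screen_layout("x", n_mock = 1, replicates = 1)[1, , drop = FALSE]
  spec <- plate_spec(lay, cells_per_field = 20, fields_per_well = 1,
                     image_size = 420, margin = 40, seed = 7)
  pl <- generate_plate(spec)
  imgs <- pl$fields[[1]]$images
  field <- segment_cells(imgs$dna, imgs$tubulin)
  expect_equal(nrow(field$meta), 20L)
  expect_equal(sum(field$meta$is_border), 0L)
  # ground-truth correspondence: nucleus centroids within 5 px
  gt <- pl$ground_truth
  for (i in seq_len(nrow(field$meta))) {
    d <- sqrt((gt$nucleus_x - field$meta$x[i])^2 +
                (gt$nucleus_y - field$meta$y[i])^2)
    expect_lt(min(d), 5)
  }
})

test_that("blank and constant fields are handled per contract", {
  blank <- matrix(0.02, 64, 64)
  noise <- matrix(0.02 + abs(rnorm(64 * 64, 0, 1e-4)), 64, 64)
  f <- segment_cells(noise, noise)
  expect_equal(nrow(f$meta), 0L)
  expect_error(segment_cells(blank, blank), "constant image")
})

test_that("watershed splits two overlapping nuclei", {
  dna <- matrix(0.02, 120, 120)
  dna[ellipse_mask(120, 50, 60, 9, 7)] <- 0.5
  dna[ellipse_mask(120, 70, 60, 9, 7)] <- 0.5
  tub <- matrix(0.02, 120, 120)
  tub[disk_mask(120, 60, 60, 35)] <- 0.3
  f <- segment_cells(dna, tub)
  expect_equal(nrow(f$meta), 2L)
})

test_that("ring area matches the analytic annulus", {
  size <- 101L
  nuc <- matrix(0L, size, size)
  nuc[disk_mask(size, 51, 51, 10)] <- 1L
  cells <- matrix(0L, size, size)
  cells[disk_mask(size, 51, 51, 40)] <- 1L
  f <- define_regions(make_field_from_masks(nuc, cells), ring_width = 3L)
  expected <- pi * (13^2 - 10^2)
  expect_equal(f$meta$ring_area, expected, tolerance = 0.15)
  expect_true(f$meta$valid_ratio)
})

test_that("degenerate regions are flagged or rejected", {
  size <- 61L
  m <- matrix(0L, size, size)
  m[disk_mask(size, 31, 31, 15)] <- 1L
  f <- define_regions(make_field_from_masks(m, m))  # nucleus fills cell
  expect_false(f$meta$valid_ratio)
  expect_warning(r <- measure_nc_ratio(matrix(0.5, size, size), f),
                 "empty ring")
  expect_true(is.na(r))
  expect_error(define_regions(make_field_from_masks(m, m),
                              band_width = 0), "band")
})

test_that("nuclear:ring ratio is exact arithmetic on constructed cells", {
  cell <- make_disk_cell(ratio = 1.0)
  expect_equal(unname(measure_nc_ratio(cell$marker, cell$field)), 1.0,
               tolerance = 0.02)
  # uniform marker image: identical region means, log-ratio zero
  cellu <- make_disk_cell()
  uni <- matrix(0.4, 101, 101)
  expect_equal(unname(measure_nc_ratio(uni, cellu$field,
                                       background = 0)), 0)
  # programmed ratio 0.5 recovered within 0.05
  cell5 <- make_disk_cell(ratio = 0.5)
  expect_equal(unname(measure_nc_ratio(cell5$marker, cell5$field)), 0.5,
               tolerance = 0.05)
})

test_that("ratio is invariant to global multiplicative scaling", {
  cell <- make_disk_cell(ratio = 0.7)
  r1 <- measure_nc_ratio(cell$marker, cell$field, background = 0)
  r2 <- measure_nc_ratio(cell$marker * 7.3, cell$field, background = 0)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("morphology features recover closed forms", {
  size <- 101L
  disk <- matrix(0L, size, size); disk[disk_mask(size, 51, 51, 25)] <- 1L
  nuc <- matrix(0L, size, size); nuc[disk_mask(size, 51, 51, 8)] <- 1L
  f <- make_field_from_masks(nuc, disk)
  uni <- matrix(0.3, size, size)
  ft <- extract_features(f, list(ch = uni), pixel_size = 1)
  expect_equal(ft$roundness, 1, tolerance = 0.1)
  expect_true(ft$roundness <= 1.1)
  expect_equal(ft$axial_ratio, 1, tolerance = 0.05)
  # uniform intensity: no second-derivative structure
  expect_equal(ft$ch_ser_ridge, 0, tolerance = 1e-8)
  # 4:1 ellipse of equal area vs disk
  ell <- matrix(0L, size, size)
  ell[ellipse_mask(size, 51, 51, 50, 12.5)] <- 1L
  nuc2 <- matrix(0L, size, size); nuc2[disk_mask(size, 51, 51, 6)] <- 1L
  ft2 <- extract_features(make_field_from_masks(nuc2, ell),
                          list(ch = uni), pixel_size = 1)
  expect_equal(ft2$axial_ratio, 4, tolerance = 0.25)
})

test_that("features are invariant to translation and 90-degree rotation", {
  lay <- screen_layout("x", n_mock = 1, replicates = 1)[1, , drop = FALSE]
  spec <- plate_spec(lay, cells_per_field = 4, fields_per_well = 1,
                     image_size = 220, margin = 60, seed = 3,
                     read_noise_sd = 0, photons = 0)
  pl <- generate_plate(spec)
  imgs <- pl$fields[[1]]$images
  quant <- function(ims) {
    f <- define_regions(segment_cells(ims$dna, ims$tubulin))
    ft <- extract_features(f, ims)
    ft[order(ft$area), -1]
  }
  base <- quant(imgs)
  shifted <- lapply(imgs, function(m) {
    out <- matrix(0.02, nrow(m), ncol(m))
    out[11:nrow(m), 6:ncol(m)] <- m[1:(nrow(m) - 10), 1:(ncol(m) - 5)]
    out
  })
  rot <- lapply(imgs, function(m) t(m)[ncol(m):1, ])
  for (other in list(quant(shifted), quant(rot))) {
    for (j in seq_along(base)) {
      rel <- abs(other[[j]] - base[[j]]) /
        pmax(abs(base[[j]]), 0.05)
      expect_lt(max(rel), 0.01)
    }
  }
})

test_that("membrane band intensity reflects edge enrichment", {
  size <- 101L
  cellm <- disk_mask(size, 51, 51, 30)
  nuc <- matrix(0L, size, size); nuc[disk_mask(size, 51, 51, 10)] <- 1L
  cl <- matrix(0L, size, size); cl[cellm] <- 1L
  f <- define_regions(make_field_from_masks(nuc, cl))
  flat <- matrix(0, size, size); flat[cellm] <- 100
  expect_equal(unname(measure_membrane_intensity(flat, f,
                                                 background = 0)), 100)
  bandm <- cellm & !disk_mask(size, 51, 51, 27)
  inband <- matrix(0, size, size); inband[bandm] <- 500
  expect_equal(unname(measure_membrane_intensity(inband, f,
                                                 background = 0)), 500)
  # edge-enriched vs flat cell: band mean strictly greater
  enriched <- flat; enriched[bandm] <- 400
  expect_gt(measure_membrane_intensity(enriched, f, background = 0),
            measure_membrane_intensity(flat, f, background = 0))
})

test_that("region masks are disjoint and consistent", {
  cell <- make_disk_cell(ratio = 0.3)
  f <- cell$field
  expect_true(all(f$nuclei[f$ring > 0] == 0))
  expect_true(all(f$cells[f$ring > 0] > 0))
  expect_true(all(f$cells[f$band > 0] > 0))
  expect_true(all(f$nuclei[f$cells == 0] == 0))
})
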