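# Adhesion tracking, phase-rate fitting, track filters, effect sizes.

test_that("a static blob yields one track of full length", {
  img0 <- matrix(0, 40, 40)
  blob <- img0; blob[18:24, 18:22] <- 1
  movie <- rep(list(blob), 10)
  tr <- segment_track_adhesions(movie, frame_interval_min = 3)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$frames), 10L)
  expect_equal(tr[[1]]$frames$t_min, seq(0, 27, by = 3))
})

test_that("a one-frame gap splits a track (no gap closing)", {
  img0 <- matrix(0, 40, 40)
  blob <- img0; blob[18:24, 18:22] <- 1
  movie <- c(rep(list(blob), 4), list(img0), rep(list(blob), 4))
  tr <- segment_track_adhesions(movie, frame_interval_min = 1.5)
  expect_length(tr, 2L)
  expect_error(segment_track_adhesions(movie, NULL), "frame interval")
  expect_error(segment_track_adhesions(movie[1:3], 1.5), "5 frames")
})

test_that("synthetic movies are tracked to ground-truth lifetimes", {
  mv <- generate_fa_movie(n_tracks = 50, n_frames = 40, seed = 5)
  tr <- segment_track_adhesions(mv$movie, mv$frame_interval_min)
  expect_length(tr, 50L)
  cent <- t(vapply(tr, function(t) c(mean(t$frames$x),
                                     mean(t$frames$y)), numeric(2)))
  m <- apply(cent, 1, function(p)
    which.min((mv$truth$x - p[1])^2 + (mv$truth$y - p[2])^2))
  expect_equal(sort(m), 1:50)
  lens <- vapply(tr, function(t) nrow(t$frames), integer(1))
  true_lens <- mv$truth$death_frame[m] - mv$truth$birth_frame[m] + 1L
  expect_true(all(abs(lens - true_lens) <= 1))
})

test_that("noiseless exponential tracks are fitted exactly", {
  tz <- generate_fa_traces(n_tracks = 3, k_a = 0.1, k_d = 0.05,
                           noise_sd = 0, seed = 2)
  ft <- fit_phase_rates(tz$tracks[[1]])
  expect_equal(ft$k_a, 0.1, tolerance = 1e-12)
  expect_equal(ft$k_d, 0.05, tolerance = 1e-12)
  expect_equal(ft$assembly_frames, tz$truth$peak_frame[1] + 1L)
  # constant intensity: zero rates, stability phase spans the track
  flat <- tz$tracks[[1]]
  flat$frames$intensity <- 1
  ff <- fit_phase_rates(flat)
  expect_equal(ff$k_a, 0, tolerance = 1e-12)
  expect_equal(ff$k_d, 0, tolerance = 1e-12)
  expect_equal(ff$stability_frames, nrow(flat$frames))
})

test_that("rates at SNR 10 are recovered within 20% median error", {
  tz <- generate_fa_traces(n_tracks = 200, k_a = 0.1, k_d = 0.05,
                           noise_sd = 0.1, seed = 3)
  fits <- lapply(tz$tracks, fit_phase_rates)
  ka <- vapply(fits, function(f) f$k_a, numeric(1))
  kd <- vapply(fits, function(f) f$k_d, numeric(1))
  expect_lte(median(abs(ka - 0.1) / 0.1, na.rm = TRUE), 0.2)
  expect_lte(median(abs(kd - 0.05) / 0.05, na.rm = TRUE), 0.2)
  # unbiased: |median signed error| within 2%
  expect_lte(abs(median((ka - 0.1) / 0.1, na.rm = TRUE)), 0.02)
  expect_lte(abs(median((kd - 0.05) / 0.05, na.rm = TRUE)), 0.02)
})

test_that("track filters apply the published boundary rules", {
  mk <- function(n, ar) {
    df <- data.frame(frame = seq_len(n), t_min = (seq_len(n) - 1) * 1.5,
                     intensity = 1, x = 0, y = 0, axial_ratio = ar,
                     area = 20)
    structure(list(track_id = 1L, frames = df,
                   frame_interval_min = 1.5), class = "fa_track")
  }
  tracks <- list(mk(4, 2), mk(5, 2), mk(10, 3), mk(10, 2.99))
  kept <- filter_tracks(tracks)
  expect_length(kept, 2L)              # 4 frames out; axial ratio 3.0 out
  expect_equal(vapply(kept, function(t) nrow(t$frames), integer(1)),
               c(5L, 10L))
  expect_identical(filter_tracks(kept), kept)   # idempotent
})

test_that("Hedges' g matches an independent formula oracle to 1e-12", {
  oracle_g <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
    (mean(b) - mean(a)) / sp * (1 - 3 / (4 * (na + nb) - 9))
  }
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4)),
               oracle_g(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), 0.5)
    expect_equal(hedges_g(a, b), oracle_g(a, b), tolerance = 1e-12)
  }
  expect_error(hedges_g(c(1, 1, 1), c(1, 1, 1)), "zero pooled variance")
})

test_that("effect-size labels reproduce the published bin assignments", {
  expect_equal(effect_size_label(1.65), "VL")
  expect_equal(effect_size_label(1.28), "VL")
  expect_equal(effect_size_label(0.101), "none")
  expect_equal(effect_size_label(-0.507), "M")
  expect_equal(effect_size_label(0.851), "L")
  expect_equal(effect_size_label(0.375), "S")
})

test_that("g is antisymmetric and affine-equivariant", {
  set.seed(42)
  a <- rnorm(15); b <- rnorm(12, 1)
  expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
  expect_equal(hedges_g(a + 3, b + 3), hedges_g(a, b), tolerance = 1e-12)
  expect_equal(hedges_g(2 * a, 2 * b), hedges_g(a, b), tolerance = 1e-12)
  # widening both spreads shrinks g proportionally around the common mean
  m <- mean(c(a, b))
  expect_equal(hedges_g(m + 2 * (a - m), m + 2 * (b - m)),
               hedges_g(a, b) / 2, tolerance = 0.1)
})

test_that("bootstrap result is internally consistent", {
  set.seed(43)
  a <- rnorm(25); b <- rnorm(25, 1)
  es <- hedges_g_bootstrap(a, b, n_boot = 500, seed = 7)
  expect_lte(es$ci_low, es$g)
  expect_gte(es$ci_high, es$g)
  expect_equal(es$label, effect_size_label(es$g))
  es2 <- hedges_g_bootstrap(a, b, n_boot = 500, seed = 7)
  expect_identical(es[c("g", "ci_low", "ci_high")],
                   es2[c("g", "ci_low", "ci_high")])
  # identical groups: zero pooled variance is an error; near-identical
  # groups give g ~ 0 and label none
  expect_equal(effect_size_label(hedges_g(a, a + rnorm(25, 0, 1e-8))),
               "none")
})

test_that("Mann-Whitney p matches exact enumeration for small groups", {
  set.seed(44)
  for (i in 1:10) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.8)
    p_pkg <- suppressWarnings(wilcox.test(b, a)$p.value)
    expect_equal(p_pkg, mann_whitney_enum(a, b), tolerance = 1e-12)
  }
})
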