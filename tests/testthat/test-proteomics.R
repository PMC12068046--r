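# Within-line scaling, log2 ratios, permutation-FDR differential calls.

test_that("scaling centres proteins and ignores global sample factors", {
  tab <- generate_abundance_table(n_proteins = 50, n_spiked = 5,
                                  delta_log2 = 1, seed = 61)
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  expect_equal(unname(rowMeans(sc)), rep(0, 50), tolerance = 1e-12)
  # multiplying one sample by 4 changes nothing after scaling
  ab2 <- tab$abundance
  ab2[, 2] <- ab2[, 2] * 4
  sc2 <- scale_within_cellline(ab2, tab$meta)
  expect_equal(sc, sc2, tolerance = 1e-9)
  # arbitrary per-sample scale factors are removed entirely, so inputs
  # differing only by such factors scale to identical tables
  fac <- c(0.2, 1, 3, 7, 0.5, 11)
  ab3 <- sweep(tab$abundance, 2, fac, "*")
  expect_equal(scale_within_cellline(ab3, tab$meta), sc,
               tolerance = 1e-9)
  one <- tab$meta[1, , drop = FALSE]
  expect_error(scale_within_cellline(tab$abundance[, 1, drop = FALSE],
                                     one), "fewer than 2")
})

test_that("log2 ratios are exact on constructed tables", {
  meta <- data.frame(sample = c("m1", "m2", "p1", "p2"),
                     cell_line = "lineA",
                     condition = c("mock", "mock", "perturbed",
                                   "perturbed"))
  ab <- matrix(c(4, 4, 8, 8,
                 2, 2, 2, 2), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), meta$sample))
  lr <- log2_ratio(log2(ab), meta)
  expect_equal(unname(lr), c(1, 0))
  bad <- meta; bad$condition <- "mock"
  expect_error(log2_ratio(log2(ab), bad), "lacks a condition")
})

test_that("spiked proteins are recovered and boundaries are strict", {
  tab <- generate_abundance_table(n_proteins = 400, n_spiked = 40,
                                  delta_log2 = 1, n_reps = 3,
                                  noise_sd = 0.2, seed = 62)
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  res <- permutation_fdr_ttest(sc, tab$meta, n_perm = 1000, seed = 1)
  sens <- mean(res$significant[tab$truth$spiked])
  expect_gte(sens, 0.8)
  fpr <- mean(res$significant[!tab$truth$spiked])
  expect_lte(fpr, 0.05)
  # boundary: log2 exactly 0.5 is never selected
  res2 <- res
  res2$log2_ratio[1] <- 0.5
  res2$q_value[1] <- 0
  sel <- select_significant(res2)
  expect_false(res2$protein[1] %in% c(sel$up, sel$down))
  # the worked CTGF-style case: log2 -0.78, q small -> down-set
  res2$log2_ratio[2] <- -0.77695
  res2$q_value[2] <- 0.01
  sel2 <- select_significant(res2)
  expect_true(res2$protein[2] %in% sel2$down)
  expect_length(intersect(sel2$up, sel2$down), 0)
})

test_that("row order does not affect per-protein results", {
  tab <- generate_abundance_table(n_proteins = 120, n_spiked = 12,
                                  delta_log2 = 1, seed = 63)
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  r1 <- permutation_fdr_ttest(sc, tab$meta, n_perm = 500, seed = 5)
  p <- sample(nrow(sc))
  r2 <- permutation_fdr_ttest(sc[p, ], tab$meta, n_perm = 500, seed = 5)
  r2 <- r2[match(r1$protein, r2$protein), ]
  expect_equal(r1$q_value, r2$q_value, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
})

test_that("relabelling mock and perturbed negates ratios and swaps sets", {
  tab <- generate_abundance_table(n_proteins = 150, n_spiked = 15,
                                  delta_log2 = 1, seed = 64)
  meta_sw <- tab$meta
  meta_sw$condition <- ifelse(meta_sw$condition == "mock", "perturbed",
                              "mock")
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  r1 <- permutation_fdr_ttest(sc, tab$meta, n_perm = 500, seed = 2)
  r2 <- permutation_fdr_ttest(sc, meta_sw, n_perm = 500, seed = 2)
  expect_equal(r1$log2_ratio, -r2$log2_ratio, tolerance = 1e-12)
  s1 <- select_significant(r1); s2 <- select_significant(r2)
  expect_setequal(s1$up, s2$down)
  expect_setequal(s1$down, s2$up)
})

test_that("q-values are monotone in |t| and null tables stay quiet", {
  tab <- generate_abundance_table(n_proteins = 300, n_spiked = 0,
                                  delta_log2 = 0, seed = 65)
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  res <- permutation_fdr_ttest(sc, tab$meta, n_perm = 500, seed = 3)
  ord <- order(abs(res$t_stat), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_lte(mean(res$significant), 0.05)
  # BH-on-permutation-p variant also runs
  res_bh <- permutation_fdr_ttest(sc, tab$meta, n_perm = 500, seed = 3,
                                  fdr_method = "bh")
  expect_true(all(res_bh$q_value >= 0 & res_bh$q_value <= 1))
})

test_that("significant-set clustering reuses the phenocluster machinery", {
  tab <- generate_abundance_table(n_proteins = 60, n_spiked = 10,
                                  delta_log2 = 2, noise_sd = 0.1,
                                  seed = 66)
  sc <- scale_within_cellline(tab$abundance, tab$meta)
  res <- permutation_fdr_ttest(sc, tab$meta, n_perm = 500, seed = 4)
  sig <- res$protein[res$significant]
  expect_gte(length(sig), 2)
  m <- sc[sig, , drop = FALSE]
  colnames(m) <- paste0("z_", colnames(m))
  d <- hierarchical_cluster(m)
  expect_s3_class(d, "phenodendro")
  expect_equal(sort(d$labels), sort(sig))
})
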