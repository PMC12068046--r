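# --- differential proteomics: scaling, log2 ratios, permutation FDR --------

#' Scale an abundance table within each cell line
#'
#' Per cell line: log2 transform, per-sample median normalisation (each
#' sample's median is aligned to the cell line's grand median), then
#' per-protein centring within the cell line (so each protein's
#' within-line mean is zero). Differences between conditions are
#' unaffected by the centring.
#'
#' @param abundance strictly positive matrix, proteins x samples.
#' @param meta data.frame with sample, cell_line, condition columns
#'   matching the table's column names.
#' @return Scaled log2 matrix of the same shape.
#' @export
scale_within_cellline <- function(abundance, meta) {
  stopifnot(is.matrix(abundance), all(abundance > 0),
            all(colnames(abundance) %in% meta$sample))
  meta <- meta[match(colnames(abundance), meta$sample), ]
  x <- log2(abundance)
  for (cl in unique(meta$cell_line)) {
    jj <- which(meta$cell_line == cl)
    if (length(jj) < 2L)
      stop("cell line ", cl, " has fewer than 2 samples")
    med <- apply(x[, jj, drop = FALSE], 2L, median)
    x[, jj] <- sweep(x[, jj, drop = FALSE], 2L, med - mean(med), "-")
    x[, jj] <- x[, jj, drop = FALSE] -
      rowMeans(x[, jj, drop = FALSE])
  }
  x
}

#' Per-protein log2 ratio of perturbed versus mock
#'
#' mean log2(perturbed) - mean log2(mock), per protein and cell line.
#'
#' @param scaled log2-scale matrix (e.g. from
#'   \code{\link{scale_within_cellline}}).
#' @param meta sample metadata (sample, cell_line, condition).
#' @return Numeric vector (single cell line) or matrix proteins x cell
#'   lines.
#' @export
log2_ratio <- function(scaled, meta) {
  meta <- meta[match(colnames(scaled), meta$sample), ]
  lines <- unique(meta$cell_line)
  out <- sapply(lines, function(cl) {
    pj <- meta$cell_line == cl & meta$condition == "perturbed"
    mj <- meta$cell_line == cl & meta$condition == "mock"
    if (!any(pj) || !any(mj))
      stop("cell line ", cl, " lacks a condition")
    rowMeans(scaled[, pj, drop = FALSE]) -
      rowMeans(scaled[, mj, drop = FALSE])
  })
  if (length(lines) == 1L) drop(out) else out
}

# Moderated two-sample statistic (Welch, with additive fuzz s0) for a
# matrix given logical group columns.
welch_s0 <- function(x, g1, g2, s0) {
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1L, var)
  v2 <- apply(x[, g2, drop = FALSE], 1L, var)
  se <- sqrt(v1 / n1 + v2 / n2)
  (m2 - m1) / (se + s0)
}

#' Permutation-FDR moderated t-test (SAM-style)
#'
#' Per protein, a Welch t statistic moderated by an additive fuzz s0 is
#' compared against a null distribution generated by permuting the
#' condition labels (all distinct assignments when few, otherwise a
#' seeded random subset). The SAM-style q-value of a protein is the
#' median permuted exceedance count over the observed exceedance count at
#' its |t|, monotonised; \code{fdr_method = "bh"} instead applies
#' Benjamini-Hochberg to per-protein permutation p-values. Significance
#' requires both q below alpha and |log2 ratio| strictly above the cut.
#'
#' @param scaled log2-scale matrix (proteins x samples), one cell line.
#' @param meta sample metadata (sample, condition); >= 2 replicates per
#'   condition.
#' @param n_perm maximum permutations (>= 100).
#' @param s0 additive fuzz on the denominator.
#' @param seed integer seed for permutation sampling.
#' @param alpha FDR threshold.
#' @param log2_cut up/down cut on the log2 ratio (strict inequality).
#' @param fdr_method \code{"sam"} or \code{"bh"}.
#' @return data.frame per protein: log2_ratio, t_stat, q_value,
#'   significant, direction ("up", "down" or "none").
#' @export
permutation_fdr_ttest <- function(scaled, meta, n_perm = 1000L, s0 = 0.1,
                                  seed = 1L, alpha = 0.05,
                                  log2_cut = 0.5,
                                  fdr_method = c("sam", "bh")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(n_perm >= 100L)
  meta <- meta[match(colnames(scaled), meta$sample), ]
  cond <- meta$condition
  stopifnot(all(cond %in% c("mock", "perturbed")),
            sum(cond == "mock") >= 2L, sum(cond == "perturbed") >= 2L)
  n <- length(cond)
  n_pert <- sum(cond == "perturbed")
  all_assign <- combn(n, n_pert)
  if (ncol(all_assign) < 10L)
    stop("fewer than 10 distinct permutations")
  obs <- welch_s0(scaled, cond == "mock", cond == "perturbed", s0)
  lr <- rowMeans(scaled[, cond == "perturbed", drop = FALSE]) -
    rowMeans(scaled[, cond == "mock", drop = FALSE])
  orig <- which(cond == "perturbed")
  keep <- which(apply(all_assign, 2L, function(a)
    !identical(sort(a), sort(orig))))
  perm_idx <- if (length(keep) <= n_perm) keep else
    with_seed(derive_seed(seed, "perm-fdr"), sample(keep, n_perm))
  perm_t <- vapply(perm_idx, function(j) {
    pert <- seq_len(n) %in% all_assign[, j]
    welch_s0(scaled, !pert, pert, s0)
  }, numeric(nrow(scaled)))
  at <- abs(obs)
  if (fdr_method == "sam") {
    ap <- abs(perm_t)
    # observed and median permuted exceedance counts at each |t|
    ord <- order(at, decreasing = TRUE)
    obs_count <- rank(-at, ties.method = "max")
    perm_counts <- vapply(seq_along(at), function(i)
      median(colSums(ap >= at[i])), numeric(1))
    q <- perm_counts / obs_count
    # monotone: q non-increasing in |t|
    q_sorted <- cummax(q[ord])
    q[ord] <- q_sorted
    q <- pmin(q, 1)
  } else {
    p <- vapply(seq_along(at), function(i)
      (1 + sum(abs(perm_t[i, ]) >= at[i])) / (1 + ncol(perm_t)),
      numeric(1))
    q <- p.adjust(p, "BH")
  }
  sig <- q < alpha & abs(lr) > log2_cut
  data.frame(protein = rownames(scaled) %||% seq_len(nrow(scaled)),
             log2_ratio = unname(lr), t_stat = unname(obs),
             q_value = unname(q), significant = unname(sig),
             direction = ifelse(!sig, "none",
                                ifelse(lr > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

#' Select significantly up- and down-regulated proteins
#'
#' up: log2 ratio strictly above the cut and q below alpha; down:
#' strictly below the negative cut and q below alpha. The sets are
#' disjoint by construction.
#'
#' @param results output of \code{\link{permutation_fdr_ttest}}.
#' @param alpha FDR threshold.
#' @param log2_cut log2-ratio cut (strict).
#' @return list with \code{up} and \code{down} protein id vectors.
#' @export
select_significant <- function(results, alpha = 0.05, log2_cut = 0.5) {
  up <- results$protein[results$log2_ratio > log2_cut &
                          results$q_value < alpha]
  down <- results$protein[results$log2_ratio < -log2_cut &
                            results$q_value < alpha]
  list(up = up, down = down)
}
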