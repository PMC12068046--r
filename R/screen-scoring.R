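# --- well aggregation, plate normalisation, Z-scores, QMS, hit calls -------

qms_metrics <- function() {
  c(paste0("p_", shape_classes()), "median_ratio", "normal_fraction")
}

#' Aggregate single-cell results to well summaries
#'
#' Per well: shape fractions over classified (phenotypic, if a normal flag
#' is present) cells, the median log10 nuclear:ring ratio, the normal
#' fraction, and the cell count. Wells on the density-gradient columns and
#' wells with too few cells are flagged excluded and never contribute to
#' mock statistics or hit calls.
#'
#' @param cells per-cell data.frame with columns well_id, class, ratio and
#'   optionally is_normal.
#' @param layout layout data.frame (well_id, condition, is_mock, plate,
#'   column).
#' @param min_cells minimum cells per well; below, the well is excluded.
#' @param density_columns plate columns excluded by design.
#' @return data.frame, one row per layout well: condition, plate, column,
#'   is_mock, n_cells, p_* fractions, median_ratio, normal_fraction,
#'   excluded.
#' @export
summarize_wells <- function(cells, layout, min_cells = 50L,
                            density_columns = c(1L, 2L, 23L, 24L)) {
  stopifnot(all(c("well_id", "class", "ratio") %in% names(cells)))
  unknown <- setdiff(unique(cells$well_id), layout$well_id)
  if (length(unknown))
    stop("cells reference unknown well(s): ",
         paste(head(unknown, 5), collapse = ", "))
  has_normal <- "is_normal" %in% names(cells)
  out <- layout[, intersect(c("well_id", "condition", "plate", "column",
                              "is_mock"), names(layout))]
  cls <- shape_classes()
  frac <- matrix(NA_real_, nrow(out), 5L,
                 dimnames = list(NULL, paste0("p_", cls)))
  out$n_cells <- 0L
  out$median_ratio <- NA_real_
  out$normal_fraction <- NA_real_
  for (i in seq_len(nrow(out))) {
    cw <- cells[cells$well_id == out$well_id[i], , drop = FALSE]
    out$n_cells[i] <- nrow(cw)
    if (nrow(cw) == 0L) next
    out$normal_fraction[i] <- if (has_normal) mean(cw$is_normal) else
      NA_real_
    tallied <- if (has_normal) cw[!cw$is_normal, , drop = FALSE] else cw
    if (nrow(tallied) > 0L)
      frac[i, ] <- as.numeric(table(factor(tallied$class, cls))) /
        nrow(tallied)
    out$median_ratio[i] <- median(cw$ratio, na.rm = TRUE)
  }
  out <- cbind(out, frac)
  out$excluded <- out$column %in% density_columns | out$n_cells < min_cells
  out
}

#' Per-plate normalisation of well metrics
#'
#' Subtracts the per-plate median of mock wells from every metric,
#' removing plate batch shifts before screen-level Z-scoring.
#' \code{method = "none"} disables it.
#'
#' @param summaries well summaries from \code{\link{summarize_wells}}.
#' @param method \code{"mock_median"} or \code{"none"}.
#' @return The summaries with metrics normalised.
#' @export
normalize_per_plate <- function(summaries, method = c("mock_median",
                                                      "none")) {
  method <- match.arg(method)
  if (method == "none") return(summaries)
  for (pl in unique(summaries$plate)) {
    on_plate <- summaries$plate == pl
    ref <- on_plate & summaries$is_mock & !summaries$excluded
    if (!any(ref)) stop("plate ", pl, " has no usable mock wells")
    for (m in qms_metrics()) {
      if (all(is.na(summaries[[m]]))) next
      summaries[[m]][on_plate] <- summaries[[m]][on_plate] -
        median(summaries[[m]][ref], na.rm = TRUE)
    }
  }
  summaries
}

#' Mock-referenced Z-scores per well and metric
#'
#' Z = (value - mean over mock wells) / SD over mock wells, computed per
#' screen after plate normalisation. Excluded wells never enter the mock
#' statistics (their own Z is still reported).
#'
#' @param summaries (plate-normalised) well summaries.
#' @param min_mock minimum usable mock wells required.
#' @return data.frame: well_id, condition, is_mock, excluded plus
#'   z_<metric> columns.
#' @export
zscore_vs_mock <- function(summaries, min_mock = 8L) {
  mock <- summaries$is_mock & !summaries$excluded
  if (sum(mock) < min_mock)
    stop("need at least ", min_mock, " usable mock wells, found ",
         sum(mock))
  out <- summaries[, c("well_id", "condition", "is_mock", "excluded")]
  for (m in qms_metrics()) {
    if (all(is.na(summaries[[m]]))) next
    mu <- mean(summaries[[m]][mock], na.rm = TRUE)
    s <- sd(summaries[[m]][mock], na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("mock SD is zero for metric ", m)
    out[[paste0("z_", m)]] <- (summaries[[m]] - mu) / s
  }
  out
}

#' Assemble per-condition quantitative morphological signatures (QMS)
#'
#' The QMS of a condition is the mean over its non-excluded replicate
#' wells of the per-well Z-scores: one Z per shape class, plus the
#' YAP/TAZ-ratio Z and the normal-fraction Z.
#'
#' @param zscores output of \code{\link{zscore_vs_mock}}.
#' @return data.frame: condition, n_wells, z_* columns.
#' @export
assemble_qms <- function(zscores) {
  keep <- !zscores$excluded
  z <- zscores[keep, , drop = FALSE]
  conds <- unique(z$condition)
  cols <- intersect(paste0("z_", qms_metrics()), names(z))
  out <- data.frame(condition = conds,
                    n_wells = as.integer(table(z$condition)[conds]))
  for (cc in cols)
    out[[cc]] <- as.numeric(tapply(z[[cc]], z$condition, mean,
                                   na.rm = TRUE)[conds])
  out
}

#' Call screen hits from Z-scores
#'
#' Per well (and per condition on the QMS): \code{yap_high} if the ratio
#' Z >= +threshold, \code{yap_low} if <= -threshold (thresholds inclusive),
#' and \code{shape_hit} if the normal-fraction Z is at or below the shape
#' threshold (penetrant depletion of normal cells). Replicate-level counts
#' are attached to the condition table.
#'
#' @param zscores per-well Z table from \code{\link{zscore_vs_mock}}.
#' @param qms per-condition QMS from \code{\link{assemble_qms}}.
#' @param yap_threshold magnitude of the ratio-Z hit threshold.
#' @param shape_threshold normal-fraction Z at or below which a condition
#'   is a shape hit.
#' @return list with \code{wells} (per-well flags) and \code{conditions}
#'   (QMS-level flags plus n_wells_yap_low/high replicate counts).
#' @export
call_hits <- function(zscores, qms = NULL, yap_threshold = 1.5,
                      shape_threshold = -1) {
  w <- zscores[!zscores$excluded, , drop = FALSE]
  w$yap_high <- w$z_median_ratio >= yap_threshold
  w$yap_low <- w$z_median_ratio <= -yap_threshold
  w$shape_hit <- if ("z_normal_fraction" %in% names(w))
    w$z_normal_fraction <= shape_threshold else NA
  out <- list(wells = w)
  if (!is.null(qms)) {
    q <- qms
    q$yap_high <- q$z_median_ratio >= yap_threshold
    q$yap_low <- q$z_median_ratio <= -yap_threshold
    q$shape_hit <- if ("z_normal_fraction" %in% names(q))
      q$z_normal_fraction <= shape_threshold else NA
    q$n_wells_yap_low <- as.integer(tapply(w$yap_low, w$condition,
                                           sum)[q$condition])
    q$n_wells_yap_high <- as.integer(tapply(w$yap_high, w$condition,
                                            sum)[q$condition])
    out$conditions <- q
  }
  out
}
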