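# --- 3D collagen invasion: per-plane counting and invasion index -----------

#' Count cells per z-plane with dual intensity filtering
#'
#' Per plane, nuclei blobs are detected on the smoothed nuclear channel
#' (automatic Otsu threshold unless given) and counted only if both the
#' blob's mean nuclear intensity and its mean GFP intensity exceed the
#' filtering thresholds, so dim debris and decoys are never counted.
#'
#' @param stack list with \code{nuclear} and \code{gfp} (lists of plane
#'   matrices, plane 1 = bottom) and \code{depth_um}.
#' @param nuclear_threshold,gfp_threshold minimum blob mean intensities;
#'   \code{NULL} uses half the robust foreground intensity of the bottom
#'   plane (shared across planes so empty planes stay empty).
#' @param sigma detection smoothing scale (px).
#' @param min_blob_area minimum blob area (px^2).
#' @return Object of class \code{invasion_stack}: data.frame
#'   \code{planes} (depth_um, count) plus the thresholds used.
#' @export
count_cells_per_plane <- function(stack, nuclear_threshold = NULL,
                                  gfp_threshold = NULL, sigma = 2,
                                  min_blob_area = 20L) {
  stopifnot(is.list(stack$nuclear), is.list(stack$gfp),
            length(stack$nuclear) == length(stack$gfp))
  n_planes <- length(stack$nuclear)
  if (n_planes < 2L)
    stop("need at least 2 planes (invasion index undefined)")
  depth <- stack$depth_um %||% ((seq_len(n_planes) - 1) * 30)
  # reference intensities from the bottom plane (always populated in the
  # assay: depth 0 is the plate bottom)
  ref_n <- stats::quantile(stack$nuclear[[1]], 0.999)
  ref_g <- stats::quantile(stack$gfp[[1]], 0.999)
  if (is.null(nuclear_threshold)) nuclear_threshold <- ref_n / 2
  if (is.null(gfp_threshold)) gfp_threshold <- ref_g / 2
  stopifnot(nuclear_threshold >= 0, gfp_threshold >= 0)
  # detection threshold shared across planes: a quarter of the way from
  # the bottom plane's background to its bright-cell reference intensity,
  # with a no-signal guard (no counting when the bottom plane has no
  # contrast above the noise floor)
  bottom <- EBImage::imageData(EBImage::gblur(as_img(stack$nuclear[[1]]),
                                              sigma = sigma))
  med_b <- median(bottom)
  no_signal <- (ref_n - med_b) < 10 * stats::mad(bottom)
  det <- med_b + 0.25 * (ref_n - med_b)
  counts <- integer(n_planes)
  if (no_signal)
    return(structure(list(planes = data.frame(depth_um = depth,
                                              count = counts),
                          nuclear_threshold = as.numeric(nuclear_threshold),
                          gfp_threshold = as.numeric(gfp_threshold)),
                     class = "invasion_stack"))
  for (p in seq_len(n_planes)) {
    img <- EBImage::gblur(as_img(stack$nuclear[[p]]), sigma = sigma)
    mask <- img > det
    lab <- EBImage::bwlabel(mask)
    lmat <- EBImage::imageData(lab)
    storage.mode(lmat) <- "integer"
    nlab <- max(lmat)
    if (nlab == 0L) next
    areas <- label_areas(lmat, nlab)
    nuc_mean <- label_sums(stack$nuclear[[p]], lmat, nlab) /
      pmax(areas, 1L)
    gfp_mean <- label_sums(stack$gfp[[p]], lmat, nlab) / pmax(areas, 1L)
    counts[p] <- sum(areas >= min_blob_area & nuc_mean > nuclear_threshold &
                       gfp_mean > gfp_threshold)
  }
  structure(list(planes = data.frame(depth_um = depth, count = counts),
                 nuclear_threshold = as.numeric(nuclear_threshold),
                 gfp_threshold = as.numeric(gfp_threshold)),
            class = "invasion_stack")
}

#' Invasion index of a z-stack
#'
#' Cells detected above the bottom plane divided by cells in all planes
#' (bottom included): I = sum(counts at depth > 0) / sum(all counts).
#'
#' @param stack an \code{invasion_stack} or a data.frame with depth_um
#'   and count columns.
#' @return Index in [0, 1]; NA with a warning if no cells were detected.
#' @export
invasion_index <- function(stack) {
  planes <- if (inherits(stack, "invasion_stack")) stack$planes else stack
  stopifnot(all(c("depth_um", "count") %in% names(planes)),
            all(planes$count >= 0))
  if (sum(planes$depth_um == 0) != 1L)
    stop("exactly one bottom plane (depth 0) required")
  total <- sum(planes$count)
  if (total == 0) {
    warning("no cells detected in any plane; invasion index undefined")
    return(NA_real_)
  }
  sum(planes$count[planes$depth_um > 0]) / total
}
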