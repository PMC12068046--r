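# --- segmentation and per-cell measurement ---------------------------------
#
# Convention: images are numeric matrices in EBImage orientation (first
# index x, second y); coordinates are 1-based pixel centres, physical scale
# via pixel_size (micrometres/px).

as_img <- function(m) EBImage::Image(m)

# Otsu threshold on the range-normalised image.
auto_threshold <- function(x) {
  x <- EBImage::imageData(x)
  r <- range(x)
  if (diff(r) < 1e-8) stop("constant image: unusable field")
  nx <- (x - r[1]) / diff(r)
  t <- EBImage::otsu(as_img(nx), range = c(0, 1))
  t * diff(r) + r[1]
}

#' Segment single cells from DNA and tubulin channels
#'
#' Nuclei are detected on the smoothed DNA channel by automatic (Otsu on
#' log intensity) thresholding and split by a distance-transform watershed;
#' cell bodies grow from the nuclear seeds over the tubulin channel inside
#' an automatic foreground mask (Voronoi-based seeded propagation). Cells
#' touching the image border are flagged so downstream stages can filter
#' them out.
#'
#' @param dna_img,tubulin_img numeric matrices of identical dimensions.
#' @param params list of tuning parameters: \code{nuc_sigma} (smoothing,
#'   px), \code{min_nucleus_area} (px^2), \code{cell_sigma},
#'   \code{watershed_tolerance}.
#' @return Object of class \code{cell_field}: list with \code{nuclei} and
#'   \code{cells} label matrices (same label per cell), \code{meta}
#'   (cell_id, x, y nucleus centroid, is_border) and \code{dim}. Empty
#'   fields yield zero rows.
#' @export
segment_cells <- function(dna_img, tubulin_img, params = list()) {
  stopifnot(identical(dim(dna_img), dim(tubulin_img)))
  p <- utils::modifyList(list(nuc_sigma = 2, min_nucleus_area = 40,
                              cell_sigma = 2, watershed_tolerance = 2),
                         params)
  if (diff(range(dna_img)) < 1e-8 || diff(range(tubulin_img)) < 1e-8)
    stop("constant image: unusable field")
  dna_s <- EBImage::imageData(EBImage::gblur(as_img(dna_img),
                                             sigma = p$nuc_sigma))
  # noise floor: stained nuclei must rise well above background noise
  floor_thr <- median(dna_s) + 6 * stats::mad(dna_s)
  thr <- tryCatch(max(auto_threshold(dna_s), floor_thr),
                  error = function(e) Inf)
  nmask <- as_img(dna_s > thr)
  nmask <- EBImage::opening(nmask, EBImage::makeBrush(5, "disc"))
  nmask <- EBImage::fillHull(nmask)
  empty <- structure(list(nuclei = matrix(0L, nrow(dna_img), ncol(dna_img)),
                          cells = matrix(0L, nrow(dna_img), ncol(dna_img)),
                          meta = data.frame(cell_id = integer(0),
                                            x = numeric(0), y = numeric(0),
                                            is_border = logical(0)),
                          dim = dim(dna_img)),
                     class = "cell_field")
  if (sum(nmask) == 0) return(empty)
  nseg <- EBImage::watershed(EBImage::distmap(nmask),
                             tolerance = p$watershed_tolerance, ext = 1)
  areas <- label_areas(as.integer(EBImage::imageData(nseg)))
  drop <- which(areas < p$min_nucleus_area)
  if (length(drop)) nseg <- EBImage::rmObjects(nseg, drop, reenumerate = TRUE)
  nlab <- as.integer(max(EBImage::imageData(nseg)))
  if (nlab == 0L) return(empty)
  tub_s <- EBImage::imageData(EBImage::gblur(as_img(tubulin_img),
                                             sigma = p$cell_sigma))
  fg <- as_img(tub_s > max(auto_threshold(tub_s),
                           median(tub_s) + 6 * stats::mad(tub_s)))
  fg <- EBImage::fillHull(EBImage::opening(fg, EBImage::makeBrush(3, "disc")))
  fg <- fg | nseg > 0
  cells <- EBImage::propagate(as_img(tub_s), seeds = nseg, mask = fg)
  nmat <- EBImage::imageData(nseg)
  cmat <- EBImage::imageData(cells)
  storage.mode(nmat) <- storage.mode(cmat) <- "integer"
  border <- sort(unique(c(cmat[1, ], cmat[nrow(cmat), ],
                          cmat[, 1], cmat[, ncol(cmat)])))
  border <- border[border > 0]
  n_area <- label_areas(nmat, nlab)
  cx <- label_sums(row(nmat), nmat, nlab) / n_area
  cy <- label_sums(col(nmat), nmat, nlab) / n_area
  meta <- data.frame(cell_id = seq_len(nlab), x = cx, y = cy,
                     is_border = seq_len(nlab) %in% border)
  structure(list(nuclei = nmat, cells = cmat, meta = meta,
                 dim = dim(dna_img)),
            class = "cell_field")
}

#' Define perinuclear ring and membrane-band regions
#'
#' The ring is the dilation of each nucleus minus the nucleus, clipped to
#' its own cell; the membrane band is the set of cell pixels within
#' \code{band_width} of the cell boundary. Cells whose ring is empty after
#' clipping are flagged invalid for ratio measurement.
#'
#' @param field a \code{cell_field} from \code{\link{segment_cells}}.
#' @param ring_width ring width in px (>= 1).
#' @param band_width membrane band width in px (>= 1).
#' @return The field with \code{ring} and \code{band} label matrices and
#'   meta columns \code{ring_area}, \code{band_area}, \code{valid_ratio}.
#' @export
define_regions <- function(field, ring_width = 4L, band_width = 3L) {
  stopifnot(inherits(field, "cell_field"))
  if (ring_width < 1L) stop("ring_width must be >= 1")
  if (band_width < 1L) stop("band_width must be >= 1 (empty membrane band)")
  nlab <- nrow(field$meta)
  if (nlab == 0L) {
    field$ring <- field$band <- field$nuclei
    return(field)
  }
  brush <- EBImage::makeBrush(2L * as.integer(ring_width) + 1L, "disc")
  dil <- EBImage::imageData(EBImage::dilate(as_img(field$nuclei), brush))
  storage.mode(dil) <- "integer"
  ring <- ifelse(dil == field$cells & field$nuclei == 0L & field$cells > 0L,
                 field$cells, 0L)
  d <- EBImage::imageData(EBImage::distmap(as_img(field$cells > 0L)))
  band <- ifelse(field$cells > 0L & d <= band_width, field$cells, 0L)
  field$ring <- ring
  field$band <- band
  field$meta$ring_area <- label_areas(ring, nlab)
  field$meta$band_area <- label_areas(band, nlab)
  field$meta$valid_ratio <- field$meta$ring_area > 0
  field
}

# Field background: median intensity over non-cell pixels.
field_background <- function(marker_img, field) {
  out <- marker_img[field$cells == 0L]
  if (!length(out)) return(0)
  median(out)
}

#' Measure the log10 nuclear:ring marker ratio per cell
#'
#' Background-subtracted mean marker intensity over the nucleus divided by
#' the mean over the perinuclear ring, on the log10 scale. This is the
#' translocation readout used for YAP/TAZ (and equally FOXO3A) reporters.
#' Cells with empty rings or non-positive region means yield NA with a
#' warning.
#'
#' @param marker_img numeric matrix.
#' @param field a \code{cell_field} with regions defined.
#' @param background \code{"field"} (median of non-cell pixels) or a
#'   numeric value (0 disables subtraction).
#' @return Numeric vector of log10 ratios indexed by cell_id.
#' @export
measure_nc_ratio <- function(marker_img, field, background = "field") {
  stopifnot(inherits(field, "cell_field"), !is.null(field$ring))
  nlab <- nrow(field$meta)
  if (nlab == 0L) return(numeric(0))
  bg <- if (identical(background, "field"))
    field_background(marker_img, field) else as.numeric(background)
  n_area <- label_areas(field$nuclei, nlab)
  nuc_mean <- label_sums(marker_img, field$nuclei, nlab) / n_area - bg
  ring_mean <- label_sums(marker_img, field$ring, nlab) /
    pmax(field$meta$ring_area, 1L) - bg
  bad <- !field$meta$valid_ratio | nuc_mean <= 0 | ring_mean <= 0
  if (any(bad))
    warning(sum(bad), " cell(s) with empty ring or non-positive region ",
            "mean; ratio set to NA")
  out <- log10(nuc_mean / ring_mean)
  out[bad] <- NA_real_
  out
}

#' Measure background-subtracted mean marker intensity in the membrane band
#'
#' @inheritParams measure_nc_ratio
#' @return Numeric vector indexed by cell_id; NA where the band is empty.
#' @export
measure_membrane_intensity <- function(marker_img, field,
                                       background = "field") {
  stopifnot(inherits(field, "cell_field"), !is.null(field$band))
  nlab <- nrow(field$meta)
  if (nlab == 0L) return(numeric(0))
  bg <- if (identical(background, "field"))
    field_background(marker_img, field) else as.numeric(background)
  out <- label_sums(marker_img, field$band, nlab) /
    pmax(field$meta$band_area, 1L) - bg
  out[field$meta$band_area == 0L] <- NA_real_
  out
}
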