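# --- morphology and texture feature extraction -----------------------------

#' Feature-name registry
#'
#' Fixed, ordered list of per-cell features shared by the classifier and
#' scoring stages: whole-cell morphology plus, per channel, the mean
#' intensity and eight second-derivative (SER-style) texture responses.
#'
#' @param channels channel names measured for texture.
#' @return Character vector of feature names (length 10 + 9 per channel).
#' @export
feature_registry <- function(channels = c("dna", "tubulin", "actin",
                                          "yaptaz")) {
  morph <- c("area", "perimeter", "roundness", "length", "width",
             "axial_ratio", "solidity", "protrusions", "nucleus_area",
             "nucleus_offset")
  tex <- c("mean", paste0("ser_", c("spot", "hole", "ridge", "valley",
                                    "saddle", "edge", "bright", "dark")))
  c(morph, as.vector(t(outer(channels, tex, paste, sep = "_"))))
}

# Shift a matrix by (dx, dy) with replicated edges.
shift_mat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dx, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dy, 1L), nc)
  m[ri, ci]
}

# Eight SER-style texture response images from the scale-space Hessian
# (and gradient) of one channel. All responses are >= 0 and vanish on
# uniform images. Formulas are this package's own (vendor texture formulas
# are unpublished): with Hessian eigenvalues lo <= hi,
#   spot   = sqrt(max(-lo,0) * max(-hi,0))   (bright blob)
#   hole   = sqrt(max(lo,0) * max(hi,0))     (dark blob)
#   ridge  = max(-lo,0) - max(-hi,0)         (bright line)
#   valley = max(hi,0) - max(lo,0)           (dark line)
#   saddle = sqrt(max(-lo,0) * max(hi,0))
#   edge   = gradient magnitude
#   bright/dark = positive/negative residual vs a 2*sigma local mean.
ser_responses <- function(img, sigma = 1) {
  # scale-space derivatives: finite differences of the Gaussian-smoothed
  # image (equivalent to Gaussian-derivative filtering at scale sigma)
  s <- EBImage::imageData(EBImage::gblur(as_img(img), sigma = sigma))
  gx <- (shift_mat(s, 1L, 0L) - shift_mat(s, -1L, 0L)) / 2
  gy <- (shift_mat(s, 0L, 1L) - shift_mat(s, 0L, -1L)) / 2
  gxx <- shift_mat(s, 1L, 0L) - 2 * s + shift_mat(s, -1L, 0L)
  gyy <- shift_mat(s, 0L, 1L) - 2 * s + shift_mat(s, 0L, -1L)
  gxy <- (shift_mat(s, 1L, 1L) - shift_mat(s, 1L, -1L) -
            shift_mat(s, -1L, 1L) + shift_mat(s, -1L, -1L)) / 4
  tr <- gxx + gyy
  dd <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
  hi <- (tr + dd) / 2
  lo <- (tr - dd) / 2
  # local mean at 2*sigma, reusing the sigma-smoothed image
  local_mean <- EBImage::imageData(
    EBImage::gblur(as_img(s), sigma = sigma * sqrt(3)))
  list(spot = sqrt(relu(-lo) * relu(-hi)),
       hole = sqrt(relu(lo) * relu(hi)),
       ridge = relu(-lo) - relu(-hi),
       valley = relu(hi) - relu(lo),
       saddle = sqrt(relu(-lo) * relu(hi)),
       edge = sqrt(gx^2 + gy^2),
       bright = relu(img - local_mean),
       dark = relu(local_mean - img))
}

# Convex-hull solidity and concavity-defect count for one contour
# (n x 2 matrix of boundary coordinates).
contour_shape <- function(pts, defect_depth = 3) {
  if (nrow(pts) < 4L) return(c(solidity = 1, protrusions = 0))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  hull_area <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                         c(hull[-1, 1], hull[1, 1]) * hull[, 2])) / 2
  poly_area <- abs(sum(pts[, 1] * c(pts[-1, 2], pts[1, 2]) -
                         c(pts[-1, 1], pts[1, 1]) * pts[, 2])) / 2
  solidity <- if (hull_area > 0) min(poly_area / hull_area, 1) else 1
  # defects: maximal distance from the contour to each hull chord
  h <- sort(h)
  n_def <- 0L
  for (i in seq_along(h)) {
    a <- h[i]; b <- if (i < length(h)) h[i + 1L] else h[1L] + nrow(pts)
    idx <- if (b <= nrow(pts)) seq(a, b) else c(seq(a, nrow(pts)), seq_len(b - nrow(pts)))
    if (length(idx) < 3L) next
    p1 <- pts[a, ]; p2 <- pts[if (b <= nrow(pts)) b else b - nrow(pts), ]
    seg <- p2 - p1
    L <- sqrt(sum(seg^2))
    if (L < 1e-9) next
    d <- abs((pts[idx, 1] - p1[1]) * seg[2] -
               (pts[idx, 2] - p1[2]) * seg[1]) / L
    if (max(d) > defect_depth) n_def <- n_def + 1L
  }
  c(solidity = solidity, protrusions = n_def)
}

#' Extract the morphology and texture feature vector for every cell
#'
#' Morphology (area, perimeter, roundness 4*pi*A/P^2, moment-based length
#' and width, axial ratio, convex-hull solidity, concavity-defect
#' protrusion count, nucleus area and offset) from the masks, plus the
#' per-channel mean intensity and eight SER texture responses (Hessian
#' decomposition at \code{ser_sigma}, energy-normalised over the cell
#' mask). Lengths and areas are in micrometres via \code{pixel_size}.
#'
#' @param field a \code{cell_field} from \code{\link{segment_cells}}.
#' @param channel_imgs named list of channel matrices.
#' @param pixel_size micrometres per pixel.
#' @param ser_sigma texture scale (px).
#' @param defect_depth minimum concavity depth (px) counted as separating
#'   protrusions.
#' @return data.frame: cell_id plus one column per registry feature.
#' @export
extract_features <- function(field, channel_imgs, pixel_size = 0.5,
                             ser_sigma = 1, defect_depth = 3) {
  stopifnot(inherits(field, "cell_field"))
  nlab <- nrow(field$meta)
  reg <- feature_registry(names(channel_imgs))
  if (nlab == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0L, length(reg) + 1L))
    names(out) <- c("cell_id", reg)
    return(out)
  }
  cmat <- field$cells
  nmat <- field$nuclei
  areas <- label_areas(cmat, nlab)
  contours <- EBImage::ocontour(as_img(cmat))
  # perimeter = closed polygonal arc length of the boundary contour
  perim <- vapply(seq_len(nlab), function(i) {
    pts <- contours[[i]]
    if (is.null(pts) || nrow(pts) < 2L) return(4)
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1L), ])^2))
    sum(d)
  }, numeric(1))
  # second moments of the cell mask
  cx <- label_sums(row(cmat), cmat, nlab) / areas
  cy <- label_sums(col(cmat), cmat, nlab) / areas
  mxx <- label_sums(row(cmat)^2, cmat, nlab) / areas - cx^2
  myy <- label_sums(col(cmat)^2, cmat, nlab) / areas - cy^2
  mxy <- label_sums(row(cmat) * col(cmat), cmat, nlab) / areas - cx * cy
  dd <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- pmax((mxx + myy + dd) / 2, 1e-6)
  l2 <- pmax((mxx + myy - dd) / 2, 1e-6)
  len <- 4 * sqrt(l1)
  wid <- 4 * sqrt(l2)
  n_area <- label_areas(nmat, nlab)
  ncx <- label_sums(row(nmat), nmat, nlab) / pmax(n_area, 1L)
  ncy <- label_sums(col(nmat), nmat, nlab) / pmax(n_area, 1L)
  cs <- t(vapply(seq_len(nlab), function(i) {
    pts <- contours[[i]]
    if (is.null(pts)) c(solidity = 1, protrusions = 0)
    else contour_shape(pts, defect_depth)
  }, numeric(2)))
  out <- data.frame(
    cell_id = seq_len(nlab),
    area = areas * pixel_size^2,
    perimeter = perim * pixel_size,
    roundness = 4 * pi * areas / pmax(perim, 1)^2,
    length = len * pixel_size,
    width = wid * pixel_size,
    axial_ratio = len / wid,
    solidity = cs[, "solidity"],
    protrusions = cs[, "protrusions"],
    nucleus_area = n_area * pixel_size^2,
    nucleus_offset = sqrt((cx - ncx)^2 + (cy - ncy)^2) /
      sqrt(pmax(areas, 1)))
  for (ch in names(channel_imgs)) {
    img <- channel_imgs[[ch]]
    resp <- ser_responses(img, ser_sigma)
    ch_mean <- label_sums(img, cmat, nlab) / areas
    energy <- sqrt(label_sums(img^2, cmat, nlab) / areas) + 1e-8
    out[[paste0(ch, "_mean")]] <- ch_mean
    for (rn in names(resp)) {
      out[[paste0(ch, "_ser_", rn)]] <-
        (label_sums(resp[[rn]], cmat, nlab) / areas) / energy
    }
  }
  stopifnot(identical(names(out)[-1], reg))
  out
}
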