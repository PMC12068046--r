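# --- wound-heal polarity: Golgi angles and migration rate ------------------

#' Golgi orientation angle relative to the wound
#'
#' For each cell, the nucleus-to-Golgi vector v is scored against the
#' wound geometry: with unit tangent t along the wound and unit inward
#' normal n (monolayer toward wound), theta = arccos(v . t / |v|) in
#' degrees, so theta = 90 means the Golgi faces the wound directly and
#' 0/180 mean it points along the wound. Cells whose Golgi sits on the
#' far side of the nucleus from the wound (v . n < 0) are flagged
#' off-wound-side and excluded from binning.
#'
#' @param cells data.frame with nucleus_x, nucleus_y, golgi_x, golgi_y.
#' @param wound_line 2 x 2 matrix; rows are two points on the wound edge.
#' @param inward_normal length-2 vector pointing from the monolayer
#'   toward the wound (need not be exactly orthogonal to the line; it is
#'   orthogonalised).
#' @return data.frame: cell_id (if present), angle (degrees in [0, 180],
#'   NA when Golgi and nucleus coincide), wound_side (logical).
#' @export
golgi_angles <- function(cells, wound_line, inward_normal) {
  stopifnot(all(c("nucleus_x", "nucleus_y", "golgi_x", "golgi_y") %in%
                  names(cells)))
  wound_line <- as.matrix(wound_line)
  stopifnot(identical(dim(wound_line), c(2L, 2L)))
  t_vec <- wound_line[2, ] - wound_line[1, ]
  tl <- sqrt(sum(t_vec^2))
  if (tl < 1e-12) stop("degenerate wound line")
  t_hat <- t_vec / tl
  n_raw <- inward_normal - sum(inward_normal * t_hat) * t_hat
  nl <- sqrt(sum(n_raw^2))
  if (nl < 1e-12) stop("inward normal parallel to the wound line")
  n_hat <- n_raw / nl
  vx <- cells$golgi_x - cells$nucleus_x
  vy <- cells$golgi_y - cells$nucleus_y
  vn <- sqrt(vx^2 + vy^2)
  dot_t <- vx * t_hat[1] + vy * t_hat[2]
  dot_n <- vx * n_hat[1] + vy * n_hat[2]
  ang <- acos(pmin(pmax(dot_t / ifelse(vn > 0, vn, NA_real_), -1), 1)) *
    180 / pi
  bad <- vn == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with coincident Golgi and nucleus")
    ang[bad] <- NA_real_
  }
  out <- data.frame(angle = ang, wound_side = dot_n >= 0)
  if (!is.null(cells$cell_id)) out <- cbind(cell_id = cells$cell_id, out)
  out
}

#' Bin Golgi angles into 30-degree orientation bins
#'
#' Bins centred at 0, 30, 60, 90, 120, 150 and 180 degrees; each angle is
#' assigned to the nearest centre with ties going to the lower bin. Only
#' wound-side cells with defined angles are counted; percentages are over
#' the included cells.
#'
#' @param angles output of \code{\link{golgi_angles}} (or a numeric
#'   vector of angles).
#' @return data.frame: bin (centre, degrees), n, percent.
#' @export
bin_angles <- function(angles) {
  if (is.data.frame(angles)) {
    keep <- angles$wound_side & !is.na(angles$angle)
    a <- angles$angle[keep]
  } else a <- angles[!is.na(angles)]
  centres <- seq(0, 180, by = 30)
  idx <- ceiling(a / 30 - 0.5)          # ties to the lower bin
  idx <- pmin(pmax(idx, 0L), 6L)
  n <- as.integer(table(factor(idx, levels = 0:6)))
  data.frame(bin = centres, n = n,
             percent = if (length(a)) 100 * n / length(a) else rep(0, 7L))
}

#' Wound-edge migration rate
#'
#' Least-squares slope of mean wound-edge displacement (micrometres)
#' against time (hours).
#'
#' @param time_h time points (hours), strictly increasing, length >= 3.
#' @param position positions of the wound edge; pixels unless
#'   \code{pixel_size} converts them.
#' @param pixel_size micrometres per position unit (1 if positions are
#'   already in micrometres).
#' @return Rate in micrometres/hour.
#' @export
migration_rate <- function(time_h, position, pixel_size = 1) {
  stopifnot(length(time_h) == length(position), length(time_h) >= 3L)
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  disp <- (position - position[1]) * pixel_size
  unname(coef(lm(disp ~ time_h))[2])
}
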