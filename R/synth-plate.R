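# Parametric archetype geometries. The five classes are defined only
# verbally in the field (spindly = elongated with two protrusions, etc.);
# here each is a polar radius function r(phi) around the cell centre, with
# documented default dimensions (px). Sizes are scaled by a per-cell jitter.
archetype_geometry <- function(class) {
  switch(class,
    spindly = list(
      rmax = 28,
      radius = function(phi, s) {
        a <- 26 * s; b <- 8 * s
        a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
      },
      nucleus = c(a = 9, b = 3.5), offset = 0),
    large_round = list(
      rmax = 23,
      radius = function(phi, s) 20 * s * (1 + 0.05 * cos(2 * phi)),
      nucleus = c(a = 7.5, b = 6.5), offset = 0),
    triangular = list(
      rmax = 20,
      radius = function(phi, s) 18 * s * (0.40 + 0.60 * pmax(cos(3 * phi), 0)),
      nucleus = c(a = 6, b = 5.5), offset = 0),
    fan = list(
      rmax = 22,
      radius = function(phi, s) 19 * s * (0.40 + 0.60 * ((1 + cos(phi)) / 2)^1.5),
      nucleus = c(a = 6, b = 5), offset = 0.25),
    small_round = list(
      rmax = 13,
      radius = function(phi, s) 11 * s,
      nucleus = c(a = 5, b = 4.5), offset = 0),
    stop("unknown shape class: ", class))
}

#' Specify a synthetic screen plate for rendering
#'
#' Couples a well layout (conditions, shape mixtures, ratio shifts) to the
#' imaging geometry of the renderer. Each well is rendered as
#' \code{fields_per_well} multi-channel fields of \code{cells_per_field}
#' cells.
#'
#' @param wells layout data.frame as from \code{\link{screen_layout}}
#'   (well_id, condition, mix_* fractions, ratio_shift, ...).
#' @param cells_per_field cells rendered per field.
#' @param fields_per_well fields per well.
#' @param image_size field side length in pixels.
#' @param pixel_size micrometres per pixel.
#' @param channels channel names rendered per field.
#' @param margin minimum distance (px) from a cell centre to the field
#'   border; lower it to produce border-touching cells.
#' @param ratio_cell_sd per-cell SD of the log10 nuclear:ring ratio.
#' @param photons photon count at unit intensity for Poisson shot noise.
#' @param read_noise_sd additive Gaussian read noise SD.
#' @param blur_sigma optical blur (Gaussian sigma, px).
#' @param seed integer seed.
#' @return Object of class \code{plate_spec}.
#' @export
plate_spec <- function(wells, cells_per_field = 60L, fields_per_well = 1L,
                       image_size = 512L, pixel_size = 0.5,
                       channels = c("dna", "tubulin", "actin", "yaptaz"),
                       margin = 36L, ratio_cell_sd = 0.15,
                       photons = 500, read_noise_sd = 0.005,
                       blur_sigma = 1, seed = 1L) {
  mix_cols <- paste0("mix_", shape_classes())
  stopifnot(is.data.frame(wells), all(c("well_id", "condition") %in%
                                        names(wells)),
            all(mix_cols %in% names(wells)))
  if (anyDuplicated(wells$well_id)) stop("well ids must be unique")
  mix <- as.matrix(wells[, mix_cols])
  if (any(mix < 0)) stop("shape mixtures must be non-negative")
  if (any(abs(rowSums(mix) - 1) > 1e-9))
    stop("shape mixtures must sum to 1")
  if (is.null(wells$ratio_shift)) wells$ratio_shift <- 0
  # grid feasibility: cells are laid out on a jittered grid
  per_side <- ceiling(sqrt(cells_per_field))
  spacing <- (image_size - 2 * margin) / max(per_side - 1, 1)
  if (cells_per_field > 1 && spacing < 40)
    stop("image too small for requested cell count (grid spacing ",
         round(spacing, 1), " px < 40 px)")
  structure(list(wells = wells, cells_per_field = as.integer(cells_per_field),
                 fields_per_well = as.integer(fields_per_well),
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, channels = channels,
                 margin = as.integer(margin), ratio_cell_sd = ratio_cell_sd,
                 photons = photons, read_noise_sd = read_noise_sd,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "plate_spec")
}

# Rasterize one cell into the channel canvases (max-composited). `canv` is
# an environment holding one matrix per channel, modified in place.
render_cell_into <- function(canv, x, y, class, ratio, size_jitter,
                             orient, image_size) {
  g <- archetype_geometry(class)
  R <- ceiling(g$rmax * size_jitter * 1.3) + 2L
  xs <- max(1L, floor(x - R)):min(image_size, ceiling(x + R))
  ys <- max(1L, floor(y - R)):min(image_size, ceiling(y + R))
  dx <- outer(xs - x, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - y)
  rr <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) - orient
  rad <- g$radius(phi, size_jitter)
  cellm <- rr <= rad
  edgem <- cellm & rr >= rad - 2.5
  # nucleus: ellipse aligned with the cell axis, offset along it for fans
  off <- g$offset * g$rmax * size_jitter
  ncx <- x + off * cos(orient); ncy <- y + off * sin(orient)
  ndx <- outer(xs - ncx, rep(1, length(ys)))
  ndy <- outer(rep(1, length(xs)), ys - ncy)
  u <- ndx * cos(orient) + ndy * sin(orient)
  v <- -ndx * sin(orient) + ndy * cos(orient)
  nucm <- (u / g$nucleus["a"])^2 + (v / g$nucleus["b"])^2 <= 1
  nucm <- nucm & cellm
  # marker values sit on top of the 0.02 canvas background so that
  # background-subtracted region means recover the programmed ratio
  bg <- 0.02
  i_ring <- bg + 0.12
  i_nuc <- bg + min(0.12 * 10^ratio, 0.93)
  put <- function(ch, mask, val) {
    idx <- cbind(rep(xs, times = length(ys))[mask],
                 rep(ys, each = length(xs))[mask])
    canv[[ch]][idx] <- pmax(canv[[ch]][idx], val)
  }
  put("dna", nucm, 0.55)
  put("tubulin", cellm, 0.30)
  put("actin", cellm, 0.22)
  put("actin", edgem, 0.45)
  put("yaptaz", cellm, i_ring)
  put("yaptaz", nucm, i_nuc)
  invisible(NULL)
}

apply_camera <- function(img, blur_sigma, photons, read_noise_sd) {
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma)
  img <- pmax(img, 0)
  if (photons > 0)
    img <- matrix(rpois(length(img), as.numeric(img) * photons) / photons,
                  nrow = nrow(img))
  if (read_noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, read_noise_sd), nrow = nrow(img))
  pmax(img, 0)
}

#' Render a synthetic screen plate
#'
#' Renders every field of every well of a \code{\link{plate_spec}}:
#' DNA = filled nuclear ellipses, tubulin/actin = archetype cell bodies
#' (actin edge-enriched), marker channel with per-cell programmed
#' log10(nuclear/ring) ratio; Gaussian optical blur plus Poisson-Gaussian
#' camera noise. Ground truth carries one record per rendered cell.
#'
#' @param spec a \code{\link{plate_spec}}.
#' @return Object of class \code{synthetic_plate}: list with \code{spec},
#'   \code{fields} (per field: well_id, field, named list of channel
#'   matrices) and \code{ground_truth} (well_id, field, cell, x, y, class,
#'   ratio).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  with_seed(spec$seed, {
    base <- class_ratio_baselines()
    n <- spec$cells_per_field
    per_side <- ceiling(sqrt(n))
    lo <- spec$margin
    hi <- spec$image_size - spec$margin
    gx <- seq(lo, hi, length.out = per_side)
    fields <- list(); gt <- list(); k <- 0L
    for (i in seq_len(nrow(spec$wells))) {
      w <- spec$wells[i, ]
      mix <- as.numeric(w[paste0("mix_", shape_classes())])
      total <- n * spec$fields_per_well
      cls_all <- sample(rep(shape_classes(),
                            as.integer(rmultinom(1L, total, mix))))
      for (f in seq_len(spec$fields_per_well)) {
        cls <- cls_all[((f - 1L) * n + 1L):(f * n)]
        canv <- new.env(parent = emptyenv())
        for (ch in spec$channels)
          assign(ch, matrix(0.02, spec$image_size, spec$image_size),
                 envir = canv)
        pos <- expand.grid(x = gx, y = gx)[seq_len(n), ]
        jit <- (hi - lo) / max(per_side - 1, 1) * 0.12
        pos$x <- pos$x + runif(n, -jit, jit)
        pos$y <- pos$y + runif(n, -jit, jit)
        ratio <- base[cls] + w$ratio_shift +
          rnorm(n, 0, spec$ratio_cell_sd)
        sizej <- runif(n, 0.9, 1.1)
        orient <- runif(n, 0, 2 * pi)
        for (ci in seq_len(n)) {
          render_cell_into(canv, pos$x[ci], pos$y[ci], cls[ci],
                           ratio[ci], sizej[ci], orient[ci],
                           spec$image_size)
        }
        canv <- setNames(lapply(spec$channels, function(ch)
          apply_camera(get(ch, envir = canv),
                       blur_sigma = spec$blur_sigma,
                       photons = spec$photons,
                       read_noise_sd = spec$read_noise_sd)),
          spec$channels)
        k <- k + 1L
        fields[[k]] <- list(well_id = w$well_id, field = f, images = canv)
        off <- vapply(seq_len(n), function(ci) {
          g <- archetype_geometry(cls[ci])
          g$offset * g$rmax * sizej[ci]
        }, numeric(1))
        gt[[k]] <- data.frame(well_id = w$well_id, field = f,
                              cell = seq_len(n), x = pos$x, y = pos$y,
                              nucleus_x = pos$x + off * cos(orient),
                              nucleus_y = pos$y + off * sin(orient),
                              class = cls, ratio = as.numeric(ratio),
                              stringsAsFactors = FALSE, row.names = NULL)
      }
    }
    structure(list(spec = spec, fields = fields,
                   ground_truth = do.call(rbind, gt)),
              class = "synthetic_plate")
  })
}

#' Write a rendered plate to disk (TIFF fields + ground-truth CSV)
#'
#' One 16-bit TIFF per field per channel plus \code{ground_truth.csv}.
#'
#' @param plate a \code{synthetic_plate}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "synthetic_plate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fl in plate$fields) {
    for (ch in names(fl$images)) {
      path <- file.path(dir, sprintf("%s_f%02d_%s.tif", fl$well_id,
                                     fl$field, ch))
      write_image_tiff(fl$images[[ch]], path)
    }
  }
  write_table_full(plate$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
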