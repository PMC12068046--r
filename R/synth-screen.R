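#' The five reference shape classes
#'
#' Order is fixed package-wide and used for deterministic tie-breaking:
#' spindly (elongated, two protrusions), large_round (spread, circular),
#' triangular (three protrusions), fan (asymmetric, offset nucleus),
#' small_round (small area, high roundness).
#'
#' @return Character vector of the five class names.
#' @export
shape_classes <- function() {
  c("spindly", "large_round", "triangular", "fan", "small_round")
}

#' Default class baselines for the log10 nuclear:ring marker ratio
#'
#' Each shape archetype carries its own baseline nuclear:ring translocation
#' ratio (dimensionless, log10 units), emulating the observation that marker
#' translocation co-varies with morphology. Values are generator defaults.
#'
#' @return Named numeric vector over \code{shape_classes()}.
#' @export
class_ratio_baselines <- function() {
  c(spindly = 0.15, large_round = 0.05, triangular = 0.30,
    fan = 0.20, small_round = 0.40)
}

#' Build a screen plate layout
#'
#' Constructs a layout table emulating the screen design: conditions arrayed
#' in replicate wells across plates, a set of mock (negative control) wells,
#' and wells on density-gradient columns (1, 2, 23, 24) flagged for
#' exclusion. Shape mixtures default to the mock mixture; per-condition
#' effects are injected via \code{mixture} and \code{ratio_shift}.
#'
#' @param conditions character vector of perturbation labels (excluding mock).
#' @param n_mock number of mock wells per plate.
#' @param replicates replicate wells per condition.
#' @param mock_mixture length-5 non-negative mixture over
#'   \code{shape_classes()}, summing to 1.
#' @param mixtures optional named list of length-5 mixtures per condition.
#' @param ratio_shifts optional named numeric vector of log10 ratio shifts
#'   per condition (mock shift is 0).
#' @param n_columns,n_rows plate geometry used to assign well ids.
#' @param density_columns columns plated at increasing density, excluded
#'   from scoring.
#' @return data.frame with one row per well: well_id, plate, row, column,
#'   condition, is_mock, mix_* fractions, ratio_shift.
#' @export
screen_layout <- function(conditions, n_mock = 8L, replicates = 4L,
                          mock_mixture = c(0.094, 0.009, 0.604, 0.037,
                                           0.255) / 0.999,
                          mixtures = NULL, ratio_shifts = NULL,
                          n_columns = 24L, n_rows = 16L,
                          density_columns = c(1L, 2L, 23L, 24L)) {
  stopifnot(length(mock_mixture) == 5L, all(mock_mixture >= 0),
            abs(sum(mock_mixture) - 1) < 1e-9)
  # interleave mock wells evenly so every plate carries mocks
  cond_labels <- rep(conditions, each = replicates)
  n_wells <- n_mock + length(cond_labels)
  mock_pos <- unique(round(seq(1, n_wells, length.out = max(n_mock, 1))))
  labels <- character(n_wells)
  labels[mock_pos[seq_len(n_mock)]] <- "mock"
  labels[labels == ""] <- cond_labels
  usable <- setdiff(seq_len(n_columns), density_columns)
  cols_needed <- ceiling(n_wells / n_rows)
  n_plates <- ceiling(cols_needed / length(usable))
  slots <- expand.grid(row = seq_len(n_rows), column = usable,
                       plate = seq_len(n_plates))
  stopifnot(nrow(slots) >= n_wells)
  slots <- slots[seq_len(n_wells), , drop = FALSE]
  mix <- matrix(rep(mock_mixture, n_wells), ncol = 5L, byrow = TRUE)
  colnames(mix) <- paste0("mix_", shape_classes())
  shift <- numeric(n_wells)
  for (i in seq_len(n_wells)) {
    cond <- labels[i]
    if (!is.null(mixtures) && cond %in% names(mixtures)) {
      m <- mixtures[[cond]]
      stopifnot(length(m) == 5L, all(m >= 0), abs(sum(m) - 1) < 1e-9)
      mix[i, ] <- m
    }
    if (!is.null(ratio_shifts) && cond %in% names(ratio_shifts))
      shift[i] <- ratio_shifts[[cond]]
  }
  out <- data.frame(
    well_id = sprintf("P%d_%s%02d", slots$plate, LETTERS[slots$row],
                      slots$column),
    plate = slots$plate, row = slots$row, column = slots$column,
    condition = labels, is_mock = labels == "mock",
    stringsAsFactors = FALSE)
  out <- cbind(out, mix)
  out$ratio_shift <- shift
  if (anyDuplicated(out$well_id)) stop("duplicate well ids in layout")
  out
}

#' Simulate a per-cell table for a screen (statistical layer)
#'
#' Draws single-cell shape classes and log10 nuclear:ring marker ratios for
#' every well of a layout, without rendering images. This is the statistical
#' core of the synthetic screen: the image renderer
#' (\code{\link{generate_plate}}) draws pixels from exactly this model.
#' Classes are multinomial in the well's mixture; ratios are normal around
#' the class baseline plus the well's ratio shift plus a per-plate batch
#' shift.
#'
#' @param layout layout from \code{\link{screen_layout}}.
#' @param cells_per_well cells drawn per well (screen default 1000).
#' @param ratio_cell_sd per-cell SD of the log10 ratio (log10 units).
#' @param plate_effect_sd SD of the per-plate additive batch shift applied
#'   to all ratios on a plate.
#' @param seed integer seed; fixed seed gives identical output.
#' @return data.frame with one row per cell: well_id, condition, plate,
#'   column, is_mock, class, ratio.
#' @export
simulate_cell_table <- function(layout, cells_per_well = 1000L,
                                ratio_cell_sd = 0.15,
                                plate_effect_sd = 0.02, seed = 1L) {
  stopifnot(all(paste0("mix_", shape_classes()) %in% names(layout)))
  base <- class_ratio_baselines()
  with_seed(seed, {
    plates <- sort(unique(layout$plate))
    plate_shift <- setNames(rnorm(length(plates), 0, plate_effect_sd),
                            plates)
    res <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      w <- layout[i, ]
      mix <- as.numeric(w[paste0("mix_", shape_classes())])
      counts <- as.integer(rmultinom(1L, cells_per_well, mix))
      cls <- rep(shape_classes(), counts)
      cls <- sample(cls)
      ratio <- base[cls] + w$ratio_shift +
        plate_shift[as.character(w$plate)] +
        rnorm(length(cls), 0, ratio_cell_sd)
      res[[i]] <- data.frame(
        well_id = w$well_id, condition = w$condition, plate = w$plate,
        column = w$column, is_mock = w$is_mock, class = cls,
        ratio = as.numeric(ratio), stringsAsFactors = FALSE,
        row.names = NULL)
    }
    do.call(rbind, res)
  })
}

#' Simulate an abundance table with spiked differential proteins
#'
#' Log-normal protein abundances for a mock and a perturbed group; a chosen
#' set of proteins is shifted by \code{delta_log2} (log2 units) in the
#' perturbed group. Ground truth records the spiked identities and the true
#' effect.
#'
#' @param n_proteins number of proteins (rows).
#' @param n_spiked number of spiked (truly differential) proteins.
#' @param delta_log2 true log2 effect applied to spiked proteins.
#' @param n_reps replicates per condition.
#' @param noise_sd per-measurement SD on the log2 scale.
#' @param n_cell_lines number of cell lines (samples replicated per line).
#' @param seed integer seed.
#' @return list with elements \code{abundance} (strictly positive matrix,
#'   proteins x samples), \code{meta} (sample, cell_line, condition,
#'   replicate), \code{truth} (protein, spiked, delta_log2).
#' @export
generate_abundance_table <- function(n_proteins = 1000L, n_spiked = 50L,
                                     delta_log2 = 1, n_reps = 3L,
                                     noise_sd = 0.2, n_cell_lines = 1L,
                                     seed = 1L) {
  stopifnot(n_spiked <= n_proteins, n_reps >= 1L)
  with_seed(seed, {
    proteins <- sprintf("prot%04d", seq_len(n_proteins))
    spiked <- if (delta_log2 == 0) character(0) else
      sample(proteins, n_spiked)
    meta <- expand.grid(replicate = seq_len(n_reps),
                        condition = c("mock", "perturbed"),
                        cell_line = paste0("line", seq_len(n_cell_lines)),
                        stringsAsFactors = FALSE)
    meta$sample <- sprintf("%s_%s_r%d", meta$cell_line, meta$condition,
                           meta$replicate)
    base_log2 <- rnorm(n_proteins, mean = 20, sd = 2)
    line_off <- setNames(rnorm(n_cell_lines, 0, 0.5),
                         unique(meta$cell_line))
    m <- matrix(0, n_proteins, nrow(meta),
                dimnames = list(proteins, meta$sample))
    for (j in seq_len(nrow(meta))) {
      mu <- base_log2 + line_off[meta$cell_line[j]]
      if (meta$condition[j] == "perturbed")
        mu[proteins %in% spiked] <- mu[proteins %in% spiked] + delta_log2
      m[, j] <- mu + if (noise_sd > 0) rnorm(n_proteins, 0, noise_sd) else 0
    }
    truth <- data.frame(protein = proteins,
                        spiked = proteins %in% spiked,
                        delta_log2 = ifelse(proteins %in% spiked,
                                            delta_log2, 0),
                        stringsAsFactors = FALSE)
    list(abundance = 2^m, meta = meta, truth = truth)
  })
}

#' Simulate a wound-heal assay with Golgi polarity ground truth
#'
#' Cells sit left of a vertical wound line. A fraction \code{polarity_bias}
#' of cells place their Golgi on the inward wound normal from the nucleus
#' (true angle 90 degrees, i.e. facing the wound); the remainder draw a
#' uniform angle in [0, 180]. Wound-front positions recede at a constant
#' speed with optional measurement noise.
#'
#' @param n_cells number of scored cells.
#' @param polarity_bias fraction in [0, 1] of polarised cells.
#' @param front_speed_um_h wound-edge speed (micrometres/hour).
#' @param hours total assay duration (hours).
#' @param dt_h sampling interval for front positions (hours).
#' @param front_noise_sd_um SD of noise on front positions (micrometres).
#' @param golgi_dist_px nucleus-to-Golgi distance (pixels).
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @return list with \code{cells} (nucleus/Golgi coordinates, true angle),
#'   \code{wound_line} (2x2 matrix of endpoints, px),
#'   \code{inward_normal} (unit vector pointing from monolayer into wound),
#'   \code{front} (data.frame time_h, position_um),
#'   \code{pixel_size}.
#' @export
generate_wound_assay <- function(n_cells = 200L, polarity_bias = 0.5,
                                 front_speed_um_h = 20, hours = 10,
                                 dt_h = 0.5, front_noise_sd_um = 0,
                                 golgi_dist_px = 8, pixel_size = 0.5,
                                 seed = 1L) {
  stopifnot(polarity_bias >= 0, polarity_bias <= 1)
  with_seed(seed, {
    wound_x <- 400
    wound_line <- rbind(c(wound_x, 0), c(wound_x, 600))
    t_hat <- c(0, 1)            # along the wound
    n_hat <- c(1, 0)            # inward normal: monolayer (x < wound) -> wound
    nx <- runif(n_cells, 50, wound_x - 30)
    ny <- runif(n_cells, 20, 580)
    polar <- runif(n_cells) < polarity_bias
    theta <- ifelse(polar, 90, runif(n_cells, 0, 180))
    # direction on the wound side: cos(theta)*t_hat + sin(theta)*n_hat
    gx <- nx + golgi_dist_px * (cos(theta * pi / 180) * t_hat[1] +
                                  sin(theta * pi / 180) * n_hat[1])
    gy <- ny + golgi_dist_px * (cos(theta * pi / 180) * t_hat[2] +
                                  sin(theta * pi / 180) * n_hat[2])
    times <- seq(0, hours, by = dt_h)
    pos <- front_speed_um_h * times +
      if (front_noise_sd_um > 0) rnorm(length(times), 0, front_noise_sd_um)
      else 0
    list(cells = data.frame(cell_id = seq_len(n_cells),
                            nucleus_x = nx, nucleus_y = ny,
                            golgi_x = gx, golgi_y = gy,
                            true_angle = theta, polarised = polar),
         wound_line = wound_line, inward_normal = n_hat,
         front = data.frame(time_h = times, position_um = pos),
         pixel_size = pixel_size)
  })
}
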