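# --- run configuration, image I/O and pipeline orchestration ---------------

#' Default run configuration
#'
#' All screen thresholds live in one block with the study defaults:
#' YAP/TAZ ratio hit |Z| >= 1.5, shape hit at normal-fraction Z <= -1,
#' phenocluster cut at uncentered PCC > 0.73, proteomics cuts
#' |log2| > 0.5 at FDR < 0.05, adhesion filters (>= 5 frames, mean axial
#' ratio < 3) and 30-degree Golgi bins.
#'
#' @return Nested named list; see \code{\link{validate_config}} for the
#'   schema.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    plate = list(n_conditions = 6L, n_mock = 8L, replicates = 4L,
                 cells_per_field = 56L, fields_per_well = 1L,
                 image_size = 360L, margin = 32L, pixel_size = 0.5),
    segmentation = list(nuc_sigma = 2, min_nucleus_area = 40,
                        cell_sigma = 2, watershed_tolerance = 2),
    regions = list(ring_width = 4L, band_width = 3L),
    classifier = list(decay = 1e-2, min_per_class = 20L, holdout = 0.2),
    scoring = list(min_cells = 20L, min_mock = 8L,
                   plate_normalization = "mock_median",
                   yap_threshold = 1.5, shape_threshold = -1),
    clustering = list(threshold = 0.73, linkage = "average"),
    fa = list(frame_interval_min = 1.5, min_frames = 5L,
              max_axial_ratio = 3, n_boot = 5000L),
    proteomics = list(n_perm = 1000L, s0 = 0.1, alpha = 0.05,
                      log2_cut = 0.5, fdr_method = "sam"),
    polarity = list(bin_width_deg = 30))
}

#' Validate a run configuration
#'
#' Checks the nested structure against the schema of
#' \code{\link{default_config}}; unknown keys are rejected, missing keys
#' filled with defaults.
#'
#' @param config nested named list.
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check <- function(cfg, ref, path = "") {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(ref)) {
      if (is.list(ref[[k]])) {
        cfg[[k]] <- check(cfg[[k]] %||% list(), ref[[k]],
                          paste0(path, k, "."))
      } else if (is.null(cfg[[k]])) cfg[[k]] <- ref[[k]]
    }
    cfg
  }
  check(config, ref)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Read/write 16-bit TIFF images
#'
#' Images are numeric matrices in [0, 1]; on disk they are 16-bit
#' greyscale TIFF, so a write-read round trip quantises to 1/65535.
#'
#' @param img numeric matrix in [0, 1].
#' @param path file path.
#' @return \code{write_image_tiff}: the path; \code{read_image_tiff}: the
#'   matrix.
#' @export
write_image_tiff <- function(img, path) {
  EBImage::writeImage(as_img(pmin(pmax(img, 0), 1)), path, type = "tiff",
                      bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  EBImage::imageData(EBImage::readImage(path))
}

#' Validate a plate layout table
#'
#' @param layout layout data.frame.
#' @return The layout, invisibly; errors when required columns or mock
#'   wells are missing.
#' @export
validate_layout <- function(layout) {
  need <- c("well_id", "condition", "is_mock", "plate", "column",
            paste0("mix_", shape_classes()))
  missing <- setdiff(need, names(layout))
  if (length(missing))
    stop("layout missing column(s): ", paste(missing, collapse = ", "))
  if (!any(layout$is_mock)) stop("layout has no mock wells")
  if (anyDuplicated(layout$well_id)) stop("duplicate well ids")
  invisible(layout)
}

# Match segmented cells to ground-truth records by nucleus centroid
# (nearest neighbour within max_dist px).
match_ground_truth <- function(meta, gt_field, max_dist = 5) {
  if (nrow(meta) == 0L) return(integer(0))
  gx <- gt_field$nucleus_x %||% gt_field$x
  gy <- gt_field$nucleus_y %||% gt_field$y
  vapply(seq_len(nrow(meta)), function(i) {
    d2 <- (gx - meta$x[i])^2 + (gy - meta$y[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) j else NA_integer_
  }, integer(1))
}

#' Quantify every field of a rendered plate into a single-cell table
#'
#' Segments each field, defines regions, measures the marker ratio and
#' extracts features; border cells are dropped. When ground truth is
#' available cells are matched by nucleus centroid so true classes can
#' supervise classifier training.
#'
#' @param plate a \code{synthetic_plate} (or list of fields with images).
#' @param config validated configuration.
#' @return data.frame: well metadata, measured ratio, features, and (if
#'   ground truth present) true_class.
#' @export
quantify_plate <- function(plate, config = default_config()) {
  config <- validate_config(config)
  res <- vector("list", length(plate$fields))
  for (i in seq_along(plate$fields)) {
    fl <- plate$fields[[i]]
    field <- segment_cells(fl$images$dna, fl$images$tubulin,
                           config$segmentation)
    field <- define_regions(field, config$regions$ring_width,
                            config$regions$band_width)
    if (nrow(field$meta) == 0L) next
    ratio <- suppressWarnings(measure_nc_ratio(fl$images$yaptaz, field))
    feats <- extract_features(field, fl$images,
                              pixel_size = plate$spec$pixel_size %||% 0.5)
    df <- cbind(data.frame(well_id = fl$well_id, field = fl$field,
                           x = field$meta$x, y = field$meta$y,
                           is_border = field$meta$is_border,
                           ratio = ratio), feats[, -1L])
    if (!is.null(plate$ground_truth)) {
      gtf <- plate$ground_truth[plate$ground_truth$well_id == fl$well_id &
                                  plate$ground_truth$field == fl$field, ]
      m <- match_ground_truth(field$meta, gtf)
      df$true_class <- gtf$class[m]
      df$true_ratio <- gtf$ratio[m]
    }
    res[[i]] <- df[!df$is_border, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the synthetic screen pipeline end to end
#'
#' Renders a plate from the configuration (or uses a supplied one),
#' quantifies cells (segment, regions, ratio, features), trains the shape
#' classifier on ground-truth-labelled cells (standing in for manual
#' exemplar annotation), classifies all cells, aggregates wells,
#' normalises per plate, Z-scores against mock, assembles QMS vectors,
#' calls hits and clusters the QMS matrix. All outputs are written to
#' \code{output_dir} (when given) together with a machine-readable run
#' report; re-running with the same configuration and seed reproduces
#' byte-identical files.
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @param output_dir optional output directory.
#' @param plate optional pre-rendered \code{synthetic_plate}.
#' @param layout optional layout (defaults to a generated screen layout
#'   with alternating mixture/ratio effects).
#' @return list with cells, summaries, zscores, qms, hits, clusters,
#'   report (and the trained models).
#' @export
run_screen_pipeline <- function(config = default_config(),
                                output_dir = NULL, plate = NULL,
                                layout = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  report <- list(seed = seed, started = "run",
                 parameters = config)
  if (is.null(plate)) {
    if (is.null(layout)) {
      nc <- config$plate$n_conditions
      conds <- sprintf("cond%02d", seq_len(nc))
      mixtures <- lapply(seq_len(nc), function(i) {
        m <- c(0.094, 0.009, 0.604, 0.037, 0.255) / 0.999
        k <- (i - 1L) %% 5L + 1L
        m[k] <- m[k] + 0.3
        m / sum(m)
      })
      names(mixtures) <- conds
      shifts <- setNames(rep(c(-0.3, 0, 0.3), length.out = nc), conds)
      layout <- screen_layout(conds, n_mock = config$plate$n_mock,
                              replicates = config$plate$replicates,
                              mixtures = mixtures, ratio_shifts = shifts)
    }
    validate_layout(layout)
    spec <- plate_spec(layout,
                       cells_per_field = config$plate$cells_per_field,
                       fields_per_well = config$plate$fields_per_well,
                       image_size = config$plate$image_size,
                       margin = config$plate$margin,
                       pixel_size = config$plate$pixel_size,
                       seed = derive_seed(seed, "plate"))
    plate <- generate_plate(spec)
  }
  layout <- plate$spec$wells
  cells <- quantify_plate(plate, config)
  report$n_cells_segmented <- nrow(cells)
  labelled <- cells[!is.na(cells$true_class) & !is.na(cells$ratio), ]
  model <- train_shape_classifier(
    labelled[, feature_registry(names(plate$fields[[1]]$images))],
    labelled$true_class, seed = derive_seed(seed, "classifier"),
    min_per_class = config$classifier$min_per_class,
    decay = config$classifier$decay,
    holdout = config$classifier$holdout)
  report$classifier_holdout_accuracy <- model$holdout_accuracy
  reg <- feature_registry(names(plate$fields[[1]]$images))
  cells$class <- classify_cells(model, cells[, reg])
  nmodel <- derive_normal_classifier(
    cells[, reg], is_mock = cells$well_id %in%
      layout$well_id[layout$is_mock],
    seed = derive_seed(seed, "normal"))
  cells$is_normal <- filter_normal(cells[, reg], nmodel)$is_normal
  summaries <- summarize_wells(cells, layout,
                               min_cells = config$scoring$min_cells)
  normed <- normalize_per_plate(summaries,
                                config$scoring$plate_normalization)
  zs <- zscore_vs_mock(normed, min_mock = config$scoring$min_mock)
  qms <- assemble_qms(zs)
  hits <- call_hits(zs, qms,
                    yap_threshold = config$scoring$yap_threshold,
                    shape_threshold = config$scoring$shape_threshold)
  qmat <- qms[qms$condition != "mock", ]
  dendro <- if (nrow(qmat) >= 2L)
    hierarchical_cluster(qmat, linkage = config$clustering$linkage)
  else NULL
  clusters <- if (!is.null(dendro))
    cut_phenoclusters(dendro, config$clustering$threshold) else NULL
  report$n_wells <- nrow(summaries)
  report$n_conditions <- nrow(qms)
  report$n_phenoclusters <- if (!is.null(clusters))
    length(unique(clusters$cluster)) else 0L
  out <- list(cells = cells, summaries = summaries, zscores = zs,
              qms = qms, hits = hits, clusters = clusters,
              dendro = dendro, shape_model = model,
              normal_model = nmodel, report = report)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_full(cells, file.path(output_dir, "cell_table.csv"))
    write_table_full(summaries, file.path(output_dir,
                                          "well_summary.csv"))
    write_table_full(zs, file.path(output_dir, "zscores.csv"))
    write_table_full(qms, file.path(output_dir, "qms.csv"))
    write_table_full(hits$wells, file.path(output_dir, "hits_wells.csv"))
    write_table_full(hits$conditions,
                     file.path(output_dir, "hits_conditions.csv"))
    if (!is.null(clusters)) {
      write_table_full(clusters, file.path(output_dir,
                                           "phenoclusters.csv"))
      write_newick(dendro, file.path(output_dir, "dendrogram.nwk"))
    }
    write_model(model, file.path(output_dir, "shape_model.json"))
    jsonlite::write_json(report, file.path(output_dir,
                                           "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
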