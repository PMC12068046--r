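# --- five-shape linear classifier and "normal cell" penetrance filter ------

# Internal: softmax scores for a linear model stored as an intercept+weight
# matrix (classes x (1+p)); ties broken by fixed class order (first wins).
linear_predict <- function(classes, beta, x) {
  scores <- cbind(1, x) %*% t(beta)
  colnames(scores) <- classes
  classes[apply(scores, 1L, which.max)]
}

standardize <- function(x, centre, scale) {
  sweep(sweep(as.matrix(x), 2L, centre, "-"), 2L, pmax(scale, 1e-12), "/")
}

#' Train the five-class linear shape classifier
#'
#' Standardises the feature matrix and fits a multinomial logistic (linear)
#' decision rule with L2 regularisation, emulating a manually trained
#' linear classifier over reference cells of the five shape archetypes.
#' Features derived from the translocation marker channel are excluded by
#' default, mirroring the screen design in which the YAP/TAZ stain never
#' informs the shape call.
#'
#' @param features data.frame or matrix of per-cell features (columns
#'   named per \code{\link{feature_registry}}; a cell_id column is
#'   ignored).
#' @param labels character/factor of shape classes, one per cell; must
#'   cover all five classes of \code{\link{shape_classes}}.
#' @param seed integer seed (hold-out split).
#' @param min_per_class minimum exemplars required per class.
#' @param decay L2 regularisation strength.
#' @param holdout fraction held out (stratified) to report accuracy.
#' @param exclude_pattern regex of feature names excluded from the model
#'   (default: marker-channel features).
#' @return Object of class \code{shape_model}: classes, feature names,
#'   standardisation parameters, weight matrix, held-out accuracy,
#'   exemplar counts.
#' @export
train_shape_classifier <- function(features, labels, seed = 1L,
                                   min_per_class = 20L, decay = 1e-2,
                                   holdout = 0.2,
                                   exclude_pattern = "^yaptaz_") {
  labels <- as.character(labels)
  classes <- shape_classes()
  if (!setequal(unique(labels), classes))
    stop("labels must contain exactly the five classes: ",
         paste(classes, collapse = ", "))
  counts <- table(factor(labels, classes))
  if (any(counts < min_per_class))
    stop("too few exemplars for class(es): ",
         paste(names(counts)[counts < min_per_class], collapse = ", "))
  x <- as.data.frame(features)
  x$cell_id <- NULL
  x <- x[, !grepl(exclude_pattern, names(x)), drop = FALSE]
  x <- as.matrix(x)
  stopifnot(all(is.finite(x)))
  centre <- colMeans(x)
  scale <- apply(x, 2L, sd)
  xs <- standardize(x, centre, scale)
  idx_test <- with_seed(derive_seed(seed, "shape-holdout"), {
    unlist(lapply(classes, function(cl) {
      i <- which(labels == cl)
      sample(i, max(1L, round(length(i) * holdout)))
    }))
  })
  fit_on <- function(rows) {
    df <- data.frame(.class = factor(labels[rows], classes),
                     xs[rows, , drop = FALSE], check.names = FALSE)
    fit <- nnet::multinom(.class ~ ., data = df, decay = decay,
                          trace = FALSE, maxit = 400,
                          MaxNWts = 100000)
    b <- coef(fit)                       # (K-1) x (p+1), baseline = class 1
    rbind(0, as.matrix(b))
  }
  beta_train <- fit_on(setdiff(seq_along(labels), idx_test))
  pred <- linear_predict(classes, beta_train, xs[idx_test, , drop = FALSE])
  acc <- mean(pred == labels[idx_test])
  beta <- fit_on(seq_along(labels))      # final model on all exemplars
  structure(list(classes = classes, feature_names = colnames(x),
                 centre = centre, scale = scale, beta = beta,
                 holdout_accuracy = acc,
                 exemplar_counts = as.integer(counts), seed = seed),
            class = "shape_model")
}

#' Classify cells with a trained shape model
#'
#' @param model a \code{shape_model}.
#' @param features per-cell features sharing the model's feature registry.
#' @return Character vector of class labels, one per cell.
#' @export
classify_cells <- function(model, features) {
  stopifnot(inherits(model, "shape_model"))
  x <- as.data.frame(features)
  x$cell_id <- NULL
  if (!all(model$feature_names %in% names(x)))
    stop("feature registry mismatch: missing ",
         paste(setdiff(model$feature_names, names(x)), collapse = ", "))
  x <- as.matrix(x[, model$feature_names, drop = FALSE])
  xs <- standardize(x, model$centre, model$scale)
  linear_predict(model$classes, model$beta, xs)
}

#' Derive the PCA-based "normal cell" classifier
#'
#' PCA on pooled standardised features of mock cells plus shape-enriched
#' populations; the normal region is the axis-aligned box centred on the
#' mean of (PC1, PC2) with half-width one SD per component, computed on a
#' designated reference population. A binary linear classifier is then
#' trained with mock cells inside the box labelled normal and all other
#' cells not-normal.
#'
#' Which population defines the box is ambiguous in the original
#' procedure; it is exposed as \code{box_population} with default
#' \code{"pooled"}.
#'
#' @param features per-cell feature table (cell_id ignored).
#' @param is_mock logical vector: mock-transfected cells.
#' @param seed integer seed.
#' @param box_population \code{"pooled"}, \code{"mock"} or
#'   \code{"perturbed"}: cells whose PC scores define the box.
#' @param decay L2 regularisation of the binary classifier.
#' @param exclude_pattern features excluded (marker channel by default).
#' @return Object of class \code{normal_model} with PCA loadings for PC1-2,
#'   the box (centre, half-widths), and binary classifier weights.
#' @export
derive_normal_classifier <- function(features, is_mock, seed = 1L,
                                     box_population = c("pooled", "mock",
                                                        "perturbed"),
                                     decay = 1e-2,
                                     exclude_pattern = "^yaptaz_") {
  box_population <- match.arg(box_population)
  x <- as.data.frame(features)
  x$cell_id <- NULL
  x <- as.matrix(x[, !grepl(exclude_pattern, names(x)), drop = FALSE])
  stopifnot(length(is_mock) == nrow(x), all(is.finite(x)))
  centre <- colMeans(x)
  scale <- apply(x, 2L, sd)
  keep <- scale > 1e-12
  xs <- standardize(x[, keep, drop = FALSE], centre[keep], scale[keep])
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  if (ncol(pc$rotation) < 2L) stop("fewer than 2 principal components")
  rot <- pc$rotation[, 1:2, drop = FALSE]
  # sign convention: largest-magnitude loading positive per component
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xs %*% rot
  ref <- switch(box_population, pooled = rep(TRUE, nrow(xs)),
                mock = is_mock, perturbed = !is_mock)
  box_centre <- colMeans(scores[ref, , drop = FALSE])
  box_half <- apply(scores[ref, , drop = FALSE], 2L, sd)
  inside <- abs(scores[, 1] - box_centre[1]) <= box_half[1] &
    abs(scores[, 2] - box_centre[2]) <= box_half[2]
  lab <- factor(ifelse(is_mock & inside, "normal", "not_normal"),
                c("normal", "not_normal"))
  if (length(unique(lab)) < 2L)
    stop("degenerate training set for the normal classifier")
  df <- data.frame(.class = lab, xs, check.names = FALSE)
  fit <- nnet::multinom(.class ~ ., data = df, decay = decay,
                        trace = FALSE, maxit = 400, MaxNWts = 100000)
  beta <- rbind(0, matrix(coef(fit), nrow = 1L))
  structure(list(feature_names = colnames(x)[keep],
                 centre = centre[keep], scale = scale[keep],
                 rotation = rot, box_centre = box_centre,
                 box_half = box_half, beta = beta,
                 box_population = box_population, seed = seed),
            class = "normal_model")
}

#' Partition cells into normal and phenotypic
#'
#' Applies the normal classifier; returns both partitions and the normal
#' fraction, the penetrance readout (depletion of normal cells marks a
#' penetrant shape perturbation).
#'
#' @param features per-cell feature table.
#' @param model a \code{normal_model}.
#' @return list with \code{is_normal} (logical per cell), \code{normal}
#'   and \code{phenotypic} (row indices) and \code{normal_fraction}.
#' @export
filter_normal <- function(features, model) {
  stopifnot(inherits(model, "normal_model"))
  x <- as.data.frame(features)
  x$cell_id <- NULL
  if (nrow(x) == 0L)
    return(list(is_normal = logical(0), normal = integer(0),
                phenotypic = integer(0), normal_fraction = NaN))
  if (!all(model$feature_names %in% names(x)))
    stop("feature registry mismatch")
  xs <- standardize(as.matrix(x[, model$feature_names, drop = FALSE]),
                    model$centre, model$scale)
  lab <- linear_predict(c("normal", "not_normal"), model$beta, xs)
  is_normal <- lab == "normal"
  list(is_normal = is_normal, normal = which(is_normal),
       phenotypic = which(!is_normal),
       normal_fraction = mean(is_normal))
}

#' Serialise / restore shape and normal models (JSON)
#'
#' @param model a \code{shape_model} or \code{normal_model}.
#' @param path file path.
#' @return \code{write_model}: the path, invisibly; \code{read_model}: the
#'   restored model giving identical predictions.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  payload <- unclass(model)
  payload$.class <- cls
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$.class
  p$.class <- NULL
  for (nm in c("beta", "rotation"))
    if (!is.null(p[[nm]])) p[[nm]] <- as.matrix(p[[nm]])
  for (nm in c("centre", "scale", "box_centre", "box_half"))
    if (!is.null(p[[nm]])) p[[nm]] <- unlist(p[[nm]])
  structure(p, class = cls)
}
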