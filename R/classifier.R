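# Three-class nucleus classifier: standardised features into an RBF SVM
# with balanced class weights and pairwise-coupled probability outputs.

#' SVM configuration for the cell classifier
#'
#' @param kernel SVM kernel (default \code{"radial"}).
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF width; \code{NULL} (default) uses
#'   \code{1 / n_features}, i.e. the standard heuristic after
#'   standardisation to unit variance.
#' @param class_weights \code{"balanced"} (default; weights inversely
#'   proportional to class frequency) or a named numeric vector.
#' @param standardise Standardise features to zero mean / unit variance
#'   (default \code{TRUE}); the statistics are stored in the model.
#' @param probability Fit pairwise-coupled class probabilities (default
#'   \code{TRUE}).
#' @param seed RNG seed used during training (probability calibration is
#'   stochastic), making training reproducible.
#' @return List of class \code{"svm_config"}.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL,
                       class_weights = "balanced", standardise = TRUE,
                       probability = TRUE, seed = 1L) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 class_weights = class_weights, standardise = standardise,
                 probability = probability, seed = as.integer(seed)),
            class = "svm_config")
}

feature_matrix <- function(features) {
  x <- features[, setdiff(names(features), "nucleus_id"), drop = FALSE]
  as.matrix(x)
}

#' Train the three-class nucleus SVM
#'
#' @param features Feature table from \code{\link{extract_features}} (the
#'   \code{nucleus_id} column is ignored).
#' @param labels Factor or character vector of cell classes, one per row;
#'   rows with \code{NA} labels are dropped.
#' @param config A \code{\link{svm_config}}.
#' @return Object of class \code{"cell_classifier"}: the fitted SVM plus
#'   the standardisation statistics, feature names, class levels and
#'   config (with a fingerprint for persistence).
#' @export
train_cell_classifier <- function(features, labels, config = svm_config()) {
  x <- feature_matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  bad <- colnames(x)[!apply(x, 2L, function(v) all(is.finite(v)))]
  if (length(bad) > 0L)
    stop(sprintf("non-finite feature values in column(s): %s",
                 paste(bad, collapse = ", ")))
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("training data must contain at least two cell classes")
  if (any(tab < 5L))
    stop(sprintf("need >= 5 examples per class; got %s",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (config$standardise) {
    center <- colMeans(x)
    scale <- apply(x, 2L, sd)
    scale[scale < 1e-12] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  cw <- config$class_weights
  if (identical(cw, "balanced")) {
    cw <- as.numeric(length(labels) / (length(tab) * tab))
    names(cw) <- names(tab)
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  fit <- with_seed(config$seed,
                   e1071::svm(x, labels, kernel = config$kernel,
                              cost = config$cost, gamma = gamma,
                              class.weights = cw, scale = FALSE,
                              probability = config$probability))
  structure(list(svm = fit, center = center, scale = scale,
                 feature_names = colnames(x), classes = levels(labels),
                 config = config,
                 fingerprint = paste0("svm-", config$kernel, "-C",
                                      config$cost, "-g",
                                      signif(gamma, 6), "-seed",
                                      config$seed)),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("cell classifier (%s SVM, C=%g): classes %s; %d support vectors\n",
              x$config$kernel, x$config$cost,
              paste(x$classes, collapse = "/"), x$svm$tot.nSV))
  invisible(x)
}

standardise_features <- function(model, features) {
  x <- feature_matrix(features)
  if (!identical(colnames(x), model$feature_names))
    stop(sprintf("feature mismatch: model expects [%s], got [%s]",
                 paste(model$feature_names, collapse = ","),
                 paste(colnames(x), collapse = ",")))
  sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
}

#' Classify segmented nuclei into a cell map
#'
#' @param model A \code{\link{train_cell_classifier}} result.
#' @param features Feature table for the nuclei to classify.
#' @param segmentation The matching segmentation (for centroids).
#' @return Object of class \code{"cell_map"}: data frame with
#'   \code{nucleus_id}, \code{class}, one \code{score_<class>} probability
#'   column per model class (rows sum to 1 when probability output is
#'   enabled), and centroid \code{x}, \code{y}.
#' @export
classify_cells <- function(model, features, segmentation) {
  stopifnot(inherits(model, "cell_classifier"),
            inherits(segmentation, "nucleus_segmentation"))
  score_cols <- paste0("score_", model$classes)
  if (nrow(features) == 0L) {
    out <- as.data.frame(c(list(nucleus_id = integer(),
                                class = character()),
                           setNames(rep(list(numeric()), length(score_cols)),
                                    score_cols),
                           list(x = numeric(), y = numeric())))
    class(out) <- c("cell_map", "data.frame")
    return(out)
  }
  x <- standardise_features(model, features)
  pr <- predict(model$svm, x, probability = model$config$probability)
  out <- data.frame(nucleus_id = features$nucleus_id,
                    class = as.character(pr),
                    stringsAsFactors = FALSE)
  if (model$config$probability) {
    probs <- attr(pr, "probabilities")[, model$classes, drop = FALSE]
    colnames(probs) <- score_cols
    out <- cbind(out, as.data.frame(probs))
  } else {
    for (sc in score_cols) out[[sc]] <- as.numeric(
      sc == paste0("score_", out$class))
  }
  cent <- segmentation$centroids
  out$x <- cent$x[match(out$nucleus_id, cent$nucleus_id)]
  out$y <- cent$y[match(out$nucleus_id, cent$nucleus_id)]
  rownames(out) <- NULL
  class(out) <- c("cell_map", "data.frame")
  out
}

#' Write a cell map as CSV
#'
#' Columns \code{nucleus_id,class,score_<class>...,x,y}.
#'
#' @param cell_map A \code{\link{classify_cells}} result.
#' @param path Output CSV path.
#' @export
write_cell_map <- function(cell_map, path) {
  stopifnot(inherits(cell_map, "cell_map"))
  write.csv(as.data.frame(cell_map), path, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a trained cell classifier
#'
#' The model is stored with its configuration fingerprint so a restored
#' model can be checked against the expected configuration.
#'
#' @param model A \code{"cell_classifier"}.
#' @param path File path.
#' @export
save_cell_classifier <- function(model, path) {
  stopifnot(inherits(model, "cell_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cell_classifier
#' @export
load_cell_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cell_classifier"))
    stop("file does not contain a cell_classifier")
  model
}
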