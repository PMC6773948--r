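# Two-stage cascade: a healthy-versus-cancer gate (stage 1) followed by a
# continuous 0-100 cellularity regressor (stage 2) applied only to patches
# the gate calls cancerous; gated-healthy patches score exactly 0.
#
# Stage models are desk-scale learners over a fixed patch descriptor
# computed after resizing: stain-concentration histograms (which encode
# area fractions of nuclear and cytoplasmic material) plus a morphological
# granulometry of the nuclear mask (which encodes object size, separating
# small lymphocyte profiles from large malignant ones) and global colour
# statistics. The default family is a random forest; the family is
# pluggable through the config.

#' Cascade configuration
#'
#' @param family Model family for both stages: \code{"rf"} (random forest,
#'   default), \code{"svm"} or \code{"logistic"} (stage 1 only; stage 2
#'   falls back to a random forest).
#' @param resize_px Input patches are resized so the long edge is this
#'   many pixels before the descriptor is computed (default 128).
#' @param threshold Stage-1 decision threshold on the cancer probability,
#'   in (0,1) (default 0.5).
#' @param ntree Trees per forest (default 300).
#' @param seed Integer RNG seed for training.
#' @return List of class \code{"cascade_config"}.
#' @export
cascade_config <- function(family = c("rf", "svm", "logistic"),
                           resize_px = 128L, threshold = 0.5,
                           ntree = 300L, seed = 1L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0,1)")
  structure(list(family = match.arg(family),
                 resize_px = as.integer(resize_px),
                 threshold = threshold, ntree = as.integer(ntree),
                 seed = as.integer(seed)),
            class = "cascade_config")
}

#' Fixed patch descriptor for the cascade stage models
#'
#' Resizes the patch so its long edge is \code{resize_px}, then computes a
#' 42-dimensional descriptor: 16-bin histograms of the raw hematoxylin and
#' eosin concentrations (area fractions of stained material), a
#' morphological granulometry of the nuclear mask (opening with disks of
#' radius 0--3 px; encodes object size), and per-channel colour mean/sd.
#'
#' @param rgb_image RGB patch array, values 0--255.
#' @param resize_px Long-edge size after resizing (default 128).
#' @return Named numeric vector of length 42.
#' @export
patch_descriptor <- function(rgb_image, resize_px = 128L) {
  check_rgb_image(rgb_image)
  d <- dim(rgb_image)
  scale <- resize_px / max(d[1:2])
  if (scale < 1) {
    img <- EBImage::resize(EBImage::Image(rgb_image / 255,
                                          colormode = "Color"),
                           w = max(1L, round(d[1] * scale)),
                           h = max(1L, round(d[2] * scale)))
    arr <- EBImage::imageData(img) * 255
  } else arr <- rgb_image
  od <- -log10(pmax(arr, 1) / 255)
  m <- he_stain_vectors()
  proj <- solve(crossprod(m), t(m))
  hc <- proj[1, 1] * od[, , 1] + proj[1, 2] * od[, , 2] + proj[1, 3] * od[, , 3]
  ec <- proj[2, 1] * od[, , 1] + proj[2, 2] * od[, , 2] + proj[2, 3] * od[, , 3]
  brk <- seq(0, 2, length.out = 17L)
  hist_frac <- function(x) {
    h <- hist(clip(x, 0, 2), breaks = brk, plot = FALSE)
    h$counts / length(x)
  }
  # granulometry: surviving nuclear-mask fraction after opening with
  # growing disks; decay rate encodes object size
  nuc <- hc > 0.3
  open_frac <- vapply(c(0L, 1L, 2L, 3L), function(r) {
    if (r == 0L) return(mean(nuc))
    if (!any(nuc)) return(0)
    k <- disk_kernel(r)
    mean(binary_dilate(binary_erode(nuc, k), k))
  }, numeric(1))
  v <- c(hist_frac(hc), hist_frac(ec), open_frac,
         mean(arr[, , 1]) / 255, sd(arr[, , 1]) / 255,
         mean(arr[, , 2]) / 255, sd(arr[, , 2]) / 255,
         mean(arr[, , 3]) / 255, sd(arr[, , 3]) / 255)
  names(v) <- c(paste0("h_od_", 1:16), paste0("e_od_", 1:16),
                paste0("open_r", 0:3),
                "mean_r", "sd_r", "mean_g", "sd_g", "mean_b", "sd_b")
  v
}

descriptor_names <- function() {
  c(paste0("h_od_", 1:16), paste0("e_od_", 1:16), paste0("open_r", 0:3),
    "mean_r", "sd_r", "mean_g", "sd_g", "mean_b", "sd_b")
}

descriptor_matrix <- function(patches, resize_px) {
  t(vapply(patches, patch_descriptor, numeric(42L), resize_px = resize_px))
}

as_descriptor_matrix <- function(x) {
  x <- rbind(x)
  stopifnot(ncol(x) == 42L)
  colnames(x) <- descriptor_names()
  x
}

check_patch_dims <- function(model, patch) {
  d <- dim(patch)[1:2]
  if (!all(d == model$input_dims))
    stop(sprintf("input size mismatch: model trained on %dx%d, got %dx%d",
                 model$input_dims[1], model$input_dims[2], d[1], d[2]))
}

#' Train the stage-1 healthy-versus-cancer gate
#'
#' @param patches List of RGB patch arrays sharing dimensions.
#' @param labels Factor/character with levels \code{healthy} and
#'   \code{cancerous} (both must be present).
#' @param config A \code{\link{cascade_config}}.
#' @param descriptors Optional precomputed \code{\link{patch_descriptor}}
#'   matrix (one row per patch); memory-light alternative to
#'   \code{patches}, which is then ignored except for \code{input_dims}.
#' @param input_dims Training patch dimensions \code{c(height,width)};
#'   required when only descriptors are supplied.
#' @return Object of class \code{"cascade_stage1"} storing the fitted
#'   model, the descriptor config, the training input dimensions, and the
#'   out-of-bag error trajectory (random-forest family).
#' @export
train_stage1 <- function(patches, labels, config = cascade_config(),
                         descriptors = NULL, input_dims = NULL) {
  labels <- factor(as.character(labels), levels = c("healthy", "cancerous"))
  stopifnot(!anyNA(labels))
  if (length(unique(labels)) < 2L)
    stop("stage-1 training needs both healthy and cancerous examples")
  if (is.null(descriptors)) {
    stopifnot(length(patches) == length(labels))
    dims <- unique(t(vapply(patches, function(p) dim(p)[1:2], integer(2))))
    if (nrow(dims) != 1L) stop("all training patches must share dimensions")
    x <- descriptor_matrix(patches, config$resize_px)
  } else {
    stopifnot(nrow(descriptors) == length(labels), !is.null(input_dims))
    x <- descriptors
    dims <- matrix(as.integer(input_dims), 1L)
  }
  x <- as_descriptor_matrix(x)
  fit <- with_seed(config$seed, switch(
    config$family,
    rf = randomForest::randomForest(x, labels, ntree = config$ntree),
    svm = e1071::svm(x, labels, probability = TRUE),
    logistic = glm.fit(cbind(1, x), as.numeric(labels == "cancerous"),
                       family = binomial())))
  curve <- if (config$family == "rf") fit$err.rate[, "OOB"] else NULL
  structure(list(fit = fit, config = config, input_dims = dims[1, ],
                 oob_curve = curve),
            class = "cascade_stage1")
}

#' Stage-1 cancer probability for one patch
#'
#' @param model A \code{\link{train_stage1}} result.
#' @param patch RGB array with the model's training dimensions.
#' @param descriptor Optional precomputed descriptor vector (skips the
#'   image path and its dimension check).
#' @return Probability in [0,1] that the patch is cancerous.
#' @export
predict_stage1 <- function(model, patch, descriptor = NULL) {
  stopifnot(inherits(model, "cascade_stage1"))
  if (is.null(descriptor)) {
    check_patch_dims(model, patch)
    x <- patch_descriptor(patch, model$config$resize_px)
  } else x <- descriptor
  x <- as_descriptor_matrix(x)
  switch(model$config$family,
         rf = unname(predict(model$fit, x, type = "prob")[, "cancerous"]),
         svm = {
           p <- predict(model$fit, x, probability = TRUE)
           unname(attr(p, "probabilities")[, "cancerous"])
         },
         logistic = {
           eta <- drop(cbind(1, x) %*% model$fit$coefficients)
           unname(1 / (1 + exp(-eta)))
         })
}

#' Train the stage-2 continuous cellularity regressor
#'
#' @param patches List of cancerous RGB patch arrays sharing dimensions.
#' @param labels Continuous TC labels in [0,100]; at least 50 examples are
#'   recommended for the default configuration.
#' @param config A \code{\link{cascade_config}}.
#' @param descriptors,input_dims Memory-light alternative to
#'   \code{patches}, as in \code{\link{train_stage1}}.
#' @return Object of class \code{"cascade_stage2"}.
#' @export
train_stage2 <- function(patches, labels, config = cascade_config(),
                         descriptors = NULL, input_dims = NULL) {
  if (any(labels < 0 | labels > 100))
    stop("stage-2 labels must lie in [0,100]")
  if (length(labels) < 50L)
    warning("fewer than 50 training patches for the default stage-2 config")
  if (is.null(descriptors)) {
    stopifnot(length(patches) == length(labels))
    dims <- unique(t(vapply(patches, function(p) dim(p)[1:2], integer(2))))
    if (nrow(dims) != 1L) stop("all training patches must share dimensions")
    x <- descriptor_matrix(patches, config$resize_px)
  } else {
    stopifnot(nrow(descriptors) == length(labels), !is.null(input_dims))
    x <- descriptors
    dims <- matrix(as.integer(input_dims), 1L)
  }
  x <- as_descriptor_matrix(x)
  fit <- with_seed(config$seed,
                   randomForest::randomForest(x, as.numeric(labels),
                                              ntree = config$ntree))
  structure(list(fit = fit, config = config, input_dims = dims[1, ]),
            class = "cascade_stage2")
}

#' Stage-2 regression score for one patch
#'
#' @param model A \code{\link{train_stage2}} result.
#' @param patch RGB array with the model's training dimensions.
#' @param descriptor Optional precomputed descriptor vector.
#' @return TC prediction clipped to [0,100].
#' @export
predict_stage2 <- function(model, patch, descriptor = NULL) {
  stopifnot(inherits(model, "cascade_stage2"))
  if (is.null(descriptor)) {
    check_patch_dims(model, patch)
    x <- patch_descriptor(patch, model$config$resize_px)
  } else x <- descriptor
  x <- as_descriptor_matrix(x)
  clip(unname(predict(model$fit, x)), 0, 100)
}

#' Predict with the full cascade
#'
#' Stage 1 gates: a cancer probability below the threshold yields a TC of
#' exactly 0 (stage \code{"gated_healthy"}); otherwise stage 2 provides
#' the continuous score (stage \code{"regressed"}).
#'
#' @param stage1,stage2 Trained stage models (compatible input sizes).
#' @param patch RGB patch array.
#' @param threshold Gate threshold in (0,1]; default from the stage-1
#'   config. A threshold of 0 disables the gate.
#' @param descriptor Optional precomputed descriptor vector.
#' @return Object of class \code{"cascade_prediction"}: list with
#'   \code{cancer_prob}, \code{tc} and \code{stage}.
#' @export
predict_cascade <- function(stage1, stage2, patch,
                            threshold = stage1$config$threshold,
                            descriptor = NULL) {
  stopifnot(inherits(stage1, "cascade_stage1"),
            inherits(stage2, "cascade_stage2"))
  if (!all(stage1$input_dims == stage2$input_dims))
    stop("input size mismatch between stage-1 and stage-2 models")
  p <- predict_stage1(stage1, patch, descriptor = descriptor)
  if (p < threshold) {
    out <- list(cancer_prob = p, tc = 0, stage = "gated_healthy")
  } else {
    out <- list(cancer_prob = p,
                tc = predict_stage2(stage2, patch, descriptor = descriptor),
                stage = "regressed")
  }
  structure(out, class = "cascade_prediction")
}

#' @export
print.cascade_prediction <- function(x, ...) {
  cat(sprintf("cascade: p(cancer)=%.3f -> TC %.1f%% (%s)\n",
              x$cancer_prob, x$tc, x$stage))
  invisible(x)
}

#' Combined prediction: stage-1 gate plus hand-engineered scoring
#'
#' Identifies cancerous patches with the stage-1 gate and scores them with
#' the hand-engineered branch; gated-healthy patches score exactly 0.
#'
#' @param stage1 Trained \code{\link{train_stage1}} gate.
#' @param classifier Trained cell classifier for the hand-engineered
#'   branch.
#' @param patch RGB patch array.
#' @param calibration Optional calibration map.
#' @param config Hand-engineered \code{\link{he_config}}.
#' @param threshold Gate threshold (default from the stage-1 config).
#' @param patch_id Optional identifier.
#' @return A \code{\link{tc_score}} with method \code{"combined"} and an
#'   extra \code{stage} field (\code{"gated_healthy"} or
#'   \code{"hand_engineered"}).
#' @export
predict_combined <- function(stage1, classifier, patch, calibration = NULL,
                             config = he_config(),
                             threshold = stage1$config$threshold,
                             patch_id = NA_character_) {
  stopifnot(inherits(stage1, "cascade_stage1"))
  p <- predict_stage1(stage1, patch)
  if (p < threshold) {
    return(tc_score(0, raw_fraction = 0, method = "combined",
                    patch_id = patch_id,
                    extra = list(stage = "gated_healthy", cancer_prob = p)))
  }
  s <- score_patch_hand_engineered(patch, classifier, calibration, config,
                                   patch_id = patch_id, method = "combined")
  s$stage <- "hand_engineered"
  s$cancer_prob <- p
  s
}
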