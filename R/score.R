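# Cellularity scoring: malignant nucleus mask -> cytoplasm dilation ->
# area fraction -> monotone calibration to pathologist-scale percentages.

#' Construct a tumour-cellularity score object
#'
#' @param value Calibrated percentage in [0,100].
#' @param raw_fraction Pre-calibration area fraction in [0,1].
#' @param method One of \code{"hand_engineered"}, \code{"cascade"},
#'   \code{"combined"}, \code{"manual"}.
#' @param patch_id Optional identifier.
#' @param extra Optional named list of provenance fields.
#' @return Object of class \code{"tc_score"}.
#' @export
tc_score <- function(value, raw_fraction = NA_real_,
                     method = c("hand_engineered", "cascade", "combined",
                                "manual"),
                     patch_id = NA_character_, extra = list()) {
  method <- match.arg(method)
  stopifnot(value >= 0, value <= 100,
            is.na(raw_fraction) || (raw_fraction >= 0 && raw_fraction <= 1))
  structure(c(list(value = value, raw_fraction = raw_fraction,
                   method = method, patch_id = patch_id), extra),
            class = "tc_score")
}

#' @export
print.tc_score <- function(x, ...) {
  cat(sprintf("TC score: %.1f%% (%s%s)\n", x$value, x$method,
              if (is.na(x$raw_fraction)) "" else
                sprintf(", raw fraction %.3f", x$raw_fraction)))
  invisible(x)
}

#' Binary mask of pixels belonging to malignant nuclei
#'
#' @param cell_map A \code{\link{classify_cells}} result.
#' @param segmentation The matching segmentation.
#' @param malignant_class Class label counted as malignant (default
#'   \code{"malignant"}). Lymphocytes and benign epithelial nuclei never
#'   contribute, which encodes the exclusion of tumour-infiltrating
#'   lymphocytes from the tumour area.
#' @return Logical matrix of the patch dimensions.
#' @export
malignant_mask <- function(cell_map, segmentation,
                           malignant_class = "malignant") {
  stopifnot(inherits(segmentation, "nucleus_segmentation"))
  ids <- cell_map$nucleus_id[cell_map$class == malignant_class]
  lab <- segmentation$labeled_mask
  if (length(ids) == 0L)
    return(matrix(FALSE, nrow(lab), ncol(lab)))
  matrix(lab %in% ids, nrow(lab), ncol(lab))
}

#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation with a disk structuring element of radius
#' \code{round(radius_um / microns_per_pixel)} pixels, where the disk is
#' the set of offsets with \code{dx^2 + dy^2 <= r^2}. Radius 0 is the
#' identity.
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius_um Dilation radius in micrometres (>= 0).
#' @param microns_per_pixel Physical pixel size.
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, radius_um, microns_per_pixel = 0.5) {
  if (radius_um < 0) stop("dilation radius must be non-negative")
  stopifnot(is.matrix(mask), microns_per_pixel > 0)
  r <- round(radius_um / microns_per_pixel)
  if (r == 0) return(mask > 0)
  binary_dilate(mask > 0, disk_kernel(r))
}

#' Fraction of mask area covered
#'
#' @param mask Logical or 0/1 matrix (non-empty).
#' @return Covered fraction in [0,1]: ones / total pixels.
#' @export
area_fraction <- function(mask) {
  if (length(mask) == 0L) stop("empty mask: area fraction undefined")
  sum(mask > 0) / length(mask)
}

#' Fit a monotone calibration from raw area fractions to manual scores
#'
#' Maps the uncalibrated malignant-area fraction to the pathologist scale.
#' The default isotonic method fits a non-decreasing step function by pool-
#' adjacent-violators and interpolates linearly between the pooled knots;
#' a raw fraction of 0 always maps to 0.
#'
#' @param raw_fractions Numeric in [0,1].
#' @param manual_scores Matching manual TC scores in [0,100]. At least 10
#'   pairs spanning at least 3 distinct manual scores are required.
#' @param method \code{"isotonic"} (default) or \code{"linear"} (least-
#'   squares slope through the origin).
#' @return Object of class \code{"calibration_map"} with a
#'   \code{\link{predict.calibration_map}} method.
#' @export
fit_calibration <- function(raw_fractions, manual_scores,
                            method = c("isotonic", "linear")) {
  method <- match.arg(method)
  stopifnot(length(raw_fractions) == length(manual_scores),
            all(raw_fractions >= 0), all(raw_fractions <= 1),
            all(manual_scores >= 0), all(manual_scores <= 100))
  if (length(raw_fractions) < 10L)
    stop("calibration needs >= 10 paired observations")
  if (length(unique(manual_scores)) < 3L)
    stop("calibration needs >= 3 distinct manual scores")
  if (diff(range(raw_fractions)) < 1e-12)
    stop("constant raw fractions: calibration map is unidentifiable")
  if (method == "isotonic") {
    iso <- isoreg(raw_fractions, manual_scores)
    xo <- iso$x[iso$ord]; yo <- iso$yf
    kx <- unique(xo)
    ky <- vapply(kx, function(v) yo[match(v, xo)], numeric(1))
    if (kx[1] > 0) { kx <- c(0, kx); ky <- c(0, ky) }
    ky[1] <- 0                                   # anchor: 0 maps to 0
    ky <- cummax(ky)
    map <- list(knots_x = kx, knots_y = ky)
  } else {
    slope <- sum(raw_fractions * manual_scores) / sum(raw_fractions^2)
    map <- list(slope = slope)
  }
  structure(c(map, list(method = method, n = length(raw_fractions))),
            class = "calibration_map")
}

#' Apply a fitted calibration map
#'
#' @param object A \code{\link{fit_calibration}} result.
#' @param raw Numeric raw fractions in [0,1].
#' @param ... Unused.
#' @return Calibrated percentages in [0,100]; non-decreasing in \code{raw}
#'   and 0 at \code{raw = 0}.
#' @export
predict.calibration_map <- function(object, raw, ...) {
  stopifnot(all(raw >= 0), all(raw <= 1))
  out <- if (object$method == "isotonic") {
    approx(object$knots_x, object$knots_y, xout = raw, rule = 2,
           ties = "ordered")$y
  } else {
    object$slope * raw
  }
  out[raw == 0] <- 0
  clip(out, 0, 100)
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration map (%s, fitted on %d pairs)\n", x$method, x$n))
  invisible(x)
}

#' Hand-engineered pipeline configuration
#'
#' @param stain_vectors Stain vectors for deconvolution.
#' @param stretch_percentiles Contrast-stretch percentiles.
#' @param segmentation \code{\link{segmentation_params}}.
#' @param dilation_radius_um Cytoplasm dilation radius (default 2.5 um).
#' @param microns_per_pixel Physical pixel size (default 0.5).
#' @param k_neighbours Spatial-feature neighbour count.
#' @param feature_groups Feature groups used by the classifier.
#' @return List of class \code{"he_config"}.
#' @export
he_config <- function(stain_vectors = he_stain_vectors(),
                      stretch_percentiles = c(0.01, 0.99),
                      segmentation = segmentation_params(),
                      dilation_radius_um = 2.5,
                      microns_per_pixel = 0.5,
                      k_neighbours = 5L,
                      feature_groups = c("appearance", "morphology",
                                         "texture", "spatial")) {
  segmentation$microns_per_pixel <- microns_per_pixel
  structure(list(stain_vectors = stain_vectors,
                 stretch_percentiles = stretch_percentiles,
                 segmentation = segmentation,
                 dilation_radius_um = dilation_radius_um,
                 microns_per_pixel = microns_per_pixel,
                 k_neighbours = as.integer(k_neighbours),
                 feature_groups = feature_groups),
            class = "he_config")
}

#' Score a patch with the hand-engineered pipeline
#'
#' Composes stain separation, nucleus segmentation, feature extraction,
#' SVM classification, malignant-mask dilation, area fraction and (when a
#' calibration map is supplied) calibration. Errors raised by a stage are
#' re-signalled with the stage name attached.
#'
#' @param rgb_image Patch array, height x width x 3, values 0--255.
#' @param classifier A trained \code{\link{train_cell_classifier}} model.
#' @param calibration Optional \code{\link{fit_calibration}} map; when
#'   \code{NULL} the score is \code{100 * raw_fraction}.
#' @param config A \code{\link{he_config}}.
#' @param patch_id Optional identifier carried into the score.
#' @param method Provenance tag for the returned score (default
#'   \code{"hand_engineered"}; \code{\link{predict_combined}} passes
#'   \code{"combined"}).
#' @return A \code{\link{tc_score}} with extra fields \code{n_nuclei} and
#'   \code{n_malignant}.
#' @export
score_patch_hand_engineered <- function(rgb_image, classifier,
                                        calibration = NULL,
                                        config = he_config(),
                                        patch_id = NA_character_,
                                        method = "hand_engineered") {
  check_rgb_image(rgb_image)
  sm <- with_stage("separate_stains",
                   separate_stains(rgb_image, config$stain_vectors,
                                   config$stretch_percentiles))
  seg <- with_stage("segment_nuclei",
                    segment_nuclei(sm, config$segmentation))
  if (seg$n == 0L) {
    return(tc_score(0, raw_fraction = 0, method = method,
                    patch_id = patch_id,
                    extra = list(n_nuclei = 0L, n_malignant = 0L)))
  }
  feats <- with_stage("extract_features",
                      extract_features(rgb_image, sm, seg,
                                       microns_per_pixel =
                                         config$microns_per_pixel,
                                       k_neighbours = config$k_neighbours,
                                       groups = config$feature_groups))
  cm <- with_stage("classify_cells", classify_cells(classifier, feats, seg))
  mask <- with_stage("malignant_mask", malignant_mask(cm, seg))
  mask <- with_stage("dilate_mask",
                     dilate_mask(mask, config$dilation_radius_um,
                                 config$microns_per_pixel))
  raw <- with_stage("area_fraction", area_fraction(mask))
  value <- if (is.null(calibration)) 100 * raw else
    with_stage("calibration", predict(calibration, raw))
  tc_score(clip(value, 0, 100), raw_fraction = raw, method = method,
           patch_id = patch_id,
           extra = list(n_nuclei = seg$n,
                        n_malignant = sum(cm$class == "malignant")))
}
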