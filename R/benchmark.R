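# Seeded synthetic benchmarks used to evaluate both scoring routes and
# the confidence-interval calibration of the ICC. Patches are generated,
# processed and discarded one at a time so whole benchmarks fit in modest
# memory.

#' Draw a family of benchmark patch specifications
#'
#' Emulates a patch set hand-selected to span the full cellularity range:
#' a fraction of patches is healthy (no malignant nuclei) and the rest
#' draw a requested malignant count uniformly up to the packing limit, so
#' realised true TC spans roughly 0--86\% (non-overlapping nuclei plus
#' cytoplasm halos saturate near there). Lymphocyte and epithelial counts
#' vary independently.
#'
#' @param n Number of patches.
#' @param seed Integer seed; per-patch sub-seeds are drawn from it.
#' @param size_px Patch edge in pixels (default 512).
#' @param healthy_frac Fraction of healthy patches (default 0.15).
#' @param max_malignant Upper bound of the requested malignant count;
#'   default scales the 512-px value of 400 with patch area.
#' @return List of \code{\link{synthetic_patch_spec}} objects.
#' @export
benchmark_patch_specs <- function(n, seed = 1L, size_px = 512L,
                                  healthy_frac = 0.15,
                                  max_malignant = NULL) {
  area_scale <- (size_px / 512)^2
  if (is.null(max_malignant))
    max_malignant <- max(10L, round(400 * area_scale))
  nl_max <- max(2L, round(30 * area_scale))
  ne_max <- max(2L, round(25 * area_scale))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      healthy <- runif(1) < healthy_frac
      nm <- if (healthy) 0L else sample.int(max_malignant, 1L)
      nl <- sample.int(nl_max, 1L)
      ne <- sample.int(ne_max, 1L)
      synthetic_patch_spec(width_px = size_px, height_px = size_px,
                           n_lymphocyte = nl, n_epithelial = ne,
                           n_malignant = nm,
                           seed = sample.int(.Machine$integer.max, 1L))
    })
  })
}

#' Run the hand-engineered scoring benchmark
#'
#' Trains the cell classifier on nuclei from seeded training patches
#' (ground-truth classes via \code{\link{match_nuclei_to_truth}}), fits
#' the isotonic calibration against simulated pathologist scores of the
#' training patches, then scores an independent seeded test set and
#' compares with the generator's exact cellularity.
#'
#' @param n_train,n_test Training / test patch counts (defaults 40 / 100).
#' @param seed Benchmark seed.
#' @param size_px Patch edge (default 512).
#' @param rater_noise_sd,rounding_step Simulated-pathologist parameters
#'   for the calibration targets (defaults 5 and 5, matching scoring to
#'   the nearest 5\%).
#' @param config Hand-engineered \code{\link{he_config}}.
#' @param progress Print per-patch progress (default \code{FALSE}).
#' @return List: \code{results} (data frame \code{patch_id, truth, score,
#'   raw_fraction}), \code{mae}, \code{icc_vs_truth}
#'   (\code{\link{icc_two_way}} estimate against truth),
#'   \code{binary_accuracy} (healthy-versus-cancer agreement with truth),
#'   \code{classifier}, \code{calibration}.
#' @export
run_he_benchmark <- function(n_train = 40L, n_test = 100L, seed = 1L,
                             size_px = 512L, rater_noise_sd = 5,
                             rounding_step = 5, config = he_config(),
                             progress = FALSE) {
  specs_train <- benchmark_patch_specs(n_train, seed = seed,
                                       size_px = size_px)
  specs_test <- benchmark_patch_specs(n_test, seed = seed + 1L,
                                      size_px = size_px)
  feats <- list(); labs <- list(); cache <- list()
  truth_train <- numeric(n_train)
  for (i in seq_len(n_train)) {
    p <- generate_patch(specs_train[[i]])
    sm <- separate_stains(p$image, config$stain_vectors,
                          config$stretch_percentiles)
    seg <- segment_nuclei(sm, config$segmentation)
    f <- extract_features(p$image, sm, seg,
                          microns_per_pixel = config$microns_per_pixel,
                          k_neighbours = config$k_neighbours,
                          groups = config$feature_groups)
    feats[[i]] <- f
    labs[[i]] <- match_nuclei_to_truth(seg, p$truth)
    cache[[i]] <- list(features = f, labeled_mask = seg$labeled_mask)
    truth_train[i] <- 100 * p$truth$true_tc_fraction
    if (progress) message(sprintf("train patch %d/%d: %d nuclei",
                                  i, n_train, seg$n))
  }
  classifier <- train_cell_classifier(do.call(rbind, feats),
                                      unlist(lapply(labs, as.character)))
  # raw fractions on the training patches with the trained classifier
  raw_train <- vapply(seq_len(n_train), function(i) {
    f <- cache[[i]]$features
    lab <- cache[[i]]$labeled_mask
    if (nrow(f) == 0L) return(0)
    seg_min <- structure(list(labeled_mask = lab, n = nrow(f),
                              centroids = data.frame(
                                nucleus_id = f$nucleus_id,
                                x = NA_real_, y = NA_real_),
                              params = config$segmentation),
                         class = "nucleus_segmentation")
    cm <- classify_cells(classifier, f, seg_min)
    mask <- dilate_mask(malignant_mask(cm, seg_min),
                        config$dilation_radius_um,
                        config$microns_per_pixel)
    area_fraction(mask)
  }, numeric(1))
  manual <- sample_manual_scores(
    data.frame(patch_id = sprintf("train_%03d", seq_len(n_train)),
               true_tc_percent = truth_train),
    rater_noise_sd = rater_noise_sd, rounding_step = rounding_step,
    seed = seed + 2L)
  calibration <- fit_calibration(raw_train, manual$score)

  res <- data.frame(patch_id = sprintf("test_%03d", seq_len(n_test)),
                    truth = NA_real_, score = NA_real_,
                    raw_fraction = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n_test)) {
    p <- generate_patch(specs_test[[i]])
    s <- score_patch_hand_engineered(p$image, classifier, calibration,
                                     config, patch_id = res$patch_id[i])
    res$truth[i] <- 100 * p$truth$true_tc_fraction
    res$score[i] <- s$value
    res$raw_fraction[i] <- s$raw_fraction
    if (progress) message(sprintf("test patch %d/%d: score %.1f truth %.1f",
                                  i, n_test, s$value, res$truth[i]))
  }
  list(results = res,
       mae = mean(abs(res$score - res$truth)),
       icc_vs_truth = icc_two_way(cbind(res$score, res$truth))$estimate,
       binary_accuracy = binary_accuracy(res$score, res$truth),
       classifier = classifier, calibration = calibration)
}

#' Run the cascade benchmark
#'
#' Trains stage 1 on healthy-versus-cancerous labels (healthy iff true TC
#' is exactly 0) and stage 2 on simulated pathologist scores of the
#' cancerous training patches, then evaluates the gated cascade on an
#' independent seeded test set.
#'
#' @param n_train,n_test Training / test patch counts (defaults 400/100).
#' @param seed Benchmark seed.
#' @param size_px Patch edge (default 512).
#' @param config A \code{\link{cascade_config}}.
#' @param rater_noise_sd,rounding_step Simulated-pathologist label
#'   parameters for stage 2 (defaults 5 and 5).
#' @param healthy_frac Healthy fraction of the benchmark family (default
#'   0.25; stage 1 needs a substantial healthy arm).
#' @param progress Print progress (default \code{FALSE}).
#' @return List: \code{results} (data frame \code{patch_id, truth,
#'   cancer_prob, tc, stage}), \code{stage1_accuracy} (held-out gate
#'   accuracy against the true healthy/cancerous split), \code{mae}
#'   (cascade TC versus truth), \code{binary_accuracy}, \code{stage1},
#'   \code{stage2}.
#' @export
run_cascade_benchmark <- function(n_train = 400L, n_test = 100L,
                                  seed = 1L, size_px = 512L,
                                  config = cascade_config(),
                                  rater_noise_sd = 5, rounding_step = 5,
                                  healthy_frac = 0.25,
                                  progress = FALSE) {
  specs_train <- benchmark_patch_specs(n_train, seed = seed,
                                       size_px = size_px,
                                       healthy_frac = healthy_frac)
  specs_test <- benchmark_patch_specs(n_test, seed = seed + 1L,
                                      size_px = size_px,
                                      healthy_frac = healthy_frac)
  desc_train <- matrix(NA_real_, n_train, 42L)
  truth_train <- numeric(n_train)
  for (i in seq_len(n_train)) {
    p <- generate_patch(specs_train[[i]])
    desc_train[i, ] <- patch_descriptor(p$image, config$resize_px)
    truth_train[i] <- 100 * p$truth$true_tc_fraction
    if (progress && i %% 50L == 0L)
      message(sprintf("train descriptor %d/%d", i, n_train))
  }
  colnames(desc_train) <- names(patch_descriptor(
    array(255, c(8L, 8L, 3L)), config$resize_px))
  labels1 <- factor(ifelse(truth_train == 0, "healthy", "cancerous"),
                    levels = c("healthy", "cancerous"))
  stage1 <- train_stage1(NULL, labels1, config,
                         descriptors = desc_train,
                         input_dims = c(size_px, size_px))
  cancerous <- truth_train > 0
  manual <- sample_manual_scores(
    data.frame(patch_id = sprintf("train_%03d", seq_len(n_train)),
               true_tc_percent = truth_train),
    rater_noise_sd = rater_noise_sd, rounding_step = rounding_step,
    seed = seed + 2L)
  stage2 <- train_stage2(NULL, manual$score[cancerous], config,
                         descriptors = desc_train[cancerous, ,
                                                  drop = FALSE],
                         input_dims = c(size_px, size_px))

  res <- data.frame(patch_id = sprintf("test_%03d", seq_len(n_test)),
                    truth = NA_real_, cancer_prob = NA_real_,
                    tc = NA_real_, stage = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_test)) {
    p <- generate_patch(specs_test[[i]])
    d <- patch_descriptor(p$image, config$resize_px)
    pr <- predict_cascade(stage1, stage2, p$image, descriptor = d)
    res$truth[i] <- 100 * p$truth$true_tc_fraction
    res$cancer_prob[i] <- pr$cancer_prob
    res$tc[i] <- pr$tc
    res$stage[i] <- pr$stage
    if (progress && i %% 25L == 0L)
      message(sprintf("test patch %d/%d", i, n_test))
  }
  pred_cancer <- res$cancer_prob >= config$threshold
  list(results = res,
       stage1_accuracy = mean(pred_cancer == (res$truth > 0)),
       mae = mean(abs(res$tc - res$truth)),
       binary_accuracy = binary_accuracy(res$tc, res$truth),
       stage1 = stage1, stage2 = stage2)
}

#' Empirical coverage of the ICC confidence interval
#'
#' Simulates subjects-by-raters score matrices from the bivariate-normal
#' construction with a known intraclass correlation (between-subject
#' variance \code{true_icc}, residual variance \code{1 - true_icc}, no
#' rater effect) and reports how often the interval covers the truth.
#'
#' @param n_sims Number of simulated matrices (default 500).
#' @param true_icc True intraclass correlation (default 0.8).
#' @param n_subjects,k_raters Matrix dimensions (defaults 30 x 2).
#' @param conf_level Interval level (default 0.95).
#' @param variant ICC variant (default \code{"agreement"}).
#' @param seed Integer seed.
#' @return List with \code{coverage} (fraction of intervals containing
#'   \code{true_icc}) and \code{n_sims}.
#' @export
run_icc_coverage <- function(n_sims = 500L, true_icc = 0.8,
                             n_subjects = 30L, k_raters = 2L,
                             conf_level = 0.95, variant = "agreement",
                             seed = 1L) {
  stopifnot(true_icc > 0, true_icc < 1)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_sims)) {
      subj <- rnorm(n_subjects, 0, sqrt(true_icc))
      m <- subj + matrix(rnorm(n_subjects * k_raters, 0,
                               sqrt(1 - true_icc)),
                         n_subjects, k_raters)
      z <- icc_two_way(m, variant = variant, conf_level = conf_level)
      if (!is.na(z$ci_lower) && z$ci_lower <= true_icc &&
          z$ci_upper >= true_icc)
        hits <- hits + 1L
    }
    list(coverage = hits / n_sims, n_sims = n_sims)
  })
}
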