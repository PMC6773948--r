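# Cellularity scoring: malignant mask, dilation, area fraction,
# calibration and the composed hand-engineered scorer.

stub_seg <- function(lab) {
  structure(list(labeled_mask = lab, n = max(lab),
                 centroids = data.frame(nucleus_id = seq_len(max(lab)),
                                        x = 0, y = 0),
                 params = segmentation_params()),
            class = "nucleus_segmentation")
}

stub_map <- function(ids, classes) {
  data.frame(nucleus_id = ids, class = classes, stringsAsFactors = FALSE)
}

test_that("malignant mask selects exactly the malignant nuclei", {
  lab <- matrix(0L, 8L, 8L)
  lab[2:3, 2:3] <- 1L; lab[5:6, 2:3] <- 2L; lab[2:3, 6:7] <- 3L
  seg <- stub_seg(lab)
  # no malignant nuclei
  m0 <- malignant_mask(stub_map(1:3, rep("epithelial", 3)), seg)
  expect_false(any(m0))
  # all malignant: union of nucleus masks
  m1 <- malignant_mask(stub_map(1:3, rep("malignant", 3)), seg)
  expect_identical(m1, lab > 0L)
  # mixed: area adds over malignant nuclei
  m2 <- malignant_mask(stub_map(1:3, c("malignant", "lymphocyte",
                                       "malignant")), seg)
  expect_identical(sum(m2), sum(lab == 1L) + sum(lab == 3L))
})

test_that("dilation radius zero is the identity and dilation is monotone", {
  set.seed(2)
  mask <- matrix(runif(400) < 0.2, 20L, 20L)
  expect_identical(dilate_mask(mask, 0), mask)
  d1 <- dilate_mask(mask, 1)          # 2 px at 0.5 um/px
  d2 <- dilate_mask(mask, 2.5)
  expect_true(all(d1[mask]))          # superset of input
  expect_true(all(d2[d1]))            # larger radius is a superset
  expect_error(dilate_mask(mask, -1), "non-negative")
})

test_that("dilating a single pixel yields the enumerated disk-kernel count", {
  for (r_px in c(1L, 3L, 5L, 8L)) {
    n <- 4L * r_px + 9L
    mask <- matrix(FALSE, n, n)
    mask[(n + 1L) %/% 2L, (n + 1L) %/% 2L] <- TRUE
    d <- dilate_mask(mask, radius_um = r_px * 0.5, microns_per_pixel = 0.5)
    expect_identical(sum(d), disk_pixel_count_oracle(r_px))
  }
})

test_that("area fraction is an exact pixel ratio", {
  expect_identical(area_fraction(matrix(FALSE, 4L, 4L)), 0)
  expect_identical(area_fraction(matrix(TRUE, 4L, 4L)), 1)
  mask <- matrix(FALSE, 512L, 512L)
  mask[seq_len(26214L)] <- TRUE
  expect_identical(area_fraction(mask), 26214 / 262144)
  expect_error(area_fraction(matrix(logical(0), 0L, 0L)), "empty")
})

test_that("isotonic calibration is anchored, monotone and error-reducing", {
  set.seed(9)
  raw <- runif(40, 0, 0.9)
  # already-linear pairs: calibration is the identity up to pooling noise
  lin <- fit_calibration(raw, 100 * raw)
  expect_lt(mean(abs(predict(lin, raw) - 100 * raw)), 1e-6)
  # curved relation: calibrated MAE never exceeds the uncalibrated MAE
  manual <- 100 * raw^2
  cal <- fit_calibration(raw, manual)
  mae_cal <- mean(abs(predict(cal, raw) - manual))
  mae_raw <- mean(abs(100 * raw - manual))
  expect_lte(mae_cal, mae_raw)
  # anchored at zero and order-preserving
  expect_identical(predict(cal, 0), 0)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(predict(cal, grid)) >= -1e-12))
})

test_that("linear calibration fits a non-negative slope through the origin", {
  set.seed(10)
  raw <- runif(30, 0.05, 0.8)
  manual <- pmin(100, 120 * raw + rnorm(30, 0, 2))
  cal <- fit_calibration(raw, manual, method = "linear")
  expect_identical(predict(cal, 0), 0)
  expect_gt(cal$slope, 100)
  expect_true(all(predict(cal, c(0.2, 0.4)) ==
                    pmin(100, cal$slope * c(0.2, 0.4))))
})

test_that("degenerate calibration inputs raise explicit errors", {
  expect_error(fit_calibration(runif(5), runif(5, 0, 100)), ">= 10")
  expect_error(fit_calibration(runif(12), rep(c(10, 20), 6)),
               "3 distinct")
  expect_error(fit_calibration(rep(0.5, 12), seq(0, 99, length.out = 12)),
               "constant raw")
})

test_that("a blank stroma patch scores exactly zero", {
  p <- generate_patch(small_spec(seed = 71L, nm = 0L, ne = 0L, nl = 0L))
  s <- score_patch_hand_engineered(p$image, mini_classifier())
  expect_identical(s$value, 0)
  expect_identical(s$raw_fraction, 0)
  expect_identical(s$method, "hand_engineered")
})

test_that("scoring the same patch twice is deterministic", {
  p <- generate_patch(small_spec(seed = 72L))
  mod <- mini_classifier()
  s1 <- score_patch_hand_engineered(p$image, mod)
  s2 <- score_patch_hand_engineered(p$image, mod)
  expect_identical(s1$value, s2$value)
  expect_identical(s1$raw_fraction, s2$raw_fraction)
})

test_that("adding malignant nuclei never decreases the uncalibrated score", {
  mod <- mini_classifier()
  vals <- vapply(c(0L, 6L, 14L, 24L), function(nm)
    score_patch_hand_engineered(
      generate_patch(small_spec(seed = 73L, nm = nm))$image,
      mod)$value, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("a larger dilation radius never lowers the score", {
  mod <- mini_classifier()
  p <- generate_patch(small_spec(seed = 74L))
  v <- vapply(c(0, 1.5, 2.5, 4), function(r)
    score_patch_hand_engineered(p$image, mod,
                                config = he_config(
                                  dilation_radius_um = r))$value,
    numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("stage errors are propagated with the stage name", {
  expect_error(score_patch_hand_engineered(array(1, c(4, 4, 2)),
                                           mini_classifier()),
               "RGB")
  p <- generate_patch(small_spec(seed = 75L))
  broken <- mini_classifier()
  broken$feature_names <- broken$feature_names[-1]
  expect_error(score_patch_hand_engineered(p$image, broken),
               "\\[classify_cells\\]")
})

test_that("hand-engineered scores recover truth on small patches", {
  mod <- mini_classifier()
  set.seed(80)
  err <- vapply(81:92, function(s) {
    p <- generate_patch(small_spec(seed = s,
                                   nm = sample(c(0L, 5L, 15L, 30L), 1)))
    s_ <- score_patch_hand_engineered(p$image, mod)
    abs(s_$value - 100 * p$truth$true_tc_fraction)
  }, numeric(1))
  expect_lt(mean(err), 10)
})

test_that("tc_score objects validate their fields", {
  expect_error(tc_score(101))
  expect_error(tc_score(50, raw_fraction = 1.2))
  s <- tc_score(42.5, 0.4, "manual", "p1")
  expect_s3_class(s, "tc_score")
  expect_output(print(s), "42.5")
})
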