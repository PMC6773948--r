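# Stain separation and nucleus segmentation.

test_that("a pure-white image yields zero stain maps with a warning", {
  w <- array(255, c(32L, 32L, 3L))
  expect_warning(expect_warning(sm <- separate_stains(w), "degenerate"),
                 "degenerate")
  expect_true(all(sm$hematoxylin == 0))
  expect_true(all(sm$eosin == 0))
})

test_that("nucleus pixels carry more hematoxylin than stroma", {
  p <- generate_patch(small_spec(seed = 8L))
  sm <- separate_stains(p$image)
  nuc <- p$truth$label_map %in% 1:3
  expect_gt(mean(sm$hematoxylin[nuc]),
            mean(sm$hematoxylin[!nuc]) + 0.2)
  # eosin-rich stroma the other way round
  expect_gt(mean(sm$eosin[p$truth$label_map == 0L]),
            mean(sm$eosin[p$truth$label_map %in% 1:3]))
})

test_that("stain maps are invariant to a global brightness rescale", {
  p <- generate_patch(small_spec(seed = 15L))
  sm <- separate_stains(p$image)
  sm8 <- separate_stains(round(p$image * 0.8))
  expect_lt(max(abs(sm$hematoxylin - sm8$hematoxylin)), 0.02)
  # the eosin range is narrower, so 8-bit quantisation of the rescaled
  # image leaves a larger per-pixel stretch residual on dark nuclei
  expect_lt(mean(abs(sm$eosin - sm8$eosin)), 0.01)
  expect_lt(max(abs(sm$eosin - sm8$eosin)), 0.1)
})

test_that("collinear stain vectors are rejected", {
  v <- cbind(c(1, 1, 1) / sqrt(3), c(1, 1, 1) / sqrt(3))
  p <- generate_patch(small_spec(seed = 2L, size = 128L, nm = 3L,
                                 ne = 3L, nl = 3L))
  expect_error(separate_stains(p$image, stain_vectors = v),
               "non-collinear")
})

test_that("a blank stroma patch segments to zero nuclei", {
  p <- generate_patch(small_spec(seed = 5L, nm = 0L, ne = 0L, nl = 0L))
  seg <- segment_nuclei(separate_stains(p$image))
  expect_identical(seg$n, 0L)
  expect_true(all(seg$labeled_mask == 0L))
})

test_that("well-separated nuclei are recovered with matching centroids", {
  p <- generate_patch(synthetic_patch_spec(seed = 2L, n_malignant = 13L,
                                           n_epithelial = 13L,
                                           n_lymphocyte = 14L))
  n_true <- nrow(p$truth$nucleus_records)
  sm <- separate_stains(p$image)
  seg <- segment_nuclei(sm)
  expect_gte(seg$n, ceiling(0.9 * n_true))
  expect_lte(seg$n, floor(1.1 * n_true))
  hits <- mapply(function(x, y)
    p$truth$label_map[round(y) + 1L, round(x) + 1L] %in% 1:3,
    seg$centroids$x, seg$centroids$y)
  expect_gte(mean(hits), 0.9)
})

test_that("two touching nuclei are split by the watershed", {
  # two disks, centre distance 1.5 x radius, drawn directly into a map
  h <- matrix(0, 96L, 96L)
  r <- 12
  for (cen in list(c(48, 36), c(48, 36 + 1.5 * r))) {
    d <- outer(seq_len(96) - cen[1], seq_len(96) - cen[2],
               function(a, b) sqrt(a^2 + b^2))
    h[d <= r] <- 0.9
  }
  sm <- structure(list(hematoxylin = h, eosin = h * 0,
                       hematoxylin_raw = h, eosin_raw = h * 0,
                       stain_vectors = he_stain_vectors(),
                       stretch_percentiles = c(0.01, 0.99)),
                  class = "stain_maps")
  seg <- segment_nuclei(sm, segmentation_params(threshold_method = "fixed",
                                                fixed_threshold = 0.5,
                                                smooth_sigma = 0))
  expect_identical(seg$n, 2L)
})

test_that("no emitted nucleus violates the configured area bounds", {
  for (s in 1:5) {
    p <- generate_patch(small_spec(seed = s, nm = 15L))
    seg <- segment_nuclei(separate_stains(p$image))
    if (seg$n > 0L) {
      expect_true(all(seg$areas_um2 >= seg$params$min_area_um2))
      expect_true(all(seg$areas_um2 <= seg$params$max_area_um2))
      expect_identical(sort(unique(seg$labeled_mask[seg$labeled_mask > 0L])),
                       seq_len(seg$n))
    }
  }
})

test_that("segmentation is deterministic for identical input", {
  p <- generate_patch(small_spec(seed = 77L))
  a <- segment_nuclei(separate_stains(p$image))
  b <- segment_nuclei(separate_stains(p$image))
  expect_identical(a$labeled_mask, b$labeled_mask)
  expect_identical(a$centroids, b$centroids)
})

test_that("boundaries are closed contours around their nuclei", {
  p <- generate_patch(small_spec(seed = 33L, size = 128L))
  seg <- segment_nuclei(separate_stains(p$image))
  expect_identical(length(seg$boundaries), seg$n)
  for (k in seq_len(min(seg$n, 5L))) {
    b <- seg$boundaries[[k]]
    expect_identical(b[1, ], b[nrow(b), ])          # closed
    # boundary pixels belong to nucleus k
    expect_true(all(seg$labeled_mask[cbind(b[, "y"] + 1L,
                                           b[, "x"] + 1L)] == k))
  }
})

test_that("segmentation artefacts round-trip through their file formats", {
  p <- generate_patch(small_spec(seed = 34L, size = 128L))
  seg <- segment_nuclei(separate_stains(p$image))
  mask_path <- tempfile(fileext = ".tiff")
  write_segmentation_mask(seg, mask_path)
  back <- round(tiff::readTIFF(mask_path) * 65535)
  expect_identical(matrix(as.integer(back), nrow(back)),
                   seg$labeled_mask)
  bnd_path <- tempfile(fileext = ".csv")
  write_boundaries(seg, bnd_path)
  bnd <- read.csv(bnd_path)
  expect_identical(sort(unique(bnd$nucleus_id)), seq_len(seg$n))
  expect_identical(names(bnd), c("nucleus_id", "x", "y"))
})

test_that("centroid-level detection F1 clears the regression gate", {
  # seeded benchmark of 100 small patches at moderate density
  set.seed(101)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:100) {
    p <- generate_patch(synthetic_patch_spec(
      width_px = 160L, height_px = 160L,
      n_lymphocyte = sample(2:8, 1), n_epithelial = sample(2:8, 1),
      n_malignant = sample(2:8, 1), seed = sample.int(1e6, 1)))
    seg <- segment_nuclei(separate_stains(p$image))
    truth <- p$truth
    hit <- mapply(function(x, y)
      truth$label_map[round(y) + 1L, round(x) + 1L] %in% 1:3,
      seg$centroids$x, seg$centroids$y)
    if (seg$n == 0L) hit <- logical(0)
    tp <- tp + sum(hit)
    fp <- fp + sum(!hit)
    fn <- fn + max(0L, nrow(truth$nucleus_records) - sum(hit))
  }
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.85)
})
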