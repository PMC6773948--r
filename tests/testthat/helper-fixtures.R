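# Shared fixtures, built once per test run and memoised. Patches are kept
# small (128-320 px) so the unit suite stays fast; the acceptance tests
# use the full benchmark sizes.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(),
                                               envir = .fixtures)
  get(name, envir = .fixtures)
}

small_spec <- function(seed = 1L, nm = 10L, ne = 10L, nl = 10L,
                       size = 256L) {
  synthetic_patch_spec(width_px = size, height_px = size,
                       n_lymphocyte = nl, n_epithelial = ne,
                       n_malignant = nm, seed = seed)
}

small_he_config <- function() {
  cfg <- he_config()
  cfg
}

# A patch processed through stains + segmentation + features + truth.
processed_patch <- function(seed = 1L, nm = 10L, ne = 10L, nl = 10L,
                            size = 256L) {
  p <- generate_patch(small_spec(seed, nm, ne, nl, size))
  sm <- separate_stains(p$image)
  seg <- segment_nuclei(sm)
  feats <- extract_features(p$image, sm, seg)
  list(patch = p, stains = sm, seg = seg, features = feats,
       labels = match_nuclei_to_truth(seg, p$truth))
}

# Cell classifier trained on ~600 nuclei from 10 small patches.
mini_classifier <- function() {
  memo("mini_classifier", function() {
    pp <- lapply(1:10, function(s) processed_patch(seed = s))
    feats <- do.call(rbind, lapply(pp, `[[`, "features"))
    labs <- unlist(lapply(pp, function(z) as.character(z$labels)))
    train_cell_classifier(feats, labs)
  })
}

# Small held-out processed patch for classifier tests.
held_out_patch <- function() memo("held_out", function()
  processed_patch(seed = 99L))

# Mini cascade trained on 70 small patches (blank-to-dense range).
mini_cascade <- function() {
  memo("mini_cascade", function() {
    cfg <- cascade_config(seed = 11L)
    n <- 70L
    specs <- benchmark_patch_specs(n, seed = 7L, size_px = 128L,
                                   healthy_frac = 0.3)
    desc <- matrix(NA_real_, n, 42L)
    truth <- numeric(n)
    for (i in seq_len(n)) {
      p <- generate_patch(specs[[i]])
      desc[i, ] <- patch_descriptor(p$image, cfg$resize_px)
      truth[i] <- 100 * p$truth$true_tc_fraction
    }
    labels <- ifelse(truth == 0, "healthy", "cancerous")
    s1 <- train_stage1(NULL, labels, cfg, descriptors = desc,
                       input_dims = c(128L, 128L))
    manual <- sample_manual_scores(
      data.frame(patch_id = seq_len(n), true_tc_percent = truth),
      rater_noise_sd = 5, rounding_step = 5, seed = 8L)
    s2 <- train_stage2(NULL, manual$score[truth > 0], cfg,
                       descriptors = desc[truth > 0, , drop = FALSE],
                       input_dims = c(128L, 128L))
    list(stage1 = s1, stage2 = s2, config = cfg, truth = truth,
         specs = specs)
  })
}
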