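# Two-stage cascade: gate contract, regression bounds, determinism.

test_that("the stage-1 gate separates blank from dense patches", {
  mc <- mini_cascade()
  # held-out set from the same family
  specs <- benchmark_patch_specs(30L, seed = 17L, size_px = 128L,
                                 healthy_frac = 0.3)
  correct <- 0L
  for (sp in specs) {
    p <- generate_patch(sp)
    prob <- predict_stage1(mc$stage1, p$image)
    truth_cancer <- p$truth$true_tc_fraction > 0
    if ((prob >= mc$config$threshold) == truth_cancer)
      correct <- correct + 1L
  }
  expect_gte(correct / length(specs), 0.95)
})

test_that("stage-1 training is seed-deterministic and label-symmetric", {
  n <- 40L
  specs <- benchmark_patch_specs(n, seed = 23L, size_px = 128L,
                                 healthy_frac = 0.4)
  desc <- matrix(NA_real_, n, 42L)
  truth <- numeric(n)
  for (i in seq_len(n)) {
    p <- generate_patch(specs[[i]])
    desc[i, ] <- patch_descriptor(p$image, 128L)
    truth[i] <- p$truth$true_tc_fraction
  }
  labels <- factor(ifelse(truth == 0, "healthy", "cancerous"),
                   levels = c("healthy", "cancerous"))
  cfg <- cascade_config(seed = 5L)
  m1 <- train_stage1(NULL, labels, cfg, descriptors = desc,
                     input_dims = c(128L, 128L))
  m2 <- train_stage1(NULL, labels, cfg, descriptors = desc,
                     input_dims = c(128L, 128L))
  p1 <- vapply(seq_len(n), function(i)
    predict_stage1(m1, NULL, descriptor = desc[i, ]), numeric(1))
  p2 <- vapply(seq_len(n), function(i)
    predict_stage1(m2, NULL, descriptor = desc[i, ]), numeric(1))
  expect_identical(p1, p2)
  # flipped labels give the mirrored classifier
  flipped <- factor(ifelse(truth == 0, "cancerous", "healthy"),
                    levels = c("healthy", "cancerous"))
  mf <- train_stage1(NULL, flipped, cfg, descriptors = desc,
                     input_dims = c(128L, 128L))
  pf <- vapply(seq_len(n), function(i)
    predict_stage1(mf, NULL, descriptor = desc[i, ]), numeric(1))
  acc <- mean((p1 >= 0.5) == (truth > 0))
  acc_f <- mean((pf >= 0.5) == (truth > 0))
  expect_lt(abs(acc_f - (1 - acc)), 0.05)
})

test_that("one-class or out-of-range training inputs are rejected", {
  desc <- matrix(rnorm(10 * 42), 10, 42)
  expect_error(train_stage1(NULL, rep("healthy", 10), cascade_config(),
                            descriptors = desc,
                            input_dims = c(64L, 64L)),
               "both healthy and cancerous")
  expect_error(train_stage2(NULL, c(seq(10, 90, 10), 101),
                            cascade_config(), descriptors = desc,
                            input_dims = c(64L, 64L)),
               "\\[0,100\\]")
})

test_that("a constant-label regressor predicts that constant", {
  mc <- mini_cascade()
  n <- 60L
  specs <- benchmark_patch_specs(n, seed = 31L, size_px = 128L,
                                 healthy_frac = 0)
  desc <- t(vapply(specs, function(sp)
    patch_descriptor(generate_patch(sp)$image, 128L), numeric(42L)))
  suppressWarnings(
    m <- train_stage2(NULL, rep(50, n), cascade_config(seed = 2L),
                      descriptors = desc, input_dims = c(128L, 128L)))
  preds <- vapply(1:10, function(i)
    predict_stage2(m, NULL, descriptor = desc[i, ]), numeric(1))
  expect_true(all(abs(preds - 50) <= 5))
})

test_that("stage-2 predictions always respect the 0-100 bounds", {
  mc <- mini_cascade()
  set.seed(3)
  for (i in 1:40) {
    img <- array(sample(0:255, 128 * 128 * 3, replace = TRUE),
                 c(128L, 128L, 3L))
    v <- predict_stage2(mc$stage2, img)
    expect_gte(v, 0)
    expect_lte(v, 100)
  }
})

test_that("the cascade gate forces exact zeros and obeys thresholds", {
  mc <- mini_cascade()
  p_blank <- generate_patch(small_spec(seed = 201L, nm = 0L, ne = 2L,
                                       nl = 2L, size = 128L))
  pr <- predict_cascade(mc$stage1, mc$stage2, p_blank$image)
  expect_identical(pr$tc, 0)
  expect_identical(pr$stage, "gated_healthy")
  # a tiny threshold disables the gate entirely
  pr0 <- predict_cascade(mc$stage1, mc$stage2, p_blank$image,
                         threshold = 0)
  expect_identical(pr0$stage, "regressed")
  # raising the threshold never un-gates a patch
  specs <- benchmark_patch_specs(15L, seed = 37L, size_px = 128L,
                                 healthy_frac = 0.4)
  gated <- vapply(c(0.25, 0.5, 0.75), function(th) {
    sum(vapply(specs, function(sp) {
      p <- generate_patch(sp)
      predict_cascade(mc$stage1, mc$stage2, p$image,
                      threshold = th)$stage == "gated_healthy"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(gated) >= 0))
})

test_that("cascade input-size mismatches raise explicit errors", {
  mc <- mini_cascade()
  wrong <- array(128, c(96L, 96L, 3L))
  expect_error(predict_cascade(mc$stage1, mc$stage2, wrong),
               "input size mismatch")
  s2 <- mc$stage2
  s2$input_dims <- c(64L, 64L)
  p <- generate_patch(small_spec(seed = 1L, size = 128L))
  expect_error(predict_cascade(mc$stage1, s2, p$image),
               "input size mismatch")
})

test_that("combined predictions equal hand-engineered scores off the gate", {
  mc <- mini_cascade()
  mod <- mini_classifier()
  cfg <- he_config()
  p_dense <- generate_patch(small_spec(seed = 211L, nm = 20L,
                                       size = 128L))
  comb <- predict_combined(mc$stage1, mod, p_dense$image, config = cfg)
  if (comb$stage == "hand_engineered") {
    he <- score_patch_hand_engineered(p_dense$image, mod, config = cfg)
    expect_identical(comb$value, he$value)
    expect_identical(comb$method, "combined")
  }
  p_blank <- generate_patch(small_spec(seed = 212L, nm = 0L, ne = 2L,
                                       nl = 2L, size = 128L))
  comb0 <- predict_combined(mc$stage1, mod, p_blank$image, config = cfg)
  expect_identical(comb0$value, 0)
  expect_identical(comb0$stage, "gated_healthy")
})

test_that("the gate only ever helps on truly healthy patches", {
  mc <- mini_cascade()
  specs <- benchmark_patch_specs(20L, seed = 41L, size_px = 128L,
                                 healthy_frac = 0.5)
  for (sp in specs) {
    p <- generate_patch(sp)
    pr <- predict_cascade(mc$stage1, mc$stage2, p$image)
    if (pr$stage == "gated_healthy") expect_identical(pr$tc, 0)
    else expect_true(pr$tc >= 0 && pr$tc <= 100)
  }
})

test_that("random-forest stage-1 records a decreasing error trajectory", {
  mc <- mini_cascade()
  curve <- mc$stage1$oob_curve
  expect_gt(length(curve), 10L)
  expect_lte(mean(tail(curve, 20)), mean(head(curve, 20)))
})
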