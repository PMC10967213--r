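test_that("patch embedding maps image patches to single grid positions", {
  sc <- small_cohort()
  model <- survmixer_init(sc$images$layout,
                          survmixer_config(channels = 8, seed = 3))
  fm <- patch_embed(model, subset_imageset(sc$images, 1:5))
  expect_identical(dim(fm), c(5L, 8L, 4L, 4L))
})

test_that("default geometry embeds a 49x49 image into a channels x 7x7 map", {
  genes <- lapply(1:40, function(i) paste0("p", i, "_", 1:3))
  names(genes) <- paste0("pw", 1:40)
  lay <- build_layout(pathway_collection(genes))
  model <- survmixer_init(lay, survmixer_config(channels = 16, seed = 1))
  img <- array(runif(2 * 49 * 49), c(2, 49, 49))
  fm <- patch_embed(model, img)
  expect_identical(dim(fm), c(2L, 16L, 7L, 7L))
})

test_that("embedding is local: blank-patch content cannot reach other slots", {
  sc <- small_cohort()
  lay <- sc$images$layout
  model <- survmixer_init(lay, survmixer_config(channels = 6, seed = 8))
  set.seed(1)
  img1 <- array(runif(144), c(1, 12, 12))
  img2 <- img1
  # scribble inside the first blank slot
  s <- lay$blank_slots[1]
  r <- (s - 1L) %/% 4L; cc <- (s - 1L) %% 4L
  img2[1, r * 3 + 1:3, cc * 3 + 1:3] <- runif(9)
  f1 <- patch_embed(model, img1)
  f2 <- patch_embed(model, img2)
  expect_equal(f1, f2)   # blank slots are masked right after embedding
})

test_that("convmixer blocks preserve the feature-map shape", {
  sc <- small_cohort()
  model <- survmixer_init(sc$images$layout,
                          survmixer_config(channels = 8, n_blocks = 2, seed = 3))
  fm <- patch_embed(model, subset_imageset(sc$images, 1:3))
  b1 <- convmixer_block(model, fm, 1)
  b2 <- convmixer_block(model, b1, 2)
  expect_identical(dim(b1), dim(fm))
  expect_identical(dim(b2), dim(fm))
  expect_error(convmixer_block(model, fm, 3), "no such block")
})

test_that("depthwise convolution matches direct convolution arithmetic", {
  # 1-channel 3x3 toy map with fixed 3x3 kernel, zero padding, stride 1
  gs <- 3L
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), gs, gs, byrow = TRUE)
  W <- matrix(c(0.1, -0.2, 0.3, 0.4, 0.5, -0.6, 0.7, 0.8, -0.9),
              1, 9, byrow = TRUE)   # taps row-major over (dr, dc)
  xm <- matrix(0, gs^2, 1)
  for (p in seq_len(gs^2))
    xm[p, 1] <- x[(p - 1) %/% gs + 1, (p - 1) %% gs + 1]
  out <- survmixr:::dw_forward(xm, W, b = 0.05,
                               Tm = survmixr:::dw_tapmat(gs, 3L),
                               n = 1L, P = gs^2)
  # oracle: explicit sliding-window sum with zero padding
  expected <- matrix(0, gs, gs)
  k <- 0
  Wk <- matrix(0, 3, 3)
  for (dr in -1:1) for (dc in -1:1) { k <- k + 1; Wk[dr + 2, dc + 2] <- W[1, k] }
  for (r in 1:gs) for (cc in 1:gs) {
    s <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rs <- r + dr; cs <- cc + dc
      if (rs >= 1 && rs <= gs && cs >= 1 && cs <= gs)
        s <- s + Wk[dr + 2, dc + 2] * x[rs, cs]
    }
    expected[r, cc] <- s + 0.05
  }
  got <- matrix(0, gs, gs)
  for (p in seq_len(gs^2))
    got[(p - 1) %/% gs + 1, (p - 1) %% gs + 1] <- out[p, 1]
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("masking zeroes blank slots across channels and is idempotent", {
  genes <- lapply(1:40, function(i) paste0("p", i, "_", 1:3))
  names(genes) <- paste0("pw", 1:40)
  lay <- build_layout(pathway_collection(genes))
  set.seed(2)
  fm <- array(runif(3 * 5 * 7 * 7) + 1, c(3, 5, 7, 7))
  masked <- mask_blank(fm, lay)
  for (s in lay$blank_slots) {
    r <- (s - 1L) %/% 7L + 1L; cc <- (s - 1L) %% 7L + 1L
    expect_true(all(masked[, , r, cc] == 0))
  }
  n_zeroed <- sum(masked == 0) - sum(fm == 0)
  expect_identical(n_zeroed, 3L * 5L * 9L)
  expect_equal(mask_blank(masked, lay), masked)

  # a layout without blank slots: identity
  genes49 <- lapply(1:49, function(i) paste0("q", i, "_", 1:2))
  names(genes49) <- paste0("pw", 1:49)
  lay49 <- build_layout(pathway_collection(genes49))
  expect_equal(mask_blank(fm, lay49), fm)
})

test_that("forward pass yields probabilities in (0,1), order-preserving", {
  model <- small_trained_model()
  sc <- small_cohort()
  p <- predict(model, sc$images)
  expect_true(all(p > 0 & p < 1))
  idx <- c(5L, 1L, 9L)
  p2 <- predict(model, subset_imageset(sc$images, idx))
  expect_equal(unname(p2), unname(p[idx]), tolerance = 1e-12)
  # exported stage functions reproduce the fused forward pass
  fm <- patch_embed(model, subset_imageset(sc$images, idx))
  for (b in seq_len(model$config$n_blocks))
    fm <- convmixer_block(model, fm, b)
  expect_equal(unname(head_score(model, fm)), unname(p[idx]),
               tolerance = 1e-10)
})

test_that("training is deterministic given a seed and reduces the loss", {
  sc <- small_cohort()
  cfg <- survmixer_config(channels = 8, epochs = 6, lr = 2e-3, seed = 99)
  f1 <- survmixer(sc$images, sc$labels, cfg)
  f2 <- survmixer(sc$images, sc$labels, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_lt(tail(f1$loss_history, 1), f1$loss_history[1])
})

test_that("training refuses single-class cohorts", {
  sc <- small_cohort()
  idx <- which(sc$labels == 1L)[1:10]
  expect_error(
    survmixer(subset_imageset(sc$images, idx), sc$labels[idx],
              survmixer_config(channels = 4, epochs = 1)),
    "each class")
})

test_that("parameter count is independent of the number of samples", {
  sc <- small_cohort()
  cfg <- survmixer_config(channels = 6, epochs = 2, seed = 1)
  i1 <- which(sc$labels == 1L)[1:4]
  i0 <- which(sc$labels == 0L)[1:4]
  f_small <- survmixer(subset_imageset(sc$images, c(i1, i0)),
                       sc$labels[c(i1, i0)], cfg)
  f_big <- survmixer(sc$images, sc$labels, cfg)
  expect_identical(f_small$n_params, f_big$n_params)
})

test_that("trained model output is invariant to blank-patch content", {
  model <- small_trained_model()
  sc <- small_cohort()
  lay <- sc$images$layout
  imgs <- subset_imageset(sc$images, 1:10)
  perturbed <- imgs
  set.seed(4)
  for (s in lay$blank_slots) {
    r <- (s - 1L) %/% 4L; cc <- (s - 1L) %% 4L
    perturbed$images[, r * 3 + 1:3, cc * 3 + 1:3] <-
      array(runif(10 * 9), c(10, 3, 3))
  }
  p0 <- predict(model, imgs)
  p1 <- predict(model, perturbed)
  expect_lt(max(abs(p0 - p1)), 1e-6)
})

test_that("model methods expose coefficients, residuals and summaries", {
  model <- small_trained_model()
  cf <- coef(model)
  expect_length(cf, model$config$channels + 1L)
  expect_named(cf[length(cf)], "intercept")
  r <- residuals(model)
  expect_equal(unname(r), unname(model$labels - model$fitted))
  s <- summary(model)
  expect_s3_class(s, "summary.survmixer")
  expect_gt(s$train_auc, 0.5)
  expect_output(print(model), "ConvMixer")
})
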