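test_that("Grad-CAM maps have grid shape, Z = positions, and are non-negative", {
  model <- small_trained_model()
  sc <- small_cohort()
  g <- gradcam(model, subset_imageset(sc$images, 1:6))
  expect_identical(dim(g$maps), c(6L, 4L, 4L))
  expect_identical(g$Z, 16L)
  expect_true(all(g$maps >= 0))
  expect_identical(g$layer, "block2")
  expect_error(gradcam(model, subset_imageset(sc$images, 1:2), layer = "xx"),
               "unknown layer")
})

test_that("channel importances match central finite differences", {
  # 2-channel toy model; perturb whole channel maps of the Grad-CAM layer
  # and push them through the remaining forward computation
  sc <- small_cohort()
  cfg <- survmixer_config(channels = 2, n_blocks = 1, epochs = 2, seed = 21)
  model <- survmixer(subset_imageset(sc$images, 1:20), sc$labels[1:20], cfg)
  imgs <- subset_imageset(sc$images, 1:3)

  for (layer in c("block1", "embed")) {
    g <- gradcam(model, imgs, layer = layer)
    fm <- patch_embed(model, imgs)
    if (layer == "block1") fm <- convmixer_block(model, fm, 1)
    rest <- function(f) {     # forward from the layer to the logit
      if (layer == "embed") f <- convmixer_block(model, f, 1)
      head_score(model, f, type = "link")
    }
    eps <- 1e-4
    Z <- model$layout$grid_side^2
    for (ch in 1:2) {
      up <- fm; up[, ch, , ] <- up[, ch, , ] + eps
      dn <- fm; dn[, ch, , ] <- dn[, ch, , ] - eps
      alpha_fd <- (rest(up) - rest(dn)) / (2 * eps) / Z
      expect_equal(g$alpha[, ch], alpha_fd, tolerance = 1e-3)
    }
  }
})

test_that("the map is the ReLU of the importance-weighted channel sum", {
  model <- small_trained_model()
  sc <- small_cohort()
  imgs <- subset_imageset(sc$images, 1:4)
  g <- gradcam(model, imgs)
  fm <- patch_embed(model, imgs)
  for (b in seq_len(model$config$n_blocks))
    fm <- convmixer_block(model, fm, b)
  gs <- model$layout$grid_side
  for (i in 1:4) {
    pre <- matrix(0, gs, gs)
    for (ch in seq_len(model$config$channels))
      pre <- pre + g$alpha[i, ch] * fm[i, ch, , ]
    expect_equal(g$maps[i, , ], pmax(pre, 0), tolerance = 1e-8)
  }
  # linearity: scaling the channel maps with fixed importances scales the
  # pre-ReLU combination
  lam <- 2.5
  pre1 <- matrix(0, gs, gs); pre2 <- pre1
  for (ch in seq_len(model$config$channels)) {
    pre1 <- pre1 + g$alpha[1, ch] * fm[1, ch, , ]
    pre2 <- pre2 + g$alpha[1, ch] * (lam * fm[1, ch, , ])
  }
  expect_equal(pre2, lam * pre1, tolerance = 1e-10)
})

test_that("pathway activations read one slot per pathway, blanks excluded", {
  sc <- small_cohort()
  lay <- sc$images$layout
  set.seed(6)
  maps <- array(runif(5 * 16), c(5, 4, 4))
  act <- pathway_activations(maps, lay)
  expect_identical(dim(act), c(5L, 12L))
  expect_identical(colnames(act), lay$pathways)
  for (j in 1:12) {
    s <- lay$pathway_slots[j]
    expect_equal(act[, j], maps[, (s - 1) %/% 4 + 1, (s - 1) %% 4 + 1])
  }
  expect_true(all(pathway_activations(array(0, c(2, 4, 4)), lay) == 0))
})

test_that("permuting pathway order permutes activation columns identically", {
  # a deterministic per-patch statistic (patch mean) stands in for the model
  set.seed(8)
  genes <- lapply(1:6, function(i) paste0("pw", i, "_", 1:4))
  names(genes) <- paste0("pw", 1:6)
  pc <- pathway_collection(genes)
  perm <- c(4, 1, 6, 2, 5, 3)
  pc_perm <- pathway_collection(genes[perm])
  x <- matrix(runif(3 * 24), 3, 24,
              dimnames = list(paste0("s", 1:3),
                              unlist(genes, use.names = FALSE)))
  patch_mean_maps <- function(imgs) {
    gs <- imgs$layout$grid_side; ps <- imgs$layout$patch_side
    n <- dim(imgs$images)[1]
    m <- array(0, c(n, gs, gs))
    for (r in 1:gs) for (cc in 1:gs)
      m[, r, cc] <- apply(imgs$images[, (r - 1) * ps + 1:ps,
                                      (cc - 1) * ps + 1:ps, drop = FALSE],
                          1, mean)
    m
  }
  i1 <- build_images(x, pc, patch_side = 2, grid_side = 3)
  i2 <- build_images(x, pc_perm, patch_side = 2, grid_side = 3)
  a1 <- pathway_activations(patch_mean_maps(i1), i1$layout)
  a2 <- pathway_activations(patch_mean_maps(i2), i2$layout)
  expect_equal(a2, a1[, colnames(a2)])
})

test_that("rank-sum p-values match exact enumeration and Bonferroni scales", {
  # identical samples in both groups: no evidence, p = 1
  act <- cbind(pw1 = c(1, 2, 3, 1, 2, 3))
  expect_equal(wilcoxon_keypathways(act, c(1, 1, 1, 0, 0, 0))$p_raw, 1)

  # {1,2,3} vs {10,11,12}: most extreme of the C(6,3) = 20 assignments,
  # two-sided exact p = 2/20
  act2 <- cbind(pw1 = c(1, 2, 3, 10, 11, 12))
  r <- wilcoxon_keypathways(act2, c(1, 1, 1, 0, 0, 0))
  expect_equal(r$p_raw, 0.1)

  # enumeration oracle for random untied small groups
  exact_p <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    W_obs <- sum(rank(pooled)[seq_len(n1)])
    combs <- combn(length(pooled), n1)
    Ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
    mu <- n1 * (length(pooled) + 1) / 2
    mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  }
  set.seed(77)
  for (i in 1:10) {
    x <- runif(sample(3:6, 1), 0, 10)
    y <- runif(sample(3:6, 1), 2, 12)
    a <- cbind(p = c(x, y))
    lab <- c(rep(1, length(x)), rep(0, length(y)))
    expect_equal(wilcoxon_keypathways(a, lab)$p_raw, exact_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies by the pathway count, capped", {
  set.seed(15)
  act <- matrix(rnorm(20 * 40), 20, 40,
                dimnames = list(NULL, paste0("pw", 1:40)))
  lab <- rep(c(0, 1), 10)
  r <- wilcoxon_keypathways(act, lab)
  expect_equal(r$p_bonferroni, pmin(1, r$p_raw * 40))
  expect_true(all(r$p_bonferroni >= r$p_raw))
  expect_true(all(r$p_bonferroni > 0 & r$p_bonferroni <= 1))
  # a raw p of 0.002 over 40 pathways is not significant after correction
  expect_equal(min(1, 0.002 * 40), 0.08)
  expect_identical(r$significant, r$p_bonferroni < 0.05)
})

test_that("pathway scores are maximal for top-ranked member genes", {
  set.seed(10)
  pc <- pathway_collection(list(set = paste0("m", 1:5)))
  genes <- c(paste0("m", 1:5), paste0("o", 1:45))
  x <- matrix(runif(20 * 50), 20, 50, dimnames = list(paste0("s", 1:20), genes))
  # sample 1: member genes at the global top, all others at the bottom
  x[1, 1:5] <- 2
  x[1, 6:50] <- -1
  sc <- gsva_scores(x, pc)
  expect_identical(unname(which.max(sc["set", ])), 1L)
  expect_gt(sc["set", 1], 0.8)
})

test_that("pathway scores centre near zero for unstructured gene sets", {
  set.seed(11)
  n_genes <- 500
  genes <- paste0("g", seq_len(n_genes))
  x <- matrix(rnorm(60 * n_genes), 60, n_genes,
              dimnames = list(paste0("s", 1:60), genes))
  sets <- lapply(1:10, function(i) sample(genes, 30))
  names(sets) <- paste0("rand", 1:10)
  sc <- gsva_scores(x, pathway_collection(sets))
  expect_lt(abs(mean(sc)), 0.05)
  expect_lt(max(abs(rowMeans(sc))), 0.12)
})

test_that("duplicated samples get identical score columns; missing genes warn", {
  set.seed(12)
  genes <- paste0("g", 1:40)
  x <- matrix(runif(10 * 40), 10, 40, dimnames = list(paste0("s", 1:10), genes))
  x <- rbind(x, s11 = x["s3", ])
  pc <- pathway_collection(list(a = genes[1:8], b = genes[9:14]))
  sc <- gsva_scores(x, pc)
  expect_equal(sc[, "s11"], sc[, "s3"])

  pc2 <- pathway_collection(list(a = c(genes[1:4], "absent1")))
  expect_warning(gsva_scores(x, pc2), "absent")
  pc3 <- pathway_collection(list(a = c("no1", "no2")))
  expect_warning(s3 <- gsva_scores(x, pc3), "no genes")
  expect_true(all(is.na(s3)))
})

test_that("KM estimates follow product-limit arithmetic on the worked case", {
  # 8 samples; the low-score group is the classic 4-sample case with
  # deaths at t = 1 and t = 2 and survivors beyond
  scores <- c(rep(0, 4), rep(1, 4))
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 1, 1, 1, 1, 1, 1)
  km <- km_logrank(scores, times, event)
  lo <- km$curves[km$curves$group == "low", ]
  expect_equal(lo$surv[lo$time == 1], 0.75)
  expect_equal(lo$surv[lo$time == 2], 0.5)
})

test_that("identical survival in both groups gives log-rank p = 1", {
  scores <- c(rep(0, 4), rep(1, 4))
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 0, 1, 0, 1, 0, 1, 0)
  km <- km_logrank(scores, times, event)
  expect_equal(km$logrank_p, 1)
  expect_error(km_logrank(rep(1, 6), times[1:6], event[1:6]), "degenerate")
})

test_that("log-rank statistic matches a risk-set enumeration oracle", {
  # independently coded observed-minus-expected over risk sets
  logrank_chisq <- function(time, event, grp) {
    evt <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in evt) {
      at_risk <- time >= t
      n <- sum(at_risk)
      n1 <- sum(at_risk & grp == 1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & grp == 1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  set.seed(19)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    scores <- runif(n)
    time <- rexp(n, 0.2)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1
    km <- km_logrank(scores, time, event)
    grp <- as.integer(km$group == "high")
    expect_equal(km$chisq, logrank_chisq(time, event, grp),
                 tolerance = 1e-10)
  }
})

test_that("the report ties tests and KM results together", {
  sc <- small_cohort()
  model <- small_trained_model()
  srv <- sc$cohort$records[match(sc$labeled$kept, sc$cohort$records$sample_id), ]
  rep <- suppressWarnings(
    key_pathway_report(model, sc$images, sc$labels,
                       sc$cohort$expression[sc$keep, , drop = FALSE],
                       sc$collection, srv$os_time, srv$event))
  expect_s3_class(rep, "KeyPathwayReport")
  expect_identical(nrow(rep$tests), 12L)
  expect_identical(rep$key, rep$tests$pathway[rep$tests$significant])
  expect_identical(dim(rep$gsva), c(12L, length(sc$labels)))
  for (pw in rep$key)
    expect_true(inherits(rep$km[[pw]], "KMComparison") ||
                inherits(rep$km[[pw]], "error"))
})
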