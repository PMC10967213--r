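#' Model configuration
#'
#' Hyperparameters of the pathway-image ConvMixer classifier. The defaults
#' follow the reference architecture: 256 filters in every convolution, two
#' ConvMixer blocks, a patch embedding whose kernel and stride both equal
#' the patch side (non-overlapping), a 3x3 shape-preserving depthwise
#' convolution, GELU activations, and a global-average-pooled linear unit
#' with sigmoid output. Training (unspecified by the architecture) uses
#' binary cross-entropy with Adam.
#'
#' @param channels Filters per convolution layer (default 256).
#' @param n_blocks Number of ConvMixer blocks (default 2).
#' @param depthwise_kernel Depthwise kernel side (default 3); applied with
#'   stride 1 and same padding so every hidden layer keeps the grid shape
#'   that masking and Grad-CAM require.
#' @param activation `"gelu"` (default) or `"relu"`.
#' @param lr Peak Adam learning rate.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay from `lr`
#'   to zero over `epochs`, the usual recipe for this architecture).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   convolution and linear weight matrices; 0 disables it.
#' @param input_noise_sd SD of Gaussian noise added to image pixels during
#'   training (augmentation; 0 disables). Only training inputs are
#'   perturbed, never predictions.
#' @param mixup_alpha Beta(alpha, alpha) mixup coefficient; each training
#'   batch is replaced by convex combinations of shuffled sample pairs and
#'   their labels. 0 disables mixup.
#' @param val_fraction Fraction of the training samples held out
#'   (stratified) as an early-stopping validation set; 0 disables early
#'   stopping and trains for exactly `epochs` epochs.
#' @param patience Early-stopping patience: training stops once the
#'   validation AUC has not improved for this many epochs, and the best
#'   weights are restored.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed making initialization and batching reproducible.
#' @param gap `"all"` (default): global average pooling divides by all grid
#'   positions, blank ones included; `"nonblank"` divides by the number of
#'   pathway slots only.
#' @return A `survmixer_config` list.
#' @export
survmixer_config <- function(channels = 256L, n_blocks = 2L,
                             depthwise_kernel = 3L, activation = "gelu",
                             lr = 1e-3, lr_schedule = c("constant", "cosine"),
                             weight_decay = 0,
                             input_noise_sd = 0, mixup_alpha = 0,
                             val_fraction = 0, patience = 10L,
                             epochs = 50L, batch_size = 32L, seed = 1L,
                             gap = c("all", "nonblank")) {
  gap <- match.arg(gap)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(channels >= 1L, n_blocks >= 1L, depthwise_kernel %% 2L == 1L,
            lr > 0, weight_decay >= 0, input_noise_sd >= 0,
            mixup_alpha >= 0, val_fraction >= 0, val_fraction < 0.5,
            patience >= 1L, epochs >= 1L, batch_size >= 1L)
  structure(list(channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks),
                 depthwise_kernel = as.integer(depthwise_kernel),
                 activation = activation, lr = lr,
                 lr_schedule = lr_schedule,
                 weight_decay = weight_decay,
                 input_noise_sd = input_noise_sd,
                 mixup_alpha = mixup_alpha,
                 val_fraction = val_fraction,
                 patience = as.integer(patience),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), gap = gap),
            class = "survmixer_config")
}

resolve_images <- function(images) {
  if (inherits(images, "PathwayImageSet"))
    list(images = images$images, layout = images$layout,
         ids = images$sample_ids)
  else stop("images must be a PathwayImageSet (see build_images)")
}

run_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit a pathway-image ConvMixer survival classifier
#'
#' Trains the network on pathway-patch images against binary horizon labels
#' (1 = died within the horizon, 0 = survived beyond it): patch embedding
#' (kernel = stride = patch side) with activation and batch normalization,
#' `n_blocks` ConvMixer blocks (depthwise 3x3 convolution with residual
#' connection, then pointwise 1x1 convolution, each followed by activation
#' and batch normalization), blank-patch masking, global average pooling,
#' and a single linear unit with sigmoid output. Blank grid slots are
#' re-zeroed after the embedding and after every block, so the model output
#' is provably invariant to any content placed inside blank patches.
#'
#' The loss is binary cross-entropy, minimized with Adam. Training is
#' deterministic given `config$seed`.
#'
#' @param images A `PathwayImageSet` from [build_images()].
#' @param labels Binary vector (0/1), one per sample, in sample order or
#'   named by sample id.
#' @param config A [survmixer_config()].
#' @return An object of class `survmixer` with components `params`,
#'   `config`, `layout`, `loss_history`, `fitted` (training-set
#'   probabilities), `labels`, and `n_params`.
#' @seealso [predict.survmixer()], [gradcam()], [repeated_cv()]
#' @export
survmixer <- function(images, labels, config = survmixer_config()) {
  ri <- resolve_images(images)
  n <- dim(ri$images)[1L]
  if (!is.null(names(labels))) {
    labels <- labels[ri$ids]
    if (anyNA(labels)) stop("labels missing for some samples")
  }
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per sample required")
  if (!all(labels %in% 0:1)) stop("labels must be 0/1")
  if (min(table(factor(labels, levels = 0:1))) < 2L)
    stop("need at least 2 samples in each class to train")

  layout <- ri$layout
  cfg <- config
  ps <- layout$patch_side
  Xp_all <- images_to_patchmat(ri$images, ps, layout$grid_side)
  P <- layout$grid_side^2

  run_with_seed(cfg$seed, {
    # optional stratified early-stopping split
    if (cfg$val_fraction > 0) {
      val_idx <- unlist(lapply(0:1, function(cl) {
        ix <- which(labels == cl)
        sample(ix, max(1L, round(length(ix) * cfg$val_fraction)))
      }))
      train_idx <- setdiff(seq_len(n), val_idx)
      if (min(table(factor(labels[train_idx], levels = 0:1))) < 2L ||
          length(unique(labels[val_idx])) < 2L)
        stop("cohort too small for the requested val_fraction")
      val_rows <- rep((val_idx - 1L) * P, each = P) + seq_len(P)
      Xp_val <- Xp_all[val_rows, , drop = FALSE]
    } else {
      train_idx <- seq_len(n)
      val_idx <- integer(0)
    }
    nt <- length(train_idx)

    params <- smx_init_params(cfg, ps)
    opt <- adam_init(params)
    losses <- numeric(0)
    val_history <- numeric(0)
    best <- list(auc = -Inf, params = NULL, epoch = 0L)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- if (cfg$lr_schedule == "cosine")
        cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs)) else cfg$lr
      ord <- train_idx[sample.int(nt)]
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, nt, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, nt)]
        m <- length(idx)
        rows <- rep((idx - 1L) * P, each = P) + seq_len(P)
        Xp <- Xp_all[rows, , drop = FALSE]
        y <- labels[idx]
        if (cfg$mixup_alpha > 0 && m >= 2L) {
          lam <- stats::rbeta(1L, cfg$mixup_alpha, cfg$mixup_alpha)
          perm <- sample.int(m)
          prows <- rep((perm - 1L) * P, each = P) + seq_len(P)
          Xp <- lam * Xp + (1 - lam) * Xp[prows, , drop = FALSE]
          y <- lam * y + (1 - lam) * y[perm]
        }
        if (cfg$input_noise_sd > 0)
          Xp <- Xp + stats::rnorm(length(Xp), 0, cfg$input_noise_sd)
        fw <- smx_forward_mat(params, Xp, m, layout, cfg,
                              train = TRUE, keep = TRUE)
        params <- fw$params      # batch-norm running stats advanced
        # mean BCE via log1p for stability
        z <- fw$z
        loss <- mean(ifelse(z > 0, z - y * z + log1p(exp(-z)),
                            -y * z + log1p(exp(z))))
        dz <- (fw$prob - y) / m
        grads <- smx_backward_mat(params, fw, layout, cfg, dz, train = TRUE)
        st <- adam_step(params, grads, opt, lr_ep,
                        weight_decay = cfg$weight_decay)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (cfg$val_fraction > 0) {
        val_prob <- smx_forward_mat(params, Xp_val, length(val_idx),
                                    layout, cfg)$prob
        vauc <- auc_score(val_prob, labels[val_idx])
        val_history[ep] <- vauc
        if (vauc > best$auc + 1e-9) {
          best <- list(auc = vauc, params = params, epoch = ep)
        } else if (ep - best$epoch >= cfg$patience) break
      }
    }
    if (cfg$val_fraction > 0 && !is.null(best$params)) params <- best$params
    fitted <- smx_forward_mat(params, Xp_all, n, layout, cfg)$prob
    structure(list(params = params, config = cfg, layout = layout,
                   loss_history = losses,
                   val_history = if (cfg$val_fraction > 0) val_history,
                   best_epoch = if (cfg$val_fraction > 0) best$epoch,
                   fitted = stats::setNames(fitted, ri$ids),
                   labels = stats::setNames(labels, ri$ids),
                   n_params = smx_count_params(params),
                   call = match.call()),
              class = "survmixer")
  })
}

#' Predict survival-class probabilities
#'
#' @param object A fitted [survmixer()] model.
#' @param images A `PathwayImageSet` with the same layout geometry.
#' @param type `"response"` (probability of death within the horizon) or
#'   `"link"` (pre-sigmoid logit).
#' @param ... Unused.
#' @return Named numeric vector, one value per sample, in input order.
#' @export
predict.survmixer <- function(object, images,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  ri <- resolve_images(images)
  check_layout_match(object$layout, ri$layout)
  Xp <- images_to_patchmat(ri$images, object$layout$patch_side,
                           object$layout$grid_side)
  fw <- smx_forward_mat(object$params, Xp, dim(ri$images)[1L],
                        object$layout, object$config)
  out <- if (type == "response") fw$prob else fw$z
  stats::setNames(out, ri$ids)
}

check_layout_match <- function(a, b) {
  if (a$patch_side != b$patch_side || a$grid_side != b$grid_side ||
      !identical(a$blank_slots, b$blank_slots))
    stop("image layout does not match the layout the model was trained on")
  invisible(TRUE)
}

#' @export
print.survmixer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("survmixer: %d-channel ConvMixer, %d block(s), %dx%d grid of %dx%d patches\n",
              cfg$channels, cfg$n_blocks, x$layout$grid_side,
              x$layout$grid_side, x$layout$patch_side, x$layout$patch_side))
  cat(sprintf("  %d parameters; trained %d epochs, final loss %.4f\n",
              x$n_params, cfg$epochs, utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.survmixer <- function(object, ...) {
  tab <- table(object$labels)
  auc <- tryCatch(auc_score(object$fitted, object$labels), error = function(e) NA)
  out <- list(config = object$config, n_params = object$n_params,
              class_counts = tab, train_auc = auc,
              loss_history = object$loss_history)
  class(out) <- "summary.survmixer"
  out
}

#' @export
print.summary.survmixer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Pathway-image ConvMixer (%d channels, %d blocks, %s, lr %g, %d epochs)\n",
              cfg$channels, cfg$n_blocks, cfg$activation, cfg$lr, cfg$epochs))
  cat(sprintf("  parameters: %d\n", x$n_params))
  cat(sprintf("  training samples: %d (label 0: %d, label 1: %d)\n",
              sum(x$class_counts), x$class_counts["0"], x$class_counts["1"]))
  cat(sprintf("  final training loss: %.4f; apparent (training) AUC: %.3f\n",
              utils::tail(x$loss_history, 1L), x$train_auc))
  invisible(x)
}

#' @export
coef.survmixer <- function(object, ...) {
  c(stats::setNames(object$params$w,
                    paste0("channel", seq_along(object$params$w))),
    intercept = object$params$b)
}

#' @export
residuals.survmixer <- function(object, ...) {
  object$labels - object$fitted
}

#' @export
plot.survmixer <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "mean binary cross-entropy",
                 main = "survmixer training loss", ...)
  invisible(x)
}

# ---- exported architecture stages (evaluation mode) ----

#' Patch embedding stage
#'
#' Applies the non-overlapping patch-embedding convolution (kernel = stride
#' = patch side), activation and batch normalization (inference statistics),
#' then zeroes blank slots. Each image patch maps to exactly one spatial
#' position of the feature map, so the embedding at a pathway slot depends
#' only on that pathway's patch.
#'
#' @param object A `survmixer` model (trained or freshly initialized via
#'   [survmixer_init()]).
#' @param images A `PathwayImageSet`, or a numeric array samples x H x W
#'   with H = W = `patch_side * grid_side`.
#' @return Feature-map array samples x channels x grid x grid.
#' @export
patch_embed <- function(object, images) {
  st <- forward_stages(object, images)
  st$embed
}

#' Apply one ConvMixer block
#'
#' Depthwise 3x3 convolution (stride 1, same padding) with residual
#' connection, then pointwise 1x1 convolution, each followed by activation
#' and batch normalization (inference statistics); blank slots re-zeroed.
#' Shape-preserving: output dimensions equal input dimensions.
#'
#' @param object A `survmixer` model supplying the block parameters.
#' @param fmap Feature-map array samples x channels x grid x grid.
#' @param block Block index (1-based).
#' @return Feature-map array of the same shape.
#' @export
convmixer_block <- function(object, fmap, block = 1L) {
  stopifnot(inherits(object, "survmixer"))
  cfg <- object$config
  if (block < 1L || block > cfg$n_blocks) stop("no such block: ", block)
  layout <- object$layout
  m <- array_to_fmap(fmap)
  n <- dim(fmap)[1L]
  gs <- layout$grid_side
  P <- gs^2
  act <- act_fun(cfg$activation)
  taps <- dw_tapmat(gs, cfg$depthwise_kernel)
  blk <- object$params$blocks[[block]]
  Zd <- dw_forward(m, blk$Wd, blk$bd, taps, n, P)
  bnd <- bn_forward(act$f(Zd), blk$bnd, train = FALSE)
  R <- m + bnd$out
  Zp <- sweep(R %*% blk$Wp, 2L, blk$bp, "+")
  bnp <- bn_forward(act$f(Zp), blk$bnp, train = FALSE)
  out <- mask_rows(bnp$out, blank_row_index(layout, n))
  fmap_to_array(out, n, gs)
}

#' Zero the blank slots of a feature map
#'
#' Sets every channel at the layout's blank grid positions to zero and
#' leaves all other positions untouched. Idempotent.
#'
#' @param fmap Feature-map array samples x channels x grid x grid (or
#'   channels x grid x grid for a single sample).
#' @param layout An `ImageLayout`.
#' @return Array of the same shape.
#' @export
mask_blank <- function(fmap, layout) {
  stopifnot(inherits(layout, "ImageLayout"))
  d <- dim(fmap)
  single <- length(d) == 3L
  if (single) fmap <- array(fmap, c(1L, d))
  gs <- layout$grid_side
  if (dim(fmap)[3L] != gs || dim(fmap)[4L] != gs)
    stop("feature map grid does not match layout grid")
  for (s in layout$blank_slots) {
    r <- (s - 1L) %/% gs + 1L
    cc <- (s - 1L) %% gs + 1L
    fmap[, , r, cc] <- 0
  }
  if (single) array(fmap, d) else fmap
}

#' Prediction head: pooling, linear unit, sigmoid
#'
#' Global average pooling over the grid positions of a feature map followed
#' by the model's single linear unit; `type = "link"` returns the
#' pre-sigmoid score, `type = "response"` the probability.
#'
#' @param object A `survmixer` model.
#' @param fmap Feature-map array samples x channels x grid x grid.
#' @param type `"response"` or `"link"`.
#' @return Numeric vector, one value per sample.
#' @export
head_score <- function(object, fmap, type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(inherits(object, "survmixer"))
  m <- array_to_fmap(fmap)
  n <- dim(fmap)[1L]
  gs <- object$layout$grid_side
  P <- gs^2
  div <- if (identical(object$config$gap, "nonblank"))
    P - length(object$layout$blank_slots) else P
  pooled <- rowsum(m, group = rep(seq_len(n), each = P), reorder = FALSE) / div
  z <- drop(pooled %*% object$params$w) + object$params$b
  if (type == "response") stats::plogis(z) else z
}

forward_stages <- function(object, images) {
  stopifnot(inherits(object, "survmixer"))
  if (inherits(images, "PathwayImageSet")) {
    check_layout_match(object$layout, images$layout)
    images <- images$images
  }
  if (length(dim(images)) == 2L)
    images <- array(images, c(1L, dim(images)))
  layout <- object$layout
  Xp <- images_to_patchmat(images, layout$patch_side, layout$grid_side)
  n <- dim(images)[1L]
  fw <- smx_forward_mat(object$params, Xp, n, layout, object$config,
                        keep = TRUE)
  out <- lapply(fw$stages, fmap_to_array, n = n, grid_side = layout$grid_side)
  out$forward <- fw
  out
}

#' Create an untrained model
#'
#' Initializes network parameters for a layout and configuration without
#' training, mainly for inspecting the architecture and for the toy models
#' used in gradient checks.
#'
#' @param layout An `ImageLayout`.
#' @param config A [survmixer_config()].
#' @return A `survmixer` object with random (seeded) weights.
#' @export
survmixer_init <- function(layout, config = survmixer_config()) {
  stopifnot(inherits(layout, "ImageLayout"))
  params <- run_with_seed(config$seed,
                          smx_init_params(config, layout$patch_side))
  structure(list(params = params, config = config, layout = layout,
                 loss_history = numeric(0), fitted = numeric(0),
                 labels = integer(0),
                 n_params = smx_count_params(params),
                 call = match.call()),
            class = "survmixer")
}
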