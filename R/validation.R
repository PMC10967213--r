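#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive sample scores higher than a randomly chosen negative one, ties
#' counted one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% 0:1)) stop("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified cross-validation with external validation
#'
#' Runs `repeats` rounds of stratified `k`-fold cross-validation: in every
#' fold the model is trained from scratch on the in-fold training portion
#' (about (k-1)/k of the samples), scored on the held-out fold (internal
#' AUC), and, if an external dataset is given, scored on the full external
#' set — which never contributes a single sample to training (external
#' AUC). With the defaults k = 5, repeats = 10 this yields 50 internal and
#' 50 external AUC values.
#'
#' Stratification guarantees both classes in every fold; model weights are
#' re-initialized per fold with a seed derived from the master seed, so the
#' whole procedure is reproducible.
#'
#' @param images A `PathwayImageSet` (training cohort).
#' @param labels Binary labels, one per sample.
#' @param config A [survmixer_config()]; its seed field is overridden
#'   per fold from `seed`.
#' @param k Folds (default 5).
#' @param repeats Repeats (default 10).
#' @param external Optional list with elements `images` (a
#'   `PathwayImageSet`) and `labels` for external validation.
#' @param seed Master seed.
#' @return A `ValidationResult`: data frame `folds` (repeat, fold,
#'   internal/external AUC), summary means and SDs, the per-repeat fold
#'   `assignments`, and the seed table.
#' @export
repeated_cv <- function(images, labels, config = survmixer_config(),
                        k = 5L, repeats = 10L, external = NULL, seed = 1L) {
  ri <- resolve_images(images)
  n <- dim(ri$images)[1L]
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (min(table(factor(labels, levels = 0:1))) < k)
    stop("each class needs at least k samples for stratified ", k, "-fold CV")
  if (!is.null(external)) {
    stopifnot(is.list(external), inherits(external$images, "PathwayImageSet"))
    check_layout_match(ri$layout, external$images$layout)
    ext_labels <- as.integer(external$labels)
  }

  res <- vector("list", repeats * k)
  assignments <- vector("list", repeats)
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- run_with_seed(seed + 7919L * r, {
      f <- integer(n)
      for (cl in 0:1) {
        idx <- which(labels == cl)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    assignments[[r]] <- fold_of
    for (fold in seq_len(k)) {
      row <- row + 1L
      test_idx <- which(fold_of == fold)
      train_idx <- which(fold_of != fold)
      fold_seed <- (seed + 104729L * r + 1299709L * fold) %% 2147483647L
      cfg <- config
      cfg$seed <- as.integer(fold_seed)
      tr_imgs <- subset_imageset(images, train_idx)
      te_imgs <- subset_imageset(images, test_idx)
      fit <- survmixer(tr_imgs, labels[train_idx], cfg)
      internal <- auc_score(predict(fit, te_imgs), labels[test_idx])
      ext_auc <- if (!is.null(external))
        auc_score(predict(fit, external$images), ext_labels) else NA_real_
      res[[row]] <- data.frame(repeat_ = r, fold = fold, seed = fold_seed,
                               internal_auc = internal,
                               external_auc = ext_auc)
    }
  }
  folds <- do.call(rbind, res)
  structure(list(
    folds = folds,
    internal = list(mean = mean(folds$internal_auc),
                    sd = stats::sd(folds$internal_auc)),
    external = if (!is.null(external))
      list(mean = mean(folds$external_auc),
           sd = stats::sd(folds$external_auc)) else NULL,
    assignments = assignments,
    sample_ids = ri$ids,
    k = k, repeats = repeats, seed = seed
  ), class = "ValidationResult")
}

#' Subset a pathway image set by sample
#'
#' @param image_set A `PathwayImageSet`.
#' @param idx Integer or logical sample index.
#' @return A `PathwayImageSet` with the selected samples.
#' @export
subset_imageset <- function(image_set, idx) {
  stopifnot(inherits(image_set, "PathwayImageSet"))
  structure(list(images = image_set$images[idx, , , drop = FALSE],
                 sample_ids = image_set$sample_ids[idx],
                 layout = image_set$layout),
            class = "PathwayImageSet")
}

#' @export
print.ValidationResult <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats (%d folds)\n", x$k, x$repeats,
              nrow(x$folds)))
  cat(sprintf("  internal AUC: %.4f +/- %.4f\n", x$internal$mean,
              x$internal$sd))
  if (!is.null(x$external))
    cat(sprintf("  external AUC: %.4f +/- %.4f\n", x$external$mean,
                x$external$sd))
  invisible(x)
}

#' Serialize a validation result as JSON
#'
#' @param result A `ValidationResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(result, path) {
  stopifnot(inherits(result, "ValidationResult"))
  jsonlite::write_json(
    list(k = result$k, repeats = result$repeats, seed = result$seed,
         internal = result$internal, external = result$external,
         folds = result$folds),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
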