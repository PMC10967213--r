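#' Grad-CAM activation maps
#'
#' Gradient-weighted class activation mapping on a trained model. For the
#' chosen layer's feature maps `A^n`, the per-channel importance is the
#' spatial global average of the gradients of the pre-sigmoid class score
#' `y^c` with respect to `A^n` (divided by `Z`, the number of positions per
#' map — 49 in the default geometry), and the activation map is the ReLU of
#' the importance-weighted sum of the channel maps. One map per sample.
#'
#' Gradients are computed by exact backpropagation through the network in
#' inference mode, so per-sample maps are independent of batch composition.
#'
#' @param object A trained [survmixer()] model.
#' @param images A `PathwayImageSet` (or image array).
#' @param layer Stage whose feature maps are used: `"embed"`, `"block1"`,
#'   ..., default the output of the last ConvMixer block (after masking).
#' @param target Class whose score is differentiated: `"death"` (the
#'   positive class, default) uses the logit, `"survival"` its negation.
#' @return An `ActivationMaps` object: `maps` (array samples x grid x grid,
#'   all entries >= 0), `alpha` (samples x channels importances), `Z`,
#'   `layer`, `target`, `sample_ids`.
#' @export
gradcam <- function(object, images, layer = NULL,
                    target = c("death", "survival")) {
  target <- match.arg(target)
  stopifnot(inherits(object, "survmixer"))
  if (length(object$loss_history) == 0L &&
      is.null(attr(object, "allow_untrained")))
    warning("model appears untrained; activation maps reflect random weights")
  if (is.null(layer)) layer <- paste0("block", object$config$n_blocks)
  ids <- if (inherits(images, "PathwayImageSet")) images$sample_ids else NULL
  st <- forward_stages(object, images)
  if (is.null(st$forward$stages[[layer]]))
    stop("unknown layer: ", layer, " (available: ",
         paste(names(st$forward$stages), collapse = ", "), ")")
  fw <- st$forward
  n <- fw$n
  layout <- object$layout
  gs <- layout$grid_side
  Z <- gs * gs
  sgn <- if (target == "death") 1 else -1
  dz <- rep(sgn, n)
  dA <- smx_backward_mat(object$params, fw, layout, object$config, dz,
                         train = FALSE, upto = layer)
  A <- fw$stages[[layer]]
  grp <- rep(seq_len(n), each = Z)
  alpha <- rowsum(dA, group = grp, reorder = FALSE) / Z
  cam_rows <- rowSums(A * alpha[grp, , drop = FALSE])
  cam_rows <- pmax(cam_rows, 0)
  maps <- array(0, dim = c(n, gs, gs))
  for (p in seq_len(Z)) {
    r <- (p - 1L) %/% gs + 1L
    cc <- (p - 1L) %% gs + 1L
    maps[, r, cc] <- cam_rows[(0:(n - 1)) * Z + p]
  }
  structure(list(maps = maps, alpha = alpha, Z = Z, layer = layer,
                 target = target, sample_ids = ids, layout = layout),
            class = "ActivationMaps")
}

#' @export
print.ActivationMaps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("ActivationMaps: %d samples, %dx%d grid (Z = %d), layer %s, target class %s\n",
              d[1L], d[2L], d[3L], x$Z, x$layer, x$target))
  invisible(x)
}

#' Per-pathway activation values
#'
#' Reads, for every sample, the scalar Grad-CAM activation at each
#' pathway's grid slot (after patch embedding one slot corresponds to one
#' pathway). Blank slots are excluded.
#'
#' @param maps An `ActivationMaps` object, or an array samples x grid x grid.
#' @param layout An `ImageLayout`; taken from `maps` when omitted.
#' @return Matrix samples x pathways, columns named by pathway.
#' @export
pathway_activations <- function(maps, layout = NULL) {
  if (inherits(maps, "ActivationMaps")) {
    if (is.null(layout)) layout <- maps$layout
    arr <- maps$maps
  } else arr <- maps
  stopifnot(inherits(layout, "ImageLayout"))
  gs <- layout$grid_side
  if (dim(arr)[2L] != gs || dim(arr)[3L] != gs)
    stop("activation map grid does not match layout")
  n <- dim(arr)[1L]
  out <- matrix(0, n, length(layout$pathway_slots),
                dimnames = list(NULL, layout$pathways))
  for (j in seq_along(layout$pathway_slots)) {
    s <- layout$pathway_slots[j]
    r <- (s - 1L) %/% gs + 1L
    cc <- (s - 1L) %% gs + 1L
    out[, j] <- arr[, r, cc]
  }
  out
}

#' Key-pathway testing by Wilcoxon rank-sum with Bonferroni correction
#'
#' Compares, per pathway, the activation values of the two ground-truth
#' label groups with a two-sided Wilcoxon rank-sum (Mann-Whitney) test —
#' exact when both groups have at most 10 samples and no ties, otherwise
#' the normal approximation with continuity and tie correction. Raw
#' p-values are Bonferroni-corrected over the number of pathways tested;
#' a pathway is flagged significant when its corrected p < `alpha`.
#'
#' @param activations Matrix samples x pathways (see
#'   [pathway_activations()]).
#' @param labels Binary 0/1 ground-truth labels, one per sample.
#' @param alpha Significance level on the corrected p-value.
#' @return Data frame: pathway, p_raw, p_bonferroni, significant.
#' @export
wilcoxon_keypathways <- function(activations, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  stopifnot(nrow(activations) == length(labels), all(labels %in% 0:1))
  g1 <- labels == 1L
  if (!any(g1) || all(g1)) stop("both label groups must be non-empty")
  m <- ncol(activations)
  p_raw <- vapply(seq_len(m), function(j) {
    x <- activations[g1, j]
    y <- activations[!g1, j]
    # fully tied data carry no rank evidence (degenerate z = 0/0 otherwise)
    if (length(unique(c(x, y))) == 1L) return(1)
    exact <- length(x) <= 10L && length(y) <= 10L &&
      !anyDuplicated(c(x, y))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    if (is.na(p)) 1 else p
  }, 0)
  p_bonf <- pmin(1, p_raw * m)
  data.frame(pathway = colnames(activations) %||% paste0("pw", seq_len(m)),
             p_raw = p_raw, p_bonferroni = p_bonf,
             significant = p_bonf < alpha,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-based single-sample pathway scores
#'
#' Per-sample enrichment score per pathway in the gene set variation
#' analysis family: expression values are converted to gene-wise empirical
#' cumulative ranks across samples, genes are ranked within each sample,
#' and a Kolmogorov-Smirnov-like running sum contrasts member against
#' non-member genes; the score is the signed sum of the maximum positive
#' and maximum negative deviation (the "maxdiff" form), so coordinated
#' up-regulation gives scores near +1, down-regulation near -1, and
#' unstructured sets scores near 0.
#'
#' Pathway genes absent from the matrix are dropped with a warning;
#' a pathway with no matched genes gets `NA` scores and a warning.
#'
#' @param x Numeric expression matrix, samples x genes, with dimnames.
#' @param collection A [pathway_collection()].
#' @return Matrix pathways x samples of scores in \[-1, 1\].
#' @export
gsva_scores <- function(x, collection) {
  x <- as.matrix(x)
  stopifnot(inherits(collection, "PathwayCollection"))
  if (nrow(x) < 3L) stop("need at least 3 samples for pathway scoring")
  if (is.null(colnames(x))) stop("expression matrix needs gene names")
  n <- nrow(x); G <- ncol(x)
  # gene-wise ECDF value of each sample, then within-sample gene ranking
  ecdf_mat <- apply(x, 2L, function(col) rank(col, ties.method = "average")) / n
  # rank 1 = highest ECDF value within the sample; ties broken by column
  # order for determinism
  ord_rank <- t(apply(ecdf_mat, 1L, function(row)
    rank(-row, ties.method = "first")))
  scores <- matrix(NA_real_, length(collection$names), n,
                   dimnames = list(collection$names, rownames(x)))
  for (j in seq_along(collection$names)) {
    genes <- collection$genes[[j]]
    idx <- match(genes, colnames(x))
    if (all(is.na(idx))) {
      warning("pathway ", collection$names[j],
              " has no genes in the matrix; scores undefined")
      next
    }
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " gene(s) of pathway ", collection$names[j],
              " absent from the expression matrix; dropped")
      idx <- idx[!is.na(idx)]
    }
    k <- length(idx)
    if (k == G) stop("pathway covers every gene; score undefined")
    for (i in seq_len(n)) {
      q <- sort(ord_rank[i, idx])
      iseq <- seq_len(k)
      d_at <- iseq / k - (q - iseq) / (G - k)          # right after hit i
      d_before <- (iseq - 1) / k - (q - iseq) / (G - k) # right before hit i
      scores[j, i] <- max(0, max(d_at)) + min(0, min(d_before))
    }
  }
  scores
}

#' Median-split Kaplan-Meier comparison with log-rank test
#'
#' Splits samples into a high group (score strictly above the median) and a
#' low group (score at or below it), estimates the product-limit survival
#' curve of each group, and tests the survival difference with the
#' two-group log-rank test.
#'
#' @param scores Numeric per-sample score (e.g. one pathway's row of
#'   [gsva_scores()]).
#' @param os_time Overall-survival times.
#' @param event Event indicator, 1 = death.
#' @return A `KMComparison`: `group` factor, `curves` (data frame of step
#'   points: group, time, surv, n.risk, n.event), `logrank_p`, `chisq`.
#' @export
km_logrank <- function(scores, os_time, event) {
  stopifnot(length(scores) == length(os_time),
            length(os_time) == length(event))
  med <- stats::median(scores)
  group <- factor(ifelse(scores > med, "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(group)) < 2L)
    stop("degenerate median split: all scores on one side of the median")
  if (min(table(group)) < 2L)
    stop("need at least 2 samples per group after the median split")
  sv <- survival::Surv(os_time, event)
  sd <- survival::survdiff(sv ~ group)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(sv ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event)
  structure(list(group = group, curves = curves,
                 logrank_p = p, chisq = sd$chisq, median = med),
            class = "KMComparison")
}

#' @export
print.KMComparison <- function(x, ...) {
  cat(sprintf("Median-split KM comparison: %d low / %d high, log-rank p = %.4g\n",
              sum(x$group == "low"), sum(x$group == "high"), x$logrank_p))
  invisible(x)
}

#' @export
plot.KMComparison <- function(x, ...) {
  lo <- x$curves[x$curves$group == "low", ]
  hi <- x$curves[x$curves$group == "high", ]
  graphics::plot(stats::stepfun(lo$time, c(1, lo$surv)), do.points = FALSE,
                 xlim = range(x$curves$time), ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability",
                 main = sprintf("log-rank p = %.3g", x$logrank_p), ...)
  graphics::lines(stats::stepfun(hi$time, c(1, hi$surv)), do.points = FALSE,
                  col = 2)
  graphics::legend("bottomleft", c("low", "high"), col = 1:2, lty = 1)
  invisible(x)
}

#' Full interpretation chain: key pathways with survival validation
#'
#' Runs the complete interpretation workflow on a trained model:
#' Grad-CAM activation maps for every sample (positive class), per-pathway
#' activations, Wilcoxon rank-sum tests between the two label groups with
#' Bonferroni correction, and — for each significant (key) pathway —
#' rank-based pathway scoring followed by a median-split Kaplan-Meier
#' comparison with log-rank test.
#'
#' @param model A trained [survmixer()] model.
#' @param images A `PathwayImageSet` of the samples to interpret.
#' @param labels Ground-truth binary labels for those samples.
#' @param expr Expression matrix (samples x genes) for pathway scoring.
#' @param collection The [pathway_collection()] behind the layout.
#' @param os_time,event Survival records for the KM comparison.
#' @param alpha Significance level on corrected p-values.
#' @param layer Grad-CAM layer, see [gradcam()].
#' @return A `KeyPathwayReport`: `tests` (the Wilcoxon table), `key`
#'   (significant pathway names), `km` (named list of `KMComparison`
#'   objects for key pathways), `activations`, `gsva`.
#' @export
key_pathway_report <- function(model, images, labels, expr, collection,
                               os_time, event, alpha = 0.05, layer = NULL) {
  maps <- gradcam(model, images, layer = layer, target = "death")
  act <- pathway_activations(maps)
  tests <- wilcoxon_keypathways(act, labels, alpha = alpha)
  sc <- gsva_scores(expr, collection)
  key <- tests$pathway[tests$significant]
  km <- list()
  for (pw in key) {
    km[[pw]] <- tryCatch(km_logrank(sc[pw, ], os_time, event),
                         error = function(e) e)
  }
  structure(list(tests = tests, key = key, km = km,
                 activations = act, gsva = sc, alpha = alpha),
            class = "KeyPathwayReport")
}

#' @export
print.KeyPathwayReport <- function(x, ...) {
  cat(sprintf("KeyPathwayReport: %d pathways tested, %d significant (Bonferroni p < %g)\n",
              nrow(x$tests), length(x$key), x$alpha))
  if (length(x$key)) {
    for (pw in x$key) {
      p <- if (inherits(x$km[[pw]], "KMComparison"))
        sprintf("log-rank p = %.3g", x$km[[pw]]$logrank_p) else "KM unavailable"
      cat(sprintf("  %s: corrected p = %.3g, %s\n", pw,
                  x$tests$p_bonferroni[x$tests$pathway == pw], p))
    }
  }
  invisible(x)
}

#' Serialize a key-pathway report
#'
#' Writes the test table as TSV and the full report (tests, key pathways,
#' log-rank p-values, KM step curves) as JSON.
#'
#' @param report A `KeyPathwayReport`.
#' @param path_json JSON output path.
#' @param path_tsv Optional TSV output path for the test table.
#' @return `path_json`, invisibly.
#' @export
write_report_json <- function(report, path_json, path_tsv = NULL) {
  stopifnot(inherits(report, "KeyPathwayReport"))
  km <- lapply(report$km, function(k) {
    if (!inherits(k, "KMComparison")) return(NULL)
    list(logrank_p = k$logrank_p, chisq = k$chisq, curves = k$curves)
  })
  jsonlite::write_json(list(tests = report$tests, key = report$key, km = km),
                       path_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(path_tsv))
    utils::write.table(report$tests, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(path_json)
}
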