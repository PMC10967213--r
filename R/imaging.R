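#' Per-gene min-max normalization
#'
#' Rescales every gene (column) to \[0, 1\] over the samples:
#' `(X - X_min) / (X_max - X_min)`, where the minimum and maximum are taken
#' per gene across all samples of the matrix. A gene that is constant across
#' samples maps to all zeros rather than being dropped, so downstream image
#' geometry never depends on the data. Idempotent: a second application is
#' a no-op.
#'
#' Datasets (e.g. a training cohort and an external validation cohort) are
#' normalized independently, each with its own per-gene ranges.
#'
#' @param x Numeric matrix, samples in rows, genes in columns, with dimnames.
#' @return Matrix of the same shape with all values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  bad <- which(!apply(x, 2L, function(col) all(is.finite(col))))
  if (length(bad)) {
    nm <- colnames(x)[bad[1L]]
    stop("non-finite expression values in gene ",
         if (is.null(nm)) bad[1L] else nm)
  }
  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  out <- sweep(x, 2L, rng[1L, ], "-")
  const <- span == 0
  span[const] <- 1           # constant genes: numerator is already 0
  out <- sweep(out, 2L, span, "/")
  out[, const] <- 0
  out
}

#' Build the patch-grid layout for a pathway collection
#'
#' Pathways are assigned row-major to the first slots of a
#' `grid_side` x `grid_side` grid of `patch_side` x `patch_side` patches;
#' the remaining trailing slots are blank patches that stay at zero for
#' every sample and are excluded from all statistics. With the defaults
#' (7 and 7) a 40-pathway collection occupies the first 40 slots and leaves
#' nine blank patches: the last two of the second-to-last row and the whole
#' last row.
#'
#' @param collection A [pathway_collection()].
#' @param patch_side Patch side in pixels (default 7); each patch holds up
#'   to `patch_side^2` genes.
#' @param grid_side Grid side in patches (default 7).
#' @return An `ImageLayout`: pathway slot assignment (row-major slot indices),
#'   blank slots, and `pad_len = patch_side^2`.
#' @export
build_layout <- function(collection, patch_side = 7L, grid_side = 7L) {
  stopifnot(inherits(collection, "PathwayCollection"))
  patch_side <- as.integer(patch_side); grid_side <- as.integer(grid_side)
  n_pw <- length(collection$names)
  n_slots <- grid_side^2
  if (n_pw > n_slots)
    stop(sprintf("layout too small: %d pathways need a grid of at least %d slots (have %d); increase grid_side to >= %d",
                 n_pw, n_pw, n_slots, ceiling(sqrt(n_pw))))
  mx <- max_pathway_size(collection)
  if (mx > patch_side^2)
    stop(sprintf("patch too small: longest pathway has %d genes but a patch holds %d; increase patch_side to >= %d",
                 mx, patch_side^2, ceiling(sqrt(mx))))
  structure(list(
    patch_side = patch_side,
    grid_side = grid_side,
    pathways = collection$names,
    pathway_slots = seq_len(n_pw),
    blank_slots = if (n_pw < n_slots) (n_pw + 1L):n_slots else integer(0),
    pad_len = patch_side * patch_side
  ), class = "ImageLayout")
}

#' @export
print.ImageLayout <- function(x, ...) {
  cat(sprintf("ImageLayout: %dx%d grid of %dx%d patches (%dx%d image), %d pathway slots, %d blank\n",
              x$grid_side, x$grid_side, x$patch_side, x$patch_side,
              x$grid_side * x$patch_side, x$grid_side * x$patch_side,
              length(x$pathway_slots), length(x$blank_slots)))
  invisible(x)
}

# slot index (1-based, row-major) -> (row, col) in the patch grid
slot_rc <- function(slot, grid_side) {
  c(row = (slot - 1L) %/% grid_side + 1L, col = (slot - 1L) %% grid_side + 1L)
}

#' Pathway expression vector with zero padding
#'
#' Gene values in pathway order; genes missing from the sample contribute 0
#' at their position, and trailing zeros pad the vector to `pad_len` (the
#' patch capacity). With defaults the longest 46-gene pathway becomes a
#' 49-long vector with 3 trailing zeros.
#'
#' @param sample_expr Named numeric vector of expression values for one sample.
#' @param genes Character vector: the pathway's genes in order.
#' @param pad_len Target length, at least `length(genes)`.
#' @return Numeric vector of length `pad_len`.
#' @export
pathway_vector <- function(sample_expr, genes, pad_len) {
  if (pad_len < length(genes))
    stop("pad_len (", pad_len, ") shorter than pathway (", length(genes), " genes)")
  v <- numeric(pad_len)
  idx <- match(genes, names(sample_expr))
  hit <- !is.na(idx)
  v[seq_along(genes)][hit] <- sample_expr[idx[hit]]
  v
}

#' Reshape a padded pathway vector into a square patch
#'
#' Row-major: element `k` lands at pixel `(k %/% s, k %% s)` (0-based).
#'
#' @param v Numeric vector of length `s^2`.
#' @param s Patch side in pixels.
#' @return An `s` x `s` matrix.
#' @export
vector_to_patch <- function(v, s) {
  if (length(v) != s^2)
    stop("vector length ", length(v), " != patch size ", s^2)
  matrix(v, nrow = s, ncol = s, byrow = TRUE)
}

#' Build per-sample pathway images
#'
#' Converts a (normalized) expression matrix into one square image per
#' sample: each pathway's padded expression vector is reshaped row-major
#' into a `patch_side` x `patch_side` patch and placed at the pathway's
#' grid slot; trailing blank slots stay all-zero. Genes present in the
#' matrix but in no pathway are ignored; pathway genes absent from the
#' matrix are zero-filled.
#'
#' @param x Numeric matrix, samples x genes, with dimnames. Values are
#'   expected in \[0, 1\]; set `normalize = TRUE` to apply
#'   [minmax_normalize()] first.
#' @param collection A [pathway_collection()].
#' @param patch_side,grid_side Image geometry, see [build_layout()].
#' @param normalize Apply min-max normalization before imaging.
#' @return A `PathwayImageSet`: `images` (array samples x H x W with
#'   H = W = `grid_side * patch_side`), `sample_ids`, and `layout`.
#' @examples
#' pc <- pathway_collection(list(p1 = c("A", "B"), p2 = c("C")))
#' x <- matrix(runif(6), 2, 3, dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' imgs <- build_images(x, pc, patch_side = 2, grid_side = 2)
#' dim(imgs$images)
#' @export
build_images <- function(x, collection, patch_side = 7L, grid_side = 7L,
                         normalize = FALSE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) stop("expression matrix needs gene column names")
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(x))) stop("duplicate gene ids")
  if (normalize) x <- minmax_normalize(x)
  layout <- build_layout(collection, patch_side, grid_side)
  ps <- layout$patch_side; gs <- layout$grid_side
  side <- ps * gs
  n <- nrow(x)
  images <- array(0, dim = c(n, side, side),
                  dimnames = list(rownames(x), NULL, NULL))
  gene_idx <- lapply(collection$genes, match, table = colnames(x))
  for (s in seq_along(layout$pathway_slots)) {
    rc <- slot_rc(layout$pathway_slots[s], gs)
    rows <- (rc["row"] - 1L) * ps + seq_len(ps)
    cols <- (rc["col"] - 1L) * ps + seq_len(ps)
    idx <- gene_idx[[s]]
    hit <- !is.na(idx)
    vals <- matrix(0, nrow = n, ncol = layout$pad_len)
    vals[, seq_along(idx)[hit]] <- x[, idx[hit], drop = FALSE]
    # fill patch row-major: vector position k -> pixel (k div ps, k mod ps)
    for (a in seq_len(ps)) {
      images[, rows[a], cols] <- vals[, (a - 1L) * ps + seq_len(ps)]
    }
  }
  structure(list(images = images, sample_ids = rownames(x), layout = layout),
            class = "PathwayImageSet")
}

#' @export
print.PathwayImageSet <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("PathwayImageSet: %d samples, %dx%d images, %d pathway / %d blank patches\n",
              d[1L], d[2L], d[3L], length(x$layout$pathway_slots),
              length(x$layout$blank_slots)))
  invisible(x)
}

#' Extract one pathway's patch from an image set
#'
#' Inverse of the placement done by [build_images()]: returns, for each
#' sample, the padded pathway vector read back out of the image (row-major
#' within the pathway's patch).
#'
#' @param image_set A `PathwayImageSet`.
#' @param pathway Pathway name or index.
#' @return Matrix samples x `pad_len`.
#' @export
extract_pathway_vectors <- function(image_set, pathway) {
  stopifnot(inherits(image_set, "PathwayImageSet"))
  layout <- image_set$layout
  if (is.character(pathway)) pathway <- match(pathway, layout$pathways)
  if (is.na(pathway) || pathway < 1L || pathway > length(layout$pathway_slots))
    stop("unknown pathway")
  ps <- layout$patch_side
  rc <- slot_rc(layout$pathway_slots[pathway], layout$grid_side)
  rows <- (rc["row"] - 1L) * ps + seq_len(ps)
  cols <- (rc["col"] - 1L) * ps + seq_len(ps)
  n <- dim(image_set$images)[1L]
  out <- matrix(0, n, layout$pad_len)
  for (a in seq_len(ps))
    out[, (a - 1L) * ps + seq_len(ps)] <- image_set$images[, rows[a], cols]
  rownames(out) <- image_set$sample_ids
  out
}

#' Serialize an image layout as JSON
#'
#' Writes the geometry, the pathway-to-slot map and the blank slots as a
#' JSON sidecar so persisted image tensors stay interpretable.
#'
#' @param layout An `ImageLayout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "ImageLayout"))
  obj <- list(
    patch_side = layout$patch_side, grid_side = layout$grid_side,
    pad_len = layout$pad_len,
    pathway_slots = as.list(stats::setNames(layout$pathway_slots, layout$pathways)),
    blank_slots = layout$blank_slots
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
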