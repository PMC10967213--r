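#' Construct a pathway collection
#'
#' A `PathwayCollection` is an ordered list of named gene sets. The order of
#' the pathways determines which patch of the image each pathway occupies,
#' and the order of genes within a pathway determines the order of pixels
#' within its patch, so both orders are preserved exactly as given.
#'
#' @param genes Named list of character vectors; names are pathway names,
#'   elements are gene symbols in pathway order.
#' @return An object of class `PathwayCollection`.
#' @examples
#' pc <- pathway_collection(list(pw1 = c("A", "B"), pw2 = c("B", "C")))
#' max_pathway_size(pc)
#' union_genes(pc)
#' @export
pathway_collection <- function(genes) {
  if (!is.list(genes) || length(genes) == 0L)
    stop("no pathways: a collection needs at least one pathway")
  nm <- names(genes)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every pathway must be named")
  if (anyDuplicated(nm))
    stop("duplicate pathway name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  genes <- lapply(genes, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    if (length(g) == 0L) stop("pathway with no genes")
    if (anyDuplicated(g))
      stop("duplicate gene symbol within a pathway: ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
    g
  })
  structure(list(names = nm, genes = genes), class = "PathwayCollection")
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated gene-set carrier used by MSigDB and most
#' enrichment tools: one set per line, fields `name`, `description`,
#' then gene symbols. The description field is discarded. Pathway order is
#' file order; gene order is line order. Gene symbols are stripped of
#' surrounding whitespace and matched case-sensitively downstream.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no pathways: empty GMT file ", path)
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("GMT parse error: line ", lineno[bad[1L]],
         " has fewer than 3 tab-separated fields")
  nm <- vapply(parts, `[[`, "", 1L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  names(genes) <- nm
  pathway_collection(genes)
}

#' Write a pathway collection as GMT
#'
#' @param collection A `PathwayCollection`.
#' @param path Output file path.
#' @param description Description field written for every set (GMT column 2).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  stopifnot(inherits(collection, "PathwayCollection"))
  lines <- vapply(seq_along(collection$names), function(i) {
    paste(c(collection$names[i], description, collection$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a two-column long-format table
#'
#' Accepted alternate input: a TSV/CSV with columns `pathway` and `gene`,
#' one membership per row. Row order defines pathway and gene order.
#'
#' @param path Path to the table.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A [pathway_collection()].
#' @export
read_pathway_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pathway", "gene")
  if (!all(need %in% names(df)))
    stop("long-format gene-set table needs columns 'pathway' and 'gene'")
  pws <- unique(df$pathway)
  genes <- lapply(pws, function(p) df$gene[df$pathway == p])
  names(genes) <- pws
  pathway_collection(genes)
}

#' Largest pathway in a collection
#'
#' @param collection A `PathwayCollection`.
#' @return Integer: the maximum number of genes over pathways.
#' @export
max_pathway_size <- function(collection) {
  stopifnot(inherits(collection, "PathwayCollection"))
  max(vapply(collection$genes, length, 1L))
}

#' Union of genes over a collection
#'
#' Deduplicated union in first-occurrence order. A gene may belong to
#' several pathways (KEGG pathways overlap); it appears once here.
#'
#' @param collection A `PathwayCollection`.
#' @return Character vector of gene symbols.
#' @export
union_genes <- function(collection) {
  stopifnot(inherits(collection, "PathwayCollection"))
  unique(unlist(collection$genes, use.names = FALSE))
}

#' @export
print.PathwayCollection <- function(x, ...) {
  sizes <- vapply(x$genes, length, 1L)
  cat(sprintf("PathwayCollection: %d pathways, %d unique genes (sizes %d-%d)\n",
              length(x$names), length(union_genes(x)), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.PathwayCollection <- function(x) length(x$names)
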