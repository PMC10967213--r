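#' Read an expression matrix
#'
#' Samples in rows, genes in columns; the first column holds sample ids and
#' the header row gene symbols. Tab- or comma-separated (guessed from the
#' extension, or set `sep`).
#'
#' @param path Input file.
#' @param sep Field separator; default guesses `","` for `.csv`, `"\t"`
#'   otherwise.
#' @return Numeric matrix with sample rownames and gene colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids in ", path)
  m
}

#' Write an expression matrix
#'
#' @param x Numeric matrix, samples x genes, with dimnames.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `sample_id`, `os_time`, `os_event` (or `event`).
#'
#' @param path Input file.
#' @param sep Field separator; guessed from the extension by default.
#' @return Data frame with columns sample_id, os_time, event.
#' @export
read_survival <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ev <- if ("os_event" %in% names(df)) "os_event" else "event"
  need <- c("sample_id", "os_time", ev)
  if (!all(need %in% names(df)))
    stop("survival table needs columns sample_id, os_time, os_event")
  data.frame(sample_id = as.character(df$sample_id),
             os_time = as.numeric(df$os_time),
             event = as.integer(df[[ev]]), stringsAsFactors = FALSE)
}

#' Write a survival table
#'
#' @param records Data frame with sample_id, os_time, event.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_survival <- function(records, path) {
  utils::write.table(
    data.frame(sample_id = records$sample_id, os_time = records$os_time,
               os_event = records$event),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
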