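#' Horizon presets in days
#'
#' Named overall-survival horizons: `short` = 1 year (365 days),
#' `mid` = 3 years (1095), `long` = 5 years (1825). Survival times must be
#' supplied in the same unit as the horizon; a warning is raised when the
#' magnitudes of the observed times suggest a unit mismatch.
#'
#' @param preset One of `"short"`, `"mid"`, `"long"`.
#' @return Horizon in days.
#' @export
horizon_days <- function(preset = c("short", "mid", "long")) {
  preset <- match.arg(preset)
  c(short = 365, mid = 1095, long = 1825)[[preset]]
}

#' Binary survival labels for a horizon
#'
#' Recasts overall survival as classification at a chosen horizon:
#' a sample observed beyond the horizon is labeled 0 (survived), a death
#' within the horizon is labeled 1, and a sample censored at or before the
#' horizon carries no information about the outcome and is dropped.
#'
#' Boundary convention: surviving the horizon requires `os_time` strictly
#' greater than `horizon`, so a record with `os_time == horizon` is label 1
#' if it is a death and dropped if censored. Set `boundary = "survived"` to
#' count an observation exactly at the horizon as label 0 instead.
#'
#' @param os_time Numeric vector of overall-survival times (>= 0), same unit
#'   as `horizon`.
#' @param event Integer vector, 1 = death observed, 0 = censored.
#' @param horizon Positive scalar horizon.
#' @param sample_ids Optional ids; defaults to names of `os_time` or indices.
#' @param boundary `"strict"` (default; survival must exceed the horizon) or
#'   `"survived"` (time equal to the horizon counts as survived).
#' @return A `LabeledCohort`: `kept` ids, `labels` (named 0/1 vector),
#'   `dropped` ids, and the `horizon`.
#' @examples
#' lc <- label_samples(c(4, 2, 6), c(0, 1, 1), horizon = 5)
#' lc$labels   # death at 2 -> 1, alive at 6 -> 0; censored at 4 dropped
#' @export
label_samples <- function(os_time, event, horizon, sample_ids = NULL,
                          boundary = c("strict", "survived")) {
  boundary <- match.arg(boundary)
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("horizon must be a positive scalar")
  os_time <- as.numeric(os_time)
  event <- as.integer(event)
  if (length(os_time) != length(event))
    stop("os_time and event lengths differ")
  if (any(!is.finite(os_time)) || any(os_time < 0))
    stop("os_time must be finite and >= 0")
  if (!all(event %in% c(0L, 1L)))
    stop("event must be 0 (censored) or 1 (death)")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(names(os_time))) names(os_time)
                  else as.character(seq_along(os_time))
  if (length(sample_ids) != length(os_time)) stop("sample_ids length mismatch")
  if (median(os_time) > 50 * horizon || (horizon > 50 * max(os_time) && max(os_time) > 0))
    warning("os_time and horizon magnitudes differ strongly; check time units (days vs months vs years)")

  survived <- if (boundary == "strict") os_time > horizon else os_time >= horizon
  died_within <- !survived & event == 1L
  dropped <- !survived & event == 0L

  labels <- rep(NA_integer_, length(os_time))
  labels[survived] <- 0L
  labels[died_within] <- 1L
  keep <- !dropped
  structure(list(
    kept = sample_ids[keep],
    labels = stats::setNames(labels[keep], sample_ids[keep]),
    dropped = sample_ids[dropped],
    horizon = horizon,
    boundary = boundary
  ), class = "LabeledCohort")
}

#' @export
print.LabeledCohort <- function(x, ...) {
  cat(sprintf("LabeledCohort: horizon %g, %d kept (%d died within / %d survived beyond), %d dropped (censored before horizon)\n",
              x$horizon, length(x$kept), sum(x$labels == 1L),
              sum(x$labels == 0L), length(x$dropped)))
  invisible(x)
}
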