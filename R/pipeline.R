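#' Write a synthetic dataset to disk
#'
#' Generates a collection and cohort from a [synthetic_spec()] and writes
#' the same file formats the real-data readers consume: a GMT gene-set
#' file, an expression TSV, a survival TSV, and a ground-truth JSON
#' (effect pathways, risk scores, generator settings).
#'
#' @param spec A [synthetic_spec()] (or a list of its arguments).
#' @param dir Output directory, created if missing.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_dataset <- function(spec, dir) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- generate_collection(spec)
  cohort <- generate_cohort(spec, pc)
  paths <- list(
    genesets = file.path(dir, "pathways.gmt"),
    expression = file.path(dir, "expression.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_gmt(pc, paths$genesets)
  write_expression(cohort$expression, paths$expression)
  write_survival(cohort$records, paths$survival)
  jsonlite::write_json(
    list(effect_pathways = cohort$truth$effect_pathways,
         effect_size = cohort$truth$effect_size,
         censor_t_max = cohort$truth$censor_t_max,
         risk = unname(cohort$truth$risk),
         spec = unclass(cohort$truth$spec), seed = spec$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

default_run_config <- function() {
  list(expression = NULL, survival = NULL, genesets = NULL,
       external_expression = NULL, external_survival = NULL,
       horizon = NULL, horizon_preset = NULL,
       patch_side = 7L, grid_side = 7L,
       model = list(), cv = list(k = 5L, repeats = 10L),
       alpha = 0.05, seed = 1L, output_dir = "survmixr_results")
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  for (f in c("expression", "survival", "genesets")) {
    if (is.null(cfg[[f]])) stop("config is missing required path: ", f)
    if (!file.exists(cfg[[f]]))
      stop("config path does not exist: ", f, " = ", cfg[[f]])
  }
  if (is.null(cfg$horizon)) {
    if (is.null(cfg$horizon_preset))
      stop("config needs either horizon (a time) or horizon_preset (short/mid/long)")
    cfg$horizon <- horizon_days(cfg$horizon_preset)
  }
  cfg
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full pipeline
#'
#' Executes the complete workflow on files named in a configuration (an R
#' list or a YAML file): read and min-max-normalize expression, build
#' pathway images, label samples at the horizon, repeated stratified
#' cross-validation (with external validation when an external dataset is
#' configured), train a final model on all labeled samples, and derive the
#' key-pathway interpretation report. Results (validation JSON, key-pathway
#' JSON/TSV, layout JSON, labels TSV) are written to the output directory;
#' every file records the master seed.
#'
#' @param config Configuration list or path to a YAML file. Required
#'   fields: `expression`, `survival`, `genesets` (paths), and `horizon`
#'   (in the time unit of the survival table) or `horizon_preset`
#'   (short/mid/long, in days). Optional: `external_expression` +
#'   `external_survival`, `model` (arguments to [survmixer_config()]),
#'   `cv` (`k`, `repeats`), `alpha`, `seed`, `output_dir`, `patch_side`,
#'   `grid_side`.
#' @return Invisibly, a list with the fitted model, validation result,
#'   key-pathway report, labeled cohort, and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  pc <- stage("read-genesets", read_gmt(cfg$genesets))
  expr <- stage("read-expression", read_expression(cfg$expression))
  surv <- stage("read-survival", read_survival(cfg$survival))
  expr <- stage("normalize", minmax_normalize(expr))

  labeled <- stage("label", {
    s <- surv[match(rownames(expr), surv$sample_id), ]
    if (anyNA(s$os_time))
      stop("survival records missing for some expression samples")
    label_samples(s$os_time, s$event, cfg$horizon, sample_ids = s$sample_id)
  })
  keep <- match(labeled$kept, rownames(expr))
  images <- stage("build-images",
                  build_images(expr[keep, , drop = FALSE], pc,
                               patch_side = cfg$patch_side,
                               grid_side = cfg$grid_side))
  labels <- labeled$labels

  mcfg <- do.call(survmixer_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$model))

  external <- NULL
  if (!is.null(cfg$external_expression)) {
    external <- stage("external", {
      ee <- minmax_normalize(read_expression(cfg$external_expression))
      es <- read_survival(cfg$external_survival)
      es <- es[match(rownames(ee), es$sample_id), ]
      el <- label_samples(es$os_time, es$event, cfg$horizon,
                          sample_ids = es$sample_id)
      ekeep <- match(el$kept, rownames(ee))
      list(images = build_images(ee[ekeep, , drop = FALSE], pc,
                                 patch_side = cfg$patch_side,
                                 grid_side = cfg$grid_side),
           labels = el$labels)
    })
  }

  validation <- stage("validate",
                      repeated_cv(images, labels, mcfg, k = cfg$cv$k,
                                  repeats = cfg$cv$repeats,
                                  external = external, seed = cfg$seed))
  model <- stage("train-final", survmixer(images, labels, mcfg))
  report <- stage("interpret", {
    s <- surv[match(labeled$kept, surv$sample_id), ]
    key_pathway_report(model, images, labels,
                       expr[keep, , drop = FALSE], pc,
                       s$os_time, s$event, alpha = cfg$alpha)
  })

  paths <- list(
    validation = file.path(cfg$output_dir, "validation.json"),
    report = file.path(cfg$output_dir, "key_pathways.json"),
    report_tsv = file.path(cfg$output_dir, "key_pathways.tsv"),
    layout = file.path(cfg$output_dir, "layout.json"),
    labels = file.path(cfg$output_dir, "labels.tsv")
  )
  write_validation_json(validation, paths$validation)
  write_report_json(report, paths$report, paths$report_tsv)
  write_layout_json(images$layout, paths$layout)
  utils::write.table(
    data.frame(sample_id = names(labels), label = labels,
               seed = cfg$seed),
    paths$labels, sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(list(model = model, validation = validation, report = report,
                 labeled = labeled, images = images, paths = paths,
                 config = cfg))
}
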