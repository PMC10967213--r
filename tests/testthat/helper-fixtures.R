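# Shared fixtures. Heavy objects (the strong-signal cohort and trained
# models) are built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# tiny 3-pathway collection on a 2x2 grid of 2x2 patches
tiny_collection <- function() {
  pathway_collection(list(p1 = c("A", "B", "C"), p2 = c("D", "E"),
                          p3 = c("F")))
}

random_tiny_images <- function(n, seed = 1) {
  pc <- tiny_collection()
  set.seed(seed)
  x <- matrix(runif(n * 6), n, 6,
              dimnames = list(sprintf("s%02d", seq_len(n)), LETTERS[1:6]))
  build_images(x, pc, patch_side = 2, grid_side = 2)
}

# small mid-scale cohort for model tests: 12 pathways on a 4x4 grid of
# 3x3 patches, clear two-pathway survival signal
small_cohort <- function() {
  fixture("small_cohort", function() {
    spec <- synthetic_spec(n_samples = 120L, n_pathways = 12L,
                           size_range = c(3L, 9L), n_background_genes = 10L,
                           effect_pathways = c(1L, 2L), effect_size = 2,
                           noise_sd = 0.3, censoring_rate = 0.2, seed = 421L)
    pc <- generate_collection(spec)
    co <- generate_cohort(spec, pc)
    lc <- label_samples(co$records$os_time, co$records$event, 3,
                        co$records$sample_id)
    keep <- match(lc$kept, rownames(co$expression))
    imgs <- build_images(co$expression[keep, , drop = FALSE], pc,
                         patch_side = 3, grid_side = 4)
    list(spec = spec, collection = pc, cohort = co, labeled = lc,
         images = imgs, labels = lc$labels, keep = keep)
  })
}

small_trained_model <- function() {
  fixture("small_trained_model", function() {
    sc <- small_cohort()
    cfg <- survmixer_config(channels = 8L, epochs = 8L, lr = 2e-3,
                            seed = 11L)
    survmixer(sc$images, sc$labels, cfg)
  })
}

# the study-condition cohort: n = 400, 40 pathways (3-46 genes),
# 2 effect pathways, effect size 2, noise SD 0.3, default 7x7 geometry
strong_cohort <- function() {
  fixture("strong_cohort", function() {
    spec <- synthetic_spec(seed = 2024L)
    pc <- generate_collection(spec)
    co <- generate_cohort(spec, pc)
    lc <- label_samples(co$records$os_time, co$records$event, 3,
                        co$records$sample_id)
    keep <- match(lc$kept, rownames(co$expression))
    imgs <- build_images(co$expression[keep, , drop = FALSE], pc)
    list(spec = spec, collection = pc, cohort = co, labeled = lc,
         images = imgs, labels = lc$labels, keep = keep)
  })
}

# reduced-size training recipe used throughout the test suite: cosine
# learning-rate decay plus input-noise and mixup augmentation
test_model_config <- function(seed = 5L) {
  survmixer_config(channels = 48L, epochs = 40L, lr = 2e-3,
                   lr_schedule = "cosine", input_noise_sd = 0.1,
                   mixup_alpha = 0.4, seed = seed)
}

strong_trained_model <- function() {
  fixture("strong_trained_model", function() {
    sc <- strong_cohort()
    survmixer(sc$images, sc$labels, test_model_config())
  })
}
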