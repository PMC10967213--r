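# survmixr

Pathway-image ConvMixer models for binary overall-survival (OS)
classification from bulk gene expression, with built-in model
interpretation and a fully synthetic test bed.

## What it does

Cancer expression cohorts are small and wide, and models that only pass
internal cross-validation often fail on data from another platform.
survmixr takes a different input representation: each sample's
expression is *structuralized* into a small image whose geometry encodes
pathway membership, and a compact convolutional network classifies
whether the patient died within a chosen horizon.

1. **Imaging.** Per-gene min-max normalization
   `x' = (x − x_min)/(x_max − x_min)`; each pathway's genes (in pathway
   order) are zero-padded to `s²` values and reshaped row-major into an
   `s × s` patch; patches tile a `g × g` grid row-major. Defaults
   `s = g = 7`: a 40-pathway collection (longest pathway 46 genes)
   becomes a 49 × 49 image with nine all-zero blank patches at the end.
2. **Labeling.** Observed beyond the horizon → 0; death within it → 1;
   censored before it → dropped (uninformative).
3. **Model.** Patch embedding (kernel = stride = 7) → batch-normalized
   GELU ConvMixer blocks (depthwise 3 × 3 + residual, pointwise 1 × 1)
   → blank-slot masking → global average pooling → linear unit →
   sigmoid. Forward pass, backpropagation, Adam (with optional
   decoupled weight decay, input-noise and mixup augmentation) are
   implemented in base R; training is deterministic given a seed.
4. **Validation.** Stratified 5-fold cross-validation × 10 repeats with
   rank-based AUC, plus scoring of a never-trained-on external dataset
   each fold.
5. **Interpretation.** Grad-CAM at the last block
   (`α_c = (1/Z) Σ_ij ∂y/∂A_ij^c`, map `= ReLU(Σ_c α_c A^c)`, `Z = 49`),
   per-pathway Wilcoxon rank-sum tests between label groups with
   Bonferroni correction, rank-based single-sample pathway scores, and
   median-split Kaplan–Meier curves with log-rank tests.

A synthetic-data module generates pathway collections, expression with
latent pathway activities, and exponential survival with calibrated
censoring, so the entire pipeline is testable offline with known ground
truth.

## Worked example

```r
library(survmixr)

spec <- synthetic_spec(n_samples = 400, effect_pathways = c(1, 2),
                       effect_size = 2, noise_sd = 0.3, seed = 11)
pc     <- generate_collection(spec)        # 40 pathways, 3-46 genes
cohort <- generate_cohort(spec, pc)

lab  <- label_samples(cohort$records$os_time, cohort$records$event,
                      horizon = 3, sample_ids = cohort$records$sample_id)
lab
#> LabeledCohort: horizon 3, 396 kept (198 died within / 198 survived beyond), 4 dropped (censored before horizon)

imgs <- build_images(cohort$expression[match(lab$kept, rownames(cohort$expression)), ], pc)
imgs
#> PathwayImageSet: 396 samples, 49x49 images, 40 pathway / 9 blank patches

cfg <- survmixer_config(channels = 48, epochs = 40, lr = 2e-3,
                        lr_schedule = "cosine", input_noise_sd = 0.1,
                        mixup_alpha = 0.4)
fit <- survmixer(imgs, lab$labels, cfg)
fit
#> survmixer: 48-channel ConvMixer, 2 block(s), 7x7 grid of 7x7 patches
#>   8593 parameters; trained 40 epochs, final loss 0.4207

cv <- repeated_cv(imgs, lab$labels, cfg, k = 5, repeats = 1, seed = 3)
cv
#> 5-fold CV x 1 repeats (5 folds)
#>   internal AUC: 0.9511 +/- 0.0257

g   <- gradcam(fit, imgs)                  # 396 maps, 7x7, Z = 49
act <- pathway_activations(g)              # 396 x 40
key <- wilcoxon_keypathways(act, lab$labels)
key[key$pathway %in% c("PW01", "PW02"), ]  # the two planted pathways
#>   pathway        p_raw p_bonferroni significant
#> 1    PW01 6.978089e-53 2.791236e-51        TRUE
#> 2    PW02 8.320099e-60 3.328040e-58        TRUE
```

The CV block prints the mean internal AUC over held-out folds (0.95
under these conditions, essentially at the cohort's Bayes-optimal
AUC); the Wilcoxon table flags the pathways whose Grad-CAM activations
separate the died-within from the survived-beyond group after
Bonferroni correction — both planted pathways are recovered
overwhelmingly (other pathways whose activations co-vary with the
prediction are flagged too; the planted ones are what the ground
truth pins).

## Command line

```sh
Rscript inst/cli/survmixr.R simulate --spec spec.yaml --out data/
Rscript inst/cli/survmixr.R run --config config.yaml
```

`run` executes the whole workflow (normalize → images → label →
repeated CV (+ external validation) → final model → Grad-CAM → key
pathways) and writes JSON/TSV results; see `?run_pipeline` for the
config schema.
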