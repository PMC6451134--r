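# lrescout

Discovery of **labelled regulatory elements (LREs)** — transcription-factor
(TF) bound genomic regions that sit in *low-accessible* chromatin — by
integrating TF ChIP-seq cistromes with ATAC-seq open-chromatin peaks, and
characterisation of how these elements behave: whether chromatin openness
can be predicted from TF occupancy alone, and how LREs are kinetically
activated by polarization stimuli.

The package is aimed at regulatory-genomics analysts working with
peak-level data (BED / ENCODE narrowPeak), tag libraries and time-course
count matrices. It ships a ground-truthed synthetic-data generator, so the
entire pipeline is testable without any sequencing downloads.

## What it computes

Given consensus cistromes for *n* TFs and an open-chromatin set, every
region of the universe (TF-bound regions plus open chromatin) is placed,
relative to a focal TF *f*, into one of four classes:

| bound by *f* | overlaps open chromatin | class |
|---|---|---|
| yes | no  | `LRE` |
| yes | yes | `TF_pos_HighAcc` |
| no  | yes | `TF_neg_HighAcc` |
| no  | no  | `TF_neg_LowAcc` |

"Overlaps" means ≥ 1 shared nucleotide under BED half-open coordinates.

The openness model asks whether TF occupancy (log2 RPKM features) predicts
the open/closed state: one random-forest classifier per non-empty TF
subset (2^n − 1 models; 31 for five TFs), 10-fold stratified
cross-validation plus an independent validation set, mean-decrease-Gini
feature importances, ROC/AUC from pooled held-out scores, and a radial
support-vector regressor for the quantitative ATAC signal (Pearson *r* on
validation). Time-course polymerase signal is tested per condition against
the untreated control (median-library normalisation, fold change with
pseudocount 1, Welch t-test on log2 counts), regulated regions (FC > 2,
p < 0.05, normalised occupancy > 30) are z-scored and k-means-clustered
into kinetic enhancer clusters, and clusters are associated with gene TSSs
inside a 100-kb-wide window.

## Worked example

```r
library(lrescout)

cfg <- sim_config(seed = 1)              # 20,000 sites, 5 TFs, defaults
sim <- simulate_cistromes(cfg)
tags <- simulate_tags(cfg, sim)

cistromes <- lapply(sim$tf_replicates, consensus_regions, min_support = 2)
atac <- consensus_regions(sim$atac_replicates, min_support = 2)
assignment <- classify_regions(cistrome_collection(cistromes, atac))

category_fractions(assignment, "PU.1")$fraction_lre
#> [1] 0.6725296
mean(!sim$truth$open[sim$truth$bound[, "PU.1"]])   # planted truth
#> [1] 0.6666928
```

Two-thirds of the pioneer-TF cistrome is planted in closed chromatin and
the classification recovers that fraction to within 0.006. Fitting the
openness models on balanced 1000-per-class training/validation sets:

```r
unified <- assignment$universe[assignment$is_unified]
occ <- occupancy_matrix(unified, tags[assignment$tf_names])
ex <- build_examples(assignment, occ, compute_rpkm(unified, tags$ATAC))
sets <- sample_training_validation(ex, n_per_class = 1000, seed = 12)

spec <- model_spec(assignment$tf_names, seed = 24)
fit <- fit_openness_classifier(sets$train, spec)
evaluate_on_validation(fit, sets$valid, spec)[c("accuracy", "auc")]
#> $accuracy
#> [1] 0.9045
#> $auc
#> [1] 0.9685645
```

The full five-TF model predicts openness with ~0.90 accuracy and AUC
~0.97, while any single TF alone stays near chance (the pioneer-only model
reaches ~0.56) — TF binding is widespread at closed chromatin, which is
exactly the LRE signature. `sweep_combinations()` runs all 31 subsets and
`sweep_size_summary()` gives the per-subset-size accuracy distribution.

The orchestrated run (`run_pipeline(run_config(seed = 1))`) executes all
stages and writes TSV tables plus a JSON manifest with parameters, seeds
and file checksums; reruns are byte-identical.

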