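---
title: "Discovering labelled regulatory elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering labelled regulatory elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological problem

Lineage-determining transcription factors (LDTFs) such as PU.1 shape the
open-chromatin landscape of macrophages through collaborative binding. A
substantial fraction of TF binding, however, occurs at chromatin that is
*not* accessible: TF-bound, low-accessible, transcriptionally quiet sites
that may represent a dormant state of future enhancers. We call these
**labelled regulatory elements (LREs)**. `lrescout` implements a complete,
testable pipeline for discovering and characterising LREs from
peak-level data:

1. **Interval algebra** — unify TF cistromes, call replicate consensus
   peaks, remove blacklist artefacts, annotate promoter/distal location.
2. **Classification** — relative to a focal TF, every region in the
   universe (TF-bound regions plus open chromatin) falls into one of four
   classes: `LRE` (bound, closed), `TF_pos_HighAcc` (bound, open),
   `TF_neg_HighAcc` (unbound, open), `TF_neg_LowAcc` (bound only by other
   TFs, closed).
3. **Openness prediction** — can TF occupancy alone predict chromatin
   accessibility?  A random-forest classifier is fitted for *every*
   non-empty TF subset (31 models for five TFs) with 10-fold stratified
   cross-validation and independent validation; a support-vector
   regressor predicts the quantitative ATAC signal.
4. **Kinetics** — time-course elongating-polymerase (RNAPII-pS2) signal
   over two stimuli and four timepoints is tested against the untreated
   control, regulated regions are selected (FC > 2, p < 0.05, minimum
   normalised occupancy) and z-scored profiles are k-means-clustered into
   kinetic enhancer clusters (ECs), then associated with genes in a fixed
   window around the TSS.

Because the original sequencing data are not required, a ground-truthed
**synthetic-data generator** reproduces the statistical structure of the
study design; every stage of the pipeline is validated against the
generator's known truth or against independent per-base oracles.

# Coordinate and overlap conventions

All files use BED conventions (0-based half-open); in memory regions are
`GRanges`. Two regions overlap iff they share at least one nucleotide,
i.e. `start_a < end_b && start_b < end_a`; bookended intervals never
overlap. This matches the behaviour of the common interval toolkits, so
results are interchangeable with shell-based workflows.

Three design points were genuinely open and were fixed as follows:

* **Consensus calling is base-level.** "Supported by at least two
  replicates" could mean peak-level voting or base-level depth; we use
  base-level depth (`consensus_regions()` keeps maximal runs of bases
  covered by `min_support` reduced replicate sets). With
  `min_support = 1` this reduces exactly to merging the concatenation,
  which gives the operation a clean algebraic identity that peak-level
  voting lacks.
* **Promoter windows are a TSS-distance rule**, default −1000/+100 bp
  around the strand-aware TSS; full genome annotation is delegated to a
  gene model, not re-derived.
* **Names are regenerated** (`chrom_start_end`) after set algebra; merged
  products have no unique parent.

# Signal quantification

`compute_rpkm()` counts a tag once per region it overlaps (fragment
any-overlap, the default of coverage-style counting; 5′-end counting is
available via `count = "five_prime"`). RPKM = tags / (region kb × library
millions). Profile matrices (`profile_matrix()`) tile a 2-kb window
around each peak summit into 25-bp bins, assign each tag to exactly one
bin by its midpoint, and scale to tags per 10 million mapped reads; the
per-10-million constant is recorded in the object because "normalized tag
counts" conventions differ between toolkits. The midpoint rule guarantees
the row sum recovers the in-window tag count exactly — a property the
test suite asserts.

# The openness models

Training examples are TF-bound (unified) regions; the label is `HighAcc`
if the region overlaps an open-chromatin consensus peak and `labelled`
otherwise. Features and the regression target are `log2(RPKM + 1)`:
coverage is heavy-tailed, and the transform stabilises both the forest
splits and the radial SVR kernel. Regions where a TF has no peak get
feature 0, not missing.

* Balanced sampling: 1000 regions per class for training and another
  1000 per class for validation, disjoint, drawn uniformly without
  replacement.
* Random forest: 500 trees, `mtry = floor(sqrt(p))` — the package
  defaults of the engine we delegate to. Determinism comes from the seed
  in the `model_spec`; the subset sweep fans out per-subset seeds as
  `base seed + subset index`, so the 31 models are individually
  reproducible.
* Cross-validation is stratified (class-balanced folds); held-out scores
  are pooled before metrics and ROC construction. The ROC is built over
  descending unique score thresholds with tie grouping, so the
  trapezoidal AUC equals the mid-rank Mann–Whitney statistic exactly
  (asserted to 1e-9 in the tests).
* Both cross-validated and independent-validation metrics are reported
  for every subset, because box-plot summaries of a subset sweep can be
  computed from either; the acceptance checks use the independent
  validation set.
* The SVR uses the radial kernel with engine defaults; its quality is
  reported as the Pearson correlation between predicted and measured
  openness on the validation set.

# Differential occupancy and kinetic clustering

The differential engine is deliberately simple and fully specified,
rather than delegating to a package whose internals would be opaque to
the tests: counts are scaled to the median library size, fold change is
computed on mean normalised occupancy with pseudocount 1, and the
p-value is a two-sided Welch t-test on `log2(normalised + 1)` replicate
values (the vectorised implementation is asserted equal to `stats::t.test`
to 1e-12). Selection uses the raw p-value (p < 0.05) with FC > 2 and a
minimum normalised occupancy (30 for distal elements, 50 for gene
bodies); a Benjamini–Hochberg column is emitted for transparency but not
used for selection, matching the filtering style this kind of analysis
reports.

Clustering uses `stats::kmeans` on row-z-scored mean profiles with 25
random restarts (best total within-cluster sum of squares wins),
`k = 8` by default. Clusters are relabelled by the condition at which
their centroid peaks (stimulus first, then timepoint), which makes the
EC numbering stable across runs. "A 100-kb-wide window" for gene
association is interpreted as ±50 kb around the TSS; the one-sided bound
is configurable (`half_window`) for the ±100 kb reading.

# What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions:

* **Genome and sites**: 20,000 candidate sites on a 5 × 10-Mb toy
  genome, placed on a jittered grid so sites never overlap and peaks
  from neighbouring sites never touch.
* **Collaborative binding**: the first TF (the PU.1 analogue) is the
  pioneer: it binds 64% of sites (motif prevalence 0.80 × binding 0.80),
  and its presence raises the binding probability of the other four TFs
  (e.g. the JUNB analogue binds at 0.75 given the pioneer vs 0.08
  without, making it the most collaborative — its solo-binding fraction
  is the smallest, as observed for AP-1 family members). Occupancy
  strengths are log-normal (meanlog log 3, sdlog 0.5).
* **Openness rule**: `score = Σ w_t · occ_t + ε`, `ε ~ N(0, 0.2)`;
  openness value is `plogis(score + intercept)` and the open state
  thresholds it at 0.5. The weights (0.15, 0.55, 0.25, 0.35, 0.30) give
  the pioneer the *smallest* weight — binding pervasively without
  opening chromatin is precisely the LRE phenomenon — and no single TF
  explains enough variance to predict openness alone. The intercept is
  calibrated at generation time so that exactly two-thirds of the
  pioneer's bound sites are closed, the scenario default for the
  labelled fraction of a pioneer cistrome.
* **Replicates and peaks**: duplicate peak sets per track, 1% peak
  drop-out per replicate (strong consensus peaks reproduce well), ±30 bp
  boundary jitter, summits at the true site centre.
* **Tags**: per-site Poisson counts with mean `tag_rate × occupancy`
  (ATAC: `80 × openness value`, so accessibility is graded rather than
  binary and co-binding strata show strictly increasing ATAC signal),
  fragments of 150 bp scattered around the summit, plus uniform
  background; the nominal library size (1e6) is the RPKM denominator.
* **Kinetics**: 4000 regulated sites drawn from the labelled sites, 8
  archetype fold-curves (3 IL-4-like, 5 LPS-like) over 1/3/6/24 h with
  baseline log-normal(log 60, 0.4), condition-level biological noise
  `exp(N(0, 0.3))` shared across replicates, and Poisson replicate
  noise; 4000 flat sites serve as negatives.

The generator does **not** emulate read-level sequences, motif content,
fragment-size distributions, copy-number or mappability artefacts,
peak-caller behaviour, or correlated replicate failure. Passing tests
therefore demonstrate that the pipeline's logic is correct and that its
statistical machinery recovers planted structure at realistic noise —
not that any particular biological dataset will reach the same numbers.

# Numerical choices and problem sizes

* All randomness flows from one master seed through fixed substream
  offsets (cistromes +101, tags +202, kinetics +303, genes +404;
  sampling/models/clustering derive analogous offsets), so every result
  is bit-reproducible and the orchestrated pipeline writes byte-identical
  outputs across reruns. Execution is serial; there is no thread-order
  nondeterminism.
* Degenerate inputs are handled explicitly: constant features warn (the
  forest tolerates them), zero-variance regression targets error,
  constant z-score rows collapse to zero, identical replicate vectors
  give p = 1, and k > n regions errors.
* The test suite validates interval algebra against per-base bitmap
  oracles on 1000 seeded random instances (100-kb genome, up to ~500
  intervals), runs the full 31-model sweep at the default 20,000-site
  configuration, and checks chance-level behaviour (AUC and CV accuracy
  0.5 ± 0.05) on 20 seeded null datasets of 9000 sites with all openness
  weights zero; the permutation-label null uses a reduced forest (150
  trees), which does not affect the chance level being tested. The
  orchestration determinism check runs a 2500-site configuration.

# Known limitations

* The four-way classification operates on merged unified regions, so a
  focal TF "binds" a region if any of its peaks overlaps the merged
  region; per-peak tallies on unmerged cistromes can differ slightly.
* JUNB-analogue tracks are retained throughout classification even
  though highly collaborative TFs with small cistromes contribute little
  to LRE-focused summaries; excluding a TF is a caller-side subsetting
  decision, not a package default.
* The differential engine is a clean, documented test — not a
  reimplementation of any specific differential-binding package; with
  two replicates per condition its power is limited, which the regulated
  selection thresholds (FC > 2 and occupancy floors) compensate for.
* `coverage_of_union()` treats method sets symmetrically and reports a
  region-level fraction; it does not model method-specific sensitivity.
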