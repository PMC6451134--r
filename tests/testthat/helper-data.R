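# Shared fixtures.  The default synthetic dataset (20,000 sites) is
# expensive enough to build once and reuse across test files; the cache
# lives for the duration of the test run.

.cache <- new.env(parent = emptyenv())

# full default-configuration dataset: cistromes, tags, consensus,
# classification, occupancy and balanced example sets
acceptance_data <- function() {
  if (!is.null(.cache$acc)) return(.cache$acc)
  cfg <- sim_config(seed = 1L)
  sim <- simulate_cistromes(cfg)
  tags <- simulate_tags(cfg, sim)
  cistromes <- lapply(sim$tf_replicates, consensus_regions, min_support = 2L)
  atac <- consensus_regions(sim$atac_replicates, min_support = 2L)
  assignment <- classify_regions(cistrome_collection(cistromes, atac))
  unified <- assignment$universe[assignment$is_unified]
  occ <- occupancy_matrix(unified, tags[names(cistromes)])
  atac_rpkm <- compute_rpkm(unified, tags$ATAC)
  examples <- build_examples(assignment, occ, atac_rpkm)
  sets <- sample_training_validation(examples, n_per_class = 1000L,
                                     seed = 11L)
  .cache$acc <- list(cfg = cfg, sim = sim, tags = tags,
                     cistromes = cistromes, atac = atac,
                     assignment = assignment, occ = occ,
                     atac_rpkm = atac_rpkm, examples = examples,
                     sets = sets)
  .cache$acc
}

# small collaborative instance for unit tests (fast)
small_sim <- function(seed = 5L, n_sites = 3000L) {
  key <- paste0("small", seed, "_", n_sites)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  cfg <- sim_config(seed = seed, n_sites = n_sites, n_chrom = 2L,
                    chrom_length = 5e6, bg_tags = 10000L,
                    n_regulated = 400L, n_flat = 400L, n_genes = 100L)
  sim <- simulate_cistromes(cfg)
  .cache[[key]] <- list(cfg = cfg, sim = sim)
  .cache[[key]]
}

# default TF parameters with the openness weights zeroed (null model)
null_tf_params <- function() {
  tfp <- sim_config()$tf_params
  tfp$weight <- rep(0, nrow(tfp))
  tfp
}

# hand-built 12-region differential fixture: regions 1-5 are designed to
# pass (FC > 2, p < 0.05, treated occupancy > 30) in the single treated
# condition; regions 6-12 each fail exactly one criterion
differential_fixture <- function() {
  asm <- toy_assembly(len = 100000L)
  regions <- region_set(rep("chrT", 12), seq(0, 11000, by = 1000) + 1,
                        seq(0, 11000, by = 1000) + 501, asm)
  conditions <- data.frame(id = c("control", "treat_1"),
                           stimulus = c("control", "treat"),
                           timepoint = c(0, 1))
  ctrl <- cbind(c(20, 30, 40, 25, 35,   20, 200, 20, 30,  5, 20, 25),
                c(22, 28, 42, 27, 33,   22, 210, 21, 31,  6, 21, 27))
  # pass rows: strong induction, clean replicates, occupancy > 30
  trt <- cbind(c(90, 130, 170, 110, 150,   20, 300, 55, 90, 28, 140, 70),
               c(95, 125, 180, 105, 155,   22, 310, 30, 10, 30,  20, 74))
  # row 6: FC = 1 (unchanged); row 7: FC < 2 (high baseline)
  # row 8/9: noisy replicates -> p >= 0.05; row 10: treated mean <= 30
  # row 11: noisy replicates -> p >= 0.05; row 12: FC just above 2? no:
  # (72+1)/(26+1) = 2.7 with clean reps -> make it fail on FC instead
  trt[12, ] <- c(48, 52)  # FC = (50+1)/(26+1) = 1.89 < 2
  counts <- array(0L, dim = c(12, 2, 2))
  counts[, 1, ] <- ctrl
  counts[, 2, ] <- trt
  lib <- matrix(1e6, nrow = 2, ncol = 2)
  list(tc = timecourse_matrix(regions, conditions, counts, lib),
       pass = region_ids(regions)[1:5])
}
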