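## End-to-end orchestration: simulate -> consensus/classify -> occupancy ->
## feature-subset sweep -> time-course clustering, with a YAML-configurable
## entry point, plain-text outputs and a JSON run manifest.  Given an
## identical configuration the run is byte-identical across reruns (all
## randomness flows from the master seed).

#' Default pipeline configuration
#'
#' @param seed master seed (forwarded to [sim_config()] and the model
#'   sweep).
#' @param out_dir output directory.
#' @param n_per_class training/validation examples per class.
#' @param cv_folds cross-validation folds.
#' @param ntree random-forest size.
#' @param run_sweep fit all 2^n - 1 subset models (set `FALSE` to fit only
#'   the full and single-TF models).
#' @param fc_min,p_max,occ_min,direction regulated-region thresholds.
#' @param k_clusters kinetic cluster count.
#' @param window_bp gene-association window width.
#' @param sim extra arguments forwarded to [sim_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("lrescout_run_"),
                       n_per_class = 1000L, cv_folds = 10L, ntree = 500L,
                       run_sweep = TRUE,
                       fc_min = 2, p_max = 0.05, occ_min = 30,
                       direction = "up",
                       k_clusters = 8L, window_bp = 100000L,
                       sim = list()) {
  stopifnot(n_per_class >= 1, cv_folds >= 2, k_clusters >= 1)
  cfg <- as.list(environment())
  cfg$sim_config <- do.call(sim_config, c(list(seed = seed), sim))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` block
#' is forwarded to [sim_config()].  Unknown keys are an error so typos
#' fail at launch, not mid-run.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "sim")
  unknown <- setdiff(names(raw), c(known, "sim"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Stages, in dependency order: simulate cistromes/tags/time course;
#' per-track replicate consensus (>= 2 supporting replicates); unified
#' cistrome and four-way classification; RPKM occupancy; balanced
#' train/validation sampling; random-forest subset sweep plus SVR
#' regression; differential selection of regulated regions and k-means
#' kinetic clustering; gene association.  All result tables are written as
#' TSV under `cfg$out_dir` along with `manifest.json` (parameters, seeds,
#' per-file checksums).
#'
#' @param cfg a [run_config()] (or path to a YAML file).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results:
#'   `assignment`, `occupancy`, `sweep`, `regression`, `clusters`,
#'   `fractions`, `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[lrescout] ", ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- cfg$sim_config

  say("simulating cistromes (", scfg$n_sites, " sites)")
  sim <- simulate_cistromes(scfg)
  say("simulating tag libraries")
  tags <- simulate_tags(scfg, sim)

  say("building consensus cistromes")
  tf_names <- scfg$tf_params$tf
  cistromes <- lapply(sim$tf_replicates, consensus_regions, min_support = 2L)
  atac <- consensus_regions(sim$atac_replicates, min_support = 2L)
  cc <- cistrome_collection(cistromes, atac)

  say("classifying regions")
  assignment <- classify_regions(cc)
  write_tsv(assignment_table(assignment),
            file.path(cfg$out_dir, "categories.tsv"))
  fractions <- category_fractions(assignment, tf_names[[1]])

  say("quantifying occupancy (RPKM)")
  unified <- assignment$universe[assignment$is_unified]
  occ <- occupancy_matrix(unified, tags[tf_names])
  atac_rpkm <- compute_rpkm(unified, tags$ATAC)
  occ_out <- data.frame(region_id = rownames(occ), occ,
                        ATAC = atac_rpkm, check.names = FALSE)
  write_tsv(occ_out, file.path(cfg$out_dir, "occupancy.tsv"))

  say("sampling training/validation sets")
  examples <- build_examples(assignment, occ, atac_rpkm)
  sets <- sample_training_validation(examples,
                                     n_per_class = cfg$n_per_class,
                                     seed = cfg$seed + 11L)
  base_spec <- model_spec(tf_names, cv_folds = cfg$cv_folds,
                          seed = cfg$seed + 23L, ntree = cfg$ntree)
  if (cfg$run_sweep) {
    say("sweeping ", 2^length(tf_names) - 1, " TF subset models")
    sweep <- sweep_combinations(sets$train, sets$valid, tf_names, base_spec)
  } else {
    say("fitting full and single-TF models")
    singles <- lapply(tf_names, function(tf) list(tf))
    sweep <- NULL
    rows <- lapply(c(singles, list(list(tf_names))), function(s) {
      spec <- model_spec(unlist(s), cv_folds = cfg$cv_folds,
                         seed = cfg$seed + 23L, ntree = cfg$ntree)
      fit <- suppressWarnings(fit_openness_classifier(sets$train, spec))
      val <- evaluate_on_validation(fit, sets$valid, spec)
      data.frame(subset = paste(unlist(s), collapse = "+"),
                 size = length(unlist(s)), val_accuracy = val$accuracy,
                 val_sensitivity = val$sensitivity,
                 val_specificity = val$specificity, val_auc = val$auc)
    })
    sweep <- list(table = do.call(rbind, rows))
  }
  write_tsv(sweep$table, file.path(cfg$out_dir, "sweep.tsv"))
  if (!is.null(sweep$importances)) {
    full <- sweep$importances[[paste(tf_names, collapse = "+")]]
    write_tsv(data.frame(feature = names(full), mean_decrease_gini = full),
              file.path(cfg$out_dir, "importance.tsv"))
  }

  say("fitting support-vector regression of openness")
  reg_spec <- model_spec(tf_names, task = "regression",
                         seed = cfg$seed + 31L)
  regression <- fit_openness_regressor(sets$train, sets$valid, reg_spec)

  say("simulating and analysing the time course")
  stc <- simulate_timecourse(scfg, sim)
  diff <- differential_all(stc$tc)
  write_tsv(diff, file.path(cfg$out_dir, "differential.tsv"))
  regulated <- select_regulated(diff, fc_min = cfg$fc_min,
                                p_max = cfg$p_max, occ_min = cfg$occ_min,
                                direction = cfg$direction)
  norm <- normalize_counts(stc$tc)
  mean_sig <- apply(norm, c(1, 2), mean)
  reg_idx <- match(regulated, region_ids(stc$tc$regions))
  clusters <- cluster_kinetics(mean_sig[reg_idx, , drop = FALSE],
                               conditions = stc$tc$conditions,
                               k = min(cfg$k_clusters, length(reg_idx)),
                               seed = cfg$seed + 41L)
  write_tsv(data.frame(region_id = names(clusters$assignment),
                       cluster = clusters$assignment),
            file.path(cfg$out_dir, "clusters.tsv"))
  write_tsv(data.frame(cluster = rownames(clusters$centroids),
                       clusters$centroids, check.names = FALSE),
            file.path(cfg$out_dir, "centroids.tsv"))

  say("associating genes within ", cfg$window_bp, " bp windows")
  genes <- simulate_genes(scfg, sim$assembly)
  assoc <- associate_genes(clusters, stc$tc$regions[reg_idx], genes,
                           window_bp = cfg$window_bp)
  write_tsv(assoc, file.path(cfg$out_dir, "gene_association.tsv"))

  files <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "lrescout",
    version = as.character(utils::packageVersion("lrescout")),
    seed = cfg$seed,
    parameters = list(
      n_sites = scfg$n_sites, sigma_open = scfg$sigma_open,
      n_per_class = cfg$n_per_class, cv_folds = cfg$cv_folds,
      ntree = cfg$ntree, fc_min = cfg$fc_min, p_max = cfg$p_max,
      occ_min = cfg$occ_min, k_clusters = cfg$k_clusters,
      window_bp = cfg$window_bp,
      profile_norm_to = 1e7,
      feature_transform = "log2(RPKM + 1)"),
    n_regulated = length(regulated),
    fraction_lre_focal = fractions$fraction_lre,
    outputs = lapply(setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", cfg$out_dir)
  invisible(list(assignment = assignment, occupancy = occ,
                 examples = examples, sets = sets, sweep = sweep,
                 regression = regression, clusters = clusters,
                 regulated = regulated, fractions = fractions,
                 timecourse = stc, manifest = manifest))
}
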