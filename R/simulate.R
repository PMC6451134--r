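## Ground-truthed synthetic data with the statistical structure the
## analysis assumes: five TF cistromes with collaborative co-binding (the
## first TF acts as the pioneer whose binding boosts the others), chromatin
## openness driven by a thresholded noisy sigmoid of weighted TF occupancy,
## replicate peak sets with drop-out, Poisson tag libraries yielding RPKM,
## and 4-timepoint / 2-stimulus activation kinetics over 8 planted
## archetypes.  All randomness flows from one master seed via fixed
## substream offsets.

.default_tf_params <- function() {
  data.frame(
    tf = c("PU.1", "IRF8", "JUNB", "CEBPA", "RUNX1"),
    prevalence = c(0.80, 0.60, 0.40, 0.55, 0.55),
    bind_hi    = c(0.80, 0.75, 0.75, 0.65, 0.70),
    bind_lo    = c(0.80, 0.30, 0.08, 0.30, 0.30),
    mu_log     = rep(log(3), 5),
    sd_log     = rep(0.5, 5),
    weight     = c(0.15, 0.55, 0.25, 0.35, 0.30),
    tag_rate   = rep(8, 5),
    stringsAsFactors = FALSE)
}

.default_archetypes <- function() {
  ## fold over baseline at 1, 3, 6, 24 h of the archetype's own stimulus;
  ## the opposite stimulus and the control stay at baseline (fold 1)
  rbind(
    IL4_early          = c(stimulus = NA, 6.0, 2.0, 1.0, 1.0),
    IL4_mid            = c(NA, 1.5, 6.0, 2.0, 1.0),
    IL4_late           = c(NA, 1.0, 1.5, 4.0, 6.0),
    LPS_early_transient = c(NA, 8.0, 3.0, 1.0, 1.0),
    LPS_early_sustained = c(NA, 6.0, 5.0, 4.0, 3.0),
    LPS_mid            = c(NA, 1.0, 6.0, 3.0, 1.0),
    LPS_broad          = c(NA, 3.0, 6.0, 6.0, 3.0),
    LPS_late           = c(NA, 1.0, 1.5, 4.0, 8.0))[, -1]
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: 20,000
#' candidate sites on a 50-Mb toy genome, five TFs with collaborative
#' co-binding (first TF = pioneer), openness as a thresholded noisy sigmoid
#' of weighted occupancy calibrated so two-thirds of the pioneer's bound
#' sites are closed, duplicate peak sets with 1% drop-out, Poisson tag
#' libraries, and 8 kinetic archetypes (3 IL-4-like, 5 LPS-like) over
#' 1/3/6/24 h.
#'
#' @param seed master seed; substreams derive from it by fixed offsets.
#' @param n_chrom,chrom_length toy genome shape.
#' @param n_sites candidate regulatory sites.
#' @param tf_params data.frame with columns `tf`, `prevalence`, `bind_hi`,
#'   `bind_lo` (binding probability given motif, with/without the pioneer),
#'   `mu_log`, `sd_log` (log-normal occupancy strength), `weight`
#'   (openness rule weight), `tag_rate` (mean tags per occupancy unit).
#' @param sigma_open noise sd of the openness score.
#' @param tau openness threshold on the sigmoid scale.
#' @param closed_fraction_focal calibrated closed fraction of the pioneer
#'   cistrome (intercept is set so this holds exactly in truth).
#' @param n_replicates replicate peak sets per track.
#' @param drop_out per-replicate peak drop-out probability.
#' @param peak_width_mean,peak_width_sd,atac_width_mean,jitter peak shape.
#' @param atac_rate mean ATAC tags at full openness.
#' @param frag_len,tag_sd fragment length and placement spread.
#' @param bg_tags uniform background tags per library.
#' @param library_size nominal mapped-library size.
#' @param timepoints,n_regulated,n_flat,sigma_kin,baseline_mu_log,
#'   baseline_sd_log,archetypes time-course shape; `archetypes` is an
#'   8 x 4 fold matrix (rownames prefixed `IL4_`/`LPS_`).
#' @param tc_replicates replicates per time-course condition.
#' @param n_genes synthetic TSS count for gene association.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L, chrom_length = 1e7,
                       n_sites = 20000L,
                       tf_params = .default_tf_params(),
                       sigma_open = 0.2, tau = 0.5,
                       closed_fraction_focal = 2 / 3,
                       n_replicates = 2L, drop_out = 0.01,
                       peak_width_mean = 250, peak_width_sd = 30,
                       atac_width_mean = 350, jitter = 30,
                       atac_rate = 80, frag_len = 150, tag_sd = 80,
                       bg_tags = 50000L, library_size = 1e6,
                       timepoints = c(1, 3, 6, 24),
                       n_regulated = 4000L, n_flat = 4000L,
                       sigma_kin = 0.3,
                       baseline_mu_log = log(60), baseline_sd_log = 0.4,
                       archetypes = .default_archetypes(),
                       tc_replicates = 2L,
                       n_genes = 500L) {
  stopifnot(n_sites > 0, sigma_open >= 0, sigma_kin >= 0,
            drop_out >= 0, drop_out <= 1,
            tau > 0, tau < 1, n_replicates >= 1)
  d <- as.matrix(dist(archetypes))
  if (any(d[upper.tri(d)] == 0))
    stop("archetype curves must be pairwise distinct")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "-", x$n_sites, "sites on",
      x$n_chrom, "x", format(x$chrom_length, big.mark = ","), "bp;",
      nrow(x$tf_params), "TFs; sigma_open", x$sigma_open, "\n")
  invisible(x)
}

sim_assembly <- function(cfg) {
  genome_assembly(setNames(rep(as.integer(cfg$chrom_length), cfg$n_chrom),
                           paste0("chr", seq_len(cfg$n_chrom))),
                  genome = "sim1")
}

place_sites <- function(cfg) {
  per <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_chrom + 1)))
  out <- lapply(seq_len(cfg$n_chrom), function(ci) {
    n <- per[ci]
    slot <- cfg$chrom_length %/% n
    margin <- min(1000, slot %/% 4)
    centers <- (seq_len(n) - 1) * slot + margin +
      floor(runif(n) * (slot - 2 * margin))
    data.frame(chrom = paste0("chr", ci), center = as.integer(centers))
  })
  do.call(rbind, out)
}

peak_granges <- function(sites, keep, width_mean, width_sd, jitter,
                         assembly, label) {
  idx <- which(keep)
  n <- length(idx)
  w <- pmin(pmax(round(rnorm(n, width_mean, width_sd)), 150L), 600L)
  off <- round(runif(n, -jitter, jitter))
  center <- sites$center[idx] + off
  start0 <- pmax(center - w %/% 2L, 0L)
  summit <- sites$center[idx] - start0
  summit <- pmin(pmax(summit, 0L), w - 1L)
  gr <- region_set(chrom = sites$chrom[idx], start = start0,
                   end = start0 + w, assembly = assembly,
                   name = sites$site_id[idx], summit = summit,
                   label = label)
  gr
}

#' Simulate collaborative TF cistromes and open chromatin
#'
#' Sites are placed without overlap on the toy genome; each TF binds via a
#' motif-prevalence x conditional-binding model in which the pioneer's
#' presence boosts the other TFs (collaborative co-binding); occupancy
#' strengths are log-normal.  The openness score is
#' `sum(w_t * occ_t) + intercept + N(0, sigma_open)`; the intercept is
#' calibrated so that `closed_fraction_focal` of the pioneer's bound sites
#' fall below the sigmoid threshold `tau`.  Replicate narrowPeak-style peak
#' sets with boundary jitter and drop-out are emitted for each TF and for
#' ATAC (ATAC peaks only where the true open state holds).
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cistromes`: `assembly`, `truth` (data.frame
#'   with per-site bound flags, occupancies, openness score/value/state),
#'   `tf_replicates` (tf -> list of replicate `GRanges`),
#'   `atac_replicates`, `intercept`, `config`.
#' @export
simulate_cistromes <- function(cfg) {
  assembly <- sim_assembly(cfg)
  if (cfg$chrom_length * cfg$n_chrom < cfg$n_sites * 1500)
    stop("genome too small for n_sites non-overlapping sites")
  set.seed(cfg$seed + 101L)
  sites <- place_sites(cfg)
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  tfp <- cfg$tf_params
  n <- nrow(sites)
  ntf <- nrow(tfp)
  bound <- matrix(FALSE, n, ntf, dimnames = list(NULL, tfp$tf))
  occ <- matrix(0, n, ntf, dimnames = list(NULL, tfp$tf))
  motif <- matrix(runif(n * ntf) < rep(tfp$prevalence, each = n), n, ntf)
  ## pioneer first: its binding conditions the others
  bound[, 1] <- motif[, 1] & (runif(n) < tfp$bind_hi[1])
  for (t in seq_len(ntf)[-1]) {
    p <- ifelse(bound[, 1], tfp$bind_hi[t], tfp$bind_lo[t])
    bound[, t] <- motif[, t] & (runif(n) < p)
  }
  for (t in seq_len(ntf))
    occ[bound[, t], t] <- rlnorm(sum(bound[, t]), tfp$mu_log[t],
                                 tfp$sd_log[t])
  score <- drop(occ %*% tfp$weight) + rnorm(n, 0, cfg$sigma_open)
  focal_bound <- bound[, 1]
  intercept <- log(cfg$tau / (1 - cfg$tau)) -
    quantile(score[focal_bound], probs = cfg$closed_fraction_focal,
             names = FALSE, type = 1)
  openness_value <- plogis(score + intercept)
  open <- openness_value > cfg$tau
  truth <- data.frame(sites,
                      bound = I(bound), occ = I(occ),
                      score = score, openness_value = openness_value,
                      open = open, stringsAsFactors = FALSE)
  tf_replicates <- setNames(lapply(seq_len(ntf), function(t) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      keep <- bound[, t] & (runif(n) >= cfg$drop_out)
      peak_granges(sites, keep, cfg$peak_width_mean, cfg$peak_width_sd,
                   cfg$jitter, assembly,
                   label = paste0(tfp$tf[t], "_rep", r))
    })
  }), tfp$tf)
  atac_replicates <- lapply(seq_len(cfg$n_replicates), function(r) {
    keep <- open & (runif(n) >= cfg$drop_out)
    peak_granges(sites, keep, cfg$atac_width_mean, cfg$peak_width_sd,
                 cfg$jitter, assembly, label = paste0("ATAC_rep", r))
  })
  structure(list(assembly = assembly, truth = truth,
                 tf_replicates = tf_replicates,
                 atac_replicates = atac_replicates,
                 intercept = unname(intercept), config = cfg),
            class = "sim_cistromes")
}

#' @export
print.sim_cistromes <- function(x, ...) {
  cat("sim_cistromes:", nrow(x$truth), "sites;",
      ncol(x$truth$bound), "TFs;",
      sum(x$truth$open), "open sites\n")
  invisible(x)
}

sim_tag_track <- function(sites, lambda, cfg, assembly, label) {
  has <- which(lambda > 0)
  n_site <- rpois(length(has), lambda[has])
  idx <- rep(has, n_site)
  center <- sites$center[idx] + round(rnorm(length(idx), 0, cfg$tag_sd))
  n_bg <- cfg$bg_tags
  bg_chrom <- sample(cfg$n_chrom, n_bg, replace = TRUE)
  bg_center <- floor(runif(n_bg) * (cfg$chrom_length - cfg$frag_len))
  chrom <- c(sites$chrom[idx], paste0("chr", bg_chrom))
  start0 <- pmax(c(center, bg_center) - cfg$frag_len %/% 2L, 0L)
  gr <- region_set(chrom = chrom, start = start0,
                   end = start0 + cfg$frag_len, assembly = assembly,
                   label = label)
  tag_library(gr, library_size = max(cfg$library_size, length(gr)),
              label = label)
}

#' Simulate tag libraries for every TF track and ATAC
#'
#' Per bound site, tag counts are Poisson with mean `tag_rate x occupancy`
#' (for ATAC: `atac_rate x openness_value`, so accessibility is graded
#' rather than binary); fragments scatter around site centers, plus a
#' uniform background.  `library_size` is the configured nominal total.
#'
#' @param cfg a [sim_config()].
#' @param sim a [simulate_cistromes()] result.
#' @return named list of [tag_library()] objects (TF names plus `"ATAC"`).
#' @export
simulate_tags <- function(cfg, sim) {
  set.seed(cfg$seed + 202L)
  sites <- sim$truth
  tfp <- cfg$tf_params
  libs <- setNames(lapply(seq_len(nrow(tfp)), function(t) {
    sim_tag_track(sites, tfp$tag_rate[t] * sites$occ[, t], cfg,
                  sim$assembly, tfp$tf[t])
  }), tfp$tf)
  libs$ATAC <- sim_tag_track(sites, cfg$atac_rate * sites$openness_value,
                             cfg, sim$assembly, "ATAC")
  libs
}

#' Simulate the RNAPII-pS2 time-course count matrix
#'
#' Regulated sites are drawn from the truth's labelled (bound, closed)
#' sites and assigned one of the 8 kinetic archetypes in equal proportions;
#' their counts follow `baseline x archetype fold x exp(N(0, sigma_kin))`
#' (biological noise shared across replicates) with Poisson replicate
#' noise, scaled by each replicate's library-size factor.  Non-regulated
#' sites stay flat at baseline; the control condition is baseline for all.
#'
#' @param cfg a [sim_config()].
#' @param sim a [simulate_cistromes()] result.
#' @return list of class `sim_timecourse`: `tc` (a
#'   [timecourse_matrix()]), `truth` (data.frame: `region_id`, `site_id`,
#'   `regulated`, `archetype`).
#' @export
simulate_timecourse <- function(cfg, sim) {
  set.seed(cfg$seed + 303L)
  truth <- sim$truth
  lre_sites <- which(rowSums(truth$bound) > 0 & !truth$open)
  if (length(lre_sites) < cfg$n_regulated)
    stop("not enough labelled sites (", length(lre_sites),
         ") for n_regulated = ", cfg$n_regulated)
  reg <- sort(sample(lre_sites, cfg$n_regulated))
  flat_pool <- setdiff(seq_len(nrow(truth)), reg)
  flat <- sort(sample(flat_pool, min(cfg$n_flat, length(flat_pool))))
  sel <- c(reg, flat)
  regulated <- c(rep(TRUE, length(reg)), rep(FALSE, length(flat)))
  arch <- cfg$archetypes
  k <- nrow(arch)
  archetype <- rep(NA_character_, length(sel))
  archetype[regulated] <- rownames(arch)[
    sample(rep_len(seq_len(k), length(reg)))]
  stimuli <- sub("_.*$", "", rownames(arch))
  conditions <- rbind(
    data.frame(id = "control", stimulus = "control", timepoint = 0),
    do.call(rbind, lapply(unique(stimuli), function(st)
      data.frame(id = paste0(st, "_", cfg$timepoints), stimulus = st,
                 timepoint = cfg$timepoints))))
  fold <- matrix(1, nrow = length(sel), ncol = nrow(conditions),
                 dimnames = list(NULL, conditions$id))
  for (a in rownames(arch)) {
    rows <- which(!is.na(archetype) & archetype == a)
    st <- sub("_.*$", "", a)
    fold[rows, paste0(st, "_", cfg$timepoints)] <-
      rep(arch[a, ], each = length(rows))
  }
  baseline <- rlnorm(length(sel), cfg$baseline_mu_log, cfg$baseline_sd_log)
  bio <- matrix(exp(rnorm(length(sel) * nrow(conditions), 0, cfg$sigma_kin)),
                nrow = length(sel))
  bio[, conditions$id == "control"] <- 1
  mu <- baseline * fold * bio
  lib <- matrix(round(runif(nrow(conditions) * cfg$tc_replicates,
                            0.85, 1.15) * cfg$library_size),
                nrow = nrow(conditions))
  med <- median(lib)
  counts <- array(0L, dim = c(length(sel), nrow(conditions),
                              cfg$tc_replicates))
  for (r in seq_len(cfg$tc_replicates)) {
    lam <- sweep(mu, 2L, lib[, r] / med, `*`)
    counts[, , r] <- rpois(length(lam), lam)
  }
  half <- 150L
  start0 <- pmax(truth$center[sel] - half, 0L)
  ord <- BiocGenerics::order(GenomicRanges::GRanges(
    truth$chrom[sel], IRanges::IRanges(start0 + 1L, width = 2L * half),
    seqinfo = sim$assembly))
  regions <- region_set(chrom = truth$chrom[sel][ord],
                        start = start0[ord], end = start0[ord] + 2L * half,
                        assembly = sim$assembly,
                        name = truth$site_id[sel][ord],
                        label = "RNAPII-pS2")
  tc <- timecourse_matrix(regions, conditions,
                          counts[ord, , , drop = FALSE], lib)
  structure(list(
    tc = tc,
    truth = data.frame(region_id = region_ids(regions),
                       site_id = truth$site_id[sel][ord],
                       regulated = regulated[ord],
                       archetype = archetype[ord],
                       stringsAsFactors = FALSE)),
    class = "sim_timecourse")
}

#' Simulate a stranded synthetic gene model (TSS set)
#'
#' @param cfg a [sim_config()].
#' @param assembly assembly from [simulate_cistromes()].
#' @return stranded width-1 `GRanges` with a `gene` column.
#' @export
simulate_genes <- function(cfg, assembly) {
  set.seed(cfg$seed + 404L)
  chrom <- paste0("chr", sample(cfg$n_chrom, cfg$n_genes, replace = TRUE))
  pos <- floor(runif(cfg$n_genes) * (cfg$chrom_length - 1)) + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = sample(c("+", "-"), cfg$n_genes,
                                               replace = TRUE),
                               seqinfo = assembly)
  gr$gene <- sprintf("gene%04d", seq_len(cfg$n_genes))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
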