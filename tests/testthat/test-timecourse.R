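# Differential occupancy against the untreated control, regulated-region
# selection, kinetic k-means clustering and gene association.

simple_tc <- function(ctrl, trt, lib = matrix(1e6, 2, 2), asm = toy_assembly()) {
  n <- nrow(ctrl)
  regions <- region_set(rep("chrT", n), seq(0, by = 1000, length.out = n) + 1,
                        seq(0, by = 1000, length.out = n) + 501, asm)
  conditions <- data.frame(id = c("control", "treat_1"),
                           stimulus = c("control", "treat"),
                           timepoint = c(0, 1))
  counts <- array(0L, dim = c(n, 2, ncol(ctrl)))
  counts[, 1, ] <- ctrl
  counts[, 2, ] <- trt
  timecourse_matrix(regions, conditions, counts, lib)
}

test_that("median-library normalisation rescales counts as specified", {
  tc <- simple_tc(cbind(c(10, 20), c(10, 20)), cbind(c(30, 40), c(30, 40)))
  norm <- normalize_counts(tc)
  expect_equal(norm, tc$counts + 0)  # equal libraries -> unchanged
  lib <- matrix(c(1e6, 2e6, 1e6, 1e6), 2, 2)  # one library 2x the median
  tc2 <- simple_tc(cbind(c(10, 20), c(8, 16)), cbind(c(30, 40), c(30, 40)),
                   lib = lib)
  norm2 <- normalize_counts(tc2)
  med <- median(lib)
  for (j in 1:2) for (r in 1:2)
    expect_equal(norm2[, j, r], tc2$counts[, j, r] * med / lib[j, r],
                 ignore_attr = TRUE)
})

test_that("differential matches the Welch oracle on the worked example", {
  # region 1: control (10,10) / treated (50,52); region 2 is a filler
  tc <- simple_tc(cbind(c(10, 99), c(10, 101)), cbind(c(50, 100), c(52, 100)))
  d <- differential_occupancy(tc, "treat_1")
  expect_equal(d$fold_change[1], (51 + 1) / (10 + 1))   # ~4.7
  expect_lt(d$p_value[1], 0.05)
  # oracle: stats::t.test on the same log2 values
  want <- t.test(log2(c(50, 52) + 1), log2(c(10, 10) + 1))$p.value
  expect_equal(d$p_value[1], want, tolerance = 1e-12)
  # identical replicates -> FC 1, p = 1
  tci <- simple_tc(cbind(c(30, 30), c(30, 30)), cbind(c(30, 30), c(30, 30)))
  di <- differential_occupancy(tci, "treat_1")
  expect_equal(di$fold_change[1], 1)
  expect_gte(di$p_value[1], 0.99)
  # treated all zero, control positive -> FC < 1
  tcd <- simple_tc(cbind(c(40, 10), c(44, 10)), cbind(c(0, 10), c(0, 10)))
  expect_lt(differential_occupancy(tcd, "treat_1")$fold_change[1], 1)
  expect_error(differential_occupancy(tc, "nope"), "unknown")
})

test_that("vectorised Welch p-values equal stats::t.test on random data", {
  set.seed(17)
  a <- matrix(rnorm(120, mean = 5), ncol = 3)
  b <- matrix(rnorm(160, mean = 4.5), ncol = 4)
  p <- lrescout:::welch_p(a, b)
  want <- vapply(seq_len(nrow(a)), function(i)
    t.test(a[i, ], b[i, ])$p.value, numeric(1))
  expect_equal(p, want, tolerance = 1e-12)
})

test_that("select_regulated returns exactly the designed passing subset", {
  fx <- differential_fixture()
  d <- differential_all(fx$tc)
  got <- select_regulated(d, fc_min = 2, p_max = 0.05, occ_min = 30)
  expect_setequal(got, fx$pass)
  # loose thresholds admit every non-degenerate region
  all_ids <- unique(d$region_id[d$p_value < 1])
  expect_setequal(select_regulated(d, fc_min = 1e-9, p_max = 1, occ_min = 0,
                                   direction = "both"),
                  all_ids)
  # an impossible fold-change admits nothing
  expect_length(select_regulated(d, fc_min = Inf), 0L)
})

test_that("select_regulated is monotone under threshold tightening", {
  set.seed(23)
  for (trial in 1:5) {
    ctrl <- matrix(rpois(40, 30), ncol = 2)
    trt <- matrix(rpois(40, 60), ncol = 2)
    tc <- simple_tc(ctrl, trt)
    d <- differential_all(tc)
    base <- select_regulated(d, fc_min = 1.2, p_max = 0.2, occ_min = 10)
    for (args in list(list(fc_min = 2), list(p_max = 0.05),
                      list(occ_min = 40))) {
      tight <- do.call(select_regulated,
                       c(list(d), modifyList(list(fc_min = 1.2, p_max = 0.2,
                                                  occ_min = 10), args)))
      expect_true(all(tight %in% base))
    }
  }
})

test_that("k-means recovers separable archetypes and is deterministic", {
  set.seed(29)
  proto <- rbind(c(10, 1, 1, 1), c(1, 1, 1, 10))
  sig <- proto[rep(1:2, each = 30), ] + matrix(rnorm(240, 0, 0.01), 60)
  rownames(sig) <- paste0("r", 1:60)
  colnames(sig) <- paste0("c", 1:4)
  cl <- cluster_kinetics(sig, k = 2, seed = 3)
  expect_equal(adjusted_rand_index(cl$assignment, rep(1:2, each = 30)), 1)
  cl2 <- cluster_kinetics(sig, k = 2, seed = 3)
  expect_identical(cl$assignment, cl2$assignment)
  expect_error(cluster_kinetics(sig, k = 100), "exceeds")
  # z rows have mean 0 / sd 1 and constant rows collapse to zero
  sig2 <- rbind(sig, flat = rep(5, 4))
  z <- zscore_rows(sig2)
  expect_equal(unname(rowMeans(z)), rep(0, 61))
  expect_equal(unname(z["flat", ]), rep(0, 4))
})

test_that("clustering beats random assignments on within-cluster SS", {
  set.seed(31)
  sig <- matrix(rnorm(400), 100, 4,
                dimnames = list(paste0("r", 1:100), paste0("c", 1:4)))
  cl <- cluster_kinetics(sig, k = 5, seed = 7, restarts = 10)
  z <- cl$z
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      rows <- z[assign == k, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
  }
  rand_wss <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    wss_of(sample(rep_len(1:5, 100)))
  }, numeric(1))
  expect_true(cl$withinss <= min(rand_wss))
})

test_that("adjusted Rand index matches the established implementation", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (i in 1:10) {
    a <- sample(1:4, 80, replace = TRUE)
    b <- sample(letters[1:3], 80, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2) * 10),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2) * 10))
})

test_that("gene association respects the window bound and matches brute force", {
  asm <- genome_assembly(c(chrT = 1000000L))
  regions <- region_set(rep("chrT", 3), c(100000, 400000, 700000),
                        c(100500, 400500, 700500), asm)
  cl <- list(assignment = setNames(c(1L, 2L, 1L), region_ids(regions)),
             k = 2L)
  class(cl) <- "enhancer_clusters"
  tss <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(c(70500, 160600), width = 1),
                                strand = "+", seqinfo = asm)
  tss$gene <- c("near", "far")  # 29.5 kb and 60 kb from region 1
  assoc <- associate_genes(cl, regions, tss, window_bp = 100000)
  expect_equal(assoc$gene, "near")
  expect_equal(assoc$cluster, 1L)
  # brute-force all-pairs distance scan on random instances
  set.seed(41)
  rdf <- random_intervals(40, len = 1000000L)
  rgr <- df_to_gr(rdf, asm)
  cl2 <- list(assignment = setNames(sample(1:3, 40, TRUE), region_ids(rgr)),
              k = 3L)
  class(cl2) <- "enhancer_clusters"
  tpos <- sort(sample.int(999000L, 25L))
  tss2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(tpos, width = 1),
                                 strand = sample(c("+", "-"), 25, TRUE),
                                 seqinfo = asm)
  tss2$gene <- paste0("g", seq_len(25))
  got <- associate_genes(cl2, rgr, tss2, window_bp = 100000)
  got_pairs <- sort(paste(got$gene, got$region_id))
  want_pairs <- character(0)
  for (i in seq_len(25)) {
    t0 <- tpos[i] - 1L  # 0-based TSS
    for (j in seq_len(40)) {
      gap <- max(rdf$start[j] - t0 - 1L, t0 - rdf$end[j], 0L)
      if (gap <= 50000L)
        want_pairs <- c(want_pairs,
                        paste(tss2$gene[i],
                              paste("chrT", rdf$start[j], rdf$end[j],
                                    sep = "_")))
    }
  }
  expect_equal(got_pairs, sort(want_pairs))
})

test_that("cluster x LRE-type overlap counts match a direct recount", {
  asm <- toy_assembly()
  set.seed(43)
  rdf <- random_intervals(60)
  regions <- df_to_gr(rdf, asm)
  cl <- list(assignment = setNames(sample(1:2, 60, TRUE),
                                   region_ids(regions)), k = 2L)
  class(cl) <- "enhancer_clusters"
  ldf <- random_intervals(80)
  lre <- df_to_gr(ldf, asm)
  sigs <- sample(c("PU.1", "PU.1+IRF8"), 80, TRUE)
  counts <- lre_cluster_enrichment(cl, regions, lre, sigs, min_overlap = 0)
  for (ty in rownames(counts)) {
    hit <- oracle_hits(gr_to_df(regions), ldf[sigs == ty, ], 100000L)
    for (k in 1:2)
      expect_equal(counts[ty, paste0("EC", k)],
                   sum(hit & cl$assignment[region_ids(regions)] == k))
  }
  # suppression threshold and disjoint case
  expect_equal(nrow(lre_cluster_enrichment(cl, regions, lre, sigs,
                                           min_overlap = 1000L)), 0L)
  far <- region_set("chrT", 99000, 99500, asm)
  clf <- list(assignment = setNames(1L, region_ids(far)), k = 1L)
  class(clf) <- "enhancer_clusters"
  near <- region_set("chrT", 0, 100, asm)
  expect_equal(nrow(lre_cluster_enrichment(clf, far, near, "PU.1",
                                           min_overlap = 1L)), 0L)
})
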