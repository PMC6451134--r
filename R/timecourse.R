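## Time-course differential occupancy and kinetic enhancer clustering:
## median-library normalisation, Welch test on log2 replicate values
## against the untreated control, threshold-based regulated-region
## selection (FC > 2, p < 0.05, minimum normalised occupancy), row
## z-scoring + k-means into kinetic enhancer clusters (ECs) and gene
## association within a fixed window.

#' Construct a time-course count container
#'
#' @param regions `GRanges` of quantified regions.
#' @param conditions data.frame with columns `id`, `stimulus`, `timepoint`
#'   (hours; the control row has `stimulus = "control"`).
#' @param counts integer array of dim (regions, conditions, replicates).
#' @param library_sizes matrix (conditions x replicates) of mapped-library
#'   sizes.
#' @param control id of the control condition (default `"control"`).
#' @return object of class `timecourse_matrix`.
#' @export
timecourse_matrix <- function(regions, conditions, counts, library_sizes,
                              control = "control") {
  stopifnot(dim(counts)[1] == length(regions),
            dim(counts)[2] == nrow(conditions),
            dim(counts)[3] == ncol(library_sizes),
            nrow(library_sizes) == nrow(conditions))
  if (!control %in% conditions$id)
    stop("control condition '", control, "' not present")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  dimnames(counts) <- list(region_ids(regions), conditions$id, NULL)
  structure(list(regions = regions, conditions = conditions,
                 counts = counts, library_sizes = library_sizes,
                 control = control),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat("timecourse_matrix:", length(x$regions), "regions x",
      nrow(x$conditions), "conditions x", dim(x$counts)[3], "replicates\n")
  invisible(x)
}

#' Median-library normalisation of time-course counts
#'
#' Each replicate's counts are scaled by `median(library_sizes) /
#' library_size`, so a library twice the median has its counts halved.
#'
#' @param tc a [timecourse_matrix()].
#' @return numeric array of normalised occupancy, same dim as `tc$counts`.
#' @export
normalize_counts <- function(tc) {
  med <- median(tc$library_sizes)
  out <- tc$counts
  for (j in seq_len(dim(out)[2]))
    for (r in seq_len(dim(out)[3]))
      out[, j, r] <- out[, j, r] * med / tc$library_sizes[j, r]
  out
}

#' Differential occupancy of one condition against the control
#'
#' Fold change is computed on mean normalised occupancy with pseudocount 1:
#' `FC = (mean treated + 1) / (mean control + 1)`; the p-value is a
#' two-sided Welch two-sample t-test on `log2(normalised + 1)` replicate
#' values.  Identical replicate vectors yield p = 1.
#'
#' @param tc a [timecourse_matrix()].
#' @param condition condition id to test.
#' @return data.frame per region: `region_id`, `condition`, `mean_control`,
#'   `mean_treated`, `fold_change`, `p_value`, `p_adjusted` (BH).
#' @export
differential_occupancy <- function(tc, condition) {
  if (!condition %in% tc$conditions$id)
    stop("unknown condition: ", condition)
  norm <- normalize_counts(tc)
  ci <- match(tc$control, tc$conditions$id)
  ti <- match(condition, tc$conditions$id)
  ctrl <- norm[, ci, , drop = TRUE]
  treat <- norm[, ti, , drop = TRUE]
  if (is.null(dim(ctrl)) || ncol(ctrl) < 2L || ncol(treat) < 2L)
    stop("at least 2 replicates required in condition and control")
  mean_c <- rowMeans(ctrl)
  mean_t <- rowMeans(treat)
  fc <- (mean_t + 1) / (mean_c + 1)
  lc <- log2(ctrl + 1)
  lt <- log2(treat + 1)
  p <- welch_p(lt, lc)
  data.frame(region_id = region_ids(tc$regions), condition = condition,
             mean_control = mean_c, mean_treated = mean_t,
             fold_change = fc, p_value = p,
             p_adjusted = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Row-wise two-sided Welch t-test (unequal variances, Welch-Satterthwaite
## df), vectorised over regions; degenerate rows (both groups constant)
## get p = 1 when the means agree and p = 0 otherwise, matching the limit
## of the test.
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  p <- numeric(length(ma))
  degen <- se2 == 0
  p[degen] <- ifelse(abs(ma[degen] - mb[degen]) < 1e-12, 1, 0)
  ok <- !degen
  tstat <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' Differential occupancy for every non-control condition
#'
#' @param tc a [timecourse_matrix()].
#' @return data.frame, rbind of [differential_occupancy()] results.
#' @export
differential_all <- function(tc) {
  conds <- setdiff(tc$conditions$id, tc$control)
  do.call(rbind, lapply(conds, function(cd) differential_occupancy(tc, cd)))
}

#' Select regulated regions by fold-change, p-value and occupancy
#'
#' A region is regulated if, in at least one tested condition, it passes
#' all three thresholds: `FC > fc_min` (direction `"up"`; `< 1/fc_min` for
#' `"down"`, either for `"both"`), raw `p < p_max`, and mean normalised
#' occupancy above `occ_min` (treated mean for up, control mean for down,
#' either for both).  Defaults follow the distal-element thresholds
#' (FC > 2, p < 0.05, occupancy > 30); use `occ_min = 50` for gene bodies.
#' No multiple-testing correction is applied to the selection (the BH
#' column in the differential table is informational).
#'
#' @param diff a [differential_all()] (or single-condition) data.frame.
#' @param fc_min fold-change threshold (default 2).
#' @param p_max p-value threshold (default 0.05).
#' @param occ_min minimum mean normalised occupancy (default 30).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of regulated `region_id`s.
#' @export
select_regulated <- function(diff, fc_min = 2, p_max = 0.05, occ_min = 30,
                             direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (fc_min <= 0 || p_max <= 0) stop("thresholds must be positive")
  up <- diff$fold_change > fc_min & diff$mean_treated > occ_min
  down <- diff$fold_change < 1 / fc_min & diff$mean_control > occ_min
  dir_ok <- switch(direction, up = up, down = down, both = up | down)
  pass <- dir_ok & diff$p_value < p_max
  unique(diff$region_id[pass])
}

#' Row z-scores
#'
#' @param m numeric matrix.
#' @return matrix with rows centred to mean 0, sd 1 (constant rows become
#'   all zero).
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' K-means clustering of kinetic profiles into enhancer clusters
#'
#' Rows (regions) of the region x condition mean-signal matrix are
#' z-scored, then clustered with `stats::kmeans` using `restarts` random
#' starts (the best by total within-cluster sum of squares wins). Clusters
#' are relabelled by the condition at which their centroid peaks (ordered
#' by stimulus, then timepoint, then decreasing size) so numbering is
#' stable across runs.
#'
#' @param signal region x condition numeric matrix (mean normalised
#'   occupancy), with condition ids as colnames.
#' @param conditions the condition data.frame (`id`, `stimulus`,
#'   `timepoint`) used for relabelling; optional.
#' @param k number of clusters (default 8).
#' @param seed RNG seed (default 1).
#' @param restarts random restarts (default 25).
#' @return list of class `enhancer_clusters`: `assignment` (integer per
#'   region, named), `centroids` (k x condition), `z`, `k`, `withinss`.
#' @export
cluster_kinetics <- function(signal, conditions = NULL, k = 8L, seed = 1L,
                             restarts = 25L) {
  if (k > nrow(signal))
    stop("k (", k, ") exceeds the number of regions (", nrow(signal), ")")
  z <- zscore_rows(signal)
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = restarts, iter.max = 100L)
  ## stable relabelling by peak condition of each centroid
  peak <- apply(km$centers, 1L, which.max)
  if (!is.null(conditions)) {
    ord_cond <- order(match(conditions$stimulus,
                            unique(conditions$stimulus)),
                      conditions$timepoint)
    peak_rank <- match(peak, ord_cond)
  } else {
    peak_rank <- peak
  }
  relabel <- order(peak_rank, -as.integer(km$size))
  new_id <- match(seq_len(k), relabel)
  assignment <- new_id[km$cluster]
  names(assignment) <- rownames(signal)
  centroids <- km$centers[relabel, , drop = FALSE]
  rownames(centroids) <- paste0("EC", seq_len(k))
  structure(list(assignment = assignment, centroids = centroids, z = z,
                 k = k, withinss = km$tot.withinss),
            class = "enhancer_clusters")
}

#' @export
print.enhancer_clusters <- function(x, ...) {
  cat("enhancer_clusters: k =", x$k, "over", length(x$assignment),
      "regions; sizes:", paste(table(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered clustering and a
#' reference labelling (1 = identical partitions, ~0 = random).
#'
#' @param a,b equal-length label vectors.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (isTRUE(all.equal(max_index, expected))) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Associate genes with regulated regions within a window
#'
#' A gene is associated with a regulated region if the distance between its
#' TSS and the nearest point of the region is at most `window_bp / 2`
#' (a "`window_bp`-wide" window centred on the TSS; set
#' `half_window = window_bp` explicitly for the +/- `window_bp`
#' alternative).  Genes inherit the kinetic clusters of their associated
#' regions.
#'
#' @param clusters an [cluster_kinetics()] result whose assignment names
#'   are region ids of `regions`.
#' @param regions `GRanges` of the clustered regulated regions.
#' @param tss stranded TSS `GRanges` with a `gene` column.
#' @param window_bp total window width (default 100000).
#' @param half_window override of the one-sided distance bound.
#' @return data.frame with `gene`, `region_id`, `cluster`, `distance`.
#' @export
associate_genes <- function(clusters, regions, tss, window_bp = 100000L,
                            half_window = NULL) {
  if (is.null(half_window)) half_window <- window_bp %/% 2L
  win <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(tss, width = 2L * half_window + 1L,
                          fix = "center", ignore.strand = TRUE)))
  ov <- GenomicRanges::findOverlaps(win, regions, ignore.strand = TRUE)
  if (!length(ov))
    return(data.frame(gene = character(), region_id = character(),
                      cluster = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  gi <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  dist <- GenomicRanges::distance(tss[gi], regions[ri],
                                  ignore.strand = TRUE)
  ids <- region_ids(regions)[ri]
  data.frame(gene = tss$gene[gi], region_id = ids,
             cluster = unname(clusters$assignment[ids]),
             distance = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Overlap counts between enhancer clusters and co-LRE types
#'
#' For each (cluster, exact TF-subset LRE type) pair, counts the regulated
#' regions overlapping (>= 1 bp) an LRE of that type; LRE types whose
#' maximum per-cluster count is below `min_overlap` are suppressed.
#'
#' @param clusters an [cluster_kinetics()] result.
#' @param regions `GRanges` of the clustered regions (ids match the
#'   assignment names).
#' @param lre_regions `GRanges` of labelled regions.
#' @param lre_signature character vector: exact bound TF subset
#'   (`+`-joined) per `lre_regions` entry.
#' @param min_overlap suppression threshold (default 100).
#' @return matrix (LRE type x cluster) of overlap counts.
#' @export
lre_cluster_enrichment <- function(clusters, regions, lre_regions,
                                   lre_signature, min_overlap = 100L) {
  stopifnot(length(lre_signature) == length(lre_regions))
  ks <- sort(unique(clusters$assignment))
  types <- unique(lre_signature)
  counts <- matrix(0L, nrow = length(types), ncol = length(ks),
                   dimnames = list(types, paste0("EC", ks)))
  ids <- region_ids(regions)
  for (ty in types) {
    lre_ty <- lre_regions[lre_signature == ty]
    hit <- GenomicRanges::countOverlaps(regions, lre_ty,
                                        ignore.strand = TRUE) > 0L
    for (j in seq_along(ks)) {
      in_k <- clusters$assignment[ids] == ks[j]
      counts[ty, j] <- sum(hit & in_k)
    }
  }
  counts[apply(counts, 1L, max) >= min_overlap, , drop = FALSE]
}
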