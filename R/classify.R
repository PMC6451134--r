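## The core classification procedure: build the unified cistrome (regions
## bound by at least one studied TF), intersect with open chromatin, assign
## the four focal-TF categories, count co-binding and enumerate co-LRE TF
## subsets.

#' Bundle TF cistromes with an open-chromatin set
#'
#' @param cistromes named list of consensus, blacklist-filtered `GRanges`,
#'   one per TF (e.g. PU.1, IRF8, JUNB, CEBPA, RUNX1).
#' @param open_chromatin ATAC-seq consensus `GRanges`.
#' @return object of class `cistrome_collection`.
#' @export
cistrome_collection <- function(cistromes, open_chromatin) {
  tf_names <- names(cistromes)
  if (is.null(tf_names) || anyDuplicated(tf_names))
    stop("cistromes must be a uniquely named list")
  if (any(vapply(cistromes, length, integer(1)) == 0L))
    stop("every cistrome must be non-empty")
  structure(list(tf_names = tf_names, cistromes = cistromes,
                 open_chromatin = open_chromatin),
            class = "cistrome_collection")
}

#' @export
print.cistrome_collection <- function(x, ...) {
  cat("cistrome_collection:", length(x$tf_names), "TFs (",
      paste(x$tf_names, collapse = ", "), ");",
      length(x$open_chromatin), "open-chromatin regions\n")
  invisible(x)
}

#' Unified cistrome: regions bound by at least one studied TF
#'
#' The concatenation of all cistromes is merged; each merged region is
#' annotated with the set of TFs whose peaks overlap it by >= 1 bp
#' (`bound` logical matrix) and the co-binding count.
#'
#' @param cc a [cistrome_collection()].
#' @return `GRanges` with a `bound` matrix column (region x TF) and
#'   `cobind_count`.
#' @export
build_unified_cistrome <- function(cc) {
  unified <- merge_overlapping(do.call(c, unname(lapply(
    cc$cistromes, function(g) { S4Vectors::mcols(g) <- NULL; g }))))
  bound <- vapply(cc$cistromes, function(g)
    GenomicRanges::countOverlaps(unified, g, ignore.strand = TRUE) > 0L,
    logical(length(unified)))
  bound <- matrix(bound, nrow = length(unified),
                  dimnames = list(NULL, cc$tf_names))
  unified$bound <- bound
  unified$cobind_count <- as.integer(rowSums(bound))
  stopifnot(all(unified$cobind_count >= 1L))
  unified
}

#' Classify the regulatory region universe
#'
#' The universe is the unified cistrome plus open-chromatin regions that do
#' not overlap it (needed for the TF-negative highly accessible class).
#' Each region carries its bound-TF set and open state (>= 1 bp overlap
#' with open chromatin).
#'
#' @param cc a [cistrome_collection()].
#' @return object of class `category_assignment`: list with `universe`
#'   (`GRanges`), `bound` (logical matrix region x TF), `open` (logical),
#'   `is_unified` (logical) and `tf_names`.
#' @export
classify_regions <- function(cc) {
  unified <- build_unified_cistrome(cc)
  open_only <- intersect_any(
    merge_overlapping(cc$open_chromatin), unified)$miss
  S4Vectors::mcols(open_only) <- NULL
  u_clean <- unified
  S4Vectors::mcols(u_clean) <- NULL
  universe <- c(u_clean, open_only)
  bound <- rbind(unified$bound,
                 matrix(FALSE, nrow = length(open_only),
                        ncol = length(cc$tf_names)))
  colnames(bound) <- cc$tf_names
  open <- GenomicRanges::countOverlaps(universe, cc$open_chromatin,
                                       ignore.strand = TRUE) > 0L
  is_unified <- c(rep(TRUE, length(unified)), rep(FALSE, length(open_only)))
  ord <- BiocGenerics::order(universe)
  structure(list(universe = universe[ord],
                 bound = bound[ord, , drop = FALSE],
                 open = open[ord],
                 is_unified = is_unified[ord],
                 tf_names = cc$tf_names),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat("category_assignment:", length(x$universe), "regions (",
      sum(x$is_unified), "TF-bound,", sum(x$open), "open );",
      length(x$tf_names), "TFs\n")
  invisible(x)
}

#' Four-way focal-TF category per universe region
#'
#' Relative to a focal TF: bound and not open -> `LRE` (labelled regulatory
#' element); bound and open -> `TF_pos_HighAcc`; not bound and open ->
#' `TF_neg_HighAcc`; not bound and not open -> `TF_neg_LowAcc` (bound by
#' other TFs only).
#'
#' @param assignment a [classify_regions()] result.
#' @param focal focal TF name.
#' @return factor with levels `LRE`, `TF_pos_HighAcc`, `TF_neg_HighAcc`,
#'   `TF_neg_LowAcc`.
#' @export
classify_focal <- function(assignment, focal) {
  if (!focal %in% assignment$tf_names)
    stop("unknown focal TF: ", focal)
  b <- assignment$bound[, focal]
  o <- assignment$open
  lab <- ifelse(b & !o, "LRE",
         ifelse(b & o, "TF_pos_HighAcc",
         ifelse(o, "TF_neg_HighAcc", "TF_neg_LowAcc")))
  factor(lab, levels = c("LRE", "TF_pos_HighAcc",
                         "TF_neg_HighAcc", "TF_neg_LowAcc"))
}

#' Signal summaries stratified by co-binding count
#'
#' Partitions the TF-bound (unified) regions by the number of co-bound TFs
#' and summarises each track per stratum (median and quartiles).
#'
#' @param assignment a [classify_regions()] result.
#' @param signal occupancy matrix whose rows align with
#'   `assignment$universe` (or with its unified subset).
#' @return data.frame from [column_summary()] with `group` = cobind count.
#' @export
cobinding_stratification <- function(assignment, signal) {
  cobind <- rowSums(assignment$bound)
  if (nrow(signal) == length(assignment$universe)) {
    signal <- signal[assignment$is_unified, , drop = FALSE]
    cobind <- cobind[assignment$is_unified]
  } else if (nrow(signal) != sum(assignment$is_unified)) {
    stop("signal rows do not align with the region universe")
  } else {
    cobind <- cobind[assignment$is_unified]
  }
  column_summary(signal, as.integer(cobind))
}

#' Exact TF-subset tallies among labelled regions (co-LREs)
#'
#' Among closed (not open) regions bound by at least one TF of interest,
#' regions are tallied by the exact bound subset; zero-count subsets are
#' omitted.
#'
#' @param assignment a [classify_regions()] result.
#' @param tfs_of_interest subset of TF names (default all).
#' @return data.frame with `subset` (`+`-joined TF names in collection
#'   order), `n_tfs`, `count`, sorted by decreasing count.
#' @export
co_lre_combinations <- function(assignment,
                                tfs_of_interest = assignment$tf_names) {
  if (length(tfs_of_interest) == 0L)
    stop("tfs_of_interest must be non-empty")
  if (!all(tfs_of_interest %in% assignment$tf_names))
    stop("unknown TF(s): ",
         paste(setdiff(tfs_of_interest, assignment$tf_names), collapse = ", "))
  b <- assignment$bound[, tfs_of_interest, drop = FALSE]
  keep <- !assignment$open & rowSums(b) > 0L
  b <- b[keep, , drop = FALSE]
  sig <- apply(b, 1L, function(row)
    paste(tfs_of_interest[row], collapse = "+"))
  tab <- sort(table(sig), decreasing = TRUE)
  data.frame(subset = names(tab),
             n_tfs = vapply(strsplit(names(tab), "+", fixed = TRUE),
                            length, integer(1)),
             count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LRE vs HighAcc split of one TF's cistrome
#'
#' Among universe regions bound by the focal TF: how many are labelled
#' (closed) vs highly accessible, with fractions summing to 1.
#'
#' @param assignment a [classify_regions()] result.
#' @param focal focal TF name.
#' @return list with `n_lre`, `n_highacc`, `fraction_lre`,
#'   `fraction_highacc`.
#' @export
category_fractions <- function(assignment, focal) {
  cat4 <- classify_focal(assignment, focal)
  n_lre <- sum(cat4 == "LRE")
  n_high <- sum(cat4 == "TF_pos_HighAcc")
  tot <- n_lre + n_high
  list(n_lre = n_lre, n_highacc = n_high,
       fraction_lre = if (tot) n_lre / tot else NA_real_,
       fraction_highacc = if (tot) n_high / tot else NA_real_)
}

#' Export a category assignment as a TSV-ready data.frame
#'
#' One row per universe region: BED coordinates, comma-joined bound TFs,
#' co-binding count, open flag and one category column per focal TF.
#'
#' @param assignment a [classify_regions()] result.
#' @return data.frame.
#' @export
assignment_table <- function(assignment) {
  u <- assignment$universe
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(u)),
    start = GenomicRanges::start(u) - 1L,
    end = GenomicRanges::end(u),
    region_id = region_ids(u),
    bound_tfs = apply(assignment$bound, 1L, function(row)
      paste(assignment$tf_names[row], collapse = ",")),
    cobind_count = as.integer(rowSums(assignment$bound)),
    open = as.integer(assignment$open),
    stringsAsFactors = FALSE)
  for (tf in assignment$tf_names)
    df[[paste0("category_", gsub("[^A-Za-z0-9]", "", tf))]] <-
      as.character(classify_focal(assignment, tf))
  df
}
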