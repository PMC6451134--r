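## Signal quantification over regions: RPKM per track and summit-centred
## profile matrices (meta-histogram / RD-plot substrate).

#' Construct a tag library
#'
#' A tag library is the set of sequenced fragments of one track plus the
#' total mapped-library size used as the normalisation denominator.  Only a
#' subset of the genome's tags need be present (e.g. in-peak tags plus
#' sampled background); `library_size` is always the full library.
#'
#' @param tags `GRanges` of fragments (or width-1 cut sites).
#' @param library_size total mapped tags; must be `>= length(tags)` and > 0.
#' @param label track label.
#' @return object of class `tag_library`.
#' @export
tag_library <- function(tags, library_size = length(tags),
                        label = NA_character_) {
  library_size <- as.numeric(library_size)
  if (library_size <= 0) stop("library_size must be > 0")
  if (library_size < length(tags))
    stop("library_size smaller than number of tags")
  structure(list(tags = tags, library_size = library_size, label = label),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library '", x$label, "': ", length(x$tags),
      " tags, library size ", format(x$library_size, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' RPKM of a tag library over regions
#'
#' RPKM = (tags overlapping the region) / (region length in kb x library
#' size in millions).  A tag counts once per region even if it overlaps it
#' several times; with `count = "five_prime"` only the fragment 5' base is
#' tested.
#'
#' @param regions `GRanges`.
#' @param lib a [tag_library()].
#' @param count `"fragment"` (any-overlap, default) or `"five_prime"`.
#' @return numeric vector of RPKM values, one per region.
#' @export
compute_rpkm <- function(regions, lib, count = c("fragment", "five_prime")) {
  count <- match.arg(count)
  tags <- lib$tags
  if (count == "five_prime")
    tags <- GenomicRanges::resize(tags, width = 1L, fix = "start")
  n <- GenomicRanges::countOverlaps(regions, tags, ignore.strand = TRUE)
  kb <- GenomicRanges::width(regions) / 1000
  n / (kb * lib$library_size / 1e6)
}

#' RPKM occupancy matrix over several tracks
#'
#' @param regions `GRanges`.
#' @param libs named list of [tag_library()] objects (names become track
#'   labels).
#' @param count see [compute_rpkm()].
#' @return numeric matrix (regions x tracks) with region ids as rownames.
#' @export
occupancy_matrix <- function(regions, libs, count = "fragment") {
  labels <- names(libs)
  if (is.null(labels))
    labels <- vapply(libs, function(l) l$label, character(1))
  m <- vapply(libs, function(l) compute_rpkm(regions, l, count = count),
              numeric(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(region_ids(regions), labels))
  m
}

region_centers <- function(regions) {
  ## absolute summit (1-based) with midpoint fallback
  centers <- GenomicRanges::start(regions) +
    floor((GenomicRanges::width(regions) - 1) / 2)
  if (!is.null(regions$summit)) {
    has <- !is.na(regions$summit)
    centers[has] <- GenomicRanges::start(regions)[has] + regions$summit[has]
  }
  centers
}

#' Summit-centred profile matrix
#'
#' Tags are assigned to `bin_width`-bp bins tiling the window
#' `[summit - window/2, summit + window/2)` by their midpoint, so each
#' in-window tag lands in exactly one bin; counts are scaled to tags per
#' `norm_to` (default 1e7) mapped library tags.  Bins extending past a
#' chromosome end are clipped (they can hold no tags) and a message is
#' emitted.
#'
#' @param anchors `GRanges` with optional `summit` column (midpoint
#'   fallback).
#' @param lib a [tag_library()].
#' @param window total window width in bp (even, divisible by `bin_width`).
#' @param bin_width bin width in bp.
#' @param norm_to library-size normalisation constant.
#' @return list of class `profile_matrix`: `values` (regions x bins),
#'   `bin_width`, `window`, `norm_to`.
#' @export
profile_matrix <- function(anchors, lib, window = 2000L, bin_width = 25L,
                           norm_to = 1e7) {
  if (window %% 2L != 0L || window %% bin_width != 0L)
    stop("window must be even and divisible by bin_width")
  nbin <- window %/% bin_width
  centers <- region_centers(anchors)      # 1-based
  left0 <- (centers - 1L) - window %/% 2L # 0-based window start
  seqlen <- GenomeInfoDb::seqlengths(anchors)[
    as.character(GenomicRanges::seqnames(anchors))]
  if (any(left0 < 0 | left0 + window > seqlen, na.rm = TRUE))
    message("profile window(s) clipped at chromosome edge")
  tags <- lib$tags
  mid0 <- (GenomicRanges::start(tags) - 1L) +
    floor((GenomicRanges::width(tags) - 1L) / 2L)
  midpoints <- GenomicRanges::GRanges(GenomicRanges::seqnames(tags),
                                      IRanges::IRanges(mid0 + 1L, width = 1L))
  windows <- suppressWarnings(GenomicRanges::trim(GenomicRanges::GRanges(
    GenomicRanges::seqnames(anchors),
    IRanges::IRanges(start = pmax(left0 + 1L, 1L),
                     end = pmin(left0 + window, seqlen)),
    seqinfo = GenomeInfoDb::seqinfo(anchors))))
  ov <- GenomicRanges::findOverlaps(windows, midpoints, ignore.strand = TRUE)
  values <- matrix(0, nrow = length(anchors), ncol = nbin,
                   dimnames = list(region_ids(anchors),
                                   as.character(seq_len(nbin) * bin_width -
                                                  window %/% 2L - bin_width)))
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    pos0 <- mid0[S4Vectors::subjectHits(ov)]
    bin <- (pos0 - left0[qi]) %/% bin_width + 1L
    keep <- bin >= 1L & bin <= nbin
    tab <- table(factor(qi[keep], levels = seq_len(length(anchors))),
                 factor(bin[keep], levels = seq_len(nbin)))
    values <- values + as.matrix(tab) * (norm_to / lib$library_size)
  }
  structure(list(values = values, bin_width = bin_width, window = window,
                 norm_to = norm_to),
            class = "profile_matrix")
}

#' Per-group median and quartiles of matrix columns
#'
#' @param m numeric matrix (regions x tracks), or a `profile_matrix`.
#' @param group_labels per-region group labels (length = nrow).
#' @return data.frame with `group`, `track`, `n`, `q1`, `median`, `q3`;
#'   empty groups are absent.
#' @export
column_summary <- function(m, group_labels) {
  if (inherits(m, "profile_matrix")) m <- m$values
  if (length(group_labels) != nrow(m))
    stop("group_labels length (", length(group_labels),
         ") does not match rows (", nrow(m), ")")
  groups <- split(seq_len(nrow(m)), group_labels, drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    qs <- apply(m[rows, , drop = FALSE], 2L, quantile,
                probs = c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, track = colnames(m), n = length(rows),
               q1 = qs[1L, ], median = qs[2L, ], q3 = qs[3L, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
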