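## Interval I/O and set algebra.
##
## The universal currency of the pipeline is a strand-agnostic GRanges
## carrying a Seqinfo (the genome assembly).  All public coordinates in
## files follow the BED convention (0-based half-open); in memory we use the
## native GRanges 1-based closed representation, so "at least one common
## nucleotide" is exactly findOverlaps() with minoverlap = 1, and bookended
## BED intervals ([100,200) / [200,300)) never overlap.

#' Read a two-column chromosome sizes table
#'
#' @param path path to a `chrom.sizes` file (chromosome name, length in bp,
#'   tab- or space-separated).
#' @param genome assembly name recorded in the returned object.
#' @return a [GenomeInfoDb::Seqinfo] object.
#' @export
read_chrom_sizes <- function(path, genome = NA_character_) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "length"))
  genome_assembly(setNames(as.integer(tab$length), tab$chrom), genome = genome)
}

#' Construct a genome assembly from named chromosome lengths
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param genome assembly name.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
genome_assembly <- function(chrom_sizes, genome = NA_character_) {
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names in assembly")
  if (any(chrom_sizes <= 0))
    stop("all chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = as.integer(chrom_sizes),
                        genome = genome)
}

#' Build a region set from BED-style coordinates
#'
#' @param chrom,start,end vectors of chromosome, 0-based inclusive start and
#'   0-based exclusive end.
#' @param assembly a `Seqinfo` (see [genome_assembly()]).
#' @param name,score,summit optional per-interval identifier, score and
#'   summit offset from `start` (narrowPeak column-10 semantics).
#' @param label track label stored in `metadata()`.
#' @return a sorted, strand-agnostic `GRanges`.
#' @export
region_set <- function(chrom, start, end, assembly,
                       name = NULL, score = NULL, summit = NULL,
                       label = NA_character_) {
  if (any(start < 0) || any(end <= start))
    stop("invalid intervals: require 0 <= start < end")
  unknown <- setdiff(unique(as.character(chrom)),
                     GenomeInfoDb::seqnames(assembly))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(assembly)[as.character(chrom)]
  oob <- end > lens
  if (any(oob)) {
    message(sum(oob), " interval(s) clipped to chromosome ends")
    end <- pmin(end, lens)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom),
                      levels = GenomeInfoDb::seqnames(assembly)),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    seqinfo = assembly)
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  if (!is.null(summit)) {
    bad <- !is.na(summit) & (summit < 0 | summit >= end - start)
    if (any(bad)) stop("summit offset outside interval for ",
                       sum(bad), " region(s)")
    gr$summit <- as.integer(summit)
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$label <- label
  gr
}

clip_to_assembly <- function(gr) {
  suppressWarnings({
    oob <- sum(GenomicRanges::end(gr) >
                 GenomeInfoDb::seqlengths(gr)[as.character(
                   GenomicRanges::seqnames(gr))], na.rm = TRUE)
    if (oob > 0)
      message(oob, " interval(s) clipped to chromosome ends")
    GenomicRanges::trim(gr)
  })
}

#' Read a BED or narrowPeak file into a region set
#'
#' Coordinates are interpreted 0-based half-open and converted to the
#' in-memory 1-based representation.  Out-of-bounds intervals are clipped
#' to chromosome ends with a message; unknown chromosomes are an error.
#'
#' @param path file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param assembly a `Seqinfo` assembly.
#' @param label track label.
#' @return sorted `GRanges`; narrowPeak input carries a `summit` metadata
#'   column (offset from start; `-1` in the file becomes `NA`).
#' @export
read_regions <- function(path, format = c("bed", "narrowPeak"), assembly,
                         label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = assembly)
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  gr <- tryCatch({
    if (format == "narrowPeak") {
      rtracklayer::import(path, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
  }, error = function(e) stop("parse error in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  unknown <- setdiff(GenomeInfoDb::seqlevelsInUse(gr),
                     GenomeInfoDb::seqnames(assembly))
  if (length(unknown))
    stop("unknown chromosome(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  GenomicRanges::strand(gr) <- "*"
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(assembly)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- assembly)
  if (format == "narrowPeak") {
    summit <- gr$peak
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    gr$summit <- summit
    gr$peak <- NULL
  }
  gr <- clip_to_assembly(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a region set as BED (0-based half-open)
#'
#' @param rs a `GRanges`.
#' @param path output path.
#' @param summit_col if `TRUE`, write 10-column narrowPeak (summit offset in
#'   column 10, `-1` when absent).
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path, summit_col = FALSE) {
  n <- length(rs)
  name <- if (!is.null(rs$name)) rs$name else region_ids(rs)
  score <- if (!is.null(rs$score)) rs$score else rep(0, n)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rs)),
                   start = GenomicRanges::start(rs) - 1L,
                   end = GenomicRanges::end(rs),
                   name = name, score = score, strand = ".")
  if (summit_col) {
    summit <- if (!is.null(rs$summit)) rs$summit else rep(NA_integer_, n)
    summit[is.na(summit)] <- -1L
    df$signalValue <- score
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- summit
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Canonical region identifiers
#'
#' Names are regenerated as `chrom_start_end` in BED coordinates; input
#' names are not preserved through set algebra because merged products have
#' no unique parent.
#'
#' @param rs a `GRanges`.
#' @return character vector of identifiers.
#' @export
region_ids <- function(rs) {
  paste(as.character(GenomicRanges::seqnames(rs)),
        GenomicRanges::start(rs) - 1L, GenomicRanges::end(rs), sep = "_")
}

#' Merge intervals closer than a gap
#'
#' Maximal runs of intervals with pairwise gap `<= min_gap` bp are collapsed
#' (bedtools `merge -d` semantics: at `min_gap = 0` overlapping and
#' bookended intervals merge, and total covered bases are unchanged).
#'
#' @param rs a `GRanges`.
#' @param min_gap maximum gap in bp; non-negative.
#' @return merged, sorted `GRanges`.
#' @export
merge_overlapping <- function(rs, min_gap = 0L) {
  if (min_gap < 0) stop("min_gap must be >= 0")
  out <- GenomicRanges::reduce(rs, min.gapwidth = min_gap + 1L,
                               ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- S4Vectors::metadata(rs)$label
  out
}

#' Do two intervals share at least one nucleotide?
#'
#' Under the half-open convention this is `start_a < end_b && start_b <
#' end_a` on the same chromosome; bookended intervals do not overlap.
#'
#' @param a,b single-interval `GRanges`.
#' @return logical.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0L
}

#' Partition a query by overlap with a reference
#'
#' @param query,reference `GRanges` on the same assembly.
#' @return list with `hit` (query intervals sharing >= 1 bp with any
#'   reference interval) and `miss` (the rest); together they partition the
#'   query.
#' @export
intersect_any <- function(query, reference) {
  hits <- GenomicRanges::countOverlaps(query, reference,
                                       ignore.strand = TRUE) > 0L
  list(hit = query[hits], miss = query[!hits])
}

#' Base-level subtraction of region sets
#'
#' Returns the maximal sub-intervals of the bases covered by `a` that are
#' not covered by `b`.
#'
#' @param a,b `GRanges` on the same assembly.
#' @return `GRanges` covering exactly `cover(a) - cover(b)`.
#' @export
subtract_regions <- function(a, b) {
  out <- GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- S4Vectors::metadata(a)$label
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Consensus regions supported by multiple replicates
#'
#' Bases covered by at least `min_support` replicate sets (each replicate
#' reduced first so internal overlaps count once) are kept; each returned
#' interval is a maximal such run.  With `min_support = 1` this equals
#' [merge_overlapping()] of the concatenation.
#'
#' @param replicates list of `GRanges` replicate peak sets.
#' @param min_support minimum number of supporting replicates (default 2).
#' @return consensus `GRanges`.
#' @export
consensus_regions <- function(replicates, min_support = 2L) {
  if (min_support < 1) stop("min_support must be >= 1")
  if (length(replicates) < min_support)
    stop("need at least min_support (", min_support, ") replicate sets; got ",
         length(replicates))
  depth <- Reduce(`+`, lapply(replicates, function(r)
    GenomicRanges::coverage(GenomicRanges::reduce(r, ignore.strand = TRUE))))
  out <- GenomicRanges::GRanges(
    IRanges::slice(depth, lower = min_support, rangesOnly = TRUE),
    seqinfo = GenomeInfoDb::seqinfo(replicates[[1]]))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Remove regions overlapping a blacklist
#'
#' A region overlapping any blacklist interval by >= 1 bp is dropped; the
#' number removed is reported as a message.
#'
#' @param rs a `GRanges`.
#' @param blacklist blacklist `GRanges` (may be empty).
#' @return filtered `GRanges`.
#' @export
filter_blacklist <- function(rs, blacklist) {
  parts <- intersect_any(rs, blacklist)
  if (length(parts$hit))
    message(length(parts$hit), " region(s) removed by blacklist filter")
  parts$miss
}

#' Extract transcription start sites from a gene model
#'
#' Accepts a GFF3 or BED12 file (any stranded interval source readable by
#' rtracklayer); the TSS is the strand-aware 5' end of each transcript.
#'
#' @param path gene model file.
#' @param assembly a `Seqinfo`.
#' @param feature_type for GFF3, feature types to keep (default
#'   `c("transcript", "mRNA", "gene")`, first type present wins).
#' @return stranded width-1 `GRanges` of TSS positions with a `gene` column.
#' @export
read_gene_model <- function(path, assembly,
                            feature_type = c("transcript", "mRNA", "gene")) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) {
    keep <- feature_type[feature_type %in% as.character(gr$type)]
    if (length(keep)) gr <- gr[as.character(gr$type) == keep[[1]]]
  }
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("gene model contains unstranded transcript(s); strand is required")
  tss <- GenomicRanges::resize(gr, width = 1L, fix = "start")
  gene <- if (!is.null(tss$Name)) as.character(tss$Name)
          else if (!is.null(tss$name)) as.character(tss$name)
          else if (!is.null(tss$ID)) as.character(tss$ID)
          else paste0("gene", seq_along(tss))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
                                GenomicRanges::ranges(tss),
                                strand = GenomicRanges::strand(tss),
                                seqinfo = assembly)
  out$gene <- gene
  out
}

#' Label regions as promoter-proximal or distal
#'
#' A region overlapping any strand-aware promoter window
#' `[TSS - upstream, TSS + downstream)` is a promoter; everything else is
#' distal ("Intergenic"/"Intron"-like regions are the distal elements used
#' downstream).
#'
#' @param rs a `GRanges`.
#' @param tss stranded TSS `GRanges` (see [read_gene_model()]).
#' @param promoter_window `c(upstream, downstream)` in bp; default
#'   `c(1000, 100)`.
#' @return factor of `"promoter"`/`"distal"` per region.
#' @export
annotate_location <- function(rs, tss, promoter_window = c(1000L, 100L)) {
  if (any(GenomicRanges::strand(tss) == "*"))
    stop("TSS set contains unstranded entries; strand is required")
  win <- suppressWarnings(GenomicRanges::trim(GenomicRanges::promoters(
    tss, upstream = promoter_window[[1]], downstream = promoter_window[[2]])))
  hit <- GenomicRanges::countOverlaps(rs, win, ignore.strand = TRUE) > 0L
  factor(ifelse(hit, "promoter", "distal"), levels = c("promoter", "distal"))
}

#' Fraction of a method union recovered by one method
#'
#' Merges all sets into a union of regions and reports the fraction of
#' union regions hit (>= 1 bp) by the focal set.
#'
#' @param method_sets list of >= 2 `GRanges`.
#' @param focal index of the focal set within `method_sets`.
#' @return fraction in `[0, 1]`.
#' @export
coverage_of_union <- function(method_sets, focal) {
  if (length(method_sets) < 2) stop("need at least two method sets")
  u <- merge_overlapping(do.call(c, unname(
    lapply(method_sets, function(g) { S4Vectors::mcols(g) <- NULL; g }))))
  if (length(u) == 0L) return(0)
  hit <- GenomicRanges::countOverlaps(u, method_sets[[focal]],
                                      ignore.strand = TRUE) > 0L
  mean(hit)
}
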