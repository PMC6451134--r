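# Independent per-base bitmap oracles for the interval algebra, plus small
# random-instance generators.  The oracles operate on plain logical/integer
# vectors over a toy genome and never call the package's interval code.

toy_assembly <- function(len = 100000L, chroms = "chrT") {
  genome_assembly(stats::setNames(rep(len, length(chroms)), chroms),
                  genome = "toy")
}

# data.frame (chrom, start, end) in BED coordinates <-> GRanges
df_to_gr <- function(df, assembly) {
  region_set(df$chrom, df$start, df$end, assembly)
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, len = 100000L, max_width = 800L,
                             chrom = "chrT") {
  start <- sample.int(len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start,
                   end = pmin(start + width, len))
  df[order(df$start, df$end), , drop = FALSE]
}

# one logical vector per chromosome; index i = base i - 1
bitmap_cover <- function(df, len, chroms = "chrT") {
  bits <- stats::setNames(lapply(chroms, function(x) logical(len)), chroms)
  for (i in seq_len(nrow(df))) {
    b <- bits[[df$chrom[i]]]
    b[(df$start[i] + 1):df$end[i]] <- TRUE
    bits[[df$chrom[i]]] <- b
  }
  bits
}

bitmap_depth <- function(dfs, len, chroms = "chrT") {
  depth <- stats::setNames(lapply(chroms, function(x) integer(len)), chroms)
  for (df in dfs) {
    cov <- bitmap_cover(df, len, chroms)
    for (ch in chroms) depth[[ch]] <- depth[[ch]] + as.integer(cov[[ch]])
  }
  depth
}

bitmap_to_df <- function(bits) {
  out <- lapply(names(bits), function(ch) {
    r <- rle(bits[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(chrom = character(), start = integer(), end = integer())
  else out
}

# oracle: merge intervals whose gap <= min_gap, by an explicit sorted scan
# (bedtools merge -d semantics; at min_gap = 0 it equals the bitmap cover)
oracle_merge <- function(df, len, min_gap = 0L, chroms = "chrT") {
  out <- lapply(chroms, function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d <- d[order(d$start, d$end), , drop = FALSE]
    starts <- d$start[1]; ends <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      k <- length(ends)
      if (d$start[i] - ends[k] <= min_gap) {
        ends[k] <- max(ends[k], d$end[i])
      } else {
        starts <- c(starts, d$start[i]); ends <- c(ends, d$end[i])
      }
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(chrom = character(), start = integer(), end = integer())
  else out
}

oracle_subtract <- function(a, b, len, chroms = "chrT") {
  ca <- bitmap_cover(a, len, chroms)
  cb <- bitmap_cover(b, len, chroms)
  bitmap_to_df(stats::setNames(
    lapply(chroms, function(ch) ca[[ch]] & !cb[[ch]]), chroms))
}

oracle_consensus <- function(dfs, len, min_support, chroms = "chrT") {
  depth <- bitmap_depth(dfs, len, chroms)
  bitmap_to_df(stats::setNames(
    lapply(chroms, function(ch) depth[[ch]] >= min_support), chroms))
}

oracle_hits <- function(query, reference, len, chroms = "chrT") {
  cb <- bitmap_cover(reference, len, chroms)
  vapply(seq_len(nrow(query)), function(i)
    any(cb[[query$chrom[i]]][(query$start[i] + 1):query$end[i]]),
    logical(1))
}

oracle_coverage_of_union <- function(dfs, focal, len, chroms = "chrT") {
  union_df <- bitmap_to_df(bitmap_cover(do.call(rbind, dfs), len, chroms))
  if (nrow(union_df) == 0) return(0)
  mean(oracle_hits(union_df, dfs[[focal]], len, chroms))
}

# strand-aware promoter-window bitmap: [TSS - up, TSS + down) in the
# direction of transcription
oracle_promoter_labels <- function(regions, tss0, strand, up, down, len,
                                   chroms = "chrT") {
  win <- do.call(rbind, lapply(seq_along(tss0), function(i) {
    if (strand[i] == "+") {
      s <- tss0[i] - up; e <- tss0[i] + down
    } else {
      s <- tss0[i] - down + 1; e <- tss0[i] + up + 1
    }
    data.frame(chrom = chroms[1], start = max(s, 0L), end = min(e, len))
  }))
  ifelse(oracle_hits(regions, win, len, chroms), "promoter", "distal")
}
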