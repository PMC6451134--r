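# Interval I/O and set algebra, checked against per-base bitmap oracles.

test_that("BED and narrowPeak files round-trip with BED coordinate semantics", {
  asm <- toy_assembly()
  bed <- tempfile(fileext = ".bed")
  writeLines("chrT\t100\t200", bed)
  rs <- read_regions(bed, "bed", asm)
  expect_length(rs, 1L)
  expect_equal(GenomicRanges::start(rs), 101L)  # 1-based internal
  expect_equal(GenomicRanges::end(rs), 200L)
  expect_equal(gr_to_df(rs), data.frame(chrom = "chrT", start = 100L,
                                        end = 200L))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chrT\t100\t300\tpk1\t0\t.\t5.5\t-1\t-1\t50", np)
  rs <- read_regions(np, "narrowPeak", asm)
  expect_equal(rs$summit, 50L)
  expect_equal(GenomicRanges::start(rs) + rs$summit, 151L)  # abs summit 150 (0-based)

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(read_regions(empty, "bed", asm), 0L)

  out <- tempfile(fileext = ".narrowPeak")
  write_regions(rs, out, summit_col = TRUE)
  back <- read_regions(out, "narrowPeak", asm)
  expect_equal(gr_to_df(back), gr_to_df(rs))
  expect_equal(back$summit, rs$summit)
})

test_that("unknown chromosomes and bad coordinates are rejected, bounds clipped", {
  asm <- toy_assembly()
  bed <- tempfile(fileext = ".bed")
  writeLines("chrZ\t0\t10", bed)
  expect_error(read_regions(bed, "bed", asm), "chrZ")
  expect_error(region_set("chrT", 10, 10, asm), "start < end")
  expect_message(rs <- region_set("chrT", 99990, 100500, asm), "clipped")
  expect_equal(GenomicRanges::end(rs), 100000L)
})

test_that("merge_overlapping collapses runs and is idempotent", {
  asm <- toy_assembly()
  rs <- df_to_gr(data.frame(chrom = "chrT",
                            start = c(100, 200, 399),
                            end = c(250, 400, 500)), asm)
  m <- merge_overlapping(rs)
  expect_equal(gr_to_df(m), data.frame(chrom = "chrT", start = 100L,
                                       end = 500L))
  disj <- df_to_gr(data.frame(chrom = "chrT", start = c(100, 300),
                              end = c(200, 400)), asm)
  expect_equal(gr_to_df(merge_overlapping(disj)), gr_to_df(disj))
  expect_length(merge_overlapping(GenomicRanges::GRanges(seqinfo = asm)), 0L)
  expect_error(merge_overlapping(rs, min_gap = -1), "min_gap")
  # idempotence on random input
  set.seed(42)
  r <- df_to_gr(random_intervals(200), asm)
  expect_equal(gr_to_df(merge_overlapping(merge_overlapping(r))),
               gr_to_df(merge_overlapping(r)))
})

test_that("one-common-nucleotide overlap rule holds at boundaries", {
  asm <- toy_assembly()
  a <- df_to_gr(data.frame(chrom = "chrT", start = 100, end = 200), asm)
  b <- df_to_gr(data.frame(chrom = "chrT", start = 199, end = 300), asm)
  c2 <- df_to_gr(data.frame(chrom = "chrT", start = 200, end = 300), asm)
  expect_true(interval_overlaps(a, b))     # share base 199
  expect_false(interval_overlaps(a, c2))   # bookended
  asm2 <- toy_assembly(chroms = c("chrT", "chrU"))
  d <- df_to_gr(data.frame(chrom = "chrU", start = 100, end = 200), asm2)
  a2 <- df_to_gr(data.frame(chrom = "chrT", start = 100, end = 200), asm2)
  expect_false(interval_overlaps(a2, d))
})

test_that("intersect_any partitions the query", {
  asm <- toy_assembly()
  q <- df_to_gr(data.frame(chrom = "chrT", start = 100, end = 200), asm)
  r <- df_to_gr(data.frame(chrom = "chrT", start = 150, end = 160), asm)
  parts <- intersect_any(q, r)
  expect_length(parts$hit, 1L)
  expect_length(parts$miss, 0L)
  parts <- intersect_any(q, GenomicRanges::GRanges(seqinfo = asm))
  expect_length(parts$hit, 0L)
  expect_equal(gr_to_df(parts$miss), gr_to_df(q))
})

test_that("subtract handles the worked example and degenerate cases", {
  asm <- toy_assembly()
  a <- df_to_gr(data.frame(chrom = "chrT", start = 100, end = 300), asm)
  b <- df_to_gr(data.frame(chrom = "chrT", start = 150, end = 200), asm)
  expect_equal(gr_to_df(subtract_regions(a, b)),
               data.frame(chrom = "chrT", start = c(100L, 200L),
                          end = c(150L, 300L)))
  expect_length(subtract_regions(a, a), 0L)
  expect_equal(gr_to_df(subtract_regions(a, GenomicRanges::GRanges(seqinfo = asm))),
               gr_to_df(a))
})

test_that("consensus keeps bases supported by enough replicates", {
  asm <- toy_assembly()
  reps <- list(
    df_to_gr(data.frame(chrom = "chrT", start = 100, end = 200), asm),
    df_to_gr(data.frame(chrom = "chrT", start = 150, end = 250), asm),
    df_to_gr(data.frame(chrom = "chrT", start = 400, end = 500), asm))
  expect_equal(gr_to_df(consensus_regions(reps, 2L)),
               data.frame(chrom = "chrT", start = 150L, end = 200L))
  ident <- list(reps[[1]], reps[[1]])
  expect_equal(gr_to_df(consensus_regions(ident, 2L)), gr_to_df(reps[[1]]))
  disj <- list(reps[[1]], df_to_gr(data.frame(chrom = "chrT", start = 300,
                                              end = 350), asm))
  expect_length(consensus_regions(disj, 2L), 0L)
  expect_error(consensus_regions(reps, 0L), "min_support")
  # min_support = 1 equals merging the concatenation
  set.seed(7)
  rr <- lapply(1:3, function(i) df_to_gr(random_intervals(100), asm))
  expect_equal(gr_to_df(consensus_regions(rr, 1L)),
               gr_to_df(merge_overlapping(do.call(c, rr))))
})

test_that("blacklist filtering removes 1-bp overlaps and nothing else", {
  asm <- toy_assembly()
  rs <- df_to_gr(data.frame(chrom = "chrT", start = c(100, 500),
                            end = c(200, 600)), asm)
  bl <- df_to_gr(data.frame(chrom = "chrT", start = 199, end = 250), asm)
  expect_message(out <- filter_blacklist(rs, bl), "1 region")
  expect_equal(gr_to_df(out), data.frame(chrom = "chrT", start = 500L,
                                         end = 600L))
  expect_equal(gr_to_df(filter_blacklist(rs, GenomicRanges::GRanges(seqinfo = asm))),
               gr_to_df(rs))
  expect_length(suppressMessages(filter_blacklist(rs, rs)), 0L)
})

test_that("promoter/distal annotation follows strand-aware TSS windows", {
  asm <- toy_assembly()
  tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10001, width = 1),
                                strand = "+", seqinfo = asm)
  tss$gene <- "g1"
  rs <- df_to_gr(data.frame(chrom = "chrT", start = c(9500, 12000),
                            end = c(9600, 12100)), asm)
  lab <- annotate_location(rs, tss, c(1000, 100))
  expect_equal(as.character(lab), c("promoter", "distal"))
  nostrand <- tss
  GenomicRanges::strand(nostrand) <- "*"
  expect_error(annotate_location(rs, nostrand), "strand")
  # randomized check vs oracle, both strands
  set.seed(13)
  regions <- random_intervals(100, max_width = 400)
  tss0 <- sample.int(90000L, 5L)
  strand <- sample(c("+", "-"), 5L, replace = TRUE)
  tssr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(tss0 + 1L, width = 1L),
                                 strand = strand, seqinfo = asm)
  got <- as.character(annotate_location(df_to_gr(regions, asm), tssr,
                                        c(1000, 100)))
  want <- oracle_promoter_labels(regions, tss0, strand, 1000L, 100L, 100000L)
  expect_equal(got, want)
})

test_that("coverage_of_union matches definition and oracle", {
  asm <- toy_assembly()
  a <- df_to_gr(data.frame(chrom = "chrT", start = c(100, 300),
                           end = c(200, 400)), asm)
  expect_equal(coverage_of_union(list(a, a), 1L), 1.0)
  expect_equal(coverage_of_union(
    list(GenomicRanges::GRanges(seqinfo = asm), a), 1L), 0.0)
  set.seed(99)
  sets <- lapply(1:3, function(i) random_intervals(50))
  got <- coverage_of_union(lapply(sets, df_to_gr, assembly = asm), 2L)
  expect_equal(got, oracle_coverage_of_union(sets, 2L, 100000L))
})

test_that("set algebra matches the bitmap oracle on random instances", {
  asm <- toy_assembly()
  len <- 100000L
  for (trial in 1:50) {
    set.seed(1000L + trial)
    a_df <- random_intervals(sample(c(5L, 60L, 200L), 1L))
    b_df <- random_intervals(sample(c(5L, 60L, 200L), 1L))
    a <- df_to_gr(a_df, asm); b <- df_to_gr(b_df, asm)
    gap <- sample(c(0L, 10L, 100L), 1L)
    expect_equal(gr_to_df(merge_overlapping(a, gap)),
                 oracle_merge(a_df, len, gap), ignore_attr = TRUE)
    expect_equal(gr_to_df(subtract_regions(a, b)),
                 oracle_subtract(a_df, b_df, len), ignore_attr = TRUE)
    hits <- oracle_hits(a_df, b_df, len)
    parts <- intersect_any(a, b)
    expect_equal(gr_to_df(parts$hit), a_df[hits, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(gr_to_df(parts$miss), a_df[!hits, , drop = FALSE],
                 ignore_attr = TRUE)
    ms <- sample(1:3, 1L)
    c_df <- random_intervals(60L)
    expect_equal(gr_to_df(consensus_regions(
                   lapply(list(a_df, b_df, c_df), df_to_gr, assembly = asm),
                   ms)),
                 oracle_consensus(list(a_df, b_df, c_df), len, ms),
                 ignore_attr = TRUE)
  }
})
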