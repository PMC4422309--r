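toy_genome <- function(n = 100000) {
  structure(stats::setNames(strrep("A", n), "chr1"), class = "genome")
}

test_that("library orientation determines the transcript strand of coverage", {
  gen <- toy_genome()
  al <- mk_align("r", "chr1", 1001, 1076, strand = "+")
  cov <- compute_coverage(al, gen, orientation = "forward-antisense")
  expect_equal(sum(as.integer(sum(cov$minus))), 76L)
  expect_equal(sum(as.integer(sum(cov$plus))), 0L)
  cov2 <- compute_coverage(al, gen, orientation = "forward-sense")
  expect_equal(sum(as.integer(sum(cov2$plus))), 76L)
  # mate 2 flips the other way
  al2 <- mk_align("r", "chr1", 1001, 1076, strand = "+", mate = 2L)
  cov3 <- compute_coverage(al2, gen, orientation = "forward-antisense",
                           mate = 2L)
  expect_equal(sum(as.integer(sum(cov3$plus))), 76L)
})

test_that("coverage conserves aligned bases exactly, split blocks included", {
  gen <- toy_genome()
  set.seed(61)
  rows <- lapply(1:60, function(i) {
    st <- sample(1:80000, 1)
    if (i %% 3 == 0)
      mk_align(sprintf("r%d", i), "chr1", st, st + 39, start2 = st + 2000,
               end2 = st + 2035, strand = sample(c("+", "-"), 1))
    else
      mk_align(sprintf("r%d", i), "chr1", st, st + 75,
               strand = sample(c("+", "-"), 1))
  })
  al <- do.call(rbind, rows)
  cov <- compute_coverage(al, gen)
  expect_identical(total_depth(cov), sum(as.numeric(al$aligned_len)))
  # two identical alignments stack
  al2 <- rbind(mk_align("a", "chr1", 500, 575), mk_align("b", "chr1", 500, 575))
  cov2 <- compute_coverage(al2, gen)
  expect_equal(max(cov2$minus$chr1), 2L)
  # beyond-chromosome alignments are a hard error
  bad <- mk_align("x", "chr1", 99990, 100065)
  expect_error(compute_coverage(bad, gen), "beyond")
})

test_that("stranded coverage round-trips through BedGraph files", {
  ch <- small_chain()
  m1 <- ch$free[ch$free$unique & ch$free$mate == 1, ]
  cov <- compute_coverage(m1, ch$genome)
  pre <- tempfile()
  write_stranded_coverage(cov, pre)
  back <- read_stranded_coverage(pre, cov$seqlengths)
  for (chrom in names(cov$seqlengths)) {
    expect_identical(as.integer(back$plus[[chrom]]),
                     as.integer(cov$plus[[chrom]]))
    expect_identical(as.integer(back$minus[[chrom]]),
                     as.integer(cov$minus[[chrom]]))
  }
})

test_that("patch calling thresholds, gap merging and minimum width behave", {
  mkcov <- function(depth) {
    structure(list(
      plus = methods::as(list(chr1 = S4Vectors::Rle(as.integer(depth))),
                         "RleList"),
      minus = methods::as(list(chr1 = S4Vectors::Rle(0L, length(depth))),
                          "RleList"),
      seqlengths = c(chr1 = length(depth))), class = "stranded_coverage")
  }
  # uniform depth 3 over 5,000 bases -> one patch, mean 3
  cov <- mkcov(rep(3L, 5000))
  p <- call_patches(cov, min_cov = 2, max_gap = 10000, min_width = 200)
  expect_length(p, 1)
  expect_equal(GenomicRanges::start(p), 1L)
  expect_equal(GenomicRanges::end(p), 5000L)
  expect_equal(p$mean_depth, 3)
  expect_equal(as.character(GenomicRanges::strand(p)), "+")

  # two runs separated by a 12,000 bp zero gap stay apart at max_gap 10,000
  cov2 <- mkcov(c(rep(3L, 2000), rep(0L, 12000), rep(3L, 2000)))
  expect_length(call_patches(cov2), 2)
  # but merge when the gap fits
  expect_length(call_patches(cov2, max_gap = 12000), 1)
  # sub-minimum patches are dropped
  cov3 <- mkcov(c(rep(0L, 100), rep(5L, 150), rep(0L, 100)))
  expect_length(call_patches(cov3), 0)
})

test_that("patch calling is monotone in min_cov", {
  ch <- small_chain()
  m1 <- ch$free[ch$free$unique, ]
  cov <- compute_coverage(m1, ch$genome, mate = 1:2)
  lower <- call_patches(cov, min_cov = 2, max_gap = 2000)
  higher <- call_patches(cov, min_cov = 4, max_gap = 2000)
  if (length(higher) > 0) {
    ov <- GenomicRanges::findOverlaps(higher, lower)
    expect_equal(length(unique(S4Vectors::queryHits(ov))), length(higher))
    # bases covered by patches shrink
    expect_lte(sum(GenomicRanges::width(GenomicRanges::reduce(higher))),
               sum(GenomicRanges::width(GenomicRanges::reduce(lower))))
  }
})

test_that("locus assembly chains patches and flags bidirectionality", {
  p1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 30000),
                               strand = "+")
  p2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(35000, 60000),
                               strand = "-")
  p3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200000, 220000),
                               strand = "+")
  patches <- c(p1, p2, p3)
  patches$mean_depth <- c(3, 3, 3); patches$max_depth <- c(5, 5, 5)
  pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  loci <- assemble_loci(patches, pos, join_gap = 50000)
  expect_length(loci, 2)
  expect_true(loci$bidirectional[1])    # plus + minus 5 kb apart
  expect_false(loci$bidirectional[2])   # lone plus patch
  expect_equal(loci$span_bp[1], 59001L)
  expect_equal(as.integer(loci$linked_positions[[1]]), 1L)
  expect_length(loci$linked_positions[[2]], 0)
})

test_that("shared junctions aggregate support and link to repeats", {
  al <- rbind(
    mk_align("a", "chr1", 1000, 1039, start2 = 5040, end2 = 5075),
    mk_align("b", "chr1", 990, 1039, start2 = 5040, end2 = 5065),
    mk_align("c", "chr1", 7000, 7039, start2 = 9040, end2 = 9075))
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(700, 1099),
                                 strand = "+")
  reps$family <- "LTR12C"; reps$repclass <- "LTR"; reps$confidence <- 1
  jn <- collect_junctions(al, reps, link_window = 1000)
  expect_equal(nrow(jn), 2)
  shared <- jn[jn$donor == 1040, ]
  expect_equal(shared$support, 2L)
  expect_equal(shared$acceptor, 5039L)
  expect_true(shared$chimeric)            # donor 0 bp from the LTR12
  expect_equal(shared$linked_element, "LTR12C")
  expect_false(jn$chimeric[jn$donor == 7040])
})

test_that("simulated junctions with two spanning reads are recovered exactly", {
  cfg <- small_sim_config(n_read_pairs = 40000,
                          n_splice_junctions = c(1, 3),
                          transcript_extent = c(5000, 10000),
                          max_junction_span = 25000)
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  rd <- simulate_reads(tx$truth, tx$genome, cfg)
  ap <- align_params()
  # map every mate of transcript origin (both mates can span junctions)
  hits <- scan_consensus(rd$reads, g$consensus, ap)
  disc <- select_discordant(rd$reads, hits)
  free <- map_genomic(setNames(disc$free_seq, disc$read_id), tx$genome, ap)
  m1 <- map_genomic(setNames(rd$reads$seq1, rd$reads$id), tx$genome, ap)
  al <- rbind(free, m1)
  jn <- collect_junctions(al[al$unique, ], g$repeats)

  # truth junction support: mates overlapping both flanks by >= min_anchor
  tr <- tx$truth$junctions
  RL <- cfg$read_length
  support <- integer(nrow(tr))
  pairs <- rd$pairs[!is.na(rd$pairs$transcript_id), ]
  for (i in seq_len(nrow(tr))) {
    p <- pairs[pairs$transcript_id == tr$transcript_id[i], ]
    if (nrow(p) == 0) next
    n_span <- 0L
    for (j in seq_len(nrow(p))) {
      for (iv in list(c(p$frag_start[j], p$frag_start[j] + RL - 1),
                      c(p$frag_end[j] - RL + 1, p$frag_end[j]))) {
        blk <- transcript_genomic_blocks(tx$truth, tr$transcript_id[i],
                                         iv[1], iv[2])
        left <- blk[blk[, "end"] == tr$intron_start[i] - 1, , drop = FALSE]
        right <- blk[blk[, "start"] == tr$intron_end[i] + 1, , drop = FALSE]
        if (nrow(left) == 1 && nrow(right) == 1 &&
            left[, "end"] - left[, "start"] + 1 >= ap$min_anchor &&
            right[, "end"] - right[, "start"] + 1 >= ap$min_anchor)
          n_span <- n_span + 1L
      }
    }
    support[i] <- n_span
  }
  well_supported <- which(support >= 2)
  expect_gt(length(well_supported), 5)
  found <- paste(jn$chrom, jn$donor, jn$acceptor)
  truth_key <- paste(tr$chrom, tr$intron_start, tr$intron_end)
  expect_gte(mean(truth_key[well_supported] %in% found), 0.95)
})
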