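ltr_repeat <- function(chrom = "chr1", start = 5000, end = 5399,
                       family = "LTR12C") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = "+")
  gr$family <- family
  gr$repclass <- ervchimera:::repeat_class_of(family)
  gr$confidence <- 1000
  gr
}

test_that("gap merging follows single-linkage semantics with exact boundaries", {
  # gaps of 1,324 / 1,999 merge at merge_gap 2,000; 2,001 / 2,124 do not
  al <- rbind(mk_align("a", "chr1", 101, 176),
              mk_align("b", "chr1", 1501, 1576))
  cl <- merge_alignments(al, 2000)           # gap 1,324
  expect_length(cl, 1)
  expect_equal(GenomicRanges::start(cl), 101L)
  expect_equal(GenomicRanges::end(cl), 1576L)

  gap_cluster_count <- function(gap) {
    al <- rbind(mk_align("a", "chr1", 101, 176),
                mk_align("b", "chr1", 177 + gap, 252 + gap))
    length(merge_alignments(al, 2000))
  }
  expect_equal(gap_cluster_count(1999), 1L)
  expect_equal(gap_cluster_count(2000), 1L)  # distance == merge_gap merges
  expect_equal(gap_cluster_count(2001), 2L)
  expect_equal(gap_cluster_count(2124), 2L)
})

test_that("merging is idempotent on random interval sets", {
  set.seed(50)
  for (rep in 1:5) {
    n <- 40
    st <- sort(sample(1:500000, n))
    al <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_align(sprintf("r%02d", i), "chr1", st[i], st[i] + 75)))
    m1 <- merge_alignments(al, 2000)
    al2 <- do.call(rbind, lapply(seq_along(m1), function(i)
      mk_align(sprintf("c%02d", i), "chr1", GenomicRanges::start(m1)[i],
               GenomicRanges::end(m1)[i])))
    m2 <- merge_alignments(al2, 2000)
    expect_equal(GenomicRanges::start(m2), GenomicRanges::start(m1))
    expect_equal(GenomicRanges::end(m2), GenomicRanges::end(m1))
  }
})

test_that("the 40 bp unique-sequence rule is an exact boundary", {
  rep40 <- ltr_repeat()
  mk_case <- function(len) {
    al <- mk_align("m", "chr1", 5600, 5600 + len - 1)   # 200 bp from the LTR
    cl <- merge_alignments(al, 2000)
    call_positions(cl, al, rep40, chimera_params(), "s")
  }
  expect_length(mk_case(39), 0)
  pos <- mk_case(40)
  expect_length(pos, 1)
  expect_equal(pos$unique_bp, 40L)
  pos76 <- mk_case(76)
  expect_equal(pos76$unique_bp, 76L)
  expect_equal(pos76$support_pairs, 1L)
})

test_that("blocks overlapping an allowed repeat body do not count as unique support", {
  rep1 <- ltr_repeat()
  # 76 bp alignment overlapping the repeat body by one base
  al <- mk_align("m", "chr1", 5399, 5474)
  cl <- merge_alignments(al, 2000)
  expect_length(call_positions(cl, al, rep1, chimera_params(), "s"), 0)
  # non-unique alignments never provide support
  al2 <- mk_align("m", "chr1", 5600, 5675, unique = FALSE)
  cl2 <- merge_alignments(al2, 2000)
  expect_length(call_positions(cl2, al2, rep1, chimera_params(), "s"), 0)
})

test_that("positions require a linked allowed-family repeat within the window", {
  al <- mk_align("m", "chr1", 5600, 5675)
  cl <- merge_alignments(al, 2000)
  # Alu is not an allowed family
  alu <- ltr_repeat(family = "AluY")
  expect_length(call_positions(cl, al, alu, chimera_params(), "s"), 0)
  # LTR12 beyond the window
  far <- ltr_repeat(start = 8000, end = 8399)
  expect_length(call_positions(cl, al, far, chimera_params(), "s"), 0)
  # within the window: called, with distance recorded
  near <- ltr_repeat()
  pos <- call_positions(cl, al, near, chimera_params(), "s")
  expect_length(pos, 1)
  expect_equal(as.integer(pos$linked_distances[[1]][1]), 200L)
  expect_equal(pos$linked_families[[1]][1], "LTR12C")
  rep_report <- attr(pos, "report")
  expect_equal(rep_report$positions_out, 1L)
})

test_that("calling is monotone in its thresholds", {
  ch <- small_chain()
  uniq <- ch$free[ch$free$unique, ]
  base <- ch$pos
  for (mub in c(50, 60, 77)) {
    p2 <- call_positions(ch$clusters, uniq, ch$repeats,
                         chimera_params(min_unique_bp = mub), "sim")
    expect_true(all(paste(GenomicRanges::start(p2)) %in%
                      paste(GenomicRanges::start(base))))
    expect_lte(length(p2), length(base))
  }
  for (msp in c(3, 10, 100)) {
    p2 <- call_positions(ch$clusters, uniq, ch$repeats,
                         chimera_params(min_support_pairs = msp), "sim")
    expect_lte(length(p2), length(base))
    expect_true(all(p2$support_pairs >= msp))
  }
})

test_that("called positions satisfy their invariants on simulated data", {
  ch <- small_chain()
  pos <- ch$pos
  expect_gt(length(pos), 0)
  expect_true(all(pos$unique_bp >= 40))
  expect_true(all(pos$support_pairs >= 1))
  expect_true(all(lengths(pos$linked_elements) >= 1))
  expect_true(all(unlist(pos$linked_distances) <= 1000))
  # every active planted element is recovered within the link window
  act <- ch$truth$elements[ch$truth$elements$active]
  d <- GenomicRanges::distanceToNearest(act, pos, ignore.strand = TRUE)
  expect_equal(length(S4Vectors::queryHits(d)), length(act))
  expect_true(all(S4Vectors::mcols(d)$distance <= 1000))
  # and the large majority of calls sit at a planted element
  rec <- recovery_metrics(pos, ch$truth, match_window = 1000)
  expect_gte(rec$precision, 0.9)
})

test_that("positions BED/TSV round-trip and per-sample counts work", {
  ch <- small_chain()
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_positions(ch$pos, bed, tsv)
  back <- rtracklayer::import(bed, format = "BED")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ch$pos))
  expect_equal(back$score, ch$pos$support_pairs)
  df <- ervchimera:::read_tsv(tsv)
  expect_equal(nrow(df), length(ch$pos))
  back2 <- ervchimera:::df_to_positions(df)
  expect_equal(GenomicRanges::end(back2), GenomicRanges::end(ch$pos))

  expect_equal(count_by_sample(ch$pos),
               stats::setNames(length(ch$pos), "sim"))
  expect_equal(count_by_sample(ch$pos, samples = c("sim", "other")),
               c(sim = length(ch$pos), other = 0L))

  empty <- ch$pos[0]
  write_positions(empty, bed)
  expect_true(startsWith(readLines(bed)[1], "#"))
})
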