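test_that("genome simulation is deterministic and plants the configured copies", {
  cfg <- small_sim_config()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$repeats, b$repeats)
  expect_length(a$repeats, 3 * cfg$n_repeat_copies)
  expect_setequal(unique(a$repeats$repclass), c("LTR", "SINE", "MaLR"))
  expect_named(unclass(a$consensus))
  expect_identical(attr(a$consensus, "joint_name"), "joint")
  # planted copies never overlap
  expect_equal(length(GenomicRanges::findOverlaps(
    a$repeats, drop.self = TRUE, drop.redundant = TRUE,
    ignore.strand = TRUE)), 0L)
})

test_that("zero divergence plants exact consensus copies", {
  cfg <- small_sim_config(consensus_divergence = 0)
  g <- simulate_genome(cfg)
  cons <- unclass(g$consensus)
  ltr <- g$repeats[g$repeats$family == "LTR12like"]
  for (i in seq_along(ltr)) {
    s <- substr(g$genome[[as.character(GenomicRanges::seqnames(ltr))[i]]],
                GenomicRanges::start(ltr)[i], GenomicRanges::end(ltr)[i])
    if (as.character(GenomicRanges::strand(ltr))[i] == "-")
      s <- ervchimera:::revcomp_chr(s)
    expect_identical(s, unname(cons["LTR12like"]))
  }
  expect_true(all(g$repeats$confidence == 100))
})

test_that("planted-copy divergence matches the configured substitution rate", {
  # pooled substitution count across seeds within the binomial 99.9% interval
  n_sub <- 0; n_base <- 0
  for (seed in 1:4) {
    g <- simulate_genome(small_sim_config(seed = seed))
    w <- GenomicRanges::width(g$repeats)
    n_sub <- n_sub + sum(round((1 - g$repeats$confidence / 100) * w))
    n_base <- n_base + sum(w)
  }
  lo <- qbinom(5e-4, n_base, 0.05)
  hi <- qbinom(1 - 5e-4, n_base, 0.05)
  expect_gte(n_sub, lo)
  expect_lte(n_sub, hi)
})

test_that("transcriptome honors bidirectional fraction and junction ranges", {
  cfg <- small_sim_config(bidirectional_fraction = 1)
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  act <- tx$truth$elements[tx$truth$elements$active]
  expect_true(all(act$direction == "both"))
  # both strands have transcripts at every active element
  for (id in act$element_id) {
    st <- tx$truth$transcripts$strand[tx$truth$transcripts$element_id == id]
    expect_setequal(st, c("+", "-"))
  }

  cfg0 <- small_sim_config(bidirectional_fraction = 0,
                           n_splice_junctions = c(0, 0))
  tx0 <- simulate_transcriptome(g$genome, g$repeats, cfg0)
  expect_true(all(tx0$truth$elements$direction != "both"))
  expect_equal(nrow(tx0$truth$junctions), 0L)
  expect_false(any(grepl(",", tx0$truth$transcripts$blocks)))
})

test_that("every transcript starts inside its element and respects spans", {
  ch <- small_chain()
  tr <- ch$truth$transcripts
  el <- ch$truth$elements
  for (i in seq_len(nrow(tr))) {
    e <- el[el$element_id == tr$element_id[i]]
    expect_gte(tr$tss[i], GenomicRanges::start(e))
    expect_lte(tr$tss[i], GenomicRanges::end(e))
    b <- ervchimera:::parse_blocks(tr$blocks[i])
    expect_lte(max(b) - min(b) + 1, ch$cfg$max_junction_span)
    # first transcript block overlaps the element
    first <- if (tr$strand[i] == "+") b[1, ] else b[nrow(b), ]
    expect_true(first["start"] <= GenomicRanges::end(e) &&
                  first["end"] >= GenomicRanges::start(e))
  }
})

test_that("junction motifs are written into the patched genome", {
  ch <- small_chain()
  jn <- ch$truth$junctions
  for (i in seq_len(nrow(jn))) {
    s <- jn$intron_start[i]; e <- jn$intron_end[i]
    chrom <- ch$genome[[jn$chrom[i]]]
    if (jn$strand[i] == "+") {
      expect_identical(substr(chrom, s, s + 1), "GT")
      expect_identical(substr(chrom, e - 1, e), "AG")
    } else {
      expect_identical(substr(chrom, s, s + 1), "CT")
      expect_identical(substr(chrom, e - 1, e), "AC")
    }
  }
})

test_that("dUTP orientation makes mate 1 antisense to the transcript", {
  ch <- small_chain()
  txseq <- ervchimera:::transcript_seq(ch$truth, ch$genome)
  names(txseq) <- ch$truth$transcripts$transcript_id
  p <- ch$pairs[!is.na(ch$pairs$transcript_id), ][1:50, ]
  idx <- match(p$id, ch$reads$id)
  m1_expect <- ervchimera:::revcomp_chr(
    substring(txseq[p$transcript_id], p$frag_end - ch$cfg$read_length + 1,
              p$frag_end))
  expect_identical(unname(ch$reads$seq1[idx]), unname(m1_expect))
  m2_expect <- substring(txseq[p$transcript_id], p$frag_start,
                         p$frag_start + ch$cfg$read_length - 1)
  expect_identical(unname(ch$reads$seq2[idx]), unname(m2_expect))
})

test_that("pure background libraries touch no transcript junction", {
  cfg <- small_sim_config(background_read_fraction = 1,
                          n_read_pairs = 2000)
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  rd <- simulate_reads(tx$truth, tx$genome, cfg)
  expect_true(all(rd$pairs$source == "bg"))
  expect_true(all(is.na(rd$pairs$transcript_id)))
})

test_that("read simulation writes byte-identical FASTQ under a fixed seed", {
  cfg <- small_sim_config(n_read_pairs = 1000)
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_reads(tx$truth, tx$genome, cfg, dir = d1)
  simulate_reads(tx$truth, tx$genome, cfg, dir = d2)
  for (f in c("reads_1.fastq", "reads_2.fastq", "truth_pairs.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("active read pairs straddle their element boundary often enough", {
  # at >= 50k pairs, every active element should emit at least one pair
  # whose consensus-anchored mate sits inside the element while its free
  # mate reaches outside
  for (seed in 1:3) {
    cfg <- small_sim_config(n_read_pairs = 50000, seed = seed)
    g <- simulate_genome(cfg)
    tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
    rd <- simulate_reads(tx$truth, tx$genome, cfg)
    tr <- tx$truth$transcripts
    el <- tx$truth$elements
    for (eid in el$element_id[el$active]) {
      tids <- tr$transcript_id[tr$element_id == eid]
      straddles <- FALSE
      for (tid in tids) {
        row <- tr[tr$transcript_id == tid, ]
        e <- el[el$element_id == eid]
        # element exonic extent along the transcript
        eL <- if (row$strand == "+") GenomicRanges::end(e) - row$tss + 1 else
          row$tss - GenomicRanges::start(e) + 1
        p <- rd$pairs[!is.na(rd$pairs$transcript_id) &
                        rd$pairs$transcript_id == tid, ]
        if (nrow(p) == 0) next
        RL <- cfg$read_length
        m2_covers <- p$frag_start <= eL & p$frag_start + RL - 1 > eL
        m1_covers <- p$frag_end - RL + 1 <= eL & p$frag_end > eL
        if (any(m2_covers | m1_covers)) { straddles <- TRUE; break }
      }
      expect_true(straddles, label = sprintf("element %s seed %d straddled",
                                             eid, seed))
    }
  }
})

test_that("regulatory tracks mark active elements only, with decoys apart", {
  ch <- small_chain()
  trk <- simulate_regulatory_tracks(ch$truth, ch$cfg)
  act <- ch$truth$elements[ch$truth$elements$active]
  inact <- ch$truth$elements[!ch$truth$elements$active]
  expect_equal(sum(grepl("^K4_", trk$k4$name)), length(act))
  expect_equal(sum(grepl("^decoy_", trk$k27$name)), ch$cfg$decoy_enhancers)
  # decoys overlap no H3K4me3 peak and sit away from elements
  dec <- trk$k27[grepl("^decoy_", trk$k27$name)]
  expect_equal(length(GenomicRanges::findOverlaps(dec, trk$k4)), 0L)
  expect_true(all(S4Vectors::mcols(GenomicRanges::distanceToNearest(
    dec, ch$truth$elements))$distance > 4000))
  # inactive elements receive no marks
  if (length(inact) > 0)
    expect_equal(length(GenomicRanges::findOverlaps(inact, trk$k4)), 0L)
  # bidirectional elements get opposite-strand CAGE clusters within 1 kb
  bid <- act[act$direction == "both"]
  for (i in seq_along(bid)) {
    near <- trk$cage[GenomicRanges::distance(trk$cage, bid[i],
                                             ignore.strand = TRUE) <= 1000 &
                       !is.na(GenomicRanges::distance(trk$cage, bid[i],
                                                      ignore.strand = TRUE))]
    expect_setequal(as.character(GenomicRanges::strand(near)), c("+", "-"))
  }

  # all elements inactive -> only decoys remain
  cfg0 <- small_sim_config(n_active_elements = 0)
  g <- simulate_genome(cfg0)
  tx0 <- simulate_transcriptome(g$genome, g$repeats, cfg0)
  trk0 <- simulate_regulatory_tracks(tx0$truth, cfg0)
  expect_length(trk0$k4, 0)
  expect_length(trk0$segments, 0)
  expect_length(trk0$cage, 0)
  expect_equal(sum(grepl("^decoy_", trk0$k27$name)), cfg0$decoy_enhancers)
})

test_that("truth tables round-trip through their TSV serialization", {
  ch <- small_chain()
  d <- tempfile()
  write_truth(ch$truth, d)
  back <- read_truth(d)
  expect_equal(back$elements$element_id, ch$truth$elements$element_id)
  expect_equal(GenomicRanges::start(back$elements),
               GenomicRanges::start(ch$truth$elements))
  expect_equal(back$elements$active, ch$truth$elements$active)
  expect_equal(back$transcripts$blocks, ch$truth$transcripts$blocks)
  expect_equal(back$junctions$intron_start, ch$truth$junctions$intron_start)
})
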