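# Shared fixtures: a desk-scale simulation + alignment + calling chain,
# built once per test run and cached.

small_sim_config <- function(...) {
  args <- list(genome_bp = 300000, n_chromosomes = 2, n_repeat_copies = 5,
               n_active_elements = 3, n_read_pairs = 20000,
               transcript_extent = c(4000L, 12000L),
               max_junction_span = 30000, min_active_separation = 40000,
               seed = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

# full small chain: simulate -> scan -> discordant -> map -> merge -> call
small_chain <- function() {
  if (!is.null(.fixture_env$chain)) return(.fixture_env$chain)
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  rd <- simulate_reads(tx$truth, tx$genome, cfg)
  ap <- align_params()
  hits <- scan_consensus(rd$reads, g$consensus, ap)
  disc <- select_discordant(rd$reads, hits)
  free <- do.call(rbind, lapply(1:2, function(m) {
    sel <- disc$free_mate == m
    if (!any(sel)) return(ervchimera:::empty_alignments())
    map_genomic(setNames(disc$free_seq[sel], disc$read_id[sel]),
                tx$genome, ap, mate = m)
  }))
  cp <- chimera_params()
  uniq <- free[free$unique, , drop = FALSE]
  clusters <- merge_alignments(uniq, cp$merge_gap)
  pos <- call_positions(clusters, uniq, g$repeats, cp, sample_id = "sim")
  .fixture_env$chain <- list(cfg = cfg, genome = tx$genome,
                             repeats = g$repeats, consensus = g$consensus,
                             truth = tx$truth, reads = rd$reads,
                             pairs = rd$pairs, hits = hits, disc = disc,
                             free = free, clusters = clusters, pos = pos)
  .fixture_env$chain
}

# a bare alignment-table row builder for constructed cases
mk_align <- function(read_id, chrom, start, end, strand = "+",
                     start2 = NA_integer_, end2 = NA_integer_,
                     mismatches = 0L, unique = TRUE, mate = 1L) {
  data.frame(read_id = read_id, mate = mate, chrom = chrom, strand = strand,
             start1 = as.integer(start), end1 = as.integer(end),
             start2 = as.integer(start2), end2 = as.integer(end2),
             mismatches = mismatches, unique = unique, motif_strand = ".",
             aligned_len = as.integer((end - start + 1) +
               ifelse(is.na(start2), 0L, end2 - start2 + 1L)),
             stringsAsFactors = FALSE)
}

random_genome <- function(n, seed, chroms = 1) {
  set.seed(seed)
  per <- n %/% chroms
  g <- vapply(seq_len(chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), per, TRUE), collapse = ""),
    character(1))
  names(g) <- paste0("chr", seq_len(chroms))
  structure(g, class = "genome")
}

# mutate k random positions of a sequence
mutate_seq <- function(s, k) {
  if (k == 0) return(s)
  pos <- sample(nchar(s), k)
  b <- strsplit(s, "")[[1]]
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
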