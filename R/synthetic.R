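# Truth-tracked simulation of a toy genome with planted repeat copies,
# LTR-initiated (optionally bidirectional, spliced) transcripts, stranded
# read pairs, and matched regulatory tracks.

.sim_families <- data.frame(
  family = c("LTR12like", "ALUlike", "THE1like"),
  length = c(400L, 300L, 350L),
  repclass = c("LTR", "SINE", "MaLR"),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Defaults describe the study conditions every planted-truth check runs
#' under: a 2 Mb two-chromosome genome, 12 copies each of an LTR12-like,
#' an Alu-like and a MaLR-like family planted at 5\% per-base divergence
#' from their consensus, 8 transcriptionally active LTR12-like elements of
#' which a quarter fire bidirectionally, and 200,000 stranded 2x76 bp read
#' pairs of which 20\% are uniform genomic background.
#'
#' @param genome_bp Total genome size in bp.
#' @param n_chromosomes Number of chromosomes (genome split evenly).
#' @param n_repeat_copies Copies planted per repeat family.
#' @param consensus_divergence Per-base substitution probability applied to
#'   each planted copy.
#' @param n_active_elements Number of LTR12-like copies that initiate
#'   transcription.
#' @param bidirectional_fraction Fraction of active elements that also
#'   transcribe the opposite strand from the same element.
#' @param n_splice_junctions Integer range (length 2) of junctions per
#'   transcript.
#' @param max_junction_span Maximum genomic span of a spliced transcript, bp.
#' @param transcript_extent Range of total exonic extent per transcript, bp.
#' @param read_length Read length, bp.
#' @param n_read_pairs Total read pairs simulated.
#' @param fragment_mean,fragment_sd Fragment-length distribution, bp.
#' @param background_read_fraction Fraction of pairs drawn uniformly from
#'   the genome rather than from transcripts.
#' @param library_orientation \code{"forward-antisense"} (dUTP-style: mate 1
#'   is antisense to the transcript) or \code{"forward-sense"}.
#' @param decoy_enhancers Number of H3K27ac-only decoy peaks placed away
#'   from all planted elements.
#' @param min_active_separation Minimum pairwise distance between active
#'   elements, bp, so planted loci stay spatially distinct and locus-level
#'   truth is unambiguous; relaxed (halved, with a warning) if the planted
#'   copies cannot accommodate it.
#' @param seed Integer seed; every simulate_* stage derives its RNG state
#'   from it.
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(genome_bp = 2e6,
                              n_chromosomes = 2,
                              n_repeat_copies = 12,
                              consensus_divergence = 0.05,
                              n_active_elements = 8,
                              bidirectional_fraction = 0.25,
                              n_splice_junctions = c(0, 4),
                              max_junction_span = 100000,
                              transcript_extent = c(5000, 50000),
                              read_length = 76,
                              n_read_pairs = 200000,
                              fragment_mean = 250,
                              fragment_sd = 40,
                              background_read_fraction = 0.2,
                              library_orientation = c("forward-antisense",
                                                      "forward-sense"),
                              decoy_enhancers = 5,
                              min_active_separation = 160000,
                              seed = 1) {
  cfg <- list(genome_bp = as.integer(genome_bp),
              n_chromosomes = as.integer(n_chromosomes),
              n_repeat_copies = as.integer(n_repeat_copies),
              consensus_divergence = consensus_divergence,
              n_active_elements = as.integer(n_active_elements),
              bidirectional_fraction = bidirectional_fraction,
              n_splice_junctions = as.integer(n_splice_junctions),
              max_junction_span = as.integer(max_junction_span),
              transcript_extent = as.integer(transcript_extent),
              read_length = as.integer(read_length),
              n_read_pairs = as.integer(n_read_pairs),
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              background_read_fraction = background_read_fraction,
              library_orientation = match.arg(library_orientation),
              decoy_enhancers = as.integer(decoy_enhancers),
              min_active_separation = as.integer(min_active_separation),
              seed = as.integer(seed))
  counts <- c("genome_bp", "n_chromosomes", "n_repeat_copies", "read_length",
              "n_read_pairs", "fragment_mean", "max_junction_span")
  for (k in counts)
    assert_that(all(cfg[[k]] > 0), sprintf("config field %s must be > 0", k))
  for (k in c("consensus_divergence", "bidirectional_fraction",
              "background_read_fraction"))
    assert_that(cfg[[k]] >= 0 && cfg[[k]] <= 1,
                sprintf("config field %s must be in [0,1]", k))
  assert_that(length(cfg$n_splice_junctions) == 2 &&
                all(cfg$n_splice_junctions >= 0),
              "n_splice_junctions must be a non-negative range")
  assert_that(cfg$n_active_elements >= 0, "n_active_elements must be >= 0")
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability p; returns the mutated
# sequence and the realized substitution count
diverge_seq <- function(seq, p) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < p)
  if (length(hit) > 0) {
    alt <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b[hit] <- alt
  }
  list(seq = paste(b, collapse = ""), n_sub = length(hit))
}

#' Simulate a genome with planted repeat copies
#'
#' Generates uniform-random background sequence, draws one consensus per
#' repeat family, and plants \code{n_repeat_copies} diverged copies of each
#' at non-overlapping positions on random strands. Planted copies are
#' reported as repeat annotations whose confidence is the realized percent
#' identity to the consensus. The returned consensus set holds the
#' LTR-family consensus plus a joint entry (the scan targets), mirroring a
#' U3 consensus collection.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{genome} (class \code{"genome"}), \code{repeats}
#'   (\code{GRanges} with family/repclass/confidence/element_id) and
#'   \code{consensus} (class \code{"consensus_set"}).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chrlen <- rep(config$genome_bp %/% config$n_chromosomes,
                config$n_chromosomes)
  names(chrlen) <- paste0("chrS", seq_len(config$n_chromosomes))
  genome <- vapply(chrlen, random_dna, character(1))

  cons <- vapply(.sim_families$length, random_dna, character(1))
  names(cons) <- .sim_families$family

  placed <- lapply(chrlen, function(x) IRanges::IRanges())
  recs <- list()
  for (f in seq_len(nrow(.sim_families))) {
    flen <- .sim_families$length[f]
    for (i in seq_len(config$n_repeat_copies)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        ci <- sample(length(chrlen), 1, prob = chrlen)
        st <- sample(chrlen[ci] - flen, 1)
        ir <- IRanges::IRanges(st, st + flen - 1L)
        if (length(IRanges::findOverlaps(ir, placed[[ci]])) == 0) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot place repeat copies without overlap; ",
                    "increase genome_bp or reduce n_repeat_copies",
                    call. = FALSE)
      placed[[ci]] <- c(placed[[ci]], ir)
      strand <- sample(c("+", "-"), 1)
      dv <- diverge_seq(cons[f], config$consensus_divergence)
      ins <- if (strand == "-") revcomp_chr(dv$seq) else dv$seq
      substr(genome[ci], st, st + flen - 1L) <- ins
      recs[[length(recs) + 1]] <- data.frame(
        chrom = names(chrlen)[ci], start = st, end = st + flen - 1L,
        strand = strand, family = .sim_families$family[f],
        repclass = .sim_families$repclass[f],
        confidence = 100 * (1 - dv$n_sub / flen),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand,
                               seqinfo = GenomeInfoDb::Seqinfo(
                                 names(chrlen), unname(chrlen)))
  gr$family <- df$family
  gr$repclass <- df$repclass
  gr$confidence <- df$confidence
  gr <- sort(gr, ignore.strand = TRUE)
  gr$element_id <- sprintf("E%03d", seq_along(gr))

  ltr <- cons[.sim_families$repclass == "LTR"]
  conset <- structure(c(ltr, joint = unname(ltr[1])),
                      class = "consensus_set", joint_name = "joint")
  list(genome = structure(genome, class = "genome"),
       repeats = gr, consensus = conset)
}

# split an exonic extent E into k exon lengths, each >= 500 bp
split_exons <- function(E, k) {
  if (k == 1) return(E)
  for (try in seq_len(100)) {
    cuts <- sort(sample(E - 1, k - 1))
    lens <- diff(c(0, cuts, E))
    if (all(lens >= 500)) return(lens)
  }
  # fall back to an even split
  lens <- rep(E %/% k, k)
  lens[k] <- lens[k] + E - sum(lens)
  lens
}

# build one transcript model anchored in an element; NULL if it cannot fit
build_transcript <- function(el_start, el_end, strand, chrlen, config) {
  tss <- sample(seq(el_start, el_end), 1)
  nj <- sample(seq(config$n_splice_junctions[1],
                   config$n_splice_junctions[2]), 1)
  for (try in seq_len(50)) {
    E <- sample(seq(config$transcript_extent[1],
                    config$transcript_extent[2]), 1)
    exons <- split_exons(E, nj + 1)
    introns <- if (nj > 0) {
      imax <- max(200, (config$max_junction_span - E) %/% nj)
      sample(seq(200, imax), nj, replace = TRUE)
    } else integer(0)
    span <- E + sum(introns)
    if (span > config$max_junction_span) next
    if (strand == "+") {
      if (tss + span - 1 > chrlen) next
      starts <- tss + c(0, cumsum(exons[-length(exons)] + introns))
      ends <- starts + exons - 1
    } else {
      if (tss - span + 1 < 1) next
      ends <- tss - c(0, cumsum(exons[-length(exons)] + introns))
      starts <- ends - exons + 1
      o <- order(starts); starts <- starts[o]; ends <- ends[o]
    }
    return(list(tss = tss, starts = starts, ends = ends, strand = strand))
  }
  NULL
}

#' Simulate an LTR-anchored chimeric transcriptome
#'
#' Chooses active LTR12-like elements (greedy, subject to
#' \code{min_active_separation}), gives each a transcript that starts inside
#' the element and extends into unique flanking sequence with 0-4 splice
#' junctions, and marks a \code{bidirectional_fraction} of the active
#' elements as also transcribing the opposite strand. Canonical GT..AG
#' (CT..AC on the minus strand) dinucleotides are written into the genome at
#' every simulated intron so a motif-aware mapper can recover the junctions;
#' the modified genome is part of the return value and must be used for all
#' downstream read extraction and mapping.
#'
#' @param genome,repeats Output of \code{\link{simulate_genome}}.
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{truth} (class \code{"truth_set"}: \code{elements}
#'   GRanges carrying \code{active}/\code{direction}/expected-interval
#'   columns, \code{transcripts} and \code{junctions} data frames) and the
#'   junction-patched \code{genome}.
#' @export
simulate_transcriptome <- function(genome, repeats, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  chrlen <- stats::setNames(nchar(genome), names(genome))
  elig <- which(repeats$repclass == "LTR")
  assert_that(length(elig) >= config$n_active_elements,
              "fewer eligible LTR copies than n_active_elements")

  # greedy separated selection, threshold halved until it fits
  pool <- elig[sample.int(length(elig))]
  sep <- config$min_active_separation
  repeat {
    chosen <- integer(0)
    if (config$n_active_elements == 0) break
    for (i in pool) {
      if (length(chosen) == 0) { chosen <- i; next }
      same <- chosen[as.character(GenomicRanges::seqnames(repeats))[chosen] ==
                       as.character(GenomicRanges::seqnames(repeats))[i]]
      d <- if (length(same) == 0) Inf else
        min(abs(GenomicRanges::start(repeats)[same] -
                  GenomicRanges::start(repeats)[i]))
      if (d >= sep) chosen <- c(chosen, i)
      if (length(chosen) == config$n_active_elements) break
    }
    if (length(chosen) == config$n_active_elements || sep == 0) break
    sep <- sep %/% 2
    warning("min_active_separation relaxed to ", sep,
            " bp to fit n_active_elements", call. = FALSE)
  }
  assert_that(length(chosen) == config$n_active_elements,
              "could not select the requested number of active elements")
  active <- chosen
  n_bidir <- round(config$bidirectional_fraction * length(active))
  bidir <- if (n_bidir > 0)
    active[sample.int(length(active))][seq_len(n_bidir)] else integer(0)

  tx_rows <- list(); jn_rows <- list()
  replace_pool <- setdiff(elig[sample.int(length(elig))], active)
  i <- 1
  while (i <= length(active)) {
    ei <- active[i]
    chrom <- as.character(GenomicRanges::seqnames(repeats))[ei]
    el_s <- GenomicRanges::start(repeats)[ei]
    el_e <- GenomicRanges::end(repeats)[ei]
    el_strand <- as.character(GenomicRanges::strand(repeats))[ei]
    strands <- if (ei %in% bidir) c(el_strand,
                                    setdiff(c("+", "-"), el_strand)) else
                                      el_strand
    models <- lapply(strands, function(s)
      build_transcript(el_s, el_e, s, chrlen[chrom], config))
    if (any(vapply(models, is.null, logical(1)))) {
      # transcript would run off the chromosome: re-draw the element
      assert_that(length(replace_pool) > 0,
                  "no replacement element available for an edge-bound locus")
      if (ei %in% bidir) bidir <- c(setdiff(bidir, ei), replace_pool[1])
      active[i] <- replace_pool[1]
      replace_pool <- replace_pool[-1]
      next
    }
    for (m in models) {
      tid <- sprintf("T%03d%s", ei, if (m$strand == "+") "p" else "m")
      tx_rows[[length(tx_rows) + 1]] <- data.frame(
        transcript_id = tid, element_id = repeats$element_id[ei],
        chrom = chrom, strand = m$strand, tss = m$tss,
        blocks = paste(sprintf("%d-%d", m$starts, m$ends), collapse = ","),
        stringsAsFactors = FALSE)
      if (length(m$starts) > 1) {
        is <- m$ends[-length(m$ends)] + 1L
        ie <- m$starts[-1] - 1L
        jn_rows[[length(jn_rows) + 1]] <- data.frame(
          transcript_id = tid, chrom = chrom, strand = m$strand,
          intron_start = is, intron_end = ie, stringsAsFactors = FALSE)
      }
    }
    i <- i + 1
  }
  transcripts <- if (length(tx_rows) > 0) do.call(rbind, tx_rows) else
    data.frame(transcript_id = character(0), element_id = character(0),
               chrom = character(0), strand = character(0), tss = integer(0),
               blocks = character(0), stringsAsFactors = FALSE)
  junctions <- if (length(jn_rows) > 0) do.call(rbind, jn_rows) else
    data.frame(transcript_id = character(0), chrom = character(0),
               strand = character(0), intron_start = integer(0),
               intron_end = integer(0), stringsAsFactors = FALSE)

  # write canonical splice motifs into the genome
  for (j in seq_len(nrow(junctions))) {
    ch <- junctions$chrom[j]
    s <- junctions$intron_start[j]; e <- junctions$intron_end[j]
    if (junctions$strand[j] == "+") {
      substr(genome[ch], s, s + 1L) <- "GT"
      substr(genome[ch], e - 1L, e) <- "AG"
    } else {
      substr(genome[ch], s, s + 1L) <- "CT"
      substr(genome[ch], e - 1L, e) <- "AC"
    }
  }

  elements <- repeats[repeats$repclass == "LTR"]
  elements$active <- elements$element_id %in% repeats$element_id[active]
  eldir <- ifelse(as.character(GenomicRanges::strand(elements)) == "+",
                  "plus", "minus")
  eldir[elements$element_id %in% repeats$element_id[bidir]] <- "both"
  eldir[!elements$active] <- "none"
  elements$direction <- eldir
  pad <- round(config$fragment_mean + 2 * config$fragment_sd)
  elements$expected_start <- pmax(1L, GenomicRanges::start(elements) - pad)
  elements$expected_end <- GenomicRanges::end(elements) + pad

  truth <- structure(list(elements = elements, transcripts = transcripts,
                          junctions = junctions),
                     class = "truth_set")
  list(truth = truth, genome = structure(genome, class = "genome"))
}

# ascending-genomic blocks of a transcript row, as integer matrix
parse_blocks <- function(blocks) {
  p <- strsplit(strsplit(blocks, ",")[[1]], "-")
  cbind(start = as.integer(vapply(p, `[`, "", 1)),
        end = as.integer(vapply(p, `[`, "", 2)))
}

# spliced transcript sequence in transcript orientation
transcript_seq <- function(truth, genome) {
  vapply(seq_len(nrow(truth$transcripts)), function(i) {
    tr <- truth$transcripts[i, ]
    b <- parse_blocks(tr$blocks)
    s <- paste(substring(genome[[tr$chrom]], b[, 1], b[, 2]), collapse = "")
    if (tr$strand == "-") revcomp_chr(s) else s
  }, character(1))
}

#' Genomic blocks covered by a transcript-coordinate interval
#'
#' Maps positions \code{a..b} along a transcript (1 = TSS side) to the
#' genomic blocks they occupy; used to reason about which reads span which
#' junctions.
#'
#' @param truth A \code{"truth_set"}.
#' @param transcript_id Transcript id from \code{truth$transcripts}.
#' @param a,b Transcript coordinates, \code{a <= b}.
#' @return Integer matrix with columns \code{start}, \code{end} (ascending
#'   genomic order).
#' @export
transcript_genomic_blocks <- function(truth, transcript_id, a, b) {
  tr <- truth$transcripts[truth$transcripts$transcript_id == transcript_id, ]
  assert_that(nrow(tr) == 1, "unknown transcript_id")
  blk <- parse_blocks(tr$blocks)
  w <- blk[, 2] - blk[, 1] + 1L
  if (tr$strand == "-") { blk <- blk[rev(seq_len(nrow(blk))), , drop = FALSE]
                          w <- rev(w) }
  cum <- cumsum(w); prev <- c(0L, cum[-length(cum)])
  out <- list()
  for (i in seq_along(w)) {
    lo <- max(a, prev[i] + 1L); hi <- min(b, cum[i])
    if (lo > hi) next
    if (tr$strand == "+") {
      out[[length(out) + 1]] <- c(blk[i, 1] + (lo - prev[i] - 1L),
                                  blk[i, 1] + (hi - prev[i] - 1L))
    } else {
      out[[length(out) + 1]] <- c(blk[i, 2] - (hi - prev[i] - 1L),
                                  blk[i, 2] - (lo - prev[i] - 1L))
    }
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Simulate stranded paired-end reads from the planted transcriptome
#'
#' Fragments are drawn from active transcripts (uniform expression across
#' transcripts) plus a \code{background_read_fraction} of uniform genomic
#' fragments; mate sequences are read from the fragment ends according to
#' \code{library_orientation}. Under the default dUTP-style
#' \code{"forward-antisense"} chemistry mate 1 is the reverse complement of
#' transcript sequence. Read ids encode their source (transcript id or
#' \code{"bg"}) for debugging only.
#'
#' @param truth A \code{"truth_set"} (from \code{\link{simulate_transcriptome}}).
#' @param genome The junction-patched genome returned alongside it.
#' @param config A \code{\link{simulation_config}}.
#' @param dir Output directory; when non-NULL, \code{reads_1.fastq},
#'   \code{reads_2.fastq} and \code{truth_pairs.tsv} are written there.
#' @return (Invisibly) a list with \code{reads} (a \code{"read_pairs"}
#'   object) and \code{pairs} (per-pair truth: source transcript and
#'   fragment coordinates in transcript space, or genomic coordinates for
#'   background pairs).
#' @export
simulate_reads <- function(truth, genome, config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  assert_that(nrow(truth$transcripts) > 0, "truth contains no transcripts")
  set.seed(config$seed + 2L)
  n <- config$n_read_pairs
  RL <- config$read_length
  txseq <- transcript_seq(truth, genome)
  tlen <- nchar(txseq)
  chrlen <- nchar(genome)

  n_bg <- round(n * config$background_read_fraction)
  is_bg <- rep(FALSE, n)
  if (n_bg > 0) is_bg[sample(n, n_bg)] <- TRUE

  flen <- pmax(RL, round(stats::rnorm(n, config$fragment_mean,
                                      config$fragment_sd)))
  tx_idx <- rep(NA_integer_, n)
  tx_idx[!is_bg] <- sample(length(txseq), sum(!is_bg), replace = TRUE)
  flen[!is_bg] <- pmin(flen[!is_bg], tlen[tx_idx[!is_bg]])

  frag <- character(n)
  fs <- fe <- rep(NA_integer_, n)
  if (any(!is_bg)) {
    i <- which(!is_bg)
    fs[i] <- 1L + floor(stats::runif(length(i)) *
                          (tlen[tx_idx[i]] - flen[i] + 1))
    fe[i] <- fs[i] + flen[i] - 1L
    frag[i] <- substring(txseq[tx_idx[i]], fs[i], fe[i])
  }
  bg_chrom <- character(n); bg_start <- rep(NA_integer_, n)
  bg_strand <- character(n)
  if (any(is_bg)) {
    i <- which(is_bg)
    ci <- sample(length(genome), length(i), replace = TRUE, prob = chrlen)
    bg_chrom[i] <- names(genome)[ci]
    bg_start[i] <- 1L + floor(stats::runif(length(i)) * (chrlen[ci] - flen[i]))
    bg_strand[i] <- sample(c("+", "-"), length(i), replace = TRUE)
    s <- substring(unname(unclass(genome)[bg_chrom[i]]), bg_start[i],
                   bg_start[i] + flen[i] - 1L)
    neg <- bg_strand[i] == "-"
    s[neg] <- revcomp_chr(s[neg])
    frag[i] <- s
  }

  first <- substring(frag, 1L, RL)
  last_rc <- revcomp_chr(substring(frag, flen - RL + 1L, flen))
  if (config$library_orientation == "forward-antisense") {
    m1 <- last_rc; m2 <- first
  } else {
    m1 <- first; m2 <- last_rc
  }
  src <- ifelse(is_bg, "bg", truth$transcripts$transcript_id[tx_idx])
  id <- sprintf("p%07d:%s", seq_len(n), src)
  qual <- strrep("I", RL)
  reads <- structure(list(id = id, seq1 = m1, qual1 = rep(qual, n),
                          seq2 = m2, qual2 = rep(qual, n)),
                     class = "read_pairs")
  pairs <- data.frame(id = id, source = src,
                      transcript_id = ifelse(is_bg, NA_character_,
                        truth$transcripts$transcript_id[tx_idx]),
                      frag_start = fs, frag_end = fe,
                      bg_chrom = ifelse(is_bg, bg_chrom, NA_character_),
                      bg_start = bg_start,
                      bg_end = bg_start + flen - 1L,
                      bg_strand = ifelse(is_bg, bg_strand, NA_character_),
                      stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(dir, "reads_1.fastq")
    f2 <- file.path(dir, "reads_2.fastq")
    writeLines(as.vector(rbind(paste0("@", id, "/1"), m1, "+",
                               rep(qual, n))), f1)
    writeLines(as.vector(rbind(paste0("@", id, "/2"), m2, "+",
                               rep(qual, n))), f2)
    fp <- file.path(dir, "truth_pairs.tsv")
    write_tsv(pairs, fp)
    files <- c(f1, f2, fp)
  }
  invisible(list(reads = reads, pairs = pairs, files = files))
}

#' Simulate regulatory tracks matched to the planted truth
#'
#' Every active element receives an H3K4me3 peak and an H3K27ac peak
#' (element +/- 1 kb), a promoter-state segment, and one CAGE TSS cluster
#' per transcript (so bidirectional elements get two, on opposite strands).
#' Inactive elements receive nothing. \code{decoy_enhancers} H3K27ac-only
#' peaks are placed at least 5 kb away from all planted elements.
#'
#' @param truth A \code{"truth_set"}.
#' @param config A \code{\link{simulation_config}}.
#' @param dir Optional output directory for the four BED files.
#' @return List of \code{GRanges}: \code{k4}, \code{k27}, \code{segments},
#'   \code{cage} (stranded, with tag-count scores).
#' @export
simulate_regulatory_tracks <- function(truth, config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  el <- truth$elements
  act <- el[el$active]
  si <- GenomeInfoDb::seqinfo(el)
  chrend <- function(gr) unname(GenomeInfoDb::seqlengths(si)[
    as.character(GenomicRanges::seqnames(gr))])
  flank1k <- function(gr) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(gr) - 1000L),
                       pmin(chrend(gr), GenomicRanges::end(gr) + 1000L)),
      seqinfo = si)
  }
  k4 <- flank1k(act)
  if (length(k4) > 0) {
    k4$name <- paste0("K4_", act$element_id)
    k4$score <- 800L + seq_along(k4)
  }
  k27 <- flank1k(act)
  if (length(k27) > 0) {
    k27$name <- paste0("K27_", act$element_id)
    k27$score <- 600L + seq_along(k27)
  }
  segments <- GenomicRanges::GRanges(GenomicRanges::seqnames(act),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(act) - 500L),
                     pmin(chrend(act), GenomicRanges::end(act) + 500L)),
    seqinfo = si)
  if (length(segments) > 0) {
    segments$name <- paste0("prom_", act$element_id)
    segments$score <- 0L
  }

  tx <- truth$transcripts
  tx <- tx[tx$element_id %in% act$element_id, , drop = FALSE]
  cage <- GenomicRanges::GRanges(tx$chrom,
    IRanges::IRanges(pmax(1L, tx$tss - 15L),
                     pmin(unname(GenomeInfoDb::seqlengths(si)[tx$chrom]),
                          tx$tss + 15L)),
    strand = tx$strand, seqinfo = si)
  if (length(cage) > 0) {
    cage$name <- paste0("cage_", tx$transcript_id)
    cage$score <- stats::rpois(length(cage), 50) + 1L
  }

  # decoy enhancer-only peaks away from all planted elements
  avoid <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(truth$elements,
                          GenomicRanges::width(truth$elements) + 10000L,
                          fix = "center")))
  chrlen <- GenomeInfoDb::seqlengths(si)
  dec <- list()
  while (length(dec) < config$decoy_enhancers) {
    ci <- sample(length(chrlen), 1, prob = chrlen)
    st <- sample(chrlen[ci] - 1500L, 1)
    cand <- GenomicRanges::GRanges(names(chrlen)[ci],
                                   IRanges::IRanges(st, st + 1499L),
                                   seqinfo = si)
    if (length(GenomicRanges::findOverlaps(cand, avoid)) == 0)
      dec[[length(dec) + 1]] <- cand
  }
  if (length(dec) > 0) {
    dgr <- do.call(c, dec)
    dgr$name <- sprintf("decoy_%02d", seq_along(dgr))
    dgr$score <- 500L
    k27 <- c(k27, dgr)
  }
  out <- list(k4 = k4, k27 = k27, segments = segments, cage = cage)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rtracklayer::export(out$k4, file.path(dir, "h3k4me3.bed"), format = "BED")
    rtracklayer::export(out$k27, file.path(dir, "h3k27ac.bed"), format = "BED")
    rtracklayer::export(out$segments, file.path(dir, "promoter_segments.bed"),
                        format = "BED")
    rtracklayer::export(out$cage, file.path(dir, "cage_clusters.bed"),
                        format = "BED")
  }
  out
}

#' Write / read the truth tables of a simulation
#'
#' Plain-TSV serialization of a \code{"truth_set"} (elements, transcripts,
#' junctions) so pipeline stages can resume from disk.
#'
#' @param truth A \code{"truth_set"}.
#' @param dir Directory for \code{truth_elements.tsv},
#'   \code{truth_transcripts.tsv}, \code{truth_junctions.tsv}.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- truth$elements
  eldf <- data.frame(element_id = el$element_id,
                     chrom = as.character(GenomicRanges::seqnames(el)),
                     start = GenomicRanges::start(el),
                     end = GenomicRanges::end(el),
                     strand = as.character(GenomicRanges::strand(el)),
                     family = el$family, confidence = el$confidence,
                     active = el$active, direction = el$direction,
                     expected_start = el$expected_start,
                     expected_end = el$expected_end,
                     chrom_length = GenomeInfoDb::seqlengths(el)[
                       as.character(GenomicRanges::seqnames(el))],
                     stringsAsFactors = FALSE)
  write_tsv(eldf, file.path(dir, "truth_elements.tsv"))
  write_tsv(truth$transcripts, file.path(dir, "truth_transcripts.tsv"))
  write_tsv(truth$junctions, file.path(dir, "truth_junctions.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  eldf <- read_tsv(file.path(dir, "truth_elements.tsv"))
  sl <- tapply(eldf$chrom_length, eldf$chrom, max)
  el <- GenomicRanges::GRanges(eldf$chrom,
                               IRanges::IRanges(eldf$start, eldf$end),
                               strand = eldf$strand,
                               seqinfo = GenomeInfoDb::Seqinfo(
                                 names(sl), as.integer(sl)))
  el$family <- eldf$family
  el$repclass <- rep("LTR", nrow(eldf))
  el$confidence <- eldf$confidence
  el$element_id <- eldf$element_id
  el$active <- eldf$active
  el$direction <- eldf$direction
  el$expected_start <- eldf$expected_start
  el$expected_end <- eldf$expected_end
  structure(list(elements = el,
                 transcripts = read_tsv(file.path(dir,
                                                  "truth_transcripts.tsv")),
                 junctions = read_tsv(file.path(dir, "truth_junctions.tsv"))),
            class = "truth_set")
}
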