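# The two alignment stages: mate-prefix scan against LTR U3 consensus
# sequences, and full-length unique splice-aware genomic mapping.
# The inner loops live in src/align.cpp.

#' Alignment parameters
#'
#' @param prefix_len Mate prefix length scanned against the consensus set,
#'   bp. Mates shorter than this are used whole.
#' @param consensus_max_mismatches Mismatch budget for the prefix scan.
#' @param genomic_max_mismatches Mismatch budget for full-length genomic
#'   mapping.
#' @param min_unique_gap Mismatch margin by which the best genomic placement
#'   must beat every alternative to count as uniquely mapped.
#' @param min_anchor Minimum bases on each side of a splice junction in a
#'   split alignment.
#' @param max_intron Maximum junction gap, bp.
#' @param min_intron Minimum junction gap, bp.
#' @param seed_len Exact-match seed length for the genomic mapper.
#' @return List of class \code{"align_params"}.
#' @export
align_params <- function(prefix_len = 30, consensus_max_mismatches = 2,
                         genomic_max_mismatches = 2, min_unique_gap = 2,
                         min_anchor = 8, max_intron = 500000,
                         min_intron = 30, seed_len = 12) {
  p <- list(prefix_len = as.integer(prefix_len),
            consensus_max_mismatches = as.integer(consensus_max_mismatches),
            genomic_max_mismatches = as.integer(genomic_max_mismatches),
            min_unique_gap = as.integer(min_unique_gap),
            min_anchor = as.integer(min_anchor),
            max_intron = as.integer(max_intron),
            min_intron = as.integer(min_intron),
            seed_len = as.integer(seed_len))
  assert_that(all(unlist(p) >= 0), "alignment parameters must be >= 0")
  assert_that(p$prefix_len >= p$seed_len, "prefix_len must be >= seed_len")
  structure(p, class = "align_params")
}

empty_alignments <- function() {
  data.frame(read_id = character(0), mate = integer(0), chrom = character(0),
             strand = character(0), start1 = integer(0), end1 = integer(0),
             start2 = integer(0), end2 = integer(0),
             mismatches = integer(0), unique = logical(0),
             motif_strand = character(0), aligned_len = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan mate prefixes against a consensus set
#'
#' The first \code{prefix_len} bases of each mate are tested ungapped
#' against every consensus sequence, on both strands and at every offset;
#' all placements within the mismatch budget are reported. Every family is
#' scanned for every mate (union of hits), so downstream filtering sees the
#' full hit/no-hit picture per mate while family identity is retained for
#' reporting.
#'
#' @param pairs A \code{"read_pairs"} object.
#' @param cons A \code{"consensus_set"}.
#' @param params An \code{\link{align_params}}.
#' @return data.frame with \code{read_id}, \code{mate}, \code{family},
#'   \code{offset} (1-based start in the consensus), \code{strand},
#'   \code{mismatches}.
#' @export
scan_consensus <- function(pairs, cons, params = align_params()) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(cons, "consensus_set"))
  n <- n_pairs(pairs)
  pre <- c(substr(pairs$seq1, 1L, params$prefix_len),
           substr(pairs$seq2, 1L, params$prefix_len))
  hits <- cpp_scan_prefix(pre, unclass(cons),
                          params$consensus_max_mismatches)
  mate <- ifelse(hits$read > n, 2L, 1L)
  idx <- ifelse(hits$read > n, hits$read - n, hits$read)
  out <- data.frame(read_id = pairs$id[idx], mate = mate,
                    family = names(cons)[hits$ref],
                    offset = hits$start, strand = hits$strand,
                    mismatches = hits$mismatches, stringsAsFactors = FALSE)
  assert_that(all(out$mismatches <= params$consensus_max_mismatches),
              "consensus hit exceeds mismatch budget")
  out
}

#' Select discordant pairs (exactly one consensus-anchored mate)
#'
#' Keeps read pairs in which one mate has at least one consensus hit and
#' the other has none; pairs where neither or both mates hit are discarded.
#'
#' @param pairs A \code{"read_pairs"} object.
#' @param hits Hit table from \code{\link{scan_consensus}}.
#' @return data.frame with \code{read_id}, \code{anchored_mate},
#'   \code{free_mate}, \code{free_seq}, \code{free_qual} and the anchoring
#'   consensus families (comma-collapsed).
#' @export
select_discordant <- function(pairs, hits) {
  stopifnot(inherits(pairs, "read_pairs"))
  h1 <- pairs$id %in% hits$read_id[hits$mate == 1L]
  h2 <- pairs$id %in% hits$read_id[hits$mate == 2L]
  keep <- xor(h1, h2)
  anchored <- ifelse(h1[keep], 1L, 2L)
  fam <- tapply(hits$family, hits$read_id,
                function(x) paste(sort(unique(x)), collapse = ","))
  data.frame(read_id = pairs$id[keep],
             anchored_mate = anchored,
             free_mate = 3L - anchored,
             free_seq = ifelse(anchored == 1L, pairs$seq2[keep],
                               pairs$seq1[keep]),
             free_qual = ifelse(anchored == 1L, pairs$qual2[keep],
                                pairs$qual1[keep]),
             anchor_families = unname(fam[pairs$id[keep]]),
             stringsAsFactors = FALSE)
}

#' Map reads full length against the genome (splice-aware, unique-tracking)
#'
#' Seed-and-extend ungapped alignment. If a read has no contiguous placement
#' within the mismatch budget, a single-junction two-block placement is
#' sought (each block at least \code{min_anchor} bp, same chromosome and
#' strand, gap within \code{[min_intron, max_intron]}), preferring canonical
#' GT..AG / CT..AC junction motifs at equal mismatch count. An alignment is
#' flagged unique when its placement beats every alternative mapping
#' location by at least \code{min_unique_gap} mismatches.
#'
#' @param reads Named character vector of read sequences (names = ids), or
#'   a data.frame with \code{read_id} and \code{seq} columns.
#' @param genome A \code{"genome"} object.
#' @param params An \code{\link{align_params}}.
#' @param mate Mate number recorded in the output (bookkeeping only).
#' @param split Set \code{FALSE} for contiguous-only mapping.
#' @return Alignment table: \code{read_id}, \code{mate}, \code{chrom},
#'   \code{strand}, blocks \code{start1/end1} (+ \code{start2/end2} for
#'   split alignments, else NA), \code{mismatches}, \code{unique},
#'   \code{motif_strand} (transcript strand inferred from the splice motif,
#'   \code{"."} otherwise) and \code{aligned_len}.
#' @export
map_genomic <- function(reads, genome, params = align_params(), mate = 1L,
                        split = TRUE) {
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$seq, reads$read_id)
  }
  stopifnot(inherits(genome, "genome"))
  if (length(reads) == 0) return(empty_alignments())
  res <- cpp_map_reads(unname(reads), unclass(genome),
                       params$seed_len, params$genomic_max_mismatches,
                       params$min_unique_gap, params$min_anchor,
                       params$max_intron, params$min_intron, split)
  if (nrow(res) == 0) return(empty_alignments())
  out <- data.frame(read_id = names(reads)[res$read], mate = mate,
                    chrom = names(genome)[res$chrom], strand = res$strand,
                    start1 = res$start1, end1 = res$end1,
                    start2 = res$start2, end2 = res$end2,
                    mismatches = res$mismatches,
                    unique = res$unique == 1L,
                    motif_strand = res$motif_strand,
                    stringsAsFactors = FALSE)
  out$aligned_len <- (out$end1 - out$start1 + 1L) +
    ifelse(is.na(out$start2), 0L, out$end2 - out$start2 + 1L)
  assert_that(all(out$mismatches <= params$genomic_max_mismatches),
              "genomic alignment exceeds mismatch budget")
  rl <- nchar(reads)[res$read]
  assert_that(all(out$aligned_len <= rl), "alignment longer than read")
  out
}

#' Alignment blocks as a GRanges (one range per block)
#'
#' @param alignments Alignment table.
#' @param genome Optional \code{"genome"} supplying sequence lengths.
#' @return \code{GRanges} with \code{align_row} (row index into
#'   \code{alignments}), \code{read_id} and \code{block} columns.
#' @export
alignment_blocks <- function(alignments, genome = NULL) {
  a <- alignments
  split <- !is.na(a$start2)
  df <- data.frame(row = seq_len(nrow(a)), chrom = a$chrom, start = a$start1,
                   end = a$end1, strand = a$strand,
                   block = rep(1L, nrow(a)), stringsAsFactors = FALSE)
  if (any(split))
    df <- rbind(df, data.frame(row = which(split), chrom = a$chrom[split],
                               start = a$start2[split], end = a$end2[split],
                               strand = a$strand[split],
                               block = rep(2L, sum(split)),
                               stringsAsFactors = FALSE))
  si <- if (is.null(genome)) NULL else genome_seqinfo(genome)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand,
                               seqinfo = si)
  gr$align_row <- df$row
  gr$read_id <- a$read_id[df$row]
  gr$block <- df$block
  sort(gr, ignore.strand = TRUE)
}
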