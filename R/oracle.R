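# Brute-force alignment oracle: exhaustive enumeration of ungapped and
# two-block placements, used to validate the seed-and-extend mapper and the
# consensus scan. Deliberately shares no code with src/align.cpp: the
# contiguous path rides on Biostrings::neditStartingAt, the split path on
# plain byte-comparison cumsums.

#' Exhaustively enumerate read placements (test oracle)
#'
#' Enumerates every ungapped placement of a read on both strands of every
#' reference sequence (\code{mode = "contiguous"}), or every two-block
#' split placement with blocks of at least \code{min_anchor} bp on one
#' chromosome/strand and a gap in \code{[min_intron, max_intron]}
#' (\code{mode = "split"}). Acceptance thresholds match the production
#' mappers. Intended for small references (test scale).
#'
#' @param read Read sequence (character scalar). An empty read yields an
#'   empty result.
#' @param reference Named character vector of reference sequences (a
#'   \code{"genome"}, \code{"consensus_set"}, or plain vector).
#' @param params An \code{\link{align_params}}.
#' @param mode \code{"contiguous"} or \code{"split"}.
#' @return data.frame of placements with mismatch counts; split placements
#'   carry both blocks, their best split point and whether the junction
#'   motif is canonical. The attribute \code{"best_mm"} and
#'   \code{"second_mm"} give the two best mismatch counts over all mapping
#'   locations (contiguous locations for contiguous mode; diagonal pairs
#'   for split mode, with the best contiguous placement as an additional
#'   competitor), from which uniqueness under \code{min_unique_gap} can be
#'   judged.
#' @export
brute_force_align <- function(read, reference, params = align_params(),
                              mode = c("contiguous", "split")) {
  mode <- match.arg(mode)
  reference <- unclass(reference)
  L <- nchar(read)
  if (L == 0) {
    out <- data.frame()
    attr(out, "best_mm") <- NA_integer_
    return(out)
  }
  if (mode == "contiguous") {
    oracle_contiguous(read, reference, params)
  } else {
    oracle_split(read, reference, params)
  }
}

oracle_contiguous <- function(read, reference, params) {
  L <- nchar(read)
  max_mm <- params$genomic_max_mismatches
  rows <- list()
  all_mm <- integer(0)
  pats <- list(`+` = Biostrings::DNAString(read),
               `-` = Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (ref_name in names(reference)) {
    subj <- Biostrings::DNAString(reference[[ref_name]])
    n <- length(subj) - L + 1
    if (n < 1) next
    for (s in c("+", "-")) {
      mm <- Biostrings::neditStartingAt(pats[[s]], subj, starting.at = 1:n,
                                        with.indels = FALSE)
      all_mm <- c(all_mm, mm)
      hit <- which(mm <= max_mm)
      if (length(hit) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ref_name, strand = s, start1 = hit, end1 = hit + L - 1L,
          start2 = NA_integer_, end2 = NA_integer_, mismatches = mm[hit],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), strand = character(0),
               start1 = integer(0), end1 = integer(0), start2 = integer(0),
               end2 = integer(0), mismatches = integer(0),
               stringsAsFactors = FALSE)
  srt <- sort(all_mm)
  attr(out, "best_mm") <- if (length(srt) > 0) srt[1] else NA_integer_
  attr(out, "second_mm") <- if (length(srt) > 1) srt[2] else NA_integer_
  out
}

# per-diagonal mismatch indicator cumsums; enumerates all (d1, d2, split)
oracle_split <- function(read, reference, params) {
  L <- nchar(read)
  max_mm <- params$genomic_max_mismatches
  a_lo <- params$min_anchor
  a_hi <- L - params$min_anchor
  rows <- list()
  pair_best <- integer(0)   # best mm per diagonal pair, for uniqueness
  contig <- oracle_contiguous(read, reference, params)
  if (a_hi < a_lo) {
    out <- contig[0, ]
    attr(out, "best_mm") <- NA_integer_
    attr(out, "second_mm") <- NA_integer_
    return(out)
  }
  for (ref_name in names(reference)) {
    refseq <- reference[[ref_name]]
    n_d <- nchar(refseq) - L + 1
    if (n_d < 2) next
    refb <- utf8ToInt(refseq)
    for (s in c("+", "-")) {
      rb <- utf8ToInt(if (s == "+") read else revcomp_chr(read))
      # M[d, x]: read base x mismatches at diagonal d (1-based genomic start)
      idx <- outer(seq_len(n_d) - 1L, seq_len(L), `+`)
      M <- matrix(refb[idx] != rep(rb, each = n_d), nrow = n_d)
      P <- M * 1L
      for (x in 2:L) P[, x] <- P[, x] + P[, x - 1L]   # prefix cumsums
      Tot <- P[, L]
      for (a in a_lo:a_hi) {
        pc <- P[, a]                 # prefix mismatches at each d1
        sc <- Tot - P[, a]           # suffix mismatches at each d2
        d1s <- which(pc <= max_mm)
        for (d1 in d1s) {
          d2 <- which(sc <= max_mm - pc[d1])
          d2 <- d2[d2 - d1 >= params$min_intron &
                     d2 - d1 <= params$max_intron]
          for (dd in d2) {
            tot <- pc[d1] + sc[dd]
            is <- d1 + a; ie <- dd + a - 1L   # intron bounds, 1-based
            di <- substr(refseq, is, is + 1L)
            ac <- substr(refseq, ie - 1L, ie)
            canonical <- (di == "GT" && ac == "AG") ||
                         (di == "CT" && ac == "AC")
            rows[[length(rows) + 1]] <- data.frame(
              chrom = ref_name, strand = s, start1 = d1, end1 = d1 + a - 1L,
              start2 = dd + a, end2 = dd + L - 1L, mismatches = tot,
              split_at = a, canonical = canonical, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), strand = character(0),
               start1 = integer(0), end1 = integer(0), start2 = integer(0),
               end2 = integer(0), mismatches = integer(0),
               split_at = integer(0), canonical = logical(0),
               stringsAsFactors = FALSE)
  # competitors for uniqueness: best mm per distinct diagonal pair, plus the
  # best contiguous placement
  if (nrow(out) > 0) {
    key <- paste(out$chrom, out$strand,
                 out$start1,                  # d1 (block 1 sits on its diagonal)
                 out$start2 - out$split_at,   # d2
                 sep = ":")
    pair_best <- tapply(out$mismatches, key, min)
  }
  comp <- sort(c(unname(pair_best), attr(contig, "best_mm")), na.last = NA)
  attr(out, "best_mm") <- if (length(comp) > 0) comp[1] else NA_integer_
  attr(out, "second_mm") <- if (length(comp) > 1) comp[2] else NA_integer_
  out
}
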