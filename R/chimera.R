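# Chimeric-position calling: gap-merge unique free-mate alignments into
# clusters, then keep clusters with enough uniquely mapped sequence sitting
# adjacent to (but not inside) an allowed-family repeat.

#' Chimeric-position calling parameters
#'
#' @param merge_gap Alignments closer than this are merged into one cluster
#'   (single-linkage, BEDTools \code{merge -d} semantics), bp.
#' @param min_unique_bp Minimum contiguous uniquely aligned bases, outside
#'   any allowed-family repeat body, that some supporting mate must
#'   contribute.
#' @param repeat_link_window Maximum distance between a cluster and an
#'   allowed-family repeat for the two to be linked, bp (overlap = 0).
#' @param min_support_pairs Minimum distinct supporting read pairs.
#' @param allowed_families Glob patterns of repeat families that can anchor
#'   a chimeric position (extensible to all ERV1-type families).
#' @return List of class \code{"chimera_params"}.
#' @export
chimera_params <- function(merge_gap = 2000, min_unique_bp = 40,
                           repeat_link_window = 1000, min_support_pairs = 1,
                           allowed_families = c("LTR12*", "ERV9*")) {
  p <- list(merge_gap = as.integer(merge_gap),
            min_unique_bp = as.integer(min_unique_bp),
            repeat_link_window = as.integer(repeat_link_window),
            min_support_pairs = as.integer(min_support_pairs),
            allowed_families = allowed_families)
  assert_that(all(c(p$merge_gap, p$min_unique_bp, p$repeat_link_window,
                    p$min_support_pairs) >= 0),
              "calling parameters must be >= 0")
  structure(p, class = "chimera_params")
}

#' Gap-merge alignments into clusters
#'
#' Single-linkage merge per chromosome: alignment blocks whose gap is at
#' most \code{merge_gap} join one cluster. Strand is ignored (positions are
#' strand-agnostic; polarity comes from coverage). The operation is
#' idempotent.
#'
#' @param alignments Alignment table (unique free-mate alignments).
#' @param merge_gap Merge distance, bp.
#' @return \code{GRanges} of clusters, sorted, with \code{align_rows}
#'   (IntegerList of member rows in \code{alignments}) and \code{read_ids}
#'   (CharacterList of distinct supporting reads).
#' @export
merge_alignments <- function(alignments, merge_gap = 2000) {
  blocks <- alignment_blocks(alignments)
  cl <- GenomicRanges::reduce(blocks, min.gapwidth = merge_gap + 1L,
                              with.revmap = TRUE, ignore.strand = TRUE)
  rv <- cl$revmap
  cl$revmap <- NULL
  cl$align_rows <- S4Vectors::endoapply(
    methods::as(rv, "IntegerList"),
    function(i) unique(blocks$align_row[i]))
  cl$read_ids <- methods::as(lapply(as.list(rv), function(i)
    unique(blocks$read_id[i])), "CharacterList")
  cl
}

#' Call chimeric positions from clusters
#'
#' A cluster becomes a chimeric position iff (a) some supporting mate has a
#' single uniquely aligned block of at least \code{min_unique_bp} bases that
#' does not overlap any allowed-family repeat body, (b) at least one
#' allowed-family repeat lies within \code{repeat_link_window} of the
#' cluster, and (c) it is supported by at least \code{min_support_pairs}
#' distinct pairs. Dropped clusters are counted in the run report
#' (\code{attr(, "report")}).
#'
#' @param clusters Output of \code{\link{merge_alignments}}.
#' @param alignments The alignment table the clusters were built from.
#' @param repeats Repeat annotation \code{GRanges} (family/repclass columns).
#' @param params A \code{\link{chimera_params}}.
#' @param sample_id Sample label carried on every position.
#' @return \code{GRanges} of chimeric positions with \code{sample_id},
#'   \code{support_pairs}, \code{unique_bp}, \code{plus_votes},
#'   \code{minus_votes}, \code{linked_elements} (IntegerList of row indices
#'   into \code{repeats}, sorted by distance), \code{linked_families},
#'   \code{linked_distances}.
#' @export
call_positions <- function(clusters, alignments, repeats,
                           params = chimera_params(), sample_id = "sample") {
  allowed <- repeats[match_family(repeats$family, params$allowed_families)]
  report <- list(clusters_in = length(clusters), dropped_unique_bp = 0L,
                 dropped_no_repeat = 0L, dropped_support = 0L,
                 positions_out = 0L)

  if (length(clusters) == 0) {
    out <- GenomicRanges::GRanges()
    attr(out, "report") <- report
    return(out)
  }

  # per-alignment-block qualifying widths (unique, long enough, outside
  # allowed repeat bodies)
  blocks <- alignment_blocks(alignments)
  buniq <- alignments$unique[blocks$align_row]
  bwidth <- GenomicRanges::width(blocks)
  in_rep <- rep(FALSE, length(blocks))
  if (length(allowed) > 0)
    in_rep <- GenomicRanges::countOverlaps(blocks, allowed,
                                           ignore.strand = TRUE) > 0
  qual <- buniq & !in_rep & bwidth >= params$min_unique_bp
  # map qualifying block widths back to alignment rows
  best_bp_of_row <- rep(0L, nrow(alignments))
  if (any(qual)) {
    agg <- tapply(bwidth[qual], blocks$align_row[qual], max)
    best_bp_of_row[as.integer(names(agg))] <- as.integer(agg)
  }

  rows <- as.list(clusters$align_rows)
  unique_bp <- vapply(rows, function(r) max(c(0L, best_bp_of_row[r])),
                      integer(1))
  support <- lengths(clusters$read_ids)
  plus_votes <- vapply(rows, function(r)
    sum(alignments$strand[r] == "+"), integer(1))
  minus_votes <- vapply(rows, function(r)
    sum(alignments$strand[r] == "-"), integer(1))

  linked <- vector("list", length(clusters))
  if (length(allowed) > 0) {
    ov <- GenomicRanges::findOverlaps(clusters, allowed,
                                      maxgap = params$repeat_link_window,
                                      ignore.strand = TRUE)
    d <- GenomicRanges::distance(clusters[S4Vectors::queryHits(ov)],
                                 allowed[S4Vectors::subjectHits(ov)],
                                 ignore.strand = TRUE)
    for (ci in unique(S4Vectors::queryHits(ov))) {
      sel <- S4Vectors::queryHits(ov) == ci
      o <- order(d[sel])
      linked[[ci]] <- data.frame(idx = S4Vectors::subjectHits(ov)[sel][o],
                                 dist = d[sel][o])
    }
  }
  has_link <- !vapply(linked, is.null, logical(1))

  ok_bp <- unique_bp >= params$min_unique_bp
  ok_sup <- support >= params$min_support_pairs
  keep <- ok_bp & has_link & ok_sup
  report$dropped_unique_bp <- sum(!ok_bp)
  report$dropped_no_repeat <- sum(ok_bp & !has_link)
  report$dropped_support <- sum(ok_bp & has_link & !ok_sup)
  report$positions_out <- sum(keep)

  out <- GenomicRanges::granges(clusters[keep])
  out$sample_id <- rep(sample_id, sum(keep))
  out$support_pairs <- support[keep]
  out$unique_bp <- unique_bp[keep]
  out$plus_votes <- plus_votes[keep]
  out$minus_votes <- minus_votes[keep]
  lk <- linked[keep]
  out$linked_elements <- methods::as(lapply(lk, `[[`, "idx"), "IntegerList")
  out$linked_families <- methods::as(lapply(lk, function(x)
    allowed$family[x$idx]), "CharacterList")
  # translate allowed-subset indices back to rows of `repeats`
  allowed_rows <- which(match_family(repeats$family, params$allowed_families))
  out$linked_elements <- S4Vectors::endoapply(out$linked_elements,
                                              function(i) allowed_rows[i])
  out$linked_distances <- methods::as(lapply(lk, `[[`, "dist"), "IntegerList")
  attr(out, "report") <- report
  out
}

#' Write chimeric positions to BED and TSV
#'
#' The BED name column carries the nearest linked family, the score the
#' supporting pair count. An empty position set writes a comment-only file.
#'
#' @param positions \code{GRanges} from \code{\link{call_positions}}.
#' @param bed Output BED path.
#' @param tsv Optional TSV path with the full annotation.
#' @export
write_positions <- function(positions, bed, tsv = NULL) {
  if (length(positions) == 0) {
    writeLines("# no chimeric positions", bed)
  } else {
    out <- GenomicRanges::granges(positions)
    out$name <- vapply(as.list(positions$linked_families),
                       function(x) x[1] %||% ".", character(1))
    out$score <- positions$support_pairs
    rtracklayer::export(out, bed, format = "BED")
  }
  if (!is.null(tsv)) write_tsv(positions_to_df(positions), tsv)
  invisible(bed)
}

positions_to_df <- function(positions) {
  if (length(positions) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample_id = character(0),
                      support_pairs = integer(0), unique_bp = integer(0),
                      plus_votes = integer(0), minus_votes = integer(0),
                      linked_families = character(0),
                      linked_distances = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(positions)),
             start = GenomicRanges::start(positions),
             end = GenomicRanges::end(positions),
             sample_id = positions$sample_id,
             support_pairs = positions$support_pairs,
             unique_bp = positions$unique_bp,
             plus_votes = positions$plus_votes,
             minus_votes = positions$minus_votes,
             linked_families = vapply(as.list(positions$linked_families),
                                      paste, character(1), collapse = ","),
             linked_distances = vapply(as.list(positions$linked_distances),
                                       paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

df_to_positions <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$sample_id <- df$sample_id
  gr$support_pairs <- df$support_pairs
  gr$unique_bp <- df$unique_bp
  gr$plus_votes <- df$plus_votes
  gr$minus_votes <- df$minus_votes
  gr$linked_families <- methods::as(
    strsplit(as.character(df$linked_families), ","), "CharacterList")
  gr$linked_distances <- methods::as(
    lapply(strsplit(as.character(df$linked_distances), ","), as.integer),
    "IntegerList")
  gr
}

#' Count chimeric positions per sample
#'
#' @param positions A positions \code{GRanges} (or list of them); per-sample
#'   counts feed the depth-vs-positions correlation.
#' @param samples Optional character vector of sample ids to report (zeros
#'   included).
#' @return Named integer vector of position counts.
#' @export
count_by_sample <- function(positions, samples = NULL) {
  if (is.list(positions) && !methods::is(positions, "GRanges"))
    positions <- do.call(c, unname(positions))
  ids <- if (length(positions) > 0) positions$sample_id else character(0)
  lv <- samples %||% sort(unique(ids))
  tab <- table(factor(ids, levels = lv))
  stats::setNames(as.integer(tab), names(tab))
}
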