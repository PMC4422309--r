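# Strand-specific coverage, transcribed-patch segmentation, locus assembly
# and splice-junction collection — the machinery behind browser-style
# figure tracks, formalized.

#' Compute strand-specific coverage from unique alignments
#'
#' Each aligned block increments the depth of the transcript strand implied
#' by the alignment strand and the library orientation: under the default
#' dUTP-style \code{"forward-antisense"} protocol a mate-1 alignment on the
#' plus strand reports a minus-strand transcript. Mate-1 alignments only by
#' default, mirroring forward-read tracks; non-unique alignments are
#' ignored.
#'
#' @param alignments Alignment table.
#' @param genome A \code{"genome"} object (supplies chromosome lengths).
#' @param orientation Library orientation, as in
#'   \code{\link{simulation_config}}.
#' @param mate Mates to include (default 1).
#' @return Object of class \code{"stranded_coverage"}: list with integer
#'   \code{RleList}s \code{plus} and \code{minus} and \code{seqlengths}.
#' @export
compute_coverage <- function(alignments, genome,
                             orientation = c("forward-antisense",
                                             "forward-sense"),
                             mate = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(genome, "genome"))
  sl <- stats::setNames(nchar(genome), names(genome))
  a <- alignments[alignments$unique & alignments$mate %in% mate, ,
                  drop = FALSE]
  over <- !is.na(a$end1) &
    (a$end1 > sl[a$chrom] | ifelse(is.na(a$end2), FALSE, a$end2 > sl[a$chrom]))
  assert_that(!any(over), "alignment extends beyond chromosome end")

  # transcript strand: mate 1 flips under forward-antisense; mate 2 is the
  # opposite of mate 1
  flip1 <- orientation == "forward-antisense"
  flips <- ifelse(a$mate == 1L, flip1, !flip1)
  tstrand <- ifelse(xor(a$strand == "-", flips), "-", "+")

  cov_of <- function(sel) {
    if (sum(sel) == 0)
      return(IRanges::RleList(lapply(sl, function(x) S4Vectors::Rle(0L, x)),
                              compress = FALSE))
    b <- alignment_blocks(a[sel, , drop = FALSE], genome)
    GenomicRanges::coverage(b)
  }
  structure(list(plus = cov_of(tstrand == "+"),
                 minus = cov_of(tstrand == "-"),
                 seqlengths = sl),
            class = "stranded_coverage")
}

#' Total depth of a stranded coverage object
#' @param cov A \code{"stranded_coverage"}.
#' @return Sum of plus- and minus-strand depth over all bases; equals the
#'   total aligned bases of the contributing alignments.
#' @export
total_depth <- function(cov) {
  sum(as.numeric(sum(cov$plus))) + sum(as.numeric(sum(cov$minus)))
}

#' Write / read stranded coverage as a BedGraph pair
#' @param cov A \code{"stranded_coverage"}.
#' @param prefix Path prefix; \code{<prefix>.plus.bedGraph} and
#'   \code{<prefix>.minus.bedGraph} are written.
#' @export
write_stranded_coverage <- function(cov, prefix) {
  write_bedgraph(cov$plus, paste0(prefix, ".plus.bedGraph"))
  write_bedgraph(cov$minus, paste0(prefix, ".minus.bedGraph"))
  invisible(prefix)
}

#' @rdname write_stranded_coverage
#' @param seqlengths Named chromosome lengths (for reading).
#' @export
read_stranded_coverage <- function(prefix, seqlengths) {
  structure(list(plus = read_bedgraph(paste0(prefix, ".plus.bedGraph"),
                                      seqlengths),
                 minus = read_bedgraph(paste0(prefix, ".minus.bedGraph"),
                                       seqlengths),
                 seqlengths = seqlengths),
            class = "stranded_coverage")
}

#' Call transcribed patches from stranded coverage
#'
#' Per strand, maximal runs with depth at least \code{min_cov} are taken,
#' runs separated by gaps of at most \code{max_gap} are merged, and patches
#' shorter than \code{min_width} are dropped.
#'
#' @param cov A \code{"stranded_coverage"}.
#' @param min_cov Minimum depth.
#' @param max_gap Merge gap, bp.
#' @param min_width Minimum patch width, bp.
#' @return \code{GRanges} of patches with \code{mean_depth} and
#'   \code{max_depth}.
#' @export
call_patches <- function(cov, min_cov = 2, max_gap = 10000, min_width = 200) {
  si <- GenomeInfoDb::Seqinfo(names(cov$seqlengths),
                              unname(cov$seqlengths))
  one_strand <- function(rlel, strand) {
    rows <- list()
    for (ch in names(rlel)) {
      rle <- rlel[[ch]]
      ir <- methods::as(IRanges::slice(rle, lower = min_cov,
                                       rangesOnly = TRUE), "IRanges")
      if (length(ir) == 0) next
      ir <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
      ir <- ir[IRanges::width(ir) >= min_width]
      if (length(ir) == 0) next
      v <- IRanges::Views(rle, ir)
      gr <- GenomicRanges::GRanges(ch, ir, strand = strand, seqinfo = si)
      gr$mean_depth <- IRanges::viewMeans(v)
      gr$max_depth <- IRanges::viewMaxs(v)
      rows[[length(rows) + 1]] <- gr
    }
    if (length(rows) == 0) {
      gr <- GenomicRanges::GRanges(seqinfo = si)
      gr$mean_depth <- numeric(0)
      gr$max_depth <- numeric(0)
      return(gr)
    }
    do.call(c, rows)
  }
  out <- c(one_strand(cov$plus, "+"), one_strand(cov$minus, "-"))
  sort(out, ignore.strand = TRUE)
}

#' Chain patches into transcribed loci
#'
#' Patches of either strand within \code{join_gap} of one another are
#' chained into a locus; a locus is bidirectional iff both strands
#' contribute patches. Chimeric positions overlapping the locus (within
#' \code{join_gap}) are attached.
#'
#' @param patches \code{GRanges} from \code{\link{call_patches}}.
#' @param positions Optional chimeric-position \code{GRanges}.
#' @param join_gap Chain gap, bp.
#' @return \code{GRanges} of loci with \code{span_bp}, \code{bidirectional},
#'   \code{n_patches} and \code{linked_positions} (IntegerList of indices
#'   into \code{positions}).
#' @export
assemble_loci <- function(patches, positions = NULL, join_gap = 50000) {
  if (length(patches) == 0) {
    out <- GenomicRanges::GRanges()
    out$span_bp <- integer(0)
    out$bidirectional <- logical(0)
    out$n_patches <- integer(0)
    out$linked_positions <- methods::as(list(), "IntegerList")
    return(out)
  }
  loci <- GenomicRanges::reduce(patches, min.gapwidth = join_gap + 1L,
                                with.revmap = TRUE, ignore.strand = TRUE)
  rv <- methods::as(loci$revmap, "IntegerList")
  loci$revmap <- NULL
  st <- as.character(GenomicRanges::strand(patches))
  loci$span_bp <- GenomicRanges::width(loci)
  loci$bidirectional <- vapply(as.list(rv), function(i)
    length(unique(st[i])) > 1, logical(1))
  loci$n_patches <- lengths(rv)
  lp <- vector("list", length(loci))
  for (i in seq_along(lp)) lp[[i]] <- integer(0)
  if (!is.null(positions) && length(positions) > 0) {
    ov <- GenomicRanges::findOverlaps(positions, loci, maxgap = join_gap,
                                      ignore.strand = TRUE)
    for (h in seq_along(ov)) {
      li <- S4Vectors::subjectHits(ov)[h]
      lp[[li]] <- c(lp[[li]], S4Vectors::queryHits(ov)[h])
    }
  }
  loci$linked_positions <- methods::as(lp, "IntegerList")
  loci
}

#' Collect splice junctions from split alignments
#'
#' Junctions are keyed by (chromosome, donor, acceptor, strand) where donor
#' and acceptor are the first and last intron base (ascending genomic
#' coordinates) and the strand is the transcript strand inferred from the
#' junction motif when canonical, the alignment strand otherwise. A
#' junction is chimeric iff either end lies within \code{link_window} of an
#' allowed-family repeat; the nearest such repeat is attached.
#'
#' @param alignments Alignment table (split rows are used).
#' @param repeats Optional repeat \code{GRanges}.
#' @param link_window Linking distance, bp.
#' @param allowed_families Family glob patterns for chimera flagging.
#' @return data.frame with \code{chrom}, \code{donor}, \code{acceptor},
#'   \code{strand}, \code{support}, \code{chimeric}, \code{linked_element}
#'   (family of the nearest linked repeat or NA),
#'   \code{linked_element_row}.
#' @export
collect_junctions <- function(alignments, repeats = NULL, link_window = 1000,
                              allowed_families = c("LTR12*", "ERV9*")) {
  a <- alignments[!is.na(alignments$start2), , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      support = integer(0), chimeric = logical(0),
                      linked_element = character(0),
                      linked_element_row = integer(0),
                      stringsAsFactors = FALSE))
  donor <- a$end1 + 1L
  acceptor <- a$start2 - 1L
  strand <- ifelse(a$motif_strand %in% c("+", "-"), a$motif_strand, a$strand)
  key <- paste(a$chrom, donor, acceptor, strand, sep = ":")
  agg <- tapply(seq_len(nrow(a)), key, identity)
  first <- vapply(agg, `[`, integer(1), 1)
  out <- data.frame(chrom = a$chrom[first], donor = donor[first],
                    acceptor = acceptor[first], strand = strand[first],
                    support = lengths(agg), stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$chrom, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out$chimeric <- FALSE
  out$linked_element <- NA_character_
  out$linked_element_row <- NA_integer_
  if (!is.null(repeats) && length(repeats) > 0) {
    allowed_rows <- which(match_family(repeats$family, allowed_families))
    allowed <- repeats[allowed_rows]
    if (length(allowed) > 0) {
      ends <- GenomicRanges::GRanges(
        rep(out$chrom, 2),
        IRanges::IRanges(c(out$donor, out$acceptor), width = 1L))
      nh <- GenomicRanges::distanceToNearest(ends, allowed,
                                             ignore.strand = TRUE)
      d <- rep(NA_integer_, length(ends))
      ei <- rep(NA_integer_, length(ends))
      d[S4Vectors::queryHits(nh)] <- S4Vectors::mcols(nh)$distance
      ei[S4Vectors::queryHits(nh)] <- S4Vectors::subjectHits(nh)
      n <- nrow(out)
      dd <- pmin(d[seq_len(n)], d[n + seq_len(n)], na.rm = TRUE)
      pick <- ifelse(!is.na(d[seq_len(n)]) &
                       (is.na(d[n + seq_len(n)]) |
                          d[seq_len(n)] <= d[n + seq_len(n)]),
                     ei[seq_len(n)], ei[n + seq_len(n)])
      hit <- !is.na(dd) & dd <= link_window
      out$chimeric <- hit
      out$linked_element[hit] <- allowed$family[pick[hit]]
      out$linked_element_row[hit] <- allowed_rows[pick[hit]]
    }
  }
  out
}
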