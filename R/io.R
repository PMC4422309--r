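# Readers and writers for the external formats the pipeline touches.
#
# Internal convention: all intervals are 1-based closed (GRanges/IRanges).
# BED and BedGraph are 0-based half-open on disk, RepeatMasker .out is
# 1-based inclusive, SAM is 1-based: every function here converts at the
# boundary so no other module ever handles an off-by-one.

#' Read a FASTA file as a genome or a consensus set
#'
#' Sequences are folded to upper case and IUPAC ambiguity codes other than
#' \code{N} are collapsed to \code{N}. Record names must be unique.
#'
#' @param path Path to a FASTA file.
#' @param as Either \code{"genome"} (chromosomes) or \code{"consensus"}
#'   (named repeat consensus sequences, e.g. LTR U3 consensuses).
#' @param joint_name Name of the joint (merged-family) consensus entry, if
#'   any. With \code{NULL} an entry literally named \code{"joint"} is
#'   auto-detected.
#' @return A named character vector of class \code{"genome"} or
#'   \code{"consensus_set"}; a consensus set carries the joint entry name in
#'   \code{attr(, "joint_name")}.
#' @export
read_fasta <- function(path, as = c("genome", "consensus"), joint_name = NULL) {
  as <- match.arg(as)
  assert_that(file.exists(path), sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  assert_that(length(seqs) > 0, sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  assert_that(length(dup) == 0,
              sprintf("duplicate FASTA record name(s): %s",
                      paste(unique(dup), collapse = ", ")))
  x <- sanitize_seq(as.character(seqs))
  names(x) <- nm
  if (as == "genome") return(structure(x, class = "genome"))
  assert_that(all(nchar(x) > 0), "consensus sequences must be non-empty")
  if (is.null(joint_name) && any(tolower(nm) == "joint"))
    joint_name <- nm[tolower(nm) == "joint"][1]
  structure(x, class = "consensus_set", joint_name = joint_name)
}

#' Write named sequences to FASTA
#' @param x Named character vector (genome or consensus set).
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# name-prefix rules mapping a repeat family name to a repeat class
repeat_class_of <- function(family) {
  cls <- rep("other", length(family))
  cls[grepl("^(LTR12|ERV)", family)] <- "LTR"
  cls[grepl("^(THE1|MST|MLT)", family)] <- "MaLR"
  cls[grepl("^(Alu|ALU|MIR)", family)] <- "SINE"
  cls[grepl("^(L1|L2)", family)] <- "LINE"
  cls
}

#' Read repeat annotations (RepeatMasker .out or BED6)
#'
#' RepeatMasker coordinates (1-based inclusive) map directly onto the
#' internal 1-based convention; orientation \code{"C"} becomes \code{"-"}.
#' The repeat class is derived from the family name by prefix rules
#' (LTR12*/ERV* are LTR, THE1*/MST*/MLT* are MaLR, Alu*/MIR* are SINE,
#' L1/L2 are LINE, anything else "other").
#'
#' @param path Annotation file.
#' @param dialect \code{"rm_out"} for RepeatMasker .out, \code{"bed"} for
#'   BED6 with the family name in column 4 and a confidence score in column 5.
#' @return A \code{GRanges} with metadata columns \code{family},
#'   \code{repclass} and \code{confidence}. An empty file yields an empty
#'   \code{GRanges} with a warning.
#' @export
read_repeatmasker <- function(path, dialect = c("rm_out", "bed")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("repeat file not found: %s", path))
  lines <- readLines(path)
  if (dialect == "rm_out") {
    # skip the standard header (two column-name lines + blank)
    body <- grep("^\\s*\\d", lines, value = FALSE)
    if (length(body) == 0) {
      warning("no repeat records in ", path)
      return(empty_repeats())
    }
    recs <- lapply(body, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 11 || is.na(suppressWarnings(as.integer(f[6]))) ||
          is.na(suppressWarnings(as.integer(f[7]))))
        stop(sprintf("malformed RepeatMasker line %d in %s", i, path),
             call. = FALSE)
      data.frame(score = as.numeric(f[1]), chrom = f[5],
                 start = as.integer(f[6]), end = as.integer(f[7]),
                 strand = if (f[9] == "C") "-" else "+",
                 family = f[10], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
  } else {
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0) {
      warning("no repeat records in ", path)
      return(empty_repeats())
    }
    fl <- strsplit(lines, "\t")
    bad <- which(vapply(fl, length, integer(1)) < 6)
    if (length(bad) > 0)
      stop(sprintf("malformed BED line %d in %s", bad[1], path), call. = FALSE)
    df <- data.frame(chrom = vapply(fl, `[`, "", 1),
                     start = as.integer(vapply(fl, `[`, "", 2)) + 1L,
                     end = as.integer(vapply(fl, `[`, "", 3)),
                     family = vapply(fl, `[`, "", 4),
                     score = as.numeric(vapply(fl, `[`, "", 5)),
                     strand = vapply(fl, `[`, "", 6),
                     stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end))
      stop(sprintf("malformed BED coordinates in %s", path), call. = FALSE)
  }
  assert_that(all(df$start <= df$end), "repeat with start > end")
  assert_that(all(df$strand %in% c("+", "-")), "invalid repeat strand")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$family <- df$family
  gr$repclass <- repeat_class_of(df$family)
  gr$confidence <- df$score
  sort(gr, ignore.strand = TRUE)
}

empty_repeats <- function() {
  gr <- GenomicRanges::GRanges()
  gr$family <- character(0)
  gr$repclass <- character(0)
  gr$confidence <- numeric(0)
  gr
}

#' Write repeat annotations as BED6
#' @param repeats `GRanges` with `family` and `confidence` metadata columns.
#' @param path Output BED file.
#' @export
write_repeats_bed <- function(repeats, path) {
  out <- repeats
  out$name <- out$family
  out$score <- round(out$confidence)
  out$family <- NULL; out$repclass <- NULL; out$confidence <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write a depth track to BedGraph
#'
#' Zero-depth runs are omitted; depths must be non-negative integers.
#' Coordinates are converted to the on-disk 0-based half-open convention.
#'
#' @param track Either an \code{RleList} of per-chromosome integer depths or
#'   a sorted non-overlapping \code{GRanges} with a \code{score} column.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  if (methods::is(track, "RleList")) {
    gr <- methods::as(track, "GRanges")
  } else if (methods::is(track, "GRanges")) {
    gr <- track
    if (length(gr) > 1) {
      so <- GenomicRanges::sort(gr, ignore.strand = TRUE)
      ov <- GenomicRanges::findOverlaps(so, drop.self = TRUE,
                                        drop.redundant = TRUE)
      assert_that(length(ov) == 0, "overlapping intervals in BedGraph track")
    }
  } else stop("track must be an RleList or GRanges", call. = FALSE)
  assert_that(all(gr$score >= 0), "negative depth in BedGraph track")
  assert_that(all(gr$score == round(gr$score)), "non-integer depth")
  gr <- gr[gr$score != 0]
  GenomicRanges::strand(gr) <- "*"
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BedGraph into per-chromosome depth vectors
#' @param path BedGraph file.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return An integer \code{RleList}, zero outside the recorded runs.
#' @export
read_bedgraph <- function(path, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  cov <- GenomicRanges::coverage(gr, weight = "score")
  IRanges::RleList(lapply(as.list(cov), function(x) {
    v <- S4Vectors::runValue(x)
    S4Vectors::runValue(x) <- as.integer(v)
    x
  }), compress = FALSE)
}

#' Read a pair of FASTQ files as mated reads
#'
#' Records are paired by order; \code{/1} and \code{/2} id suffixes are
#' stripped. A length mismatch between the two files, or ids that disagree
#' after stripping, is a hard error naming the offending record.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return A \code{"read_pairs"} object: list with character vectors
#'   \code{id}, \code{seq1}, \code{qual1}, \code{seq2}, \code{qual2}.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    s <- Biostrings::readBStringSet(p, format = "fastq", with.qualities = TRUE)
    list(id = unname(sub("/[12]$", "", sub("\\s.*$", "", names(s)))),
         seq = unname(sanitize_seq(as.character(s))),
         qual = unname(as.character(S4Vectors::mcols(s)$qualities)))
  }
  a <- rd(path1); b <- rd(path2)
  if (length(a$id) != length(b$id))
    stop(sprintf("FASTQ files differ in length: record %d missing in %s",
                 min(length(a$id), length(b$id)) + 1L,
                 if (length(a$id) > length(b$id)) path2 else path1),
         call. = FALSE)
  bad <- which(a$id != b$id)
  if (length(bad) > 0)
    stop(sprintf("mate id mismatch at record %d: '%s' vs '%s'",
                 bad[1], a$id[bad[1]], b$id[bad[1]]), call. = FALSE)
  assert_that(all(nchar(a$seq) == nchar(a$qual)) &&
                all(nchar(b$seq) == nchar(b$qual)),
              "sequence/quality length mismatch")
  structure(list(id = a$id, seq1 = a$seq, qual1 = a$qual,
                 seq2 = b$seq, qual2 = b$qual),
            class = "read_pairs")
}

#' Number of read pairs
#' @param x A \code{"read_pairs"} object.
#' @export
n_pairs <- function(x) length(x$id)

#' Write genomic alignments as minimal SAM
#'
#' Emits \code{@HD}, one \code{@SQ} per chromosome and one record per
#' alignment. Split (two-block) alignments are encoded with \code{N} in the
#' CIGAR; minus-strand records set FLAG 16 and store the reverse-complemented
#' sequence, as SAM requires.
#'
#' @param alignments Alignment table from \code{\link{map_genomic}}.
#' @param reads Named character vector of read sequences (names = read ids);
#'   optional, \code{*} is written when a sequence is unavailable.
#' @param genome A \code{"genome"} object naming the reference chromosomes.
#' @param path Output SAM file.
#' @export
write_sam <- function(alignments, genome, path, reads = NULL) {
  bad <- setdiff(unique(alignments$chrom), names(genome))
  assert_that(length(bad) == 0,
              sprintf("alignment chromosome(s) not in genome: %s",
                      paste(bad, collapse = ", ")))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  if (nrow(alignments) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  split <- !is.na(alignments$start2)
  len1 <- alignments$end1 - alignments$start1 + 1L
  cigar <- ifelse(split,
                  sprintf("%dM%dN%dM", len1,
                          alignments$start2 - alignments$end1 - 1L,
                          alignments$end2 - alignments$start2 + 1L),
                  sprintf("%dM", len1))
  seq <- rep("*", nrow(alignments))
  if (!is.null(reads)) {
    hit <- alignments$read_id %in% names(reads)
    seq[hit] <- unname(reads[alignments$read_id[hit]])
    minus <- hit & alignments$strand == "-"
    seq[minus] <- revcomp_chr(seq[minus])
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  mapq <- ifelse(alignments$unique, 60L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                 alignments$read_id, flag, alignments$chrom,
                 alignments$start1, mapq, cigar, seq,
                 alignments$mismatches)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file as an alignment table (external-alignment bypass)
#'
#' Accepts alignments produced by an external splice-aware mapper in place
#' of \code{\link{map_genomic}} output. Only \code{M}/\code{=}/\code{X} and
#' single-\code{N} CIGARs are representable; records with other operations
#' or more than one junction are skipped with a warning. Uniqueness is taken
#' from the mapping quality.
#'
#' @param path SAM file.
#' @param mapq_unique Mapping-quality threshold at or above which an
#'   alignment counts as unique (default 30).
#' @return Alignment table in \code{\link{map_genomic}} format.
#' @export
read_sam <- function(path, mapq_unique = 30) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(empty_alignments())
  f <- strsplit(lines, "\t")
  skipped <- 0L
  rows <- vector("list", length(f))
  for (i in seq_along(f)) {
    x <- f[[i]]
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0) next  # unmapped
    ops <- regmatches(x[6], gregexpr("\\d+[MIDNSHP=X]", x[6]))[[1]]
    opc <- substring(ops, nchar(ops))
    opl <- as.integer(substring(ops, 1, nchar(ops) - 1))
    keep <- opc %in% c("M", "=", "X", "N")
    if (!all(keep) || sum(opc == "N") > 1) { skipped <- skipped + 1L; next }
    pos <- as.integer(x[4])
    if (any(opc == "N")) {
      ni <- which(opc == "N")
      l1 <- sum(opl[seq_len(ni - 1)]); gl <- opl[ni]
      l2 <- sum(opl[seq(ni + 1, length(opl))])
      rows[[i]] <- data.frame(read_id = x[1], mate = 1L, chrom = x[3],
                              strand = if (bitwAnd(flag, 16L)) "-" else "+",
                              start1 = pos, end1 = pos + l1 - 1L,
                              start2 = pos + l1 + gl,
                              end2 = pos + l1 + gl + l2 - 1L,
                              mismatches = NA_integer_,
                              unique = as.integer(x[5]) >= mapq_unique,
                              motif_strand = ".", stringsAsFactors = FALSE)
    } else {
      l <- sum(opl)
      rows[[i]] <- data.frame(read_id = x[1], mate = 1L, chrom = x[3],
                              strand = if (bitwAnd(flag, 16L)) "-" else "+",
                              start1 = pos, end1 = pos + l - 1L,
                              start2 = NA_integer_, end2 = NA_integer_,
                              mismatches = NA_integer_,
                              unique = as.integer(x[5]) >= mapq_unique,
                              motif_strand = ".", stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " SAM record(s) with unrepresentable CIGARs skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_alignments())
  out <- do.call(rbind, rows)
  out$aligned_len <- (out$end1 - out$start1 + 1L) +
    ifelse(is.na(out$start2), 0L, out$end2 - out$start2 + 1L)
  out
}

#' Read gene models from a GTF-lite file
#'
#' Only \code{gene} and \code{exon} features are retained; from the
#' attribute column only \code{gene_id} is parsed.
#'
#' @param path GTF file.
#' @return \code{GRanges} with \code{feature} and \code{gene_id} columns.
#' @export
read_gtf_lite <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("seqname", "source", "feature",
                                        "start", "end", "score", "strand",
                                        "frame", "attributes"))
  df <- df[df$feature %in% c("gene", "exon"), , drop = FALSE]
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df$attributes)
  gr <- GenomicRanges::GRanges(df$seqname, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$feature <- df$feature
  gr$gene_id <- gid
  gr
}
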