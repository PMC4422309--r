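# Chromatin-context classification from histone-mark peaks and
# promoter-state segments, CAGE TSS evidence, and cross-sample comparison.

#' Classify chromatin state of positions or elements
#'
#' The standard two-mark logic: a target overlapping H3K4me3 (within
#' \code{flank}) is a promoter (with or without H3K27ac); H3K27ac with
#' H3K4me3 depletion is an enhancer; neither mark is "none". Peak signal
#' magnitude is ignored for classification and only carried for reporting.
#'
#' @param targets \code{GRanges} of chimeric positions or repeat elements.
#' @param k4_peaks,k27_peaks H3K4me3 / H3K27ac peak \code{GRanges}.
#' @param promoter_segments Optional promoter-state segment \code{GRanges}
#'   (e.g. HMM chromatin-state output consumed as-is).
#' @param flank Overlap flank around each target, bp.
#' @return \code{targets} with added columns \code{h3k4me3},
#'   \code{h3k27ac}, \code{in_promoter_segment}, \code{state}.
#' @export
classify_state <- function(targets, k4_peaks, k27_peaks,
                           promoter_segments = NULL, flank = 1000) {
  if (length(targets) == 0) {
    targets$h3k4me3 <- logical(0)
    targets$h3k27ac <- logical(0)
    targets$in_promoter_segment <- logical(0)
    targets$state <- character(0)
    return(targets)
  }
  ext <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(GenomicRanges::granges(targets),
                          GenomicRanges::width(targets) + 2L * flank,
                          fix = "center")))
  hit <- function(track) {
    if (is.null(track) || length(track) == 0) return(rep(FALSE,
                                                         length(targets)))
    GenomicRanges::countOverlaps(ext, track, ignore.strand = TRUE) > 0
  }
  targets$h3k4me3 <- hit(k4_peaks)
  targets$h3k27ac <- hit(k27_peaks)
  targets$in_promoter_segment <- hit(promoter_segments)
  targets$state <- ifelse(targets$h3k4me3, "promoter",
                          ifelse(targets$h3k27ac, "enhancer", "none"))
  targets
}

#' Attach CAGE TSS evidence
#'
#' Counts CAGE clusters per strand within \code{window} of each target and
#' flags element-scale bidirectionality (clusters on both strands).
#'
#' @param calls \code{GRanges}, typically output of
#'   \code{\link{classify_state}}.
#' @param cage_clusters Stranded CAGE cluster \code{GRanges}.
#' @param window Distance window, bp.
#' @return \code{calls} with added \code{tss_plus}, \code{tss_minus},
#'   \code{bidirectional_tss}.
#' @export
attach_tss <- function(calls, cage_clusters, window = 1000) {
  if (length(calls) == 0) {
    calls$tss_plus <- integer(0)
    calls$tss_minus <- integer(0)
    calls$bidirectional_tss <- logical(0)
    return(calls)
  }
  count_strand <- function(s) {
    if (is.null(cage_clusters) || length(cage_clusters) == 0)
      return(rep(0L, length(calls)))
    cc <- cage_clusters[as.character(GenomicRanges::strand(cage_clusters))
                        == s]
    GenomicRanges::countOverlaps(calls, cc, maxgap = window,
                                 ignore.strand = TRUE)
  }
  calls$tss_plus <- count_strand("+")
  calls$tss_minus <- count_strand("-")
  calls$bidirectional_tss <- calls$tss_plus >= 1L & calls$tss_minus >= 1L
  calls
}

#' Compare chimeric positions across samples
#'
#' Positions from all samples are pooled and gap-merged into cross-sample
#' keys (same merge semantics as calling); each key records which samples
#' contribute at least one position and, when only one does, which sample
#' the key is exclusive to.
#'
#' @param position_sets Named list (length >= 2) of position \code{GRanges}.
#' @param merge_gap Key-building merge distance, bp.
#' @return data.frame with \code{key} (chrom:start-end), \code{chrom},
#'   \code{start}, \code{end}, \code{present_in} (comma-separated),
#'   \code{n_samples}, \code{exclusive_to} (NA unless exactly one sample).
#' @export
compare_samples <- function(position_sets, merge_gap = 2000) {
  assert_that(is.list(position_sets) && length(position_sets) >= 2,
              "compare_samples needs at least 2 samples")
  assert_that(!is.null(names(position_sets)) &&
                all(nzchar(names(position_sets))),
              "position sets must be named by sample")
  pool <- do.call(c, lapply(unname(position_sets), GenomicRanges::granges))
  if (length(pool) == 0)
    return(data.frame(key = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      present_in = character(0), n_samples = integer(0),
                      exclusive_to = character(0), stringsAsFactors = FALSE))
  keys <- GenomicRanges::reduce(sort(pool), min.gapwidth = merge_gap + 1L,
                                ignore.strand = TRUE)
  present <- matrix(FALSE, nrow = length(keys), ncol = length(position_sets),
                    dimnames = list(NULL, names(position_sets)))
  for (s in names(position_sets)) {
    ps <- position_sets[[s]]
    if (length(ps) == 0) next
    ov <- GenomicRanges::findOverlaps(keys, ps, ignore.strand = TRUE)
    present[unique(S4Vectors::queryHits(ov)), s] <- TRUE
  }
  pres_str <- apply(present, 1, function(x)
    paste(sort(colnames(present)[x]), collapse = ","))
  n_samp <- rowSums(present)
  excl <- ifelse(n_samp == 1, pres_str, NA_character_)
  data.frame(key = sprintf("%s:%d-%d",
                           as.character(GenomicRanges::seqnames(keys)),
                           GenomicRanges::start(keys),
                           GenomicRanges::end(keys)),
             chrom = as.character(GenomicRanges::seqnames(keys)),
             start = GenomicRanges::start(keys),
             end = GenomicRanges::end(keys),
             present_in = pres_str, n_samples = as.integer(n_samp),
             exclusive_to = excl, stringsAsFactors = FALSE)
}
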