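# Scale factors, the depth-vs-positions correlation, and planted-truth
# recovery metrics.

#' Relative sequencing depth (scale factor) per library
#'
#' Geometric-mean normalization: \code{SF_i = n_i / gm(n)}. This is a
#' documented stand-in for pipeline-internal depth normalization; when
#' externally computed scale factors are available they are consumed as
#' data instead.
#'
#' @param counts Named numeric vector of mapped-read counts per library.
#' @return Named numeric vector of scale factors.
#' @export
compute_scale_factor <- function(counts) {
  assert_that(length(counts) >= 1 && all(counts > 0),
              "all libraries need a positive mapped-read count")
  counts / exp(mean(log(counts)))
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' \code{r = sum(dx dy) / sqrt(sum(dx^2) sum(dy^2))}, with
#' \code{t = r sqrt((n-2)/(1-r^2))} referred to a t distribution on
#' \code{n - 2} degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List of class \code{"correlation_result"}: \code{r}, \code{n},
#'   \code{t_stat}, \code{p_value}.
#' @export
pearson_with_p <- function(x, y) {
  assert_that(length(x) == length(y), "x and y differ in length")
  n <- length(x)
  assert_that(n >= 3, "need at least 3 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx^2); vy <- sum(dy^2)
  assert_that(vx > 0 && vy > 0, "zero variance in x or y")
  r <- sum(dx * dy) / sqrt(vx * vy)
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, n = n, t_stat = t_stat, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d, t = %.3f, p = %.3g)\n",
              x$r, x$n, x$t_stat, x$p_value))
  invisible(x)
}

#' Per-library scale factors and chimeric-position counts for eleven ENCODE
#' CSHL long non-polyA stranded libraries
#'
#' A small packaged table of relative sequencing depth (scale factor, SF)
#' and the number of chimeric positions mapped per library, used as the
#' regression fixture for the depth-vs-positions correlation.
#'
#' @return data.frame with \code{sample}, \code{positions},
#'   \code{scale_factor}.
#' @export
encode_library_stats <- function() {
  read_tsv(system.file("extdata", "encode_cshl_libraries.tsv",
                       package = "ervchimera", mustWork = TRUE))
}

#' Recovery of planted truth by called positions
#'
#' A truth element matches when some called position lies within
#' \code{match_window} of it (one truth element may absorb several calls; a
#' call may match several elements but is counted once). Sensitivity is the
#' fraction of transcriptionally active truth elements matched; precision
#' is the fraction of calls matched to any planted truth element — under
#' the simulator's uniform background model, consensus-matching repeat
#' copies without a planted transcript still attract genuine read signal,
#' so a call at any planted element reflects the input data rather than a
#' caller artifact (see the methods vignette).
#'
#' @param positions Called chimeric positions (\code{GRanges}).
#' @param truth A \code{"truth_set"} or its \code{elements} \code{GRanges}
#'   (needs \code{active} and \code{element_id} columns).
#' @param match_window Matching distance, bp.
#' @return List of class \code{"recovery_metrics"}: \code{sensitivity},
#'   \code{precision}, \code{precision_defined} (FALSE when there are no
#'   calls), \code{matched} (call/element index pairs), plus counts.
#' @export
recovery_metrics <- function(positions, truth, match_window = 1000) {
  el <- if (inherits(truth, "truth_set")) truth$elements else truth
  assert_that(length(el) > 0, "empty truth")
  active <- which(el$active)
  if (length(positions) == 0) {
    return(structure(list(sensitivity = 0, precision = 0,
                          precision_defined = FALSE,
                          matched = data.frame(call = integer(0),
                                               element = integer(0)),
                          n_calls = 0L, n_active_truth = length(active),
                          n_truth_matched = 0L),
                     class = "recovery_metrics"))
  }
  ov <- GenomicRanges::findOverlaps(positions, el, maxgap = match_window,
                                    ignore.strand = TRUE)
  matched <- data.frame(call = S4Vectors::queryHits(ov),
                        element = S4Vectors::subjectHits(ov))
  matched_truth <- unique(matched$element)
  matched_calls <- unique(matched$call)
  sens <- if (length(active) == 0) NA_real_ else
    length(intersect(matched_truth, active)) / length(active)
  prec <- length(matched_calls) / length(positions)
  structure(list(sensitivity = sens, precision = prec,
                 precision_defined = TRUE, matched = matched,
                 n_calls = length(positions),
                 n_active_truth = length(active),
                 n_truth_matched = length(intersect(matched_truth, active))),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "Recovery vs planted truth: sensitivity %.3f (%d/%d active), precision %.3f (%d calls)%s\n",
    x$sensitivity, x$n_truth_matched, x$n_active_truth, x$precision,
    x$n_calls, if (x$precision_defined) "" else " [no calls]"))
  invisible(x)
}
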