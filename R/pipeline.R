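# End-to-end orchestration: simulate -> align -> call -> coverage -> loci ->
# integrate -> stats, every stage communicating through plain-text files in
# the run directory so any stage can be resumed from prior outputs.

.pipeline_stages <- c("simulate", "align", "call", "coverage", "loci",
                      "integrate", "stats")

#' Default run configuration
#'
#' Nested sections mirror the per-module parameter objects; every field has
#' a default. \code{seed} drives all randomness of a run.
#'
#' @return Nested list of class \code{"run_config"}.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    sample_id = "sim",
    simulation = unclass(simulation_config())[
      setdiff(names(simulation_config()), "seed")],
    alignment = unclass(align_params()),
    calling = unclass(chimera_params()),
    coverage = list(min_cov = 2L, max_gap = 10000L, min_width = 200L,
                    orientation = "forward-antisense", mate = 1L),
    loci = list(join_gap = 50000L),
    junctions = list(link_window = 1000L),
    integration = list(flank = 1000L, tss_window = 1000L)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a (possibly partial) nested list; unknown
#' keys, type mismatches and constraint violations are all collected and
#' reported together rather than at first failure.
#'
#' @param x Path to a YAML config file, a list, or NULL (pure defaults).
#' @return A completed \code{"run_config"}; errors with the full problem
#'   list otherwise.
#' @export
validate_config <- function(x = NULL) {
  if (is.character(x)) {
    assert_that(file.exists(x), sprintf("config file not found: %s", x))
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  x <- x %||% list()
  assert_that(is.list(x), "config must be a list or YAML file")
  def <- default_run_config()
  errors <- character(0)
  merged <- unclass(def)

  unknown_top <- setdiff(names(x), names(def))
  if (length(unknown_top) > 0)
    errors <- c(errors, sprintf("unknown config section/key: %s",
                                paste(unknown_top, collapse = ", ")))
  for (k in intersect(names(x), names(def))) {
    if (is.list(def[[k]])) {
      if (!is.list(x[[k]])) {
        errors <- c(errors, sprintf("section %s must be a mapping", k))
        next
      }
      unk <- setdiff(names(x[[k]]), names(def[[k]]))
      if (length(unk) > 0)
        errors <- c(errors, sprintf("unknown key(s) in %s: %s", k,
                                    paste(unk, collapse = ", ")))
      for (kk in intersect(names(x[[k]]), names(def[[k]]))) {
        want_num <- is.numeric(def[[k]][[kk]])
        if (want_num && !is.numeric(x[[k]][[kk]])) {
          errors <- c(errors, sprintf("%s.%s must be numeric", k, kk))
        } else merged[[k]][[kk]] <- x[[k]][[kk]]
      }
    } else {
      merged[[k]] <- x[[k]]
    }
  }
  # constraint checks via the module constructors
  ctor <- function(expr, label) {
    tryCatch({ expr(); NULL },
             error = function(e) sprintf("%s: %s", label, conditionMessage(e)))
  }
  errors <- c(errors, unlist(list(
    ctor(function() do.call(simulation_config,
                            c(merged$simulation, list(seed = merged$seed))),
         "simulation"),
    ctor(function() do.call(align_params, merged$alignment), "alignment"),
    ctor(function() do.call(chimera_params, merged$calling), "calling"))))
  if (any(c(merged$coverage$min_cov, merged$coverage$max_gap,
            merged$loci$join_gap, merged$junctions$link_window,
            merged$integration$flank) < 0))
    errors <- c(errors, "coverage/loci/integration thresholds must be >= 0")
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(merged, class = "run_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

write_stage_counts <- function(dir, counts) {
  jsonlite::write_json(counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' Executes all stages in order under \code{outdir}; every stage reads its
#' inputs from the files earlier stages wrote, so a run can resume from any
#' stage whose predecessors' outputs still exist. A manifest (config
#' snapshot, package version, per-stage record counts, md5 digest per
#' output file) is written at the end; reruns with the same seed produce
#' byte-identical manifests.
#'
#' @param config A \code{"run_config"} (see \code{\link{validate_config}}).
#' @param outdir Run directory (created if needed).
#' @param resume_from Stage name to restart from (earlier stages are not
#'   rerun); default runs everything.
#' @return (Invisibly) the manifest list.
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         resume_from = NULL) {
  config <- validate_config(unclass(config))
  stages <- .pipeline_stages
  from <- if (is.null(resume_from)) 1L else match(resume_from, stages)
  assert_that(!is.na(from), sprintf("unknown stage: %s",
                                    resume_from %||% ""))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (st in stages[from:length(stages)]) {
    t0 <- Sys.time()
    ok <- tryCatch({
      switch(st,
             simulate = stage_simulate(config, outdir),
             align = stage_align(config, outdir),
             call = stage_call(config, outdir),
             coverage = stage_coverage(config, outdir),
             loci = stage_loci(config, outdir),
             integrate = stage_integrate(config, outdir),
             stats = stage_stats(config, outdir))
      TRUE
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", st,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_msg(st, sprintf("done in %.1fs",
                          as.numeric(Sys.time() - t0, units = "secs")))
  }
  manifest <- build_manifest(config, outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config, outdir) {
  d <- file.path(outdir, "sim")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(simulation_config,
                 c(config$simulation, list(seed = config$seed)))
  assert_that(cfg$n_read_pairs > 0, "n_read_pairs must be positive")
  g <- simulate_genome(cfg)
  tx <- simulate_transcriptome(g$genome, g$repeats, cfg)
  rd <- simulate_reads(tx$truth, tx$genome, cfg, dir = d)
  simulate_regulatory_tracks(tx$truth, cfg, dir = file.path(d, "tracks"))
  write_fasta(tx$genome, file.path(d, "genome.fa"))
  write_fasta(g$consensus, file.path(d, "consensus.fa"))
  write_repeats_bed(g$repeats, file.path(d, "repeats.bed"))
  write_truth(tx$truth, d)
  write_stage_counts(d, list(
    pairs_in = n_pairs(rd$reads),
    elements_planted = length(g$repeats),
    elements_active = sum(tx$truth$elements$active),
    transcripts = nrow(tx$truth$transcripts),
    junctions_planted = nrow(tx$truth$junctions)))
  invisible(TRUE)
}

stage_align <- function(config, outdir) {
  d <- file.path(outdir, "align")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  sd <- file.path(outdir, "sim")
  genome <- read_fasta(file.path(sd, "genome.fa"), as = "genome")
  cons <- read_fasta(file.path(sd, "consensus.fa"), as = "consensus")
  reads <- read_fastq_pair(file.path(sd, "reads_1.fastq"),
                           file.path(sd, "reads_2.fastq"))
  ap <- do.call(align_params, config$alignment)

  hits <- scan_consensus(reads, cons, ap)
  write_tsv(hits, file.path(d, "consensus_hits.tsv"))
  disc <- select_discordant(reads, hits)
  write_tsv(disc[, c("read_id", "anchored_mate", "free_mate",
                     "anchor_families")],
            file.path(d, "discordant.tsv"))

  free_al <- do.call(rbind, lapply(c(1L, 2L), function(m) {
    sel <- disc$free_mate == m
    if (!any(sel)) return(empty_alignments())
    map_genomic(stats::setNames(disc$free_seq[sel], disc$read_id[sel]),
                genome, ap, mate = m)
  }))
  write_tsv(free_al, file.path(d, "free_alignments.tsv"))
  free_seqs <- stats::setNames(disc$free_seq, disc$read_id)
  write_sam(free_al, genome, file.path(d, "free_alignments.sam"),
            reads = free_seqs)

  m1 <- map_genomic(stats::setNames(reads$seq1, reads$id), genome, ap,
                    mate = 1L)
  write_tsv(m1, file.path(d, "mate1_alignments.tsv"))
  write_stage_counts(d, list(
    pairs_in = n_pairs(reads),
    pairs_with_consensus_hit = length(unique(hits$read_id)),
    discordant_kept = nrow(disc),
    free_unique_alignments = sum(free_al$unique),
    mate1_unique_alignments = sum(m1$unique)))
  invisible(TRUE)
}

read_alignments_tsv <- function(path) {
  a <- read_tsv(path, colClasses = c(read_id = "character"))
  if (nrow(a) == 0) return(empty_alignments())
  a$unique <- as.logical(a$unique)
  a
}

stage_call <- function(config, outdir) {
  d <- file.path(outdir, "call")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  al <- read_alignments_tsv(file.path(outdir, "align",
                                      "free_alignments.tsv"))
  repeats <- read_repeatmasker(file.path(outdir, "sim", "repeats.bed"),
                               dialect = "bed")
  cp <- do.call(chimera_params, config$calling)
  uniq <- al[al$unique, , drop = FALSE]
  clusters <- merge_alignments(uniq, cp$merge_gap)
  pos <- call_positions(clusters, uniq, repeats, cp,
                        sample_id = config$sample_id)
  write_positions(pos, file.path(d, "positions.bed"),
                  tsv = file.path(d, "positions.tsv"))
  jsonlite::write_json(attr(pos, "report"), file.path(d, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stage_counts(d, list(clusters = length(clusters),
                             positions = length(pos)))
  invisible(TRUE)
}

stage_coverage <- function(config, outdir) {
  d <- file.path(outdir, "coverage")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(file.path(outdir, "sim", "genome.fa"), as = "genome")
  m1 <- read_alignments_tsv(file.path(outdir, "align",
                                      "mate1_alignments.tsv"))
  cov <- compute_coverage(m1, genome,
                          orientation = config$coverage$orientation,
                          mate = config$coverage$mate)
  write_stranded_coverage(cov, file.path(d, "coverage"))
  patches <- call_patches(cov, min_cov = config$coverage$min_cov,
                          max_gap = config$coverage$max_gap,
                          min_width = config$coverage$min_width)
  write_tsv(data.frame(
    chrom = as.character(GenomicRanges::seqnames(patches)),
    start = GenomicRanges::start(patches),
    end = GenomicRanges::end(patches),
    strand = as.character(GenomicRanges::strand(patches)),
    mean_depth = round(patches$mean_depth, 4),
    max_depth = patches$max_depth), file.path(d, "patches.tsv"))
  write_stage_counts(d, list(patches = length(patches),
                             total_depth = total_depth(cov)))
  invisible(TRUE)
}

read_patches_tsv <- function(path, seqlengths = NULL) {
  df <- read_tsv(path)
  si <- if (is.null(seqlengths)) NULL else
    GenomeInfoDb::Seqinfo(names(seqlengths), unname(seqlengths))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand, seqinfo = si)
  gr$mean_depth <- df$mean_depth
  gr$max_depth <- df$max_depth
  gr
}

stage_loci <- function(config, outdir) {
  d <- file.path(outdir, "loci")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  patches <- read_patches_tsv(file.path(outdir, "coverage", "patches.tsv"))
  pos <- df_to_positions(read_tsv(file.path(outdir, "call",
                                            "positions.tsv")))
  loci <- assemble_loci(patches, pos, join_gap = config$loci$join_gap)
  write_tsv(data.frame(
    chrom = if (length(loci)) as.character(GenomicRanges::seqnames(loci))
            else character(0),
    start = GenomicRanges::start(loci),
    end = GenomicRanges::end(loci),
    span_bp = loci$span_bp,
    bidirectional = loci$bidirectional,
    n_patches = loci$n_patches,
    linked_positions = vapply(as.list(loci$linked_positions), paste,
                              character(1), collapse = ",")),
    file.path(d, "loci.tsv"))

  repeats <- read_repeatmasker(file.path(outdir, "sim", "repeats.bed"),
                               dialect = "bed")
  al <- rbind(read_alignments_tsv(file.path(outdir, "align",
                                            "free_alignments.tsv")),
              read_alignments_tsv(file.path(outdir, "align",
                                            "mate1_alignments.tsv")))
  jn <- collect_junctions(al[al$unique, , drop = FALSE], repeats,
                          link_window = config$junctions$link_window,
                          allowed_families = config$calling$allowed_families)
  write_tsv(jn, file.path(d, "junctions.tsv"))
  write_stage_counts(d, list(loci = length(loci),
                             bidirectional_loci = sum(loci$bidirectional),
                             junctions = nrow(jn),
                             chimeric_junctions = sum(jn$chimeric)))
  invisible(TRUE)
}

stage_integrate <- function(config, outdir) {
  d <- file.path(outdir, "integrate")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  td <- file.path(outdir, "sim", "tracks")
  k4 <- rtracklayer::import(file.path(td, "h3k4me3.bed"), format = "BED")
  k27 <- rtracklayer::import(file.path(td, "h3k27ac.bed"), format = "BED")
  seg <- rtracklayer::import(file.path(td, "promoter_segments.bed"),
                             format = "BED")
  cage <- rtracklayer::import(file.path(td, "cage_clusters.bed"),
                              format = "BED")
  pos <- df_to_positions(read_tsv(file.path(outdir, "call",
                                            "positions.tsv")))
  truth <- read_truth(file.path(outdir, "sim"))

  annotate <- function(gr, label) {
    out <- classify_state(gr, k4, k27, seg, flank = config$integration$flank)
    out <- attach_tss(out, cage, window = config$integration$tss_window)
    df <- data.frame(target = label,
                     chrom = as.character(GenomicRanges::seqnames(out)),
                     start = GenomicRanges::start(out),
                     end = GenomicRanges::end(out),
                     state = out$state, h3k4me3 = out$h3k4me3,
                     h3k27ac = out$h3k27ac,
                     in_promoter_segment = out$in_promoter_segment,
                     tss_plus = out$tss_plus, tss_minus = out$tss_minus,
                     bidirectional_tss = out$bidirectional_tss,
                     stringsAsFactors = FALSE)
    df
  }
  res <- rbind(annotate(pos, "position"),
               annotate(truth$elements, "element"))
  write_tsv(res, file.path(d, "regulatory.tsv"))
  write_stage_counts(d, list(
    positions_annotated = length(pos),
    elements_annotated = length(truth$elements),
    promoter_calls = sum(res$state == "promoter")))
  invisible(TRUE)
}

stage_stats <- function(config, outdir) {
  d <- file.path(outdir, "stats")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  truth <- read_truth(file.path(outdir, "sim"))
  pos <- df_to_positions(read_tsv(file.path(outdir, "call",
                                            "positions.tsv")))
  rec <- recovery_metrics(pos, truth,
                          match_window = config$calling$repeat_link_window)
  jsonlite::write_json(list(sensitivity = rec$sensitivity,
                            precision = rec$precision,
                            precision_defined = rec$precision_defined,
                            n_calls = rec$n_calls,
                            n_active_truth = rec$n_active_truth,
                            n_truth_matched = rec$n_truth_matched),
                       file.path(d, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stage_counts(d, list(n_calls = rec$n_calls))
  invisible(TRUE)
}

build_manifest <- function(config, outdir) {
  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  dig <- as.list(tools::md5sum(file.path(outdir, files)))
  names(dig) <- files
  counts <- list()
  for (st in c("sim", "align", "call", "coverage", "loci", "integrate",
               "stats")) {
    cf <- file.path(outdir, st, "counts.json")
    if (file.exists(cf)) counts[[st]] <- jsonlite::read_json(cf)
  }
  # internal consistency of stage record counts
  if (!is.null(counts$align) && !is.null(counts$sim))
    assert_that(counts$align$discordant_kept <= counts$sim$pairs_in,
                "manifest inconsistency: discordant > pairs")
  if (!is.null(counts$call))
    assert_that(counts$call$positions <= counts$call$clusters,
                "manifest inconsistency: positions > clusters")
  list(tool = "ervchimera",
       version = as.character(utils::packageVersion("ervchimera")),
       config = unclass(config),
       counts = counts,
       files = dig)
}
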