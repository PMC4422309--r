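# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase and collapse non-ACGTN IUPAC codes to N
sanitize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# glob family patterns ("LTR12*") -> single regex
family_regex <- function(patterns) {
  paste(vapply(patterns, utils::glob2rx, character(1)), collapse = "|")
}

match_family <- function(families, patterns) {
  grepl(family_regex(patterns), families)
}

# Seqinfo for a genome object so GRanges built against it carry lengths
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = unname(nchar(genome)))
}

# stable numeric formatting for TSV round-trips
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  assert_that(file.exists(path), sprintf("missing input file: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", ...)
}
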