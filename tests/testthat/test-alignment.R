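test_that("consensus scan finds exact substrings on both strands", {
  cons <- structure(c(F = paste(rep("ACGTG", 20), collapse = "")),
                    class = "consensus_set")
  sub30 <- substr(unclass(cons)[1], 11, 40)
  rp <- structure(list(id = c("a", "b"),
                       seq1 = c(sub30, ervchimera:::revcomp_chr(sub30)),
                       qual1 = rep(strrep("I", 30), 2),
                       seq2 = rep(strrep("T", 30), 2),
                       qual2 = rep(strrep("I", 30), 2)),
                  class = "read_pairs")
  h <- scan_consensus(rp, cons, align_params())
  h1 <- h[h$read_id == "a" & h$mate == 1, ]
  expect_true(any(h1$offset == 11 & h1$strand == "+" & h1$mismatches == 0))
  h2 <- h[h$read_id == "b" & h$mate == 1, ]
  expect_true(any(h2$offset == 11 & h2$strand == "-" & h2$mismatches == 0))
})

test_that("consensus scan equals the brute-force oracle on random mates", {
  set.seed(11)
  cons_seq <- c(FAM1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                             collapse = ""),
                FAM2 = paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                             collapse = ""))
  cons <- structure(cons_seq, class = "consensus_set")
  p <- align_params()
  n <- 300
  reads <- character(n)
  for (i in seq_len(n)) {
    kind <- i %% 3
    if (kind == 0) {
      reads[i] <- paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                        collapse = "")
    } else {
      src <- cons_seq[[1 + (i %% 2)]]
      st <- sample(nchar(src) - 29, 1)
      s <- mutate_seq(substr(src, st, st + 29), sample(0:3, 1))
      if (kind == 2) s <- ervchimera:::revcomp_chr(s)
      reads[i] <- s
    }
  }
  rp <- structure(list(id = sprintf("r%03d", seq_len(n)), seq1 = reads,
                       qual1 = rep(strrep("I", 30), n),
                       seq2 = rep(strrep("N", 30), n),
                       qual2 = rep(strrep("I", 30), n)),
                  class = "read_pairs")
  got <- scan_consensus(rp, cons, p)
  got <- got[got$mate == 1, c("read_id", "family", "offset", "strand",
                              "mismatches")]
  want <- do.call(rbind, lapply(seq_len(n), function(i) {
    pl <- brute_force_align(reads[i], cons,
                            align_params(genomic_max_mismatches =
                                           p$consensus_max_mismatches),
                            mode = "contiguous")
    if (nrow(pl) == 0) return(NULL)
    data.frame(read_id = sprintf("r%03d", i), family = pl$chrom,
               offset = pl$start1, strand = pl$strand,
               mismatches = pl$mismatches, stringsAsFactors = FALSE)
  }))
  key <- function(d) sort(do.call(paste, c(d, sep = ":")))
  expect_identical(key(got), key(want))
})

test_that("pair filtering keeps exactly the single-anchored pairs", {
  rp <- structure(list(id = c("both", "m1only", "m2only", "none"),
                       seq1 = rep("A", 4), qual1 = rep("I", 4),
                       seq2 = rep("A", 4), qual2 = rep("I", 4)),
                  class = "read_pairs")
  hits <- data.frame(read_id = c("both", "both", "m1only", "m2only"),
                     mate = c(1L, 2L, 1L, 2L),
                     family = "F", offset = 1L, strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  d <- select_discordant(rp, hits)
  expect_setequal(d$read_id, c("m1only", "m2only"))
  expect_equal(d$free_mate[d$read_id == "m1only"], 2L)
  expect_equal(d$free_mate[d$read_id == "m2only"], 1L)
})

test_that("unique and repeated placements are flagged correctly", {
  gen <- random_genome(30000, seed = 3)
  p <- align_params()
  rd <- substr(gen[[1]], 10001, 10076)
  al <- map_genomic(c(u = rd), gen, p)
  expect_equal(nrow(al), 1)
  expect_equal(al$start1, 10001L)
  expect_true(is.na(al$start2))
  expect_equal(al$mismatches, 0L)
  expect_true(al$unique)

  # same 76-mer copied to a second locus: margin 0, not unique
  g2 <- gen
  substr(g2[[1]], 20001, 20076) <- rd
  al2 <- map_genomic(c(u = rd), g2, p)
  expect_equal(nrow(al2), 2)
  expect_false(any(al2$unique))
})

test_that("alignments never exceed their mismatch budget", {
  gen <- random_genome(20000, seed = 5)
  set.seed(6)
  reads <- vapply(1:100, function(i) {
    st <- sample(20000 - 76, 1)
    mutate_seq(substr(gen[[1]], st, st + 75), sample(0:4, 1))
  }, character(1))
  names(reads) <- sprintf("m%03d", 1:100)
  al <- map_genomic(reads, gen, align_params())
  expect_true(all(al$mismatches <= 2))
  expect_true(all(al$aligned_len <= 76))
})

test_that("uniqueness is symmetric under genome reverse-complement relabeling", {
  gen <- random_genome(20000, seed = 9)
  rcg <- structure(c(chr1 = ervchimera:::revcomp_chr(gen[[1]])),
                   class = "genome")
  set.seed(10)
  reads <- vapply(1:50, function(i) {
    st <- sample(20000 - 76, 1)
    mutate_seq(substr(gen[[1]], st, st + 75), sample(0:2, 1))
  }, character(1))
  names(reads) <- sprintf("s%02d", 1:50)
  a <- map_genomic(reads, gen, align_params())
  b <- map_genomic(reads, rcg, align_params())
  a <- a[order(a$read_id), ]; b <- b[order(b$read_id), ]
  expect_equal(a$read_id, b$read_id)
  expect_equal(a$mismatches, b$mismatches)
  expect_equal(a$unique, b$unique)
  # coordinates mirror: start' = L - end + 1
  expect_equal(b$start1, 20000L - a$end1 + 1L)
})

test_that("junction-spanning reads recover the exact planted junction", {
  gen <- random_genome(60000, seed = 21)
  g <- gen[[1]]
  set.seed(22)
  n_ok <- 0; n <- 60
  truth <- list()
  for (i in 1:n) {
    d_end <- sample(20000:30000, 1)       # last exonic base before intron
    gap <- sample(500:20000, 1)
    substr(g, d_end + 1, d_end + 2) <- "GT"
    substr(g, d_end + gap - 1, d_end + gap) <- "AG"
    truth[[i]] <- c(d_end, gap)
  }
  gen2 <- structure(c(chr1 = g), class = "genome")
  reads <- character(n)
  for (i in 1:n) {
    d_end <- truth[[i]][1]; gap <- truth[[i]][2]
    a <- sample(10:66, 1)                  # bases left of the junction
    reads[i] <- paste0(substr(g, d_end - a + 1, d_end),
                       substr(g, d_end + gap + 1, d_end + gap + 76 - a))
  }
  names(reads) <- sprintf("j%03d", 1:n)
  al <- map_genomic(reads, gen2, align_params())
  for (i in 1:n) {
    row <- al[al$read_id == names(reads)[i] & !is.na(al$start2), ]
    if (nrow(row) == 1 &&
        row$end1 == truth[[i]][1] &&
        row$start2 == truth[[i]][1] + truth[[i]][2] + 1)
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("short reads fall back to contiguous-only mapping", {
  gen <- random_genome(5000, seed = 30)
  rd <- substr(gen[[1]], 101, 112)  # 12 bp, < 2 * min_anchor would split
  al <- map_genomic(c(tiny = rd), gen, align_params(min_anchor = 8))
  expect_true(all(is.na(al$start2)))
})
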