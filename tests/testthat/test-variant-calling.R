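ref24 <- paste0("ATGGCTGAACTGTCTAAAGGTCCG", "GAAACCATTGTTCGTGCAGACTAA") # 16 codons
q40 <- function(n) strrep(rawToChar(as.raw(40 + 33)), n)
qvec <- function(q) paste(rawToChar(as.raw(q + 33)), collapse = "")

mutate_codon <- function(seq, pos, codon) {
  substr(seq, 3 * pos - 2, 3 * pos) <- codon
  seq
}

test_that("exact-anchor alignment finds unique offsets and rejects others", {
  cfg <- calling_config()
  expect_identical(align_read(ref24, ref24, cfg), 0L)
  # mutation at a downstream codon leaves the anchor intact
  rd <- mutate_codon(ref24, 10, "GGG")
  expect_identical(align_read(rd, ref24, cfg), 0L)
  # partial read starting mid-gene
  sub <- substr(ref24, 25, 48)
  expect_identical(align_read(sub, ref24, cfg), 24L)
  # anchor error: rejected, and a brute-force scan over all offsets agrees
  bad <- rd
  substr(bad, 3, 3) <- if (substr(bad, 3, 3) == "A") "C" else "A"
  off <- align_read(bad, ref24, cfg)
  expect_true(is.na(off))
  scan <- vapply(0:(nchar(ref24) - 20), function(o)
    substr(ref24, o + 1, o + 20) == substr(bad, 1, 20), logical(1))
  expect_equal(sum(scan), 0)
  # ambiguous anchor (repeated sequence) is rejected
  rep_ref <- strrep("ATGGCTGAACTGTCTAAAGGTCCG", 2)
  expect_true(is.na(align_read(substr(rep_ref, 1, 24), rep_ref,
                               calling_config(anchor_length = 12))))
  # read overhanging the reference end is rejected
  expect_true(is.na(align_read(paste0(substr(ref24, 25, 48), "AAA"), ref24, cfg)))
})

test_that("per-read calling applies quality thresholds strictly", {
  cfg <- calling_config()
  n <- nchar(ref24)
  rd <- mutate_codon(ref24, 5, "CCC")
  # clean variant
  cl <- call_read(rd, q40(n), 0L, ref24, cfg)
  expect_equal(cl$status, "variant")
  expect_equal(cl$position, 5)
  expect_equal(cl$wt_codon, substr(ref24, 13, 15))
  expect_equal(cl$mut_codon, "CCC")
  # codon mean quality exactly 30 -> rejected ("more than 30" is strict)
  q <- rep(40, n); q[13:15] <- 30
  expect_equal(call_read(rd, qvec(q), 0L, ref24, cfg)$status, "rejected_codonq")
  q[13:15] <- 29
  expect_equal(call_read(rd, qvec(q), 0L, ref24, cfg)$status, "rejected_codonq")
  q[13:15] <- 31
  expect_equal(call_read(rd, qvec(q), 0L, ref24, cfg)$status, "variant")
  # read mean quality exactly 30 -> rejected
  expect_equal(call_read(rd, qvec(rep(30, n)), 0L, ref24, cfg)$status, "rejected_readq")
  # wild-type read: depth-only call
  expect_equal(call_read(ref24, q40(n), 0L, ref24, cfg)$status, "wt")
  # two mutated codons -> artifact, rejected
  rd2 <- mutate_codon(rd, 9, "TTT")
  expect_equal(call_read(rd2, q40(n), 0L, ref24, cfg)$status, "rejected_multi")
  # non-frame offset -> rejected
  expect_equal(call_read(substr(ref24, 2, 22), q40(21), 1L, ref24, cfg)$status,
               "rejected_frame")
})

test_that("count matrix applies the 3-read cutoff and records depth", {
  cfg <- calling_config()
  n <- nchar(ref24)
  # positions beyond codon 7 keep the 20-nt anchor intact
  mk <- function(pos, codon, times) rep(list(mutate_codon(ref24, pos, codon)), times)
  seqs <- c(unlist(mk(9, "CCC", 3)), unlist(mk(11, "GGG", 2)), rep(ref24, 4))
  calls <- call_reads(seqs, rep(q40(n), length(seqs)), ref24, cfg)
  m <- build_count_matrix(calls, cfg, 16)
  # variant seen twice removed; seen 3 times kept at 3
  expect_equal(nrow(m$counts), 1)
  expect_equal(m$counts$position, 9)
  expect_equal(m$counts$count, 3)
  # depth counts every retained read at every covered position
  expect_true(all(m$depth == 9))
  # conservation: retained calls = wt + variant reads
  st <- vapply(calls, `[[`, character(1), "status")
  expect_equal(sum(st %in% c("wt", "variant")), 9)
})

test_that("an enumerated 100-read fixture is called exactly", {
  cfg <- calling_config()
  n <- nchar(ref24)
  seqs <- character(0); quals <- character(0)
  # 40 wild type, 30 clean single-codon mutants at pos 10 (kept),
  # 10 single mutants with bad codon quality (rejected),
  # 10 double mutants (rejected), 10 low-mean-quality reads (rejected)
  seqs <- c(seqs, rep(ref24, 40)); quals <- c(quals, rep(q40(n), 40))
  m4 <- mutate_codon(ref24, 10, "AAA")
  seqs <- c(seqs, rep(m4, 30)); quals <- c(quals, rep(q40(n), 30))
  qbad <- rep(40, n); qbad[28:30] <- 25
  seqs <- c(seqs, rep(m4, 10)); quals <- c(quals, rep(qvec(qbad), 10))
  dbl <- mutate_codon(m4, 14, "TTT")
  seqs <- c(seqs, rep(dbl, 10)); quals <- c(quals, rep(q40(n), 10))
  seqs <- c(seqs, rep(m4, 10)); quals <- c(quals, rep(qvec(rep(25, n)), 10))
  calls <- call_reads(seqs, quals, ref24, cfg)
  st <- table(vapply(calls, `[[`, character(1), "status"))
  expect_equal(unname(st["wt"]), 40)
  expect_equal(unname(st["variant"]), 30)
  expect_equal(unname(st["rejected_codonq"]), 10)
  expect_equal(unname(st["rejected_multi"]), 10)
  expect_equal(unname(st["rejected_readq"]), 10)
  m <- build_count_matrix(calls, cfg, 16)
  expect_equal(m$counts$count, 30)
  expect_true(all(m$depth == 70))
})

test_that("caller equals the naive quadratic oracle on random reads", {
  cfg <- calling_config()
  set.seed(9)
  pool <- list()
  n <- nchar(ref24)
  for (i in 1:200) {
    pos <- sample(1:16, 1)
    codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    type <- sample(c("wt", "mut", "mut", "bad_anchor", "lowq"), 1)
    s <- ref24
    q <- rep(40L, n)
    if (type == "mut") s <- mutate_codon(s, pos, codon)
    if (type == "bad_anchor") substr(s, 5, 5) <- "N"
    if (type == "lowq") q <- rep(sample(c(20L, 29L, 31L), 1), n)
    pool[[i]] <- list(s = s, q = qvec(q))
  }
  seqs <- vapply(pool, `[[`, character(1), "s")
  quals <- vapply(pool, `[[`, character(1), "q")
  got <- build_count_matrix(call_reads(seqs, quals, ref24, cfg), cfg, 16)
  want <- naive_call_sample(seqs, quals, ref24, cfg)
  expect_equal(got$counts$position, want$counts$position)
  expect_equal(got$counts$wt, want$counts$wt)
  expect_equal(got$counts$mut, want$counts$mut)
  expect_equal(got$counts$count, want$counts$count)
  expect_equal(unname(got$depth), want$depth)
})

test_that("filters are monotone", {
  s <- scored_experiment()
  cfg <- s$config
  x <- s$counts[["reference_unselected_1"]]
  fq <- tempfile(fileext = ".fastq.gz")
  cfg_lo <- cfg; cfg_lo$low_q_fraction <- 0.3
  emit_reads(x, cfg_lo, fq)
  base <- call_fastq(fq, cfg$reference, calling_config(), flank5 = cfg$flank5)
  stricter_count <- call_fastq(fq, cfg$reference,
                               calling_config(min_reads_per_variant = 10),
                               flank5 = cfg$flank5)
  k <- function(m) paste(m$counts$position, m$counts$wt, m$counts$mut)
  m <- match(k(stricter_count), k(base))
  expect_true(all(!is.na(m)))
  expect_true(all(stricter_count$counts$count <= base$counts$count[m] + 0))
  expect_true(sum(stricter_count$counts$count) <= sum(base$counts$count))
  stricter_q <- call_fastq(fq, cfg$reference,
                           calling_config(min_read_mean_q = 45),
                           flank5 = cfg$flank5)
  expect_true(all(stricter_q$depth <= base$depth))
})

test_that("amino-acid collapse sums synonymous codons and flags classes", {
  counts <- data.frame(
    position = c(10, 10, 10, 3, 3, 5),
    wt = c("GCT", "GCT", "GCT", "AAA", "AAA", "TGG"),
    mut = c("GCA", "GCG", "CCG", "AAG", "TAA", "NGG"),
    count = c(5, 7, 4, 3, 6, 9), stringsAsFactors = FALSE)
  x <- mutant_counts(counts, depth = rep(100, 12), level = "codon")
  expect_warning(aa <- collapse_to_aa(x), "N")
  # two Ala codons at position 10 sum to 12; A->P separate
  a10 <- aa$counts[aa$counts$position == 10 & aa$counts$mut == "A", ]
  expect_equal(a10$count, 12)
  expect_true(a10$synonymous)
  expect_equal(aa$counts[aa$counts$position == 10 & aa$counts$mut == "P", "count"], 4)
  # K->K synonymous, K->* stop
  expect_true(aa$counts[aa$counts$position == 3 & aa$counts$mut == "K", "synonymous"])
  expect_true(aa$counts[aa$counts$position == 3 & aa$counts$mut == "*", "stop"])
  # N-containing codon excluded
  expect_false(any(aa$counts$position == 5))
  expect_error(collapse_to_aa(aa), "codon-level")
})

test_that("AA-level entry count matches enumeration over the codon catalogue", {
  s <- scored_experiment()
  lib <- s$truth
  aa <- collapse_to_aa(s$counts[["reference_unselected_1"]])
  # oracle: enumerate unique AA substitutions among codon entries with
  # retained counts
  x <- s$counts[["reference_unselected_1"]]$counts
  x <- x[x$count >= 3, ]
  key_lib <- paste(lib$position, lib$wt_codon, lib$mut_codon)
  m <- match(paste(x$position, x$wt, x$mut), key_lib)
  aa_keys <- unique(paste(lib$position[m], lib$wt_aa[m], lib$mut_aa[m]))
  expect_equal(nrow(aa$counts), length(aa_keys))
  ns <- !lib$synonymous[m] & !lib$stop[m]
  expect_equal(sum(!aa$counts$synonymous & !aa$counts$stop),
               length(unique(paste(lib$position[m], lib$mut_aa[m])[ns])))
})

test_that("SAM ingestion matches the internal caller", {
  skip_if_not_installed("Rsamtools")
  n <- nchar(ref24)
  seqs <- c(ref24, mutate_codon(ref24, 6, "CAC"), mutate_codon(ref24, 6, "CAC"),
            mutate_codon(ref24, 6, "CAC"), substr(ref24, 25, 48))
  quals <- rep(q40(n), 5)
  quals[5] <- q40(24)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", sprintf("@SQ\tSN:ref\tLN:%d", n))
  recs <- vapply(seq_along(seqs), function(i) {
    pos <- if (i == 5) 25L else 1L
    sprintf("read%d\t0\tref\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
            i, pos, nchar(seqs[i]), seqs[i], quals[i])
  }, character(1))
  writeLines(c(hdr, recs), sam)
  m <- call_sam(sam, ref24)
  expect_equal(m$counts$position, 6)
  expect_equal(m$counts$count, 3)
  expect_equal(unname(m$depth[1:8]), rep(4, 8))
  expect_equal(unname(m$depth[9:16]), rep(5, 8))
})
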