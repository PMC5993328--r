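# Variant calling: amplicon reads -> filtered codon-level single-site count
# matrix -> amino-acid-level collapse. Reproduces the Q>30 read/codon filters
# and the >=3-reads-per-variant count cutoff.

#' Variant-calling configuration
#'
#' A variant is called only if the average Q-score of the read and of the
#' mutated codon is more than `min_read_mean_q` / `min_codon_mean_q`
#' (strictly greater: a mean of exactly 30 fails). Variants seen fewer than
#' `min_reads_per_variant` times are zeroed. Reads carrying more than
#' `max_mutated_codons_per_read` mutated codons are discarded as artifacts
#' (the library is single-site).
#'
#' @param min_read_mean_q,min_codon_mean_q Phred thresholds (default 30).
#' @param min_reads_per_variant count cutoff (default 3; "at least" — a
#'   variant seen exactly 3 times is kept).
#' @param anchor_length exact-match anchor length for alignment (nt).
#' @param max_mutated_codons_per_read reads above this are rejected.
#' @return object of class `calling_config`.
#' @export
calling_config <- function(min_read_mean_q = 30, min_codon_mean_q = 30,
                           min_reads_per_variant = 3L, anchor_length = 20L,
                           max_mutated_codons_per_read = 1L) {
  stopifnot(min_read_mean_q > 0, min_codon_mean_q > 0,
            min_reads_per_variant > 0, anchor_length > 0,
            max_mutated_codons_per_read > 0)
  structure(list(min_read_mean_q = min_read_mean_q,
                 min_codon_mean_q = min_codon_mean_q,
                 min_reads_per_variant = as.integer(min_reads_per_variant),
                 anchor_length = as.integer(anchor_length),
                 max_mutated_codons_per_read = as.integer(max_mutated_codons_per_read)),
            class = "calling_config")
}

#' Single-site mutant count matrix
#'
#' Long-format container for per-sample variant counts plus per-codon-position
#' retained-read depth. `level` is `"codon"` (wt/mut are codons) or
#' `"amino_acid"` (wt/mut are residues, with `synonymous` and `stop` flags).
#'
#' @param counts data.frame with columns `position` (1-based codon index),
#'   `wt`, `mut`, `count` (and, at amino-acid level, `synonymous`, `stop`).
#' @param depth numeric vector of retained-read coverage per codon position
#'   (index = position).
#' @param level `"codon"` or `"amino_acid"`.
#' @param environment,pool,replicate sample metadata; `pool` is
#'   `"selected"` or `"unselected"`.
#' @return object of class `mutant_counts`.
#' @export
mutant_counts <- function(counts, depth, level = c("codon", "amino_acid"),
                          environment = "env", pool = c("unselected", "selected"),
                          replicate = 1L) {
  level <- match.arg(level)
  pool <- match.arg(pool)
  stopifnot(is.data.frame(counts),
            all(c("position", "wt", "mut", "count") %in% names(counts)),
            all(counts$count >= 0))
  if (nrow(counts) > 0) {
    per_pos <- tapply(counts$count, counts$position, sum)
    over <- per_pos > depth[as.integer(names(per_pos))]
    if (any(over, na.rm = TRUE)) {
      stop("variant counts at position(s) ", paste(names(per_pos)[which(over)], collapse = ", "),
           " exceed recorded depth", call. = FALSE)
    }
  }
  structure(list(counts = counts, depth = depth, level = level,
                 environment = environment, pool = pool,
                 replicate = as.integer(replicate)),
            class = "mutant_counts")
}

#' @export
print.mutant_counts <- function(x, ...) {
  cat(sprintf("mutant_counts [%s level] %s/%s rep %d: %d variants, %d with count>0\n",
              x$level, x$environment, x$pool, x$replicate,
              nrow(x$counts), sum(x$counts$count > 0)))
  invisible(x)
}

#' Align one read against the reference by exact anchor match
#'
#' The read's first `anchor_length` nucleotides must match the reference at
#' exactly one location, and the read must then fall fully within the
#' reference. Returns the 0-based offset, or `NA` with a `reason` attribute
#' (`"no_anchor"`, `"ambiguous"`, `"overhang"`).
#'
#' @param read read sequence (character).
#' @param reference reference coding sequence (length divisible by 3).
#' @param config a [calling_config()].
#' @return integer offset (0-based) or `NA`.
#' @export
align_read <- function(read, reference, config = calling_config()) {
  if (nchar(reference) %% 3 != 0) stop("reference length must be divisible by 3", call. = FALSE)
  if (nchar(read) < config$anchor_length) return(structure(NA_integer_, reason = "no_anchor"))
  anchor <- substr(read, 1L, config$anchor_length)
  # exact scan over every offset (overlap-safe, unlike regex search)
  n_off <- nchar(reference) - config$anchor_length + 1L
  if (n_off < 1L) return(structure(NA_integer_, reason = "no_anchor"))
  starts <- seq_len(n_off)
  hits <- starts[substring(reference, starts, starts + config$anchor_length - 1L) == anchor]
  if (length(hits) == 0L) return(structure(NA_integer_, reason = "no_anchor"))
  if (length(hits) > 1L) return(structure(NA_integer_, reason = "ambiguous"))
  offset <- hits[1L] - 1L
  if (offset + nchar(read) > nchar(reference)) {
    return(structure(NA_integer_, reason = "overhang"))
  }
  offset
}

#' Call at most one codon variant from an aligned read
#'
#' Codons are compared in frame. The read is rejected if its mean quality is
#' not strictly greater than `min_read_mean_q`, if any mutated codon's mean
#' base quality is not strictly greater than `min_codon_mean_q`, if it is not
#' frame-aligned (offset and length multiples of 3), or if it carries more
#' than `max_mutated_codons_per_read` mutated codons. A read identical to the
#' reference yields a wild-type call (depth contribution only).
#'
#' @param read,qual read and quality strings (Phred+33).
#' @param offset 0-based alignment offset from [align_read()].
#' @param reference reference coding sequence.
#' @param config a [calling_config()].
#' @return list with `status` in `wt`, `variant`, `rejected_*`; for variants
#'   also `position`, `wt_codon`, `mut_codon`; and `span` (codon index range
#'   covered by the read).
#' @export
call_read <- function(read, qual, offset, reference, config = calling_config()) {
  if (is.na(offset)) return(list(status = paste0("rejected_", attr(offset, "reason") %||% "align")))
  if (offset %% 3 != 0 || nchar(read) %% 3 != 0) return(list(status = "rejected_frame"))
  q <- utf8ToInt(qual) - 33L
  if (!(mean(q) > config$min_read_mean_q)) return(list(status = "rejected_readq"))
  first_codon <- offset %/% 3L + 1L
  n_codons <- nchar(read) %/% 3L
  span <- c(first_codon, first_codon + n_codons - 1L)
  ref_part <- substr(reference, offset + 1L, offset + nchar(read))
  read_codons <- substring(read, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  ref_codons <- substring(ref_part, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  diff <- which(read_codons != ref_codons)
  if (length(diff) == 0L) return(list(status = "wt", span = span))
  if (length(diff) > config$max_mutated_codons_per_read) return(list(status = "rejected_multi"))
  for (d in diff) {
    cq <- q[(3L * d - 2L):(3L * d)]
    if (!(mean(cq) > config$min_codon_mean_q)) return(list(status = "rejected_codonq"))
  }
  d <- diff[1L]
  list(status = "variant", position = first_codon + d - 1L,
       wt_codon = ref_codons[d], mut_codon = read_codons[d], span = span)
}

#' Call all reads of one sample
#'
#' Convenience wrapper running [align_read()] and [call_read()] over vectors
#' of sequences and qualities.
#'
#' @param seqs,quals character vectors of read sequences and Phred+33 quality
#'   strings.
#' @param reference reference coding sequence.
#' @param config a [calling_config()].
#' @return list of per-read call lists.
#' @export
call_reads <- function(seqs, quals, reference, config = calling_config()) {
  stopifnot(length(seqs) == length(quals))
  # fast path: full-length perfect-anchor amplicons all share offset 0
  lapply(seq_along(seqs), function(i) {
    off <- align_read(seqs[i], reference, config)
    call_read(seqs[i], quals[i], off, reference, config)
  })
}

#' Build the codon-level count matrix from per-read calls
#'
#' Variant calls are tabulated per (position, wt codon, mutant codon);
#' variants seen fewer than `min_reads_per_variant` times are removed.
#' Per-position depth counts every retained read (wild-type or variant)
#' covering the position; reads rejected by the quality filters contribute
#' nothing.
#'
#' @param calls list of calls from [call_reads()] (single sample).
#' @param config a [calling_config()].
#' @param gene_length_codons gene length (codons).
#' @param environment,pool,replicate sample metadata.
#' @return codon-level [mutant_counts()].
#' @export
build_count_matrix <- function(calls, config = calling_config(),
                               gene_length_codons,
                               environment = "env", pool = "unselected",
                               replicate = 1L) {
  status <- vapply(calls, `[[`, character(1), "status")
  kept <- calls[status %in% c("wt", "variant")]
  depth <- numeric(gene_length_codons)
  for (cl in kept) {
    depth[cl$span[1]:cl$span[2]] <- depth[cl$span[1]:cl$span[2]] + 1
  }
  var_calls <- kept[vapply(kept, `[[`, character(1), "status") == "variant"]
  if (length(var_calls) > 0) {
    key <- vapply(var_calls, function(cl)
      codon_sub_id(cl$position, cl$wt_codon, cl$mut_codon), character(1))
    tab <- table(key)
    first <- var_calls[match(names(tab), key)]
    counts <- data.frame(
      position = vapply(first, `[[`, numeric(1), "position"),
      wt = vapply(first, `[[`, character(1), "wt_codon"),
      mut = vapply(first, `[[`, character(1), "mut_codon"),
      count = as.integer(tab), stringsAsFactors = FALSE)
    counts <- counts[counts$count >= config$min_reads_per_variant, , drop = FALSE]
    counts <- counts[order(counts$position, counts$wt, counts$mut), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(position = integer(0), wt = character(0),
                         mut = character(0), count = integer(0),
                         stringsAsFactors = FALSE)
  }
  mutant_counts(counts, depth, level = "codon", environment = environment,
                pool = pool, replicate = replicate)
}

# Shift amplicon-frame calls into CDS codon coordinates, clipping spans to
# [1, gene_length]. Calls landing entirely in the flank are demoted to
# rejections; a variant call inside the flank (possible only with sequencing
# errors there) is demoted to a wild-type depth contribution.
shift_calls_to_cds <- function(calls, flank_codons, gene_length_codons) {
  if (flank_codons == 0L) return(calls)
  lapply(calls, function(cl) {
    if (!(cl$status %in% c("wt", "variant"))) return(cl)
    span <- c(max(1L, cl$span[1] - flank_codons),
              min(gene_length_codons, cl$span[2] - flank_codons))
    if (span[2] < span[1]) return(list(status = "rejected_frame"))
    if (cl$status == "variant") {
      pos <- cl$position - flank_codons
      if (pos < 1L || pos > gene_length_codons) return(list(status = "wt", span = span))
      cl$position <- pos
    }
    cl$span <- span
    cl
  })
}

#' Call a FASTQ file into a count matrix
#'
#' @param fastq path to a FASTQ (optionally gzipped).
#' @param reference reference coding sequence.
#' @param config a [calling_config()].
#' @param flank5 constant 5' primer-region sequence preceding the coding
#'   sequence in the reads (length divisible by 3; `""` if reads start at
#'   the CDS).
#' @param gene_length_codons gene length; defaults to `nchar(reference)/3`.
#' @param environment,pool,replicate sample metadata.
#' @return codon-level [mutant_counts()].
#' @export
call_fastq <- function(fastq, reference, config = calling_config(), flank5 = "",
                       gene_length_codons = nchar(reference) %/% 3L,
                       environment = "env", pool = "unselected", replicate = 1L) {
  if (nchar(flank5) %% 3 != 0) stop("flank5 length must be divisible by 3", call. = FALSE)
  # suppressWarnings: Biostrings warns about dropped metadata columns on read
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- as.character(x)
  quals <- as.character(Biostrings::quality(x))
  amplicon <- paste0(flank5, reference)
  calls <- call_reads(unname(seqs), unname(quals), amplicon, config)
  calls <- shift_calls_to_cds(calls, nchar(flank5) %/% 3L, gene_length_codons)
  build_count_matrix(calls, config, gene_length_codons, environment, pool, replicate)
}

#' Call an externally aligned SAM/BAM file into a count matrix
#'
#' Alternative ingestion path for reads aligned with an external tool. Only
#' reads with a simple full-match CIGAR (`<n>M`) are used; the mapping
#' position replaces the internal anchor aligner and the same quality/count
#' filters apply.
#'
#' @param sam path to a SAM or BAM file.
#' @inheritParams call_fastq
#' @return codon-level [mutant_counts()].
#' @export
call_sam <- function(sam, reference, config = calling_config(),
                     gene_length_codons = nchar(reference) %/% 3L,
                     environment = "env", pool = "unselected", replicate = 1L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM ingestion requires the Rsamtools package", call. = FALSE)
  }
  path <- sam
  if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("pos", "seq", "qual", "cigar")))[[1]]
  ok <- !is.na(b$pos) & grepl("^[0-9]+M$", b$cigar)
  seqs <- as.character(b$seq[ok])
  quals <- as.character(b$qual[ok])
  offsets <- b$pos[ok] - 1L
  calls <- lapply(seq_along(seqs), function(i)
    call_read(seqs[i], quals[i], offsets[i], reference, config))
  build_count_matrix(calls, config, gene_length_codons, environment, pool, replicate)
}

#' Collapse a codon-level matrix to amino-acid level
#'
#' Counts of codon variants encoding the same amino-acid substitution at the
#' same position are summed (plain summation over synonymous codons).
#' Substitutions whose mutant amino acid equals the wild type are flagged
#' synonymous; stop-codon variants are retained with a stop flag. Codon
#' entries containing `N` are excluded with a warning.
#'
#' @param x codon-level [mutant_counts()].
#' @return amino-acid-level [mutant_counts()].
#' @export
collapse_to_aa <- function(x) {
  stopifnot(inherits(x, "mutant_counts"))
  if (x$level != "codon") stop("input must be a codon-level matrix", call. = FALSE)
  tab <- x$counts
  bad <- grepl("N", tab$wt, fixed = TRUE) | grepl("N", tab$mut, fixed = TRUE)
  if (any(bad)) {
    warning(sum(bad), " codon entries containing N excluded")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) > 0) {
    wt_aa <- translate_codons(tab$wt)
    mut_aa <- translate_codons(tab$mut)
    key <- paste(tab$position, wt_aa, mut_aa, sep = "|")
    agg <- tapply(tab$count, key, sum)
    parts <- strsplit(names(agg), "|", fixed = TRUE)
    counts <- data.frame(
      position = as.integer(vapply(parts, `[[`, character(1), 1)),
      wt = vapply(parts, `[[`, character(1), 2),
      mut = vapply(parts, `[[`, character(1), 3),
      count = as.vector(agg), stringsAsFactors = FALSE)
    counts$synonymous <- counts$wt == counts$mut
    counts$stop <- counts$mut == "*"
    counts <- counts[order(counts$position, counts$wt, counts$mut), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(position = integer(0), wt = character(0),
                         mut = character(0), count = integer(0),
                         synonymous = logical(0), stop = logical(0),
                         stringsAsFactors = FALSE)
  }
  mutant_counts(counts, x$depth, level = "amino_acid",
                environment = x$environment, pool = x$pool,
                replicate = x$replicate)
}
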