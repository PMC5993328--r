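#' @keywords internal
"_PACKAGE"

# Standard genetic code (NCBI table 1), taken from Biostrings at load time.
genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a vector of codons
#'
#' Standard genetic code (NCBI table 1). Codons containing characters other
#' than ACGT translate to `NA`.
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of single-letter amino acids (`"*"` for stop).
#' @export
translate_codons <- function(codons) {
  stopifnot(is.character(codons))
  gc <- genetic_code()
  aa <- unname(gc[toupper(codons)])
  aa[!(toupper(codons) %in% names(gc))] <- NA_character_
  aa
}

# Substitution id in the field's WT+position+MUT convention, e.g. "L5P".
aa_sub_id <- function(position, wt_aa, mut_aa) {
  paste0(wt_aa, position, mut_aa)
}

codon_sub_id <- function(position, wt_codon, mut_codon) {
  sprintf("c%d.%s>%s", position, wt_codon, mut_codon)
}

# Sanger Phred+33 helpers.
phred_to_char <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

char_to_phred <- function(s) {
  lapply(strsplit(s, ""), function(ch) vapply(ch, function(c) utf8ToInt(c) - 33L, integer(1)))
}

# Mean Phred quality of each quality string, vectorized.
mean_qual <- function(qual_strings) {
  vapply(qual_strings, function(s) mean(utf8ToInt(s)) - 33, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGTacgt]", seq)) {
    stop(what, " contains non-ACGT symbols; only unambiguous DNA is accepted", call. = FALSE)
  }
  invisible(toupper(seq))
}

# Midrank percentile (0-100) of each value within x; monotone-invariant.
percentile_rank <- function(x) {
  n <- sum(!is.na(x))
  100 * (rank(x, ties.method = "average", na.last = "keep") - 0.5) / n
}
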