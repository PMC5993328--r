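# Shared fixtures and independent oracles, built in code at test time.

# -- PDB fixture writer (fixed-width ATOM records) ---------------------------
mk_atom <- function(serial, name, resname, chain, resseq, x, y, z,
                    occ = 1, altloc = " ") {
  name4 <- formatC(paste0(" ", name), width = -4)
  sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          serial, name4, altloc, resname, chain, resseq, x, y, z, occ, 0,
          substr(name, 1, 1))
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Toy dimer: chain A with an active residue 147, chain B a +10 A x-shifted copy.
toy_dimer_lines <- function() {
  c(mk_atom(1, "N", "ALA", "A", 1, 0, 0, 0),
    mk_atom(2, "CA", "ALA", "A", 1, 1, 0, 0),
    mk_atom(3, "CA", "GLY", "A", 2, 4, 0, 0),
    mk_atom(4, "CA", "ASP", "A", 147, 0, 4, 0),
    mk_atom(5, "CB", "ASP", "A", 147, 3, 4, 0),
    mk_atom(6, "CA", "ALA", "B", 1, 11, 0, 0),
    mk_atom(7, "CA", "GLY", "B", 2, 14, 0, 0))
}

# Random many-atom structure for brute-force distance oracles.
random_structure_lines <- function(n_res = 30, seed = 42, chain = "A",
                                   offset = c(0, 0, 0)) {
  set.seed(seed)
  serial <- 0L
  lines <- character(0)
  for (r in seq_len(n_res)) {
    n_atoms <- sample(2:4, 1)
    names_r <- c("CA", "N", "CB", "CG")[seq_len(n_atoms)]
    for (a in names_r) {
      serial <- serial + 1L
      xyz <- runif(3, 0, 30) + offset
      lines <- c(lines, mk_atom(serial, a, "ALA", chain, r,
                                xyz[1], xyz[2], xyz[3]))
    }
  }
  lines
}

# -- naive quadratic variant caller (independent oracle) ---------------------
naive_call_sample <- function(seqs, quals, reference, config = calling_config(),
                              gene_length = nchar(reference) %/% 3L) {
  depth <- numeric(gene_length)
  tab <- list()
  n_wt <- 0L
  for (i in seq_along(seqs)) {
    read <- seqs[i]
    # scan every offset for an exact anchor match
    anchor <- substr(read, 1, config$anchor_length)
    hits <- integer(0)
    for (o in 0:(nchar(reference) - config$anchor_length)) {
      if (substr(reference, o + 1, o + config$anchor_length) == anchor) hits <- c(hits, o)
    }
    if (length(hits) != 1) next
    o <- hits[1]
    if (o + nchar(read) > nchar(reference)) next
    if (o %% 3 != 0 || nchar(read) %% 3 != 0) next
    q <- utf8ToInt(quals[i]) - 33
    if (!(mean(q) > config$min_read_mean_q)) next
    muts <- list()
    ok <- TRUE
    for (c_i in seq_len(nchar(read) %/% 3)) {
      rc <- substr(read, 3 * c_i - 2, 3 * c_i)
      fc <- substr(reference, o + 3 * c_i - 2, o + 3 * c_i)
      if (rc != fc) {
        if (!(mean(q[(3 * c_i - 2):(3 * c_i)]) > config$min_codon_mean_q)) ok <- FALSE
        muts[[length(muts) + 1]] <- list(pos = o %/% 3 + c_i, wt = fc, mut = rc)
      }
    }
    if (!ok || length(muts) > config$max_mutated_codons_per_read) next
    span <- (o %/% 3 + 1):(o %/% 3 + nchar(read) %/% 3)
    depth[span] <- depth[span] + 1
    if (length(muts) == 0) { n_wt <- n_wt + 1L; next }
    m <- muts[[1]]
    k <- paste(m$pos, m$wt, m$mut)
    tab[[k]] <- (tab[[k]] %||% 0L) + 1L
  }
  keep <- names(tab)[unlist(tab) >= config$min_reads_per_variant]
  keep <- sort(keep)
  parts <- strsplit(keep, " ")
  counts <- data.frame(
    position = as.integer(vapply(parts, `[[`, character(1), 1)),
    wt = vapply(parts, `[[`, character(1), 2),
    mut = vapply(parts, `[[`, character(1), 3),
    count = as.integer(unlist(tab[keep])), stringsAsFactors = FALSE)
  counts <- counts[order(counts$position, counts$wt, counts$mut), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, depth = depth, n_wt = n_wt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- rank-then-Pearson Spearman oracle ---------------------------------------
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"),
             method = "pearson")
}

# -- hand-constructable fitness tables ---------------------------------------
make_ft <- function(ids, F_rep1, F_rep2 = F_rep1, synonymous = FALSE,
                    survived = TRUE, environment = "test") {
  n <- length(ids)
  df <- data.frame(
    id = ids, position = seq_len(n), wt = rep("A", n), mut = rep("V", n),
    synonymous = rep_len(synonymous, n), stop = FALSE,
    F_rep1 = F_rep1, F_rep2 = F_rep2,
    stringsAsFactors = FALSE)
  df$F <- rowMeans(cbind(F_rep1, F_rep2))
  df$survived <- rep_len(survived, n)
  df$F[!df$survived] <- NA
  df$F_rep1[!df$survived] <- NA
  df$F_rep2[!df$survived] <- NA
  df$class <- ifelse(df$survived, NA_character_, "eliminated")
  structure(df, environment = environment, class = c("fitness_table", "data.frame"))
}

# -- small scored synthetic experiment, shared across test files -------------
# Moderate scale: full NNK library over 25 codons, depth 3e4.
scored_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(gene_length_codons = 25, depth_per_sample = 3e4, seed = 101)
    truth <- assign_true_features(generate_library(cfg), cfg)
    counts <- simulate_counts(truth, cfg)
    aa <- lapply(counts, collapse_to_aa)
    nm <- names(aa)
    fts <- list()
    for (e in names(cfg$environments)) {
      sel <- aa[sort(grep(paste0("^", e, "_selected_"), nm, value = TRUE))]
      uns <- aa[sort(grep(paste0("^", e, "_unselected_"), nm, value = TRUE))]
      ft <- suppressWarnings(preferential_enrichment(unname(sel), unname(uns)))
      fts[[e]] <- classify_fitness(ft, neutrality_thresholds(unname(uns)))
    }
    cache <<- list(config = cfg, truth = truth, counts = counts, aa = aa,
                   fitness = fts)
    cache
  }
})
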