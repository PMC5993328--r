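# Synthetic DMS experiment generator: single-site mutant library, biophysical
# ground-truth fitness (folding x binding sigmoid cliffs), multinomial count
# sampling per pool/replicate/environment, and FASTQ emission.

#' Specify a selection environment
#'
#' An environment is characterized by a folding-stress shift `delta_g`
#' (kcal/mol added to every mutant's effective ddG; positive at elevated
#' temperature, negative with chemical chaperones such as TMAO or glycerol),
#' a binding cliff position `d0` (distance from the active site, in Angstrom,
#' below which fitness collapses; larger at higher antibiotic dose) and an
#' `elimination_floor` (true fitness below which a mutant is completely
#' removed from the selected pool before sampling).
#'
#' @param name environment label.
#' @param delta_g folding stress shift, kcal/mol. The reference environment
#'   has `delta_g = 0`.
#' @param d0 binding cliff position, Angstrom (default 15).
#' @param elimination_floor log2-fitness below which a mutant is eliminated.
#' @return an object of class `env_spec`.
#' @export
env_spec <- function(name, delta_g = 0, d0 = 15, elimination_floor = -4) {
  stopifnot(is.character(name), length(name) == 1L, d0 >= 0)
  structure(list(name = name, delta_g = delta_g, d0 = d0,
                 elimination_floor = elimination_floor),
            class = "env_spec")
}

#' Configure a synthetic DMS experiment
#'
#' Defaults state the emulated experiment: a 177-codon resistance gene, an
#' NNK single-site codon library, read depth 1e5 per sample, two biological
#' replicates, and a reference plus a heat-stressed environment.
#'
#' @param gene_length_codons gene length in codons (>= 10).
#' @param library_spec `"all_single_codon_NNK"` or `"random_subset"`.
#' @param subset_size number of non-synonymous codon entries kept in
#'   `random_subset` mode.
#' @param subset_size_syn number of synonymous codon entries kept in
#'   `random_subset` mode.
#' @param depth_per_sample reads per sample.
#' @param n_replicates biological replicates per pool.
#' @param environments list of [env_spec()] objects; the first is the
#'   reference.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @param reference reference coding sequence (character, length divisible
#'   by 3). `NULL` draws a random stop-free sequence from the seed.
#' @param flank5 constant 5' primer-region sequence prepended to every
#'   simulated read (length divisible by 3). Mutations never fall in it, so
#'   the caller's exact-anchor alignment works for every codon position.
#' @param read_length simulated read length; defaults to the full amplicon.
#' @param q_high,q_low two-point base-quality mixture (Phred).
#' @param low_q_fraction fraction of reads carrying `q_low` bases.
#' @param error_rate per-base substitution probability in [0, 0.01].
#' @param g0 folding cliff midpoint, kcal/mol.
#' @param k_g folding sigmoid width, kcal/mol.
#' @param k_d binding sigmoid width, Angstrom.
#' @param f_min fitness of a fully non-functional mutant, log2 units.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(gene_length_codons = 177L,
                       library_spec = c("all_single_codon_NNK", "random_subset"),
                       subset_size = 2000L,
                       subset_size_syn = 150L,
                       depth_per_sample = 1e5,
                       n_replicates = 2L,
                       environments = list(env_spec("reference", delta_g = 0, d0 = 7.5),
                                           env_spec("heat", delta_g = 1, d0 = 7.5),
                                           env_spec("high_dose", delta_g = 0, d0 = 15)),
                       seed = 1L,
                       reference = NULL,
                       flank5 = "ACACGACGCTCTTCCGATCTG",
                       read_length = NULL,
                       q_high = 40L, q_low = 20L, low_q_fraction = 0,
                       error_rate = 0,
                       g0 = 2, k_g = 0.5, k_d = 2, f_min = -6) {
  library_spec <- match.arg(library_spec)
  stopifnot(gene_length_codons >= 10L || library_spec == "all_single_codon_NNK",
            depth_per_sample >= 1, n_replicates >= 1L,
            error_rate >= 0, error_rate <= 0.01,
            length(environments) >= 1L,
            all(vapply(environments, inherits, logical(1), "env_spec")))
  if (environments[[1L]]$delta_g != 0) {
    stop("the first (reference) environment must have delta_g = 0", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- random_reference(gene_length_codons, seed)
  } else {
    reference <- assert_dna(reference, "reference")
    if (nchar(reference) %% 3 != 0) stop("reference length must be divisible by 3", call. = FALSE)
    gene_length_codons <- nchar(reference) %/% 3L
  }
  flank5 <- assert_dna(flank5, "flank5")
  if (nchar(flank5) %% 3 != 0) stop("flank5 length must be divisible by 3", call. = FALSE)
  if (is.null(read_length)) read_length <- 3L * gene_length_codons + nchar(flank5)
  names(environments) <- vapply(environments, `[[`, character(1), "name")
  structure(list(
    gene_length_codons = as.integer(gene_length_codons),
    library_spec = library_spec,
    subset_size = as.integer(subset_size),
    subset_size_syn = as.integer(subset_size_syn),
    depth_per_sample = depth_per_sample,
    n_replicates = as.integer(n_replicates),
    environments = environments,
    seed = as.integer(seed),
    reference = reference,
    flank5 = flank5,
    read_length = as.integer(read_length),
    q_high = as.integer(q_high), q_low = as.integer(q_low),
    low_q_fraction = low_q_fraction,
    error_rate = error_rate,
    g0 = g0, k_g = k_g, k_d = k_d, f_min = f_min
  ), class = "sim_config")
}

# Random stop-free coding sequence starting with ATG; deterministic in seed.
random_reference <- function(n_codons, seed) {
  stopifnot(n_codons >= 1)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  withr_seed(seed, {
    paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""))
  })
}

# Local seed scope: evaluates expr under set.seed(seed) and restores RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Enumerate NNK codons
#'
#' The 32 degenerate codons with G or T in the third position.
#'
#' @return character vector of 32 codons.
#' @export
nnk_codons <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(outer(outer(bases, bases, paste0), c("G", "T"), paste0))
}

#' Generate the single-site mutant catalogue
#'
#' Every entry differs from the reference in exactly one codon. In NNK mode
#' all 32 NNK codons are enumerated per position and entries equal to the
#' wild-type codon are dropped; synonymous entries (mutant codon differing
#' from the wild type but encoding the same amino acid) are retained and
#' flagged.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `position`, `wt_codon`, `mut_codon`,
#'   `wt_aa`, `mut_aa`, `synonymous`, `stop`, `codon_id`, `aa_id`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- assert_dna(config$reference, "reference")
  n <- config$gene_length_codons
  if (n < 10L) stop("gene_length_codons must be >= 10", call. = FALSE)
  wt_codons <- substring(ref, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  nnk <- nnk_codons()
  cat_pos <- rep(seq_len(n), each = length(nnk))
  cat_wt <- wt_codons[cat_pos]
  cat_mut <- rep(nnk, times = n)
  keep <- cat_mut != cat_wt
  out <- data.frame(position = cat_pos[keep],
                    wt_codon = cat_wt[keep],
                    mut_codon = cat_mut[keep],
                    stringsAsFactors = FALSE)
  out$wt_aa <- translate_codons(out$wt_codon)
  out$mut_aa <- translate_codons(out$mut_codon)
  out$synonymous <- out$wt_aa == out$mut_aa
  out$stop <- out$mut_aa == "*"
  if (config$library_spec == "random_subset") {
    out <- withr_seed(config$seed, {
      ns <- which(!out$synonymous)
      sy <- which(out$synonymous)
      keep_ns <- sort(sample(ns, min(config$subset_size, length(ns))))
      keep_sy <- sort(sample(sy, min(config$subset_size_syn, length(sy))))
      out[sort(c(keep_ns, keep_sy)), , drop = FALSE]
    })
    rownames(out) <- NULL
  }
  out$codon_id <- codon_sub_id(out$position, out$wt_codon, out$mut_codon)
  out$aa_id <- aa_sub_id(out$position, out$wt_aa, out$mut_aa)
  out
}

#' Attach ground-truth biophysical features and fitness
#'
#' Non-synonymous amino-acid substitutions draw ddG from a right-skewed
#' shifted gamma (shape 2, rate 1, shifted by -1 kcal/mol: support >= -1,
#' mean 1); ddG is a property of the amino-acid substitution, so codon
#' variants encoding the same substitution share one value. Each codon
#' position draws one distance-to-active-site from U[3, 40] Angstrom, shared
#' by all substitutions at that position. Synonymous mutants have ddG = 0
#' and true fitness exactly 0 in every environment; nonsense (stop) mutants
#' are maximally destabilized.
#'
#' @param catalogue output of [generate_library()].
#' @param config a [sim_config()].
#' @return `catalogue` with columns `ddG`, `dist_active`, and per environment
#'   `F_true.<env>` and `survives.<env>`.
#' @export
assign_true_features <- function(catalogue, config) {
  stopifnot(nrow(catalogue) > 0, inherits(config, "sim_config"))
  withr_seed(config$seed + 1L, {
    positions <- sort(unique(catalogue$position))
    dist_by_pos <- stats::runif(length(positions), 3, 40)
    names(dist_by_pos) <- positions
    catalogue$dist_active <- unname(dist_by_pos[as.character(catalogue$position)])
    aa_key <- paste(catalogue$position, catalogue$mut_aa)
    uniq <- unique(aa_key)
    ddg_by_sub <- stats::rgamma(length(uniq), shape = 2, rate = 1) - 1
    names(ddg_by_sub) <- uniq
    ddg <- unname(ddg_by_sub[aa_key])
    ddg[catalogue$synonymous] <- 0
    # nonsense mutants truncate the protein: treated as maximally destabilized
    ddg[catalogue$stop] <- Inf
    catalogue$ddG <- ddg
  })
  for (env in config$environments) {
    f <- true_fitness(catalogue$ddG, catalogue$dist_active, env,
                      g0 = config$g0, k_g = config$k_g, k_d = config$k_d,
                      f_min = config$f_min)
    f[catalogue$synonymous] <- 0
    catalogue[[paste0("F_true.", env$name)]] <- f
    catalogue[[paste0("survives.", env$name)]] <- f > env$elimination_floor
  }
  catalogue
}

#' Ground-truth fitness from the folding x binding cliff model
#'
#' `F = f_min + (0 - f_min) * w_f * w_b` with folding weight
#' `w_f = 1 / (1 + exp((ddG + delta_g - g0) / k_g))` and binding weight
#' `w_b = 1 / (1 + exp((d0 - distance) / k_d))`. A stable mutation far from
#' the active site has fitness ~0; crossing either cliff drives fitness
#' towards `f_min`. Monotone non-increasing in ddG and non-decreasing in
#' distance.
#'
#' @param ddg destabilization, kcal/mol (may be `Inf`).
#' @param distance distance from the active site, Angstrom.
#' @param env an [env_spec()].
#' @param g0 folding cliff midpoint (kcal/mol); `k_g`, `k_d` sigmoid widths;
#'   `f_min` floor fitness (log2 units).
#' @param k_g,k_d,f_min see above.
#' @return numeric vector of true log2 fitness values.
#' @export
true_fitness <- function(ddg, distance, env, g0 = 2, k_g = 0.5, k_d = 2,
                         f_min = -6) {
  stopifnot(inherits(env, "env_spec"), k_g > 0, k_d > 0)
  w_f <- 1 / (1 + exp((ddg + env$delta_g - g0) / k_g))
  w_f[is.infinite(ddg) & ddg > 0] <- 0
  w_b <- 1 / (1 + exp((env$d0 - distance) / k_d))
  f_min + (0 - f_min) * w_f * w_b
}

#' Export ground truth as an amino-acid-level feature table
#'
#' Collapses the codon-level truth catalogue to unique amino-acid
#' substitutions and returns their biophysical features in the feature-table
#' layout (`position`, `wt`, `mut`, `ddG`, `dist_active`, `dlogP`, `dpI`),
#' ready for the constraint-analysis and landscape stages.
#'
#' @param truth output of [assign_true_features()].
#' @return a `feature_table` data.frame.
#' @export
truth_features <- function(truth) {
  ns <- truth[!truth$synonymous & !truth$stop, , drop = FALSE]
  key <- paste(ns$position, ns$wt_aa, ns$mut_aa)
  ns <- ns[!duplicated(key), , drop = FALSE]
  pd <- property_deltas(ns$wt_aa, ns$mut_aa)
  structure(data.frame(position = ns$position, wt = ns$wt_aa, mut = ns$mut_aa,
                       ddG = ns$ddG, dist_active = ns$dist_active,
                       dlogP = pd$dlogP, dpI = pd$dpI,
                       stringsAsFactors = FALSE),
            coverage = 1, class = c("feature_table", "data.frame"))
}

#' Simulate selected/unselected count pairs
#'
#' Unselected counts are multinomial draws at `depth_per_sample` over uniform
#' library proportions. Selected proportions are the uniform proportions
#' weighted by `2^F_true`, with mutants at or below the environment's
#' elimination floor zeroed before renormalization (complete elimination of
#' highly deleterious mutants); counts are then drawn multinomially. One pair
#' per replicate per environment, all under the config seed.
#'
#' @param truth output of [assign_true_features()].
#' @param config a [sim_config()].
#' @return named list of [mutant_counts()] objects, names
#'   `<env>_<pool>_<replicate>`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  n_var <- nrow(truth)
  p_unif <- rep(1 / n_var, n_var)
  out <- list()
  withr_seed(config$seed + 2L, {
    for (env in config$environments) {
      f_true <- truth[[paste0("F_true.", env$name)]]
      w <- p_unif * 2^f_true
      w[f_true <= env$elimination_floor] <- 0
      if (all(w == 0)) stop("degenerate selection: all mutants eliminated in ",
                            env$name, call. = FALSE)
      p_sel <- w / sum(w)
      for (rep_i in seq_len(config$n_replicates)) {
        for (pool in c("unselected", "selected")) {
          p <- if (pool == "unselected") p_unif else p_sel
          counts <- as.vector(stats::rmultinom(1, size = config$depth_per_sample, prob = p))
          out[[sprintf("%s_%s_%d", env$name, pool, rep_i)]] <-
            mutant_counts(
              data.frame(position = truth$position,
                         wt = truth$wt_codon, mut = truth$mut_codon,
                         count = counts, stringsAsFactors = FALSE),
              depth = rep(config$depth_per_sample, config$gene_length_codons),
              level = "codon", environment = env$name, pool = pool,
              replicate = rep_i)
        }
      }
    }
  })
  out
}

#' Emit FASTQ reads for a count matrix
#'
#' Each mutant contributes exactly `count` full-amplicon reads: the constant
#' 5' flank (primer region) followed by the reference with the mutant's
#' codon substituted. Base qualities follow a two-point mixture: a
#' `low_q_fraction` of reads carries uniform Phred `q_low` (mean quality below
#' the caller's filter), the rest `q_high`. With `error_rate > 0` each base
#' substitutes uniformly to another base. Deterministic given the config seed.
#'
#' @param counts a codon-level [mutant_counts()] object.
#' @param config a [sim_config()].
#' @param path output FASTQ path (`.gz` supported). `NULL` returns the
#'   sequences invisibly without writing.
#' @return invisibly, a list with `sequences` and `qualities` (character
#'   vectors); writes `path` if given.
#' @export
emit_reads <- function(counts, config, path = NULL) {
  stopifnot(inherits(counts, "mutant_counts"), inherits(config, "sim_config"))
  ref <- paste0(config$flank5, config$reference)
  flank_codons <- nchar(config$flank5) %/% 3L
  if (config$read_length < nchar(ref)) {
    stop("read_length must cover the full amplicon in default mode", call. = FALSE)
  }
  tab <- counts$counts[counts$counts$count > 0, , drop = FALSE]
  n_reads <- sum(tab$count)
  seqs <- character(n_reads)
  if (n_reads > 0) {
    idx <- rep(seq_len(nrow(tab)), tab$count)
    starts <- 3L * (tab$position + flank_codons) - 2L
    mut_seq <- vapply(seq_len(nrow(tab)), function(i) {
      s <- ref
      substr(s, starts[i], starts[i] + 2L) <- tab$mut[i]
      s
    }, character(1))
    seqs <- mut_seq[idx]
  }
  sample_tag <- sprintf("%s_%s_%s", counts$environment, counts$pool, counts$replicate)
  quals <- character(n_reads)
  withr_seed(config$seed + 3L + counts$replicate +
               1000L * match(counts$pool, c("unselected", "selected")), {
    if (n_reads > 0) {
      low <- stats::runif(n_reads) < config$low_q_fraction
      qchar_hi <- strrep(rawToChar(as.raw(config$q_high + 33L)), nchar(ref))
      qchar_lo <- strrep(rawToChar(as.raw(config$q_low + 33L)), nchar(ref))
      quals <- ifelse(low, qchar_lo, qchar_hi)
      if (config$error_rate > 0) {
        bases <- c("A", "C", "G", "T")
        for (i in seq_len(n_reads)) {
          hits <- which(stats::runif(nchar(ref)) < config$error_rate)
          for (h in hits) {
            cur <- substr(seqs[i], h, h)
            substr(seqs[i], h, h) <- sample(setdiff(bases, cur), 1)
          }
        }
      }
    }
  })
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- if (n_reads > 0) sprintf("%s_read%06d", sample_tag, seq_len(n_reads)) else character(0)
    x <- Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
  }
  invisible(list(sequences = seqs, qualities = quals))
}
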