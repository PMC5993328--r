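# End-to-end orchestration: simulate -> call -> score -> selection stats ->
# constraint analysis -> landscapes, with a machine-readable run report,
# plus a reproduction mode recomputing environment statistics from
# previously written fitness tables.

#' Pipeline run configuration
#'
#' @param samples data.frame with columns `environment`, `pool`
#'   (`selected`/`unselected`), `replicate`, `path` (FASTQ or SAM); or
#'   `NULL` when starting from count matrices.
#' @param counts named list of codon-level [mutant_counts()] (alternative
#'   entry point; names `<env>_<pool>_<rep>`).
#' @param reference reference coding sequence (character) or path to a
#'   single-record FASTA.
#' @param reference_environment name of the reference environment.
#' @param feature_table path to a per-substitution feature TSV, or a loaded
#'   `feature_table`, or `NULL` to skip constraint/landscape stages.
#' @param calling a [calling_config()].
#' @param flank5 constant 5' primer-region sequence preceding the CDS in
#'   the reads (passed to [call_fastq()]).
#' @param out_dir output directory (`NULL`: nothing written).
#' @param seed integer seed for all stochastic stages.
#' @param n_draws posterior draws.
#' @return object of class `run_config`.
#' @export
run_config <- function(samples = NULL, counts = NULL, reference,
                       reference_environment, feature_table = NULL,
                       calling = calling_config(), flank5 = "",
                       out_dir = NULL, seed = 1L, n_draws = 1000L) {
  if (is.null(samples) && is.null(counts)) {
    stop("provide either sample read files or count matrices", call. = FALSE)
  }
  if (length(reference) == 1 && file.exists(reference) &&
      grepl("\\.(fa|fasta)$", reference, ignore.case = TRUE)) {
    ref_set <- Biostrings::readDNAStringSet(reference)
    if (length(ref_set) != 1) stop("reference FASTA must contain one record", call. = FALSE)
    reference <- as.character(ref_set[[1]])
  }
  reference <- assert_dna(reference, "reference")
  cfg <- structure(list(samples = samples, counts = counts,
                        reference = reference,
                        reference_environment = reference_environment,
                        feature_table = feature_table, calling = calling,
                        flank5 = flank5,
                        out_dir = out_dir, seed = as.integer(seed),
                        n_draws = as.integer(n_draws)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$samples)) {
    s <- cfg$samples
    need <- c("environment", "pool", "replicate", "path")
    if (!all(need %in% names(s))) {
      stop("samples must have columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    envs <- unique(s$environment)
    for (e in envs) {
      se <- s[s$environment == e, ]
      sel_reps <- sort(se$replicate[se$pool == "selected"])
      uns_reps <- sort(se$replicate[se$pool == "unselected"])
      if (!identical(sel_reps, uns_reps) || length(sel_reps) == 0) {
        stop("environment '", e, "': every selected pool needs a matching unselected pool",
             call. = FALSE)
      }
    }
    if (!(cfg$reference_environment %in% envs)) {
      stop("reference environment '", cfg$reference_environment, "' not among samples",
           call. = FALSE)
    }
  } else {
    nm <- names(cfg$counts)
    envs <- unique(sub("_(selected|unselected)_[0-9]+$", "", nm))
    if (!(cfg$reference_environment %in% envs)) {
      stop("reference environment '", cfg$reference_environment, "' not among count matrices",
           call. = FALSE)
    }
    for (e in envs) {
      sel <- grep(paste0("^", e, "_selected_"), nm, value = TRUE)
      uns <- grep(paste0("^", e, "_unselected_"), nm, value = TRUE)
      if (length(sel) == 0 || length(sel) != length(uns)) {
        stop("environment '", e, "': every selected pool needs a matching unselected pool",
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

sample_key <- function(environment, pool, replicate) {
  sprintf("%s_%s_%s", environment, pool, replicate)
}

#' Run the full analysis pipeline
#'
#' Stages: variant calling (FASTQ/SAM) or count ingestion, amino-acid
#' collapse, fitness scoring with neutrality classification, per-environment
#' selection statistics against the reference environment, and, when a
#' feature table is supplied, constraint analysis and landscape grids.
#' Writes per-environment fitness TSVs, a summary TSV and a JSON run report
#' into `out_dir` when given.
#'
#' @param cfg a [run_config()].
#' @return object of class `dms_report`: `fitness` (list of
#'   `fitness_table`), `summaries`, `summary_table`, `thresholds`,
#'   `correlations`, `subsets`, `subset_selection`, `grids`, `seed`.
#' @export
run_dms <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  # --- stage: counts ---
  counts <- cfg$counts
  if (is.null(counts)) {
    counts <- list()
    for (i in seq_len(nrow(cfg$samples))) {
      s <- cfg$samples[i, ]
      counts[[sample_key(s$environment, s$pool, s$replicate)]] <-
        if (grepl("\\.(sam|bam)$", s$path, ignore.case = TRUE)) {
          call_sam(s$path, cfg$reference, cfg$calling,
                   environment = s$environment, pool = s$pool, replicate = s$replicate)
        } else {
          call_fastq(s$path, cfg$reference, cfg$calling, flank5 = cfg$flank5,
                     environment = s$environment, pool = s$pool, replicate = s$replicate)
        }
    }
  }
  aa <- lapply(counts, collapse_to_aa)
  nm <- names(aa)
  envs <- unique(sub("_(selected|unselected)_[0-9]+$", "", nm))
  # --- stage: scoring ---
  fitness <- list(); thresholds <- list()
  for (e in envs) {
    sel <- aa[sort(grep(paste0("^", e, "_selected_"), nm, value = TRUE))]
    uns <- aa[sort(grep(paste0("^", e, "_unselected_"), nm, value = TRUE))]
    ft <- preferential_enrichment(unname(sel), unname(uns))
    thr <- if (length(uns) >= 2) neutrality_thresholds(unname(uns)) else NULL
    if (!is.null(thr)) ft <- classify_fitness(ft, thr)
    fitness[[e]] <- ft
    thresholds[[e]] <- thr
  }
  # --- stage: selection statistics ---
  ref_ft <- fitness[[cfg$reference_environment]]
  summaries <- list()
  for (e in envs) {
    summaries[[e]] <- environment_summary(fitness[[e]], ref_ft,
                                          n_draws = cfg$n_draws,
                                          seed = cfg$seed + 10L * match(e, envs))
  }
  summary_table <- do.call(rbind, lapply(summaries, function(x) {
    data.frame(environment = x$environment,
               n_non = x$survival$n_non, n_syn = x$survival$n_syn,
               v_non = x$survival$k_non / x$survival$n_non,
               v_syn = x$survival$k_syn / x$survival$n_syn,
               s = x$s, pMCMC_vs_ref = x$pMCMC_vs_ref,
               delta_F = x$delta_F, rho = x$rho,
               n_pos = x$n_pos, n_neg = x$n_neg, pos_neg = x$pos_neg,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_table) <- NULL
  # --- stage: constraints + landscape ---
  correlations <- subsets <- subset_selection <- grids <- NULL
  features <- cfg$feature_table
  if (!is.null(features)) {
    if (is.character(features)) features <- load_feature_table(features)
    correlations <- feature_fitness_correlations(fitness, features)
    subsets <- assign_subsets(features)
    subset_selection <- lapply(seq_along(envs), function(i)
      subsetwise_selection(fitness[[envs[i]]], subsets,
                           n_draws = cfg$n_draws, seed = cfg$seed + 100L * i))
    names(subset_selection) <- envs
    fkey <- paste(features$position, features$wt, features$mut)
    grids <- lapply(fitness, function(ft) {
      sv <- ns_survivors(ft)
      m <- match(paste(sv$position, sv$wt, sv$mut), fkey)
      ok <- !is.na(m)
      build_grid(features$ddG[m[ok]], features$dist_active[m[ok]], sv$F[ok])
    })
  }
  report <- structure(list(fitness = fitness, summaries = summaries,
                           summary_table = summary_table,
                           thresholds = thresholds,
                           correlations = correlations, subsets = subsets,
                           subset_selection = subset_selection, grids = grids,
                           reference_environment = cfg$reference_environment,
                           seed = cfg$seed,
                           version = as.character(utils::packageVersion("envdms"))),
                      class = "dms_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.dms_report <- function(x, ...) {
  cat("DMS run report (reference:", x$reference_environment, ")\n")
  print(x$summary_table, digits = 3)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (e in names(report$fitness)) {
    write_fitness_table(report$fitness[[e]],
                        file.path(out_dir, paste0("fitness_", e, ".tsv")))
  }
  utils::write.table(report$summary_table,
                     file.path(out_dir, "environment_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  thr <- lapply(report$thresholds, function(t)
    if (is.null(t)) NULL else t[c("lower", "upper", "mu0", "sigma0")])
  json <- list(reference_environment = report$reference_environment,
               seed = report$seed, version = report$version,
               neutrality_thresholds = thr,
               environments = stats::setNames(
                 lapply(report$summaries, function(s)
                   list(s = s$s, s_ci = s$s_ci, pMCMC_vs_ref = s$pMCMC_vs_ref,
                        delta_F = s$delta_F, rho = s$rho,
                        n_pos = s$n_pos, n_neg = s$n_neg)),
                 names(report$summaries)))
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes the reference FASTA, mutant catalogue + ground truth TSV, count
#' matrices per sample, and (optionally) FASTQ reads named
#' `<env>_<pool>_<rep>.fastq.gz`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param write_fastq emit FASTQ reads (default `FALSE`; counts are always
#'   written).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with the `catalogue` (with truth columns),
#'   `counts` list, and file `manifest`.
#' @export
simulate_dataset <- function(config, out_dir, write_fastq = FALSE,
                             overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalogue <- generate_library(config)
  truth <- assign_true_features(catalogue, config)
  counts <- simulate_counts(truth, config)
  writeLines(c(">reference", config$reference), file.path(out_dir, "reference.fasta"))
  utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c("reference.fasta", "ground_truth.tsv")
  for (nmi in names(counts)) {
    f <- paste0("counts_", nmi, ".tsv")
    utils::write.table(counts[[nmi]]$counts, file.path(out_dir, f),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, f)
    if (write_fastq) {
      fq <- paste0(nmi, ".fastq.gz")
      emit_reads(counts[[nmi]], config, file.path(out_dir, fq))
      manifest <- c(manifest, fq)
    }
  }
  invisible(list(catalogue = truth, counts = counts, manifest = manifest))
}

#' Recompute environment statistics from written fitness tables
#'
#' Reproduction mode: reads per-environment fitness tables (as written by
#' [write_fitness_table()] or an equivalent deposited table with columns
#' `id`, `position`, `wt`, `mut`, `synonymous`, `F`, `survived`) and
#' recomputes s point estimates, delta-F and rho against the named reference
#' environment.
#'
#' @param paths named character vector of TSV paths (names = environment).
#' @param reference_environment name of the reference environment.
#' @param n_draws,seed posterior draw settings.
#' @return data.frame with `environment`, `s`, `delta_F`, `rho`.
#' @export
reproduce_stats <- function(paths, reference_environment, n_draws = 1000L,
                            seed = 1L) {
  stopifnot(reference_environment %in% names(paths))
  tabs <- lapply(paths, read_fitness_table)
  for (e in names(tabs)) attr(tabs[[e]], "environment") <- e
  ref <- tabs[[reference_environment]]
  out <- do.call(rbind, lapply(names(tabs), function(e) {
    ft <- tabs[[e]]
    post <- survival_posterior(survival_data(ft), n_draws,
                               seed + match(e, names(tabs)))
    data.frame(environment = e, s = post$s_mean,
               delta_F = delta_F(ft, ref), rho = robustness_rho(ft, ref),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
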