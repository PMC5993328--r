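# Fitness scoring: depth-normalized frequencies, log2 preferential
# enrichment vs the unselected pool, neutrality thresholds from
# unselected-vs-unselected replicate enrichments, and neutrality classes.

#' Depth-normalize a count matrix
#'
#' frequency(i) = count(i) / depth(position(i)), per sample.
#'
#' @param x a [mutant_counts()].
#' @return data.frame `counts` with an added `freq` column.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "mutant_counts"))
  tab <- x$counts
  d <- x$depth[tab$position]
  if (any(d <= 0 & tab$count > 0)) {
    stop("zero depth at position(s) carrying nonzero counts: inconsistent matrix",
         call. = FALSE)
  }
  tab$freq <- ifelse(tab$count == 0, 0, tab$count / d)
  tab
}

mutant_key <- function(tab) paste(tab$position, tab$wt, tab$mut, sep = "|")

#' Per-environment fitness scores from selected/unselected pool pairs
#'
#' For each replicate r, `F_r(i) = log2(freq_selected(i) / freq_unselected(i))`
#' with depth-normalized frequencies. The per-environment score `F` is the
#' mean of the per-replicate scores (not the score of pooled counts). A
#' mutant absent (zero count after filters) from any selected replicate is
#' marked eliminated: `survived = FALSE` and `F = NA` (null fitness marker).
#' Mutants absent from an unselected replicate cannot be scored and are
#' excluded with a warning.
#'
#' No pseudocounts by default; `pseudocount > 0` adds it to both counts
#' before normalization (elimination is then decided before its addition).
#'
#' @param selected,unselected lists of [mutant_counts()], one per replicate
#'   (paired by list order), same level and environment.
#' @param pseudocount numeric >= 0 (default 0).
#' @return a `fitness_table` data.frame: `id`, `position`, `wt`, `mut`,
#'   `synonymous`, `stop`, one `F_rep<k>` column per replicate, `F`,
#'   `survived`, `class` (filled by [classify_fitness()], `NA` until then);
#'   attribute `environment`.
#' @export
preferential_enrichment <- function(selected, unselected, pseudocount = 0) {
  stopifnot(length(selected) == length(unselected), length(selected) >= 1)
  n_rep <- length(selected)
  lev <- selected[[1]]$level
  # union of mutants seen in any unselected replicate defines the scorable set
  uns_tabs <- lapply(unselected, normalize_counts)
  sel_tabs <- lapply(selected, normalize_counts)
  base <- uns_tabs[[1]][, intersect(c("position", "wt", "mut", "synonymous", "stop"),
                                    names(uns_tabs[[1]])), drop = FALSE]
  for (k in seq_len(n_rep)[-1]) {
    extra <- uns_tabs[[k]][!(mutant_key(uns_tabs[[k]]) %in% mutant_key(base)),
                           names(base), drop = FALSE]
    base <- rbind(base, extra)
  }
  base <- base[order(base$position, base$wt, base$mut), , drop = FALSE]
  key <- mutant_key(base)
  # mutants missing from some unselected replicate cannot be scored
  in_all_uns <- Reduce(`&`, lapply(uns_tabs, function(t)
    key %in% mutant_key(t)[t$count > 0]))
  if (any(!in_all_uns)) {
    warning(sum(!in_all_uns),
            " mutant(s) absent from an unselected replicate excluded (cannot be scored)")
    base <- base[in_all_uns, , drop = FALSE]
    key <- key[in_all_uns]
  }
  if (!"synonymous" %in% names(base)) base$synonymous <- NA
  if (!"stop" %in% names(base)) base$stop <- NA
  f_rep <- matrix(NA_real_, nrow(base), n_rep)
  present_sel <- matrix(FALSE, nrow(base), n_rep)
  for (k in seq_len(n_rep)) {
    su <- uns_tabs[[k]][match(key, mutant_key(uns_tabs[[k]])), ]
    ss <- sel_tabs[[k]][match(key, mutant_key(sel_tabs[[k]])), ]
    sel_count <- ifelse(is.na(ss$count), 0, ss$count)
    present_sel[, k] <- sel_count > 0
    fu <- su$count + pseudocount
    fs <- sel_count + pseudocount
    du <- unselected[[k]]$depth[base$position]
    ds <- selected[[k]]$depth[base$position]
    f_rep[, k] <- log2((fs / ds) / (fu / du))
  }
  survived <- apply(present_sel, 1, all)
  f_rep[!survived, ] <- NA_real_
  if (pseudocount == 0) f_rep[is.infinite(f_rep)] <- NA_real_
  out <- data.frame(
    id = if (lev == "amino_acid") aa_sub_id(base$position, base$wt, base$mut)
         else codon_sub_id(base$position, base$wt, base$mut),
    position = base$position, wt = base$wt, mut = base$mut,
    synonymous = base$synonymous, stop = base$stop,
    stringsAsFactors = FALSE)
  for (k in seq_len(n_rep)) out[[paste0("F_rep", k)]] <- f_rep[, k]
  out$F <- rowMeans(f_rep)
  out$survived <- survived
  out$class <- ifelse(survived, NA_character_, "eliminated")
  rownames(out) <- NULL
  structure(out, environment = selected[[1]]$environment,
            class = c("fitness_table", "data.frame"))
}

#' Neutrality thresholds from unselected replicate pairs
#'
#' Computes per-mutant enrichments of unselected replicate A vs B (all
#' ordered pairs i < j when more than two replicates exist), fits their mean
#' and SD, and returns `mu0 +- 2 sigma0`.
#'
#' @param unselected list of >= 2 unselected [mutant_counts()] replicates.
#' @return list with `lower`, `upper`, `mu0`, `sigma0`, class
#'   `neutrality_thresholds`.
#' @export
neutrality_thresholds <- function(unselected) {
  if (length(unselected) < 2) stop("need >= 2 unselected replicates", call. = FALSE)
  tabs <- lapply(unselected, normalize_counts)
  enr <- numeric(0)
  for (i in seq_along(tabs)) for (j in seq_along(tabs)) {
    if (i >= j) next
    a <- tabs[[i]]; b <- tabs[[j]]
    m <- match(mutant_key(a), mutant_key(b))
    fa <- a$freq; fb <- b$freq[m]
    ok <- !is.na(fb) & fa > 0 & fb > 0
    enr <- c(enr, log2(fa[ok] / fb[ok]))
  }
  mu0 <- mean(enr)
  sigma0 <- stats::sd(enr)
  if (length(enr) == 1 || !is.finite(sigma0)) sigma0 <- 0
  structure(list(lower = mu0 - 2 * sigma0, upper = mu0 + 2 * sigma0,
                 mu0 = mu0, sigma0 = sigma0),
            class = "neutrality_thresholds")
}

#' Assign neutrality classes
#'
#' Surviving mutants are `enriched` above the upper threshold, `depleted`
#' below the lower one, and `neutral` inside the closed interval
#' `[lower, upper]`. Eliminated mutants keep the `eliminated` class.
#'
#' @param ft a `fitness_table` from [preferential_enrichment()].
#' @param thresholds a [neutrality_thresholds()] result.
#' @return `ft` with the `class` column filled.
#' @export
classify_fitness <- function(ft, thresholds) {
  stopifnot(inherits(ft, "fitness_table"), inherits(thresholds, "neutrality_thresholds"))
  cls <- ft$class
  surv <- ft$survived & !is.na(ft$F)
  cls[surv] <- ifelse(ft$F[surv] > thresholds$upper, "enriched",
                      ifelse(ft$F[surv] < thresholds$lower, "depleted", "neutral"))
  ft$class <- cls
  ft
}

#' Write / read a fitness table as TSV
#'
#' @param ft a `fitness_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(ft, path) {
  df <- as.data.frame(ft)
  df$environment <- attr(ft, "environment")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_table
#' @export
read_fitness_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  env <- if ("environment" %in% names(df)) df$environment[1] else "env"
  df$environment <- NULL
  structure(df, environment = env, class = c("fitness_table", "data.frame"))
}
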