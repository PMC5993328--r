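# Biophysical-constraint analysis: Spearman feature-fitness correlation
# matrix with hierarchical clustering, folding x binding mutant subsets
# (FB / cFB / FcB / cFcB at the feature medians with a percentile exclusion
# band), subset-wise selection coefficients, exact Mann-Whitney comparisons,
# and bootstrap cross-environment correlation resampling per subset.

ns_survivors <- function(ft) {
  ft[ft$survived & !is.na(ft$F) & !ft$synonymous & !(ft$stop %in% TRUE), , drop = FALSE]
}

#' Feature-fitness Spearman correlation matrix
#'
#' One cell per (feature, environment): Spearman's r_s and two-sided p-value
#' between the feature and the fitness scores of surviving non-synonymous
#' mutants, missing features dropped pairwise. Cells with fewer than
#' `min_n` complete pairs, or a constant feature, are `NA`.
#'
#' @param fitness_tables named list of `fitness_table`s (one per
#'   environment).
#' @param features a `feature_table` (keyed `position`, `wt`, `mut`).
#' @param min_n minimum complete pairs per cell (default 10).
#' @return object of class `correlation_matrix`: matrices `r`, `p`, `n`
#'   (features x environments).
#' @export
feature_fitness_correlations <- function(fitness_tables, features, min_n = 10L) {
  feats <- intersect(feature_cols, names(features))
  fkey <- paste(features$position, features$wt, features$mut)
  envs <- names(fitness_tables)
  r <- p <- nm <- matrix(NA_real_, length(feats), length(envs),
                         dimnames = list(feats, envs))
  for (e in envs) {
    ft <- ns_survivors(fitness_tables[[e]])
    m <- match(paste(ft$position, ft$wt, ft$mut), fkey)
    for (fc in feats) {
      x <- features[[fc]][m]
      ok <- !is.na(x) & is.finite(x) & !is.na(ft$F)
      n_ok <- sum(ok)
      nm[fc, e] <- n_ok
      if (n_ok < min_n || length(unique(x[ok])) < 2) next
      ct <- suppressWarnings(stats::cor.test(x[ok], ft$F[ok], method = "spearman",
                                             exact = FALSE))
      r[fc, e] <- unname(ct$estimate)
      p[fc, e] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nm), class = "correlation_matrix")
}

#' Cluster the correlation matrix
#'
#' Agglomerative hierarchical clustering (Euclidean distance on the rows /
#' columns of the r_s matrix, average linkage); leaf orders are
#' deterministic, ties broken by input order.
#'
#' @param cm a [feature_fitness_correlations()] result or a plain numeric
#'   matrix.
#' @return list with `row_order`, `col_order` (integer leaf orders) and the
#'   two `hclust` objects.
#' @export
cluster_correlations <- function(cm) {
  r <- if (inherits(cm, "correlation_matrix")) cm$r else cm
  if (any(apply(r, 1, function(v) all(is.na(v)))) ||
      any(apply(r, 2, function(v) all(is.na(v))))) {
    stop("all-NA rows/columns cannot be clustered", call. = FALSE)
  }
  r0 <- r
  r0[is.na(r0)] <- 0
  hr <- stats::hclust(stats::dist(r0, method = "euclidean"), method = "average")
  hc <- stats::hclust(stats::dist(t(r0), method = "euclidean"), method = "average")
  list(row_order = hr$order, col_order = hc$order, row_hclust = hr, col_hclust = hc)
}

#' Assign folding x binding subsets
#'
#' Cutoffs are the medians of ddG (m_G) and distance-to-active-site (m_D)
#' over all non-synonymous mutants. Proper folding F means `ddG <= m_G`;
#' proper binding B means `distance >= m_D`. Mutants whose midrank
#' percentile on either axis falls in the open (50 - band, 50 + band)
#' interval (default band 10: the 40th-60th percentile window around the
#' median) are excluded, reducing the influence of feature uncertainty.
#'
#' @param features a `feature_table` (or truth table) with `ddG` and
#'   `dist_active`; synonymous entries (if flagged) are ignored.
#' @param band half-width of the exclusion window, percentile points
#'   (default 10).
#' @return data.frame `position`, `wt`, `mut`, `subset` in
#'   {FB, cFB, FcB, cFcB, excluded}; attributes `m_G`, `m_D`.
#' @export
assign_subsets <- function(features, band = 10) {
  df <- as.data.frame(features)
  if ("synonymous" %in% names(df)) df <- df[!df$synonymous, , drop = FALSE]
  if (!all(c("ddG", "dist_active") %in% names(df))) {
    stop("features must carry ddG and dist_active", call. = FALSE)
  }
  ok <- is.finite(df$ddG) & is.finite(df$dist_active)
  g <- df$ddG; d <- df$dist_active
  if (length(unique(g[ok])) < 2 || length(unique(d[ok])) < 2) {
    stop("degenerate feature distribution: medians do not separate mutants", call. = FALSE)
  }
  m_g <- stats::median(g[ok]); m_d <- stats::median(d[ok])
  pg <- pd <- rep(NA_real_, nrow(df))
  pg[ok] <- percentile_rank(g[ok])
  pd[ok] <- percentile_rank(d[ok])
  in_band <- function(p) p > 50 - band & p < 50 + band
  subset <- rep("excluded", nrow(df))
  assignable <- ok & !in_band(pg) & !in_band(pd)
  fold_ok <- g <= m_g
  bind_ok <- d >= m_d
  subset[assignable & fold_ok & bind_ok] <- "FB"
  subset[assignable & !fold_ok & bind_ok] <- "cFB"
  subset[assignable & fold_ok & !bind_ok] <- "FcB"
  subset[assignable & !fold_ok & !bind_ok] <- "cFcB"
  out <- data.frame(position = df$position,
                    wt = if ("wt" %in% names(df)) df$wt else df$wt_aa,
                    mut = if ("mut" %in% names(df)) df$mut else df$mut_aa,
                    subset = subset, stringsAsFactors = FALSE)
  structure(out, m_G = m_g, m_D = m_d, band = band,
            class = c("subset_assignment", "data.frame"))
}

#' Subset-wise selection coefficient posteriors
#'
#' s per subset and environment, with the non-synonymous class restricted to
#' the subset's mutants and the synonymous class unrestricted (synonymous
#' mutants have no substitution identity on the feature axes).
#'
#' @param fitness_table an amino-acid-level `fitness_table`.
#' @param subsets a [assign_subsets()] result.
#' @param n_draws,seed passed to [survival_posterior()].
#' @return named list of `selection_posterior` per subset (`NULL` with a
#'   warning for empty subsets).
#' @export
subsetwise_selection <- function(fitness_table, subsets, n_draws = 1000L, seed = 1L) {
  ft <- fitness_table
  syn <- ft[!is.na(ft$synonymous) & ft$synonymous, , drop = FALSE]
  skey <- paste(subsets$position, subsets$wt, subsets$mut)
  fkey <- paste(ft$position, ft$wt, ft$mut)
  out <- list()
  for (sb in c("FB", "cFB", "FcB", "cFcB")) {
    members <- skey[subsets$subset == sb]
    rows <- ft[fkey %in% members & !ft$synonymous & !(ft$stop %in% TRUE), , drop = FALSE]
    if (nrow(rows) == 0) {
      warning("empty subset ", sb)
      out[[sb]] <- NULL
      next
    }
    dat <- list(k_non = sum(rows$survived), n_non = nrow(rows),
                k_syn = sum(syn$survived), n_syn = nrow(syn),
                environment = paste0(attr(ft, "environment"), ":", sb))
    out[[sb]] <- survival_posterior(dat, n_draws, seed + match(sb, c("FB", "cFB", "FcB", "cFcB")))
  }
  out
}

# Exact Mann-Whitney U: number of (x, y) pairs with x > y (+0.5 per tie).
mann_whitney_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' One-sided Mann-Whitney test by exact enumeration
#'
#' Tests `alternative: y stochastically greater than x` (p = Pr(U_y >= u_y)
#' under the permutation null). Exact enumeration of all
#' choose(n_x + n_y, n_x) group assignments for n <= `exact_max` per group;
#' normal approximation with tie correction beyond.
#'
#' @param x,y numeric vectors (per-environment s point estimates of two
#'   subsets).
#' @param exact_max use enumeration when both groups are at most this size
#'   (default 12; the study's designs have 7-8 environments).
#' @return list with `U` (of `y`), `p`.
#' @export
mann_whitney_greater <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  u_y <- mann_whitney_u(y, x)
  if (nx <= exact_max && ny <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(nx + ny, ny)
    us <- apply(idx, 2, function(iy) mann_whitney_u(pooled[iy], pooled[-iy]))
    p <- mean(us >= u_y - 1e-12)
  } else {
    mu <- nx * ny / 2
    ties <- table(c(x, y))
    n <- nx + ny
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- stats::pnorm((u_y - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
  list(U = u_y, p = p)
}

#' Compare subset s vectors against FB across environments
#'
#' One-sided Mann-Whitney tests (alternative: the other subset's s values
#' are greater than FB's), one per non-FB subset, treating each
#' environment's s point estimate as one observation.
#'
#' @param s_matrix numeric matrix, rows = subsets (must include "FB"),
#'   columns = environments, cells = s point estimates.
#' @return data.frame `subset`, `U`, `p`.
#' @export
subset_significance <- function(s_matrix) {
  stopifnot("FB" %in% rownames(s_matrix), ncol(s_matrix) >= 4)
  others <- setdiff(rownames(s_matrix), "FB")
  res <- lapply(others, function(sb) {
    mw <- mann_whitney_greater(s_matrix["FB", ], s_matrix[sb, ])
    data.frame(subset = sb, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bootstrap cross-environment correlation per subset
#'
#' For each subset, resamples (with replacement, B times) the mutants
#' surviving in both environments and records the Spearman correlation of
#' their fitness scores per resample; reports median, 50% and 95% intervals.
#' Subset pairs are compared on the paired resample draws:
#' `P_MCMC = 2 * min(Pr(rho_A - rho_B > 0), Pr(rho_A - rho_B < 0))`,
#' floored at 1/B.
#'
#' @param test,ref `fitness_table`s of the environment pair.
#' @param subsets a [assign_subsets()] result.
#' @param B bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param min_size minimum common survivors per subset (default 5).
#' @return object of class `subset_crossenv`: `draws` (B x subsets matrix),
#'   `summary` data.frame, `contrasts` data.frame with `P_MCMC`.
#' @export
cross_env_correlation_resample <- function(test, ref, subsets, B = 1000L,
                                           seed = 1L, min_size = 5L) {
  tkey <- test$id; rkey <- ref$id
  ok_t <- test$survived & !is.na(test$F) & !test$synonymous & !(test$stop %in% TRUE)
  ok_r <- ref$survived & !is.na(ref$F) & !ref$synonymous & !(ref$stop %in% TRUE)
  skey <- aa_sub_id(subsets$position, subsets$wt, subsets$mut)
  sbs <- c("FB", "cFB", "FcB", "cFcB")
  draws <- matrix(NA_real_, B, length(sbs), dimnames = list(NULL, sbs))
  withr_seed(seed, {
    for (sb in sbs) {
      members <- skey[subsets$subset == sb]
      common <- intersect(intersect(tkey[ok_t], rkey[ok_r]), members)
      if (length(common) < min_size) {
        warning("subset ", sb, " below minimum size (", length(common), ")")
        next
      }
      ft <- test$F[match(common, tkey)]
      fr <- ref$F[match(common, rkey)]
      n <- length(common)
      for (b in seq_len(B)) {
        i <- sample.int(n, n, replace = TRUE)
        draws[b, sb] <- stats::cor(ft[i], fr[i], method = "spearman")
      }
    }
  })
  summ <- do.call(rbind, lapply(sbs, function(sb) {
    d <- draws[, sb]
    if (all(is.na(d))) {
      data.frame(subset = sb, median = NA, l50 = NA, u50 = NA, l95 = NA, u95 = NA)
    } else {
      q <- stats::quantile(d, c(0.5, 0.25, 0.75, 0.025, 0.975), names = FALSE)
      data.frame(subset = sb, median = q[1], l50 = q[2], u50 = q[3],
                 l95 = q[4], u95 = q[5])
    }
  }))
  pairs <- utils::combn(sbs, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- draws[, a] - draws[, b]
    p <- if (all(is.na(d))) NA_real_ else {
      d <- d[!is.na(d)]
      max(2 * min(mean(d > 0), mean(d < 0)), 1 / B)
    }
    data.frame(subset_a = a, subset_b = b, P_MCMC = p, stringsAsFactors = FALSE)
  }))
  structure(list(draws = draws, summary = summ, contrasts = contrasts,
                 B = B, method = "bootstrap over common survivors"),
            class = "subset_crossenv")
}
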