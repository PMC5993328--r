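# Environment-level selection statistics: viability selection coefficient s
# with conjugate Bayesian posteriors and cross-environment contrasts, delta-F,
# mutational robustness rho, and the n_pos/n_neg ratio with replicate-noise
# thresholds.

#' Survival counts of the two mutant classes
#'
#' @param fitness_table an amino-acid-level `fitness_table`; stop-codon
#'   variants are excluded from both classes.
#' @return object of class `survival_data` with `k_non`, `n_non`, `k_syn`,
#'   `n_syn`.
#' @export
survival_data <- function(fitness_table) {
  stopifnot(inherits(fitness_table, "fitness_table"))
  ft <- fitness_table[!is.na(fitness_table$synonymous), , drop = FALSE]
  ft <- ft[!(ft$stop %in% TRUE), , drop = FALSE]
  non <- ft[!ft$synonymous, , drop = FALSE]
  syn <- ft[ft$synonymous, , drop = FALSE]
  structure(list(k_non = sum(non$survived), n_non = nrow(non),
                 k_syn = sum(syn$survived), n_syn = nrow(syn),
                 environment = attr(fitness_table, "environment")),
            class = "survival_data")
}

#' Posterior of the mean viability selection coefficient s
#'
#' Survival of each class is a binomial response with a flat prior on the
#' probability scale: `v_non ~ Beta(k_non + 1, n_non - k_non + 1)` and
#' `v_syn ~ Beta(k_syn + 1, n_syn - k_syn + 1)`, drawn independently. Each
#' paired draw gives `s = 1 - v_non / v_syn`; the point estimate is the
#' posterior mean over `n_draws` draws (1000 by default, mirroring thinned
#' MCMC output).
#'
#' @param data a [survival_data()] (list with `k_non`, `n_non`, `k_syn`,
#'   `n_syn` also accepted).
#' @param n_draws number of posterior draws.
#' @param seed integer seed for the draws.
#' @return object of class `selection_posterior`: `draws` (data.frame
#'   `v_non`, `v_syn`, `s`), `s_mean`, `ci` (95% equal-tailed).
#' @export
survival_posterior <- function(data, n_draws = 1000L, seed = 1L) {
  stopifnot(data$n_non > 0, data$n_syn > 0,
            data$k_non >= 0, data$k_non <= data$n_non,
            data$k_syn >= 0, data$k_syn <= data$n_syn)
  if (data$k_syn == 0) {
    stop("k_syn = 0: selection coefficient undefined against an extinct synonymous class",
         call. = FALSE)
  }
  draws <- withr_seed(seed, {
    v_non <- stats::rbeta(n_draws, data$k_non + 1, data$n_non - data$k_non + 1)
    v_syn <- stats::rbeta(n_draws, data$k_syn + 1, data$n_syn - data$k_syn + 1)
    data.frame(v_non = v_non, v_syn = v_syn, s = 1 - v_non / v_syn)
  })
  structure(list(draws = draws, s_mean = mean(draws$s),
                 ci = stats::quantile(draws$s, c(0.025, 0.975), names = FALSE),
                 environment = data$environment %||% NA_character_),
            class = "selection_posterior")
}

#' @export
print.selection_posterior <- function(x, ...) {
  cat(sprintf("s posterior (%s): mean %.4f, 95%% CI [%.4f, %.4f], %d draws\n",
              x$environment, x$s_mean, x$ci[1], x$ci[2], nrow(x$draws)))
  invisible(x)
}

#' Bayesian contrast of two s posteriors
#'
#' `Delta = s_A - s_B` per paired draw;
#' `pMCMC = 2 * min(Pr(Delta >= 0), Pr(Delta <= 0))`, floored at `1/n_draws`
#' and capped at 1 (tie-inclusive tails, so identical posteriors give 1).
#'
#' @param a,b `selection_posterior` objects with equal draw counts.
#' @return list with `delta_mean`, `pMCMC`.
#' @export
contrast_s <- function(a, b) {
  stopifnot(inherits(a, "selection_posterior"), inherits(b, "selection_posterior"),
            nrow(a$draws) == nrow(b$draws))
  delta <- a$draws$s - b$draws$s
  n <- length(delta)
  # tie-inclusive tails: identical posteriors give p = 1, not 0
  p <- 2 * min(mean(delta >= 0), mean(delta <= 0))
  p <- min(1, max(p, 1 / n))
  list(delta_mean = mean(delta), pMCMC = p)
}

#' Change in average fitness between environments
#'
#' `delta_F = mean(F over non-synonymous mutants surviving in the test
#' environment) - mean(F over non-synonymous mutants surviving in the
#' reference environment)`; per-environment survivor sets, not their
#' intersection (elimination of highly deleterious mutants is part of the
#' signal).
#'
#' @param test,ref `fitness_table`s.
#' @return numeric delta-F (log2 units).
#' @export
delta_F <- function(test, ref) {
  f_of <- function(ft) {
    x <- ft[ft$survived & !is.na(ft$F) & !ft$synonymous & !(ft$stop %in% TRUE), "F"]
    if (length(x) == 0) stop("no surviving non-synonymous mutants", call. = FALSE)
    mean(x)
  }
  f_of(test) - f_of(ref)
}

#' Mutational robustness: rank correlation with the reference environment
#'
#' Spearman rank correlation of F over non-synonymous mutants surviving in
#' both environments (average ranks under ties).
#'
#' @param test,ref `fitness_table`s.
#' @return Spearman rho in [-1, 1].
#' @export
robustness_rho <- function(test, ref) {
  key_t <- test$id; key_r <- ref$id
  ok_t <- test$survived & !is.na(test$F) & !test$synonymous & !(test$stop %in% TRUE)
  ok_r <- ref$survived & !is.na(ref$F) & !ref$synonymous & !(ref$stop %in% TRUE)
  common <- intersect(key_t[ok_t], key_r[ok_r])
  if (length(common) < 3) stop("fewer than 3 common survivors", call. = FALSE)
  stats::cor(test$F[match(common, key_t)], ref$F[match(common, key_r)],
             method = "spearman")
}

#' Counts of mutants with positive/negative effects vs the reference
#'
#' Within-replicate fitness changes (F_rep_i - F_rep_j over all ordered
#' replicate pairs i < j, over surviving mutants) give the noise scale of
#' each environment: means `mu_test`, `mu_ref` and SDs `sigma_test`,
#' `sigma_ref`. The noise thresholds are
#' `T = (mu_test + mu_ref)/2 +- 2 * sqrt((sigma_test^2 + sigma_ref^2)/2)`.
#' A mutant undergoes a positive effect if its between-environment change
#' `F_test - F_ref` exceeds `T_plus`, negative if below `T_minus`.
#'
#' @param test,ref `fitness_table`s with >= 2 replicate columns.
#' @return list with `n_pos`, `n_neg`, `ratio` (`Inf` when `n_neg` is 0 and
#'   `n_pos` > 0), `T_plus`, `T_minus`, `mu`, `sigma` per environment.
#' @export
pos_neg_ratio <- function(test, ref) {
  within_changes <- function(ft) {
    reps <- grep("^F_rep", names(ft), value = TRUE)
    if (length(reps) < 2) stop("need >= 2 replicates", call. = FALSE)
    keep <- ft$survived & !ft$synonymous & !(ft$stop %in% TRUE)
    d <- numeric(0)
    for (i in seq_along(reps)) for (j in seq_along(reps)) {
      if (i >= j) next
      d <- c(d, ft[keep, reps[i]] - ft[keep, reps[j]])
    }
    d[!is.na(d)]
  }
  dt <- within_changes(test); dr <- within_changes(ref)
  mu_t <- mean(dt); mu_r <- mean(dr)
  s_t <- stats::sd(dt); s_r <- stats::sd(dr)
  centre <- (mu_t + mu_r) / 2
  half <- 2 * sqrt((s_t^2 + s_r^2) / 2)
  t_plus <- centre + half; t_minus <- centre - half
  ok_t <- test$survived & !is.na(test$F) & !test$synonymous & !(test$stop %in% TRUE)
  ok_r <- ref$survived & !is.na(ref$F) & !ref$synonymous & !(ref$stop %in% TRUE)
  common <- intersect(test$id[ok_t], ref$id[ok_r])
  between <- test$F[match(common, test$id)] - ref$F[match(common, ref$id)]
  n_pos <- sum(between > t_plus)
  n_neg <- sum(between < t_minus)
  ratio <- if (n_neg == 0) {
    if (n_pos == 0) NaN else Inf
  } else n_pos / n_neg
  list(n_pos = n_pos, n_neg = n_neg, ratio = ratio,
       T_plus = t_plus, T_minus = t_minus,
       mu = c(test = mu_t, ref = mu_r), sigma = c(test = s_t, ref = s_r))
}

#' Summarize one environment against the reference
#'
#' Bundles the four environment-characterization parameters: s (posterior),
#' delta-F, rho and n_pos/n_neg, plus the pMCMC of the s contrast.
#'
#' @param test,ref `fitness_table`s (test may equal ref for the reference
#'   row).
#' @param n_draws,seed passed to [survival_posterior()].
#' @return list of class `environment_summary`.
#' @export
environment_summary <- function(test, ref, n_draws = 1000L, seed = 1L) {
  sd_t <- survival_data(test)
  sd_r <- survival_data(ref)
  post_t <- survival_posterior(sd_t, n_draws, seed)
  post_r <- survival_posterior(sd_r, n_draws, seed + 1L)
  pn <- pos_neg_ratio(test, ref)
  structure(list(
    environment = attr(test, "environment"),
    reference = attr(ref, "environment"),
    survival = sd_t,
    s = post_t$s_mean, s_ci = post_t$ci, posterior = post_t,
    pMCMC_vs_ref = contrast_s(post_t, post_r)$pMCMC,
    delta_F = delta_F(test, ref),
    rho = robustness_rho(test, ref),
    n_pos = pn$n_pos, n_neg = pn$n_neg, pos_neg = pn$ratio,
    T_plus = pn$T_plus, T_minus = pn$T_minus
  ), class = "environment_summary")
}

#' @export
print.environment_summary <- function(x, ...) {
  cat(sprintf("%s vs %s: s=%.3f, dF=%.3f, rho=%.3f, n_pos/n_neg=%s (pMCMC=%.3g)\n",
              x$environment, x$reference, x$s, x$delta_F, x$rho,
              format(x$pos_neg, digits = 3), x$pMCMC_vs_ref))
  invisible(x)
}
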