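make_feat <- function(position, wt, mut, ddG, dist_active, ...) {
  structure(data.frame(position = position, wt = wt, mut = mut, ddG = ddG,
                       dist_active = dist_active, ..., stringsAsFactors = FALSE),
            class = c("feature_table", "data.frame"))
}

test_that("feature-fitness correlation matrix is Spearman per cell", {
  n <- 60
  set.seed(21)
  f <- sort(rnorm(n))
  ft <- make_ft(paste0("m", 1:n), F_rep1 = f)
  feats <- make_feat(1:n, "A", "V", ddG = rank(f), dist_active = 10)
  cm <- feature_fitness_correlations(list(envA = ft), feats)
  expect_equal(unname(cm$r["ddG", "envA"]), 1)
  # constant feature: undefined, NA
  expect_true(is.na(cm$r["dist_active", "envA"]))
  expect_equal(unname(cm$n["ddG", "envA"]), n)
  # permuted (independent) feature stays near 0 in nearly all seeds
  hits <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    n2 <- 500
    f2 <- rnorm(n2)
    ft2 <- make_ft(paste0("m", 1:n2), F_rep1 = f2)
    feats2 <- make_feat(1:n2, "A", "V", ddG = sample(f2), dist_active = runif(n2))
    cm2 <- feature_fitness_correlations(list(e = ft2), feats2)
    if (abs(cm2$r["ddG", "e"]) < 0.15) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # below min_n: NA
  small <- feature_fitness_correlations(list(e = make_ft(paste0("m", 1:5), F_rep1 = rnorm(5))),
                                        make_feat(1:5, "A", "V", rnorm(5), runif(5)))
  expect_true(is.na(small$r["ddG", "e"]))
})

test_that("correlation clustering is deterministic average-linkage Euclidean", {
  r <- rbind(a = c(0.9, 0.8, 0.7), b = c(0.9, 0.8, 0.7), c = c(-0.5, -0.4, -0.3))
  colnames(r) <- c("e1", "e2", "e3")
  cl <- cluster_correlations(r)
  # identical rows merge first at height 0
  expect_equal(cl$row_hclust$height[1], 0)
  expect_equal(sort(cl$row_hclust$merge[1, ]), c(-2, -1))
  # 3-point hand agglomeration: d(a,b)=0; d({a,b},c) = mean of pairwise dists
  d_ac <- sqrt(sum((r["a", ] - r["c", ])^2))
  expect_equal(cl$row_hclust$height[2], d_ac) # d_bc == d_ac here
  # permuting input order leaves merge heights unchanged
  perm <- r[c(3, 1, 2), ]
  expect_equal(sort(cluster_correlations(perm)$row_hclust$height),
               sort(cl$row_hclust$height))
})

test_that("subset assignment respects medians and the exclusion band", {
  # 100 mutants with known percentile structure
  g <- seq(0.5, 100, by = 0.5)[1:100]         # strictly increasing ddG
  d <- rev(seq(0.5, 100, by = 0.5)[1:100])    # strictly decreasing distance
  feats <- make_feat(1:100, "A", "V", ddG = g, dist_active = d)
  sa <- assign_subsets(feats, band = 10)
  # mutant at the 5th ddG percentile has the 95th distance percentile: FB
  expect_equal(sa$subset[5], "FB")
  expect_equal(sa$subset[96], "cFcB")
  # 45th percentile on either axis: excluded regardless of the other
  expect_equal(sa$subset[45], "excluded")
  expect_equal(sa$subset[55], "excluded")
  # percentile-based labels are invariant to monotone rescaling
  sa2 <- assign_subsets(make_feat(1:100, "A", "V", ddG = exp(g / 20),
                                  dist_active = d^3), band = 10)
  expect_equal(sa2$subset, sa$subset)
  expect_error(assign_subsets(make_feat(1:5, "A", "V", ddG = 1, dist_active = 1)),
               "degenerate")
})

test_that("uniform features give ~16% per subset, matching a brute-force oracle", {
  set.seed(33)
  n <- 1000
  g <- runif(n); d <- runif(n)
  feats <- make_feat(1:n, "A", "V", ddG = g, dist_active = d)
  sa <- assign_subsets(feats, band = 10)
  # independent classification: order-statistic percentiles
  perc <- function(x) 100 * (rank(x, ties.method = "average") - 0.5) / length(x)
  pg <- perc(g); pd <- perc(d)
  excl <- (pg > 40 & pg < 60) | (pd > 40 & pd < 60)
  lab <- ifelse(excl, "excluded",
                ifelse(g <= median(g) & d >= median(d), "FB",
                       ifelse(g > median(g) & d >= median(d), "cFB",
                              ifelse(g <= median(g), "FcB", "cFcB"))))
  expect_equal(sa$subset, lab)
  counts <- table(sa$subset)[c("FB", "cFB", "FcB", "cFcB")]
  expect_true(all(abs(counts - 160) < 50))
})

test_that("subset-wise selection restricts the non-synonymous class only", {
  s <- scored_experiment()
  ft <- s$fitness$heat
  feats <- truth_features(s$truth)
  sa <- assign_subsets(feats, band = 0)   # no exclusion: subsets partition
  posts <- suppressWarnings(subsetwise_selection(ft, sa, n_draws = 500, seed = 3))
  # restriction identity: all subsets together equal the global counts
  sdat <- survival_data(ft)
  ktot <- 0; ntot <- 0
  fkey <- paste(ft$position, ft$wt, ft$mut)
  for (sb in names(posts)) {
    members <- paste(sa$position, sa$wt, sa$mut)[sa$subset == sb]
    rows <- ft[fkey %in% members & !ft$synonymous & !(ft$stop %in% TRUE), ]
    ktot <- ktot + sum(rows$survived); ntot <- ntot + nrow(rows)
  }
  expect_equal(ntot, sdat$n_non)
  expect_equal(ktot, sdat$k_non)
  # two-mutant toy subset matches the closed-form Beta posterior mean
  toy_ft <- make_ft(c("A1V", "A2V", "S1S"), F_rep1 = c(1, 0, 0),
                    survived = c(TRUE, FALSE, TRUE))
  toy_ft$synonymous <- c(FALSE, FALSE, TRUE)
  toy_ft$position <- c(1, 2, 3); toy_ft$wt <- "A"; toy_ft$mut <- "V"
  toy_sa <- structure(data.frame(position = c(1, 2), wt = "A", mut = "V",
                                 subset = c("FB", "FB")),
                      class = c("subset_assignment", "data.frame"))
  post <- suppressWarnings(subsetwise_selection(toy_ft, toy_sa,
                                                n_draws = 8000, seed = 4))
  # v_non ~ Beta(2, 2) mean 0.5; v_syn ~ Beta(2, 1) mean 2/3
  expect_equal(mean(post$FB$draws$v_non), 0.5, tolerance = 0.02)
  expect_equal(mean(post$FB$draws$v_syn), 2 / 3, tolerance = 0.02)
})

test_that("exact Mann-Whitney matches enumeration, hand values and wilcox.test", {
  # hand value: {1,2} vs {3,4}: U_y = 4, p = 1/6
  mw <- mann_whitney_greater(c(1, 2), c(3, 4))
  expect_equal(mw$U, 4)
  expect_equal(mw$p, 1 / 6)
  # independent oracle: rank-sum over all group assignments
  set.seed(41)
  x <- rnorm(8); y <- rnorm(8) + 1
  mw2 <- mann_whitney_greater(x, y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  idx <- utils::combn(16, 8)
  u_all <- apply(idx, 2, function(iy) sum(rk[iy]) - 8 * 9 / 2)
  u_obs <- sum(rk[9:16]) - 8 * 9 / 2
  expect_equal(mw2$p, mean(u_all >= u_obs - 1e-12))
  # dual route: wilcox.test exact on tie-free data
  wt <- wilcox.test(y, x, alternative = "greater", exact = TRUE)
  expect_equal(mw2$p, wt$p.value)
  # completely separated vectors of length 8: exact minimum 1/choose(16,8)
  sep <- mann_whitney_greater(1:8, 101:108)
  expect_equal(sep$p, 1 / choose(16, 8))
  # identical vectors: ties-adjusted p near 0.5 (>= 0.5 by convention)
  idp <- mann_whitney_greater(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(idp$p, 0.5)
  expect_lte(idp$p, 0.65)
  # matrix wrapper
  sm <- rbind(FB = c(0.1, 0.2, 0.15, 0.12), cFB = c(0.5, 0.6, 0.55, 0.52),
              FcB = c(0.3, 0.35, 0.32, 0.31), cFcB = c(0.7, 0.75, 0.72, 0.71))
  res <- subset_significance(sm)
  expect_equal(res$subset, c("cFB", "FcB", "cFcB"))
  expect_true(all(res$p <= 1 / choose(8, 4) + 1e-12))
})

test_that("cross-environment bootstrap respects degeneracy and determinism", {
  n <- 40
  set.seed(55)
  f <- rnorm(n)
  ids <- paste0("A", 1:n, "V")
  t1 <- make_ft(ids, F_rep1 = f)
  t1$position <- 1:n; t1$wt <- "A"; t1$mut <- "V"
  t2 <- t1
  sa <- structure(data.frame(position = 1:n, wt = "A", mut = "V",
                             subset = rep(c("FB", "cFB", "FcB", "cFcB"), each = n / 4)),
                  class = c("subset_assignment", "data.frame"))
  res <- cross_env_correlation_resample(t1, t2, sa, B = 200, seed = 9)
  # perfectly correlated pair: every draw is 1 (to numeric precision)
  expect_true(all(abs(res$draws - 1) < 1e-12))
  expect_equal(res$summary$median, rep(1, 4))
  # seed determinism
  res2 <- cross_env_correlation_resample(t1, t2, sa, B = 200, seed = 9)
  expect_identical(res$draws, res2$draws)
  # small subsets yield NA with warning
  sa_small <- sa
  sa_small$subset[sa_small$subset == "FB"][-(1:3)] <- "cFB"
  expect_warning(res3 <- cross_env_correlation_resample(t1, t2, sa_small, B = 50,
                                                        seed = 1),
                 "below minimum")
  expect_true(all(is.na(res3$draws[, "FB"])))
})
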