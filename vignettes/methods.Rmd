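---
title: "Methods: environment-resolved DMS scoring, selection statistics and biophysical constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment-resolved DMS scoring, selection statistics and biophysical constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(envdms)
```

This vignette is the package's own account of the models it implements, the
defaults it ships, the numerical conventions it adopts where the design was
genuinely open, and what its synthetic-data generator does and does not
establish. It states no empirical result that the test suite does not itself
compute.

## 1. From reads to counts

Reads are full-length amplicons of a single-site mutant library. Alignment
is by exact match of the read's first `anchor_length` (20) nucleotides
against the reference; an anchor matching zero or several positions, or a
read overhanging the reference, is rejected. This replaces a general-purpose
aligner deliberately: the library contains only single-codon substitutions,
so an exact anchor either identifies the unique offset or the read is
unusable. Real amplicons carry constant primer flanks; the simulator
prepends a 21-nt 5' flank and the caller accepts a `flank5` argument so
that substitutions in the first codons never corrupt the anchor.
Coordinate-sorted SAM/BAM from an external aligner is accepted as an
alternative entry point (simple `nM` CIGARs only), after which the same
filters apply.

Calling conventions:

* a variant is called only if the mean Q-score of the read **and** of the
  mutated codon is *strictly greater than* 30. "More than 30" is read
  literally: a mean of exactly 30 fails. Both thresholds are configurable.
* reads with more than one mutated codon are discarded
  (`max_mutated_codons_per_read = 1`). The library is single-site, so
  multi-codon reads are most parsimoniously PCR/sequencing artifacts. This
  is a choice the source text does not force; it is configurable.
* variants seen fewer than 3 times in a sample are removed (anomalous low
  counts). The count filter is "at least 3": exactly 3 reads survive.
* per-position depth counts every retained read (wild-type or variant)
  covering the position, *including* reads whose variant was later zeroed
  by the count filter — depth measures sequencing coverage, not call yield.
* codon counts collapse to amino-acid level by plain summation over
  synonymous codons. A codon-usage weighting was considered and rejected:
  no reproducible weighting rule is derivable, and summation preserves the
  count total. Stop-codon variants are kept with a `stop` flag; codons
  containing N are excluded with a warning.
* coordinates are 1-based codon indices; substitutions are written
  WT+position+MUT (`L5P`).

## 2. Fitness scores

With depth-normalized frequencies `f = count/depth(position)`, the score of
mutant *i* in one replicate is `F_i = log2(f_selected / f_unselected)`. The
per-environment score is the **mean of per-replicate scores**, not the score
of pooled counts. Pooling was rejected because the replicate-level scores
are needed downstream (the n_pos/n_neg noise model is built from
within-replicate score changes), and averaging keeps the replicate the unit
of biological variation.

Elimination: a mutant with zero selected count (after the count filter) in
*any* selected replicate is assigned the null-fitness marker (`F = NA`,
`survived = FALSE`). Requiring presence in every replicate makes the
mean-of-replicates F always well defined for survivors and makes "survival"
a replicate-consistent event rather than a single-replicate fluctuation. No
pseudocounts are added by default — a pseudocount would manufacture finite
scores for eliminated mutants and dilute the elimination signal the
selection statistics rely on; a `pseudocount` argument exists but is off.

Mutants absent from an unselected replicate cannot be scored at all and are
excluded with a warning (they were never reliably in the library).

Neutrality: scoring unselected replicate A against unselected replicate B
(all ordered pairs when there are more than two) yields a null enrichment
distribution with mean μ0 and SD σ0; the neutral band is `μ0 ± 2σ0`,
**closed** at both ends (a score exactly at a boundary is neutral —
boundary classifications should not flip on floating-point noise).
Survivors above/below the band are `enriched`/`depleted`.

## 3. Environment-level selection statistics

**Viability selection coefficient.** Survival counts (k out of n) of the
non-synonymous and synonymous classes give conjugate posteriors
`v ~ Beta(k+1, n−k+1)` under a flat Beta(1, 1) prior on the probability
scale. 1000 independent paired draws of `s = 1 − v_non/v_syn` mirror the
thinned-MCMC sample size of the latent-variable GLMM this replaces; the
marginal survival posteriors are identical in the two formulations while
the conjugate sampler is exact, fast and seedable. Stop-codon variants
belong to neither class: they are not amino-acid substitutions and their
survival is dominated by truncation, not by the folding/binding biology the
s statistic targets.

**Contrasts.** `pMCMC = 2·min(Pr(Δ ≥ 0), Pr(Δ ≤ 0))` over paired draws,
floored at 1/n_draws and capped at 1. Tails are tie-inclusive so that
identical posteriors give 1 rather than 0.

**ΔF** uses each environment's own survivor set (not the intersection):
complete elimination of highly deleterious mutants is part of the signal and
can push ΔF positive under stress even as selection strengthens.

**ρ** is Spearman over common survivors, average ranks under ties. Common
survivors (rather than null-imputed unions) were chosen because eliminated
mutants carry no rank.

**n_pos/n_neg.** Within-replicate score changes (F_rep_i − F_rep_j, ordered
pairs, surviving non-synonymous mutants) give μ and σ per environment; the
thresholds are `(μ_test+μ_ref)/2 ± 2·sqrt((σ_test²+σ_ref²)/2)`. A mutant
whose between-environment change exceeds T_plus is positive, below T_minus
negative. n_neg = 0 reports an infinity marker, not an error.

## 4. Structure-derived features

Distance of a residue to the active site is the minimum over all atoms of
the active-site residue (default residue 147, the catalytic aspartate of
the modeled acetyltransferase) of the Euclidean distance to the residue's
Cα — min-over-site-atoms maximizes sensitivity close to the site. Interface
distance, which the source analysis leaves undefined, is taken by analogy:
Cα of the query residue to any atom of the partner chain; the convention is
recorded in output metadata. The PDB parser keeps the first model, drops
HETATM/waters, keeps the highest-occupancy altLoc conformer, skips
insertion-coded and nonstandard residues with a count, and reports (but
tolerates) residues missing a Cα.

ΔΔG, conservation (evolutionary rate per site), residue depth, flexibility
and ΔSASA are *ingested* from a TSV produced by external predictors — they
are predictions, and recomputing them is out of scope. Loading validates key
uniqueness, constancy of positional features within a position, and ≥ 90%
coverage of the library. ΔΔG follows the destabilizing-positive sign
convention. logP and pI of the 20 amino acids ship as a versioned TSV of
reference literature values; property deltas are `prop(mut) − prop(wt)`.

## 5. Subsets, subset-wise selection, resampling

Folding/binding subsets cut at the medians m_G (ΔΔG) and m_D (distance)
over non-synonymous mutants: F ⇔ ΔΔG ≤ m_G, B ⇔ distance ≥ m_D. "Within 10
percentiles around the median" is implemented as the open (40th, 60th)
midrank-percentile window on either axis (the `band` parameter makes the
45–55 reading available). Percentile ranks are midranks, so labels are
invariant to monotone rescaling of either axis.

Subset-wise s restricts the non-synonymous class to the subset; the
synonymous comparator stays global, because synonymous mutants have no
substitution identity on the feature axes. FB-vs-other comparisons across
environments use a one-sided Mann-Whitney U with the *exact* enumeration
null for group sizes ≤ 12 (the target designs have 7–8 environments, where
the normal approximation is poor) and a tie-corrected normal approximation
beyond. The exact p is `Pr(U ≥ u_obs)` including ties, so identical vectors
give ≈ 0.5 and complete separation gives `1/choose(n_x+n_y, n_x)`.

Cross-environment correlations per subset use a bootstrap over common
survivors (B = 1000 by default) — the unspecified "Bayesian resampling" of
the source is implemented as a bootstrap and labeled as such in outputs.
Subset contrasts are two-sided `P_MCMC` on paired resamples, floored at 1/B.

## 6. Fitness landscapes

The (ΔΔG, distance) plane is min-max normalized per axis before the
nearest-neighbor search — unnormalized kcal/mol against Å would let the
distance axis dominate. Each cell of the (default 100×100) grid takes the F
of the nearest surviving mutant in normalized Euclidean distance, ties
broken by lowest input index, so every cell value is an observed score.
Refining the resolution never changes values at shared grid points. Batch
rendering shares one color scale across environments. Streamline overlays
are cosmetic and out of scope; the gradient field is derivable from the
grid.

## 7. The synthetic world

The generator emulates the study design: a 177-codon gene, an NNK
single-site codon library (~2000 non-synonymous + ~150 synonymous entries
in `random_subset` mode), read depth 1e5 per sample, two biological
replicates, full-amplicon reads with a two-point base-quality mixture
(q_high = 40 / q_low = 20 — enough to exercise the Q filters without a full
error model).

True fitness comes from a folding×binding cliff model:

    F_true = F_min + (0 − F_min) · w_f · w_b
    w_f = 1 / (1 + exp((ΔΔG + δ_e − G0) / k_G))
    w_b = 1 / (1 + exp((D0_e − d) / k_D))

with defaults chosen once, before any acceptance run, and not revisited:

* `G0 = 2` kcal/mol and `D0 = 15` Å — the folding and (high-dose) binding
  cliff positions reported for this system;
* the default *reference* and *heat* environments use `D0 = 7.5` Å: at the
  minimal antibiotic dose the binding constraint is confined close to the
  active site, and the 15 Å cliff is a high-dose phenomenon (the default
  `high_dose` environment uses 15);
* `k_G = 0.5` kcal/mol, `k_D = 2` Å — cliffs are steep but not step
  functions;
* `F_min = −6` log2 units (span of strongly depleted scores),
  elimination floor −4;
* ΔΔG ~ gamma(shape 2, rate 1) − 1 per amino-acid substitution
  (right-skewed, support ≥ −1, mean 1); distance ~ U[3, 40] Å per position;
  synonymous mutants have ΔΔG = 0 and F_true ≡ 0; nonsense mutants are
  maximally destabilized.

Selection acts as a single multiplicative round: selected proportions ∝
uniform library proportions × 2^F_true, with sub-floor mutants zeroed
before renormalization (complete elimination), then multinomial sampling at
the configured depth. The number of generations in the real competition is
unknown; scores are end-point enrichments, not growth rates, so generations
are absorbed into F_true.

**What a green test does and does not establish.** The generator reproduces
sampling noise, elimination, dose/stress dependence and the biophysical
sign structure, so recovery and ordering tests validate the *estimators*.
It does not emulate: PCR bias, indels, barcode demultiplexing, paired-end
structure, epistasis, expression-level effects — or genotype-by-environment
interactions that *reorder* fitness within a subset. That last gap has a
visible consequence: mutants with proper folding and binding (FB) have
essentially zero true fitness variance here, so their cross-environment
correlation is noise-limited (range restriction) and falls below that of
cliff-straddling subsets — the opposite of the empirical observation this
model otherwise mirrors. The acceptance suite therefore asserts the
correlation *sign pattern*, the subset ordering of s and the landscape
plateau, but not the FB-vs-cFB correlation contrast.

## 8. Numerical conventions and degenerate inputs

* All stochastic operations take explicit seeds; identical configs are
  byte-identical, and RNG state is restored after each generator call.
* Classification boundaries: neutral band closed; subset exclusion band
  open; Q filters strict (`> 30`); count filter inclusive (`≥ 3`).
* Degenerate cases: all mutants eliminated → error (degenerate selection);
  synonymous class extinct → error (s undefined); fewer than 3 common
  survivors → error for ρ; landscape with collinear points proceeds; a
  single landscape point fills the grid with a warning.
* `n_pos/n_neg` with n_neg = 0 → `Inf` (or `NaN` when both are 0).

## 9. Known limitations

Single-site substitutions only; no indel calling or paired-end merging; the
anchor aligner assumes amplicon sequencing (use the SAM path for anything
else); feature ingestion trusts the external predictors' scales; the exact
Mann-Whitney enumerates `choose(n_x+n_y, n_x)` assignments and is
restricted to group sizes ≤ 12; reproduction of the original study's
printed statistics requires its deposited fitness tables, which are not
bundled — the reproduce mode runs on any table in the documented TSV
layout.
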