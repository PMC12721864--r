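---
title: "Synthetic haplotypes from pairwise logic: model, tuning and audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic haplotypes from pairwise logic: model, tuning and audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicgen)
```

## The generative model

`logicgen` treats a phased cohort as a binary matrix: one row per haplotype,
one column per biallelic SNP (0 = reference allele, 1 = alternate). A
synthetic haplotype is an assignment to one Boolean variable per site that
satisfies a conjunction of two-literal clauses, each clause forbidding one
joint allele pattern at one site pair. The clauses are derived from a
*cluster* — a real haplotype and its `cluster_size - 1` Hamming-nearest
neighbours (ties broken toward the lower row index, so clustering is a pure
function of the matrix). Overlapping clusters keep every individual
coverable while localizing the constraint statistics.

Three parameters shape the constraint set:

* **`cluster_size` (N, default 150).** Patterns are counted over N cluster
  members. Small clusters see few patterns and constrain the output
  tightly (toward memorization); large clusters admit more diversity.
* **`exclusion_prob` (L, default 0.99).** Each unordered site pair enters
  the constraint set independently with probability 1 − L. The *fraction*
  is what is tuned: with S sites each site still participates in
  (1 − L)(S − 1) constrained pairs on average, so on large panels even
  L = 0.99 constrains every site hundreds of times, while on a few hundred
  sites the same L leaves the output nearly free. Scaled-down experiments
  should therefore scale L so that the per-site constraint degree, not the
  global fraction, is comparable.
* **`privacy_alpha` (α, default 0.5).** Per considered pair an integer
  threshold Z = ⌊Uniform[0, α + 1)⌋ is drawn; observed patterns with
  frequency ≤ Z are forbidden alongside the unobserved ones. At α = 0.5,
  Z is 1 with probability 1/3: a pattern carried by exactly one cluster
  member — the privacy-critical case — survives two times out of three.
  Z is drawn independently per pair, so suppression is spread across the
  genome rather than switched globally.

Two constraint-building details are deliberate. If a draw would forbid all
four patterns of a pair, the highest-frequency pattern is kept allowed
(ties resolved to the lexicographically smallest pattern), so no single
pair is contradictory. And at α = 0 every cluster member is itself a model
of the CNF — each of its patterns has frequency ≥ 1 — which guarantees
satisfiability and is the fallback that makes generation total.

## Solving

No SAT solver exists in the R ecosystem this package targets, and the CNF
machinery is the heart of the method, so the package ships a small DPLL
solver (C++, two-watched-literal propagation, chronological backtracking)
with randomized decision order and polarity. Randomization serves output
diversity: different solver seeds sample different models of the same CNF.
The solver takes an optional conflict budget; `generate_haplotypes()` runs
suppressed (α > 0) instances under a budget of 20&nbsp;000 conflicts and treats
exhaustion like unsatisfiability — retry with fresh pair/threshold draws,
and after `max_retries` failures halve α. Since α reaches 0 after a few
halvings and α = 0 is always satisfiable, generation terminates; the
per-haplotype provenance log records the retries and the effective α.
Returned models are re-checked clause by clause before being accepted.

## Reverse auditing

For a haplotype generated with L = 0, any pattern it exhibits had frequency
≥ 1 in its source cluster. `build_reconstruction_problem()` encodes exactly
this necessary condition: one selection variable per cohort row, one clause
per site pair requiring at least one selected row to match the target's
pattern there, and an exactly-M sequential-counter cardinality constraint.
The encoding uses frequency ≥ 1 (not > Z) because an auditor does not know
the thresholds that were drawn; the audit is therefore conservative — the
feasible family can only be larger than the truth, and the certified
backbone (members whose exclusion makes the problem unsatisfiable) only
smaller. Reconstruction under L > 0 is not supported: pair exclusion makes
the generation consequence probabilistic and no sound clause can be
written.

`enumerate_reconstructions()` samples distinct feasible subsets by adding a
blocking clause per solution and re-randomizing the solver; if the space is
exhausted the result carries a completeness flag. `exposed_members()` (the
intersection of sampled subsets) over-approximates the backbone;
`certify_exposure()` is the exact test used wherever a guarantee is
asserted.

`exposure_risk_experiment()` repeats, per iteration: sample G sites and a
pool, generate one synthetic haplotype from M pool rows (L = 0, given α),
reconstruct against the pool, and score whether anyone is exposed. The
pool is a configurable superset of the generation rows (default
3M) — auditing against only the M generating rows would make every subset
unique and the risk trivially 1, while the full cohort is unnecessarily
expensive; the choice is exposed as `pool_size`. Confidence intervals are
exact binomial at level 0.90.

## Accuracy and privacy statistics

* **PCA + sliced Wasserstein.** Components are fit on the real rows only
  and both clouds are projected onto them, so synthetic data is judged in
  the real coordinate system (an option to fit on pooled data exists for
  sensitivity checks). The sliced distance averages 1-D Wasserstein-1
  distances over 100 random unit directions by default — enough to hold
  the score's relative jitter near 1% on the fixtures used here — and is
  seeded.
* **Raw-data Wasserstein %.** Computed in the axis-decomposed form: the sum
  over sites of the per-site 1-D Wasserstein distance (for 0/1 data, the
  absolute allele-frequency difference), divided by the site count — the
  maximal per-haplotype displacement — times 100. Identical cohorts score
  0%, the bitwise complement of a constant cohort 100%, and the statistic
  is deterministic. The normalization is recorded on the result object.
* **LD error.** On phased haplotypes the Rogers–Huff r² estimator reduces
  to the squared Pearson correlation of allele indicators, which is what
  `ld_r2_pairs()` computes; monomorphic sites yield `NA` and are skipped.
  `ld_square_error()` averages (r²_real − r²_synth)² over pairs within each
  base-pair window and attaches percentile bootstrap intervals resampling
  SNP pairs (the averaging unit), 1000 replicates by default. The window
  grid is a parameter (default five equal increments, 50–250 kb).
* **Attribute inference.** The cohort is split into random halves,
  synthetic data generated from each, and every real row's
  nearest-neighbour Hamming distance computed against the same-half
  (*in*) and other-half (*out*) synthetic sets. Medians are taken over
  real rows; `leakage = out_median - in_median`. The generation backend is
  injectable so any method can be scored. Detecting memorization needs
  enough synthetic haplotypes for typical rows to have a near neighbour;
  120 per half (the scale at which the experiment is defined) is the
  default.
* **Quadruplet revelation.** Four-site patterns are sampled uniformly
  (sites uniform without replacement, the 16 patterns uniform) and labelled
  *private* (real count exactly 1) or *fictitious* (count 0) by exact
  rescan, until quotas — default 10&nbsp;000 each — are met. Revelation is
  reported both as the fraction of quadruplets appearing in at least one
  synthetic dataset (the headline) and as the mean per-dataset rate, since
  "occurrence across datasets" is ambiguous between the two.

## The simulator, and what passing tests do not show

`simulate_cohort()` builds the three data features the statistics measure:

* a **1/f site-frequency spectrum** (ancestral frequencies log-uniform on
  `maf_range`, default 0.01–0.5): rare variants are what make pairwise
  patterns informative about individuals; a flat spectrum would leave the
  α = 0 CNF nearly unconstrained and every privacy statistic blind;
* **population structure** via Balding–Nichols population frequencies at a
  given F_ST (populations share one founder pool when F_ST = 0, so labels
  carry no signal exactly when differentiation is zero);
* **LD blocks** by founder copying: sites fall into Poisson-length blocks
  (mean `block_len`), each haplotype copies one of `n_founders` founder
  block-haplotypes per block and then flips sites at `mutation_rate`,
  giving r² > 0 within blocks and ≈ 0 between. Positions are spaced
  1 kb, so the 50–250 kb windows of panel-scale analyses translate to
  50–250 sites.

The simulator is deliberately not a coalescent: no recombination maps,
demographic history, or selection. Tests passing on it show the *logic* of
generation and auditing (hallucination-freedom, round trips, monotone risk
in α) and the *directions* of the accuracy/privacy trade-offs; they do not
show panel-scale effect sizes, which depend on real LD and frequency
structure.

Experiment recipes used by the test suite, chosen once as scaled-down
analogues of panel-scale settings: hallucination checks on a 200 × 300
two-population cohort with N = 150; exposure-risk curves with G = 10 sites,
M = 8 of a 24-row pool, 50 iterations and 100 reconstructions per α; the
attribute-inference comparison on a 200 × 120 cohort with N = 30, L = 0
(pair exclusion off, isolating the α effect, as in the absolute-privacy
experiment), 120 synthetic haplotypes per half and 10 paired seeds.

## Numerical and interface choices

* MAF filtering compares allele *counts* (`min(c, n - c) >= min_maf * n`
  with a 1e-9 guard), so the boundary case — one copy in 100 rows at
  threshold 0.01 — is retained exactly.
* Missing or unphased genotypes are rejected by default; `drop_site`
  removes and counts the affected sites. Multiallelic and indel records
  are always skipped with a logged count. Refusing to impute silently is
  the conservative contract.
* Haplotypes are the genomic unit throughout; diploid VCF output is
  produced only by pairing consecutive synthetic rows, and files written
  by the package carry no timestamps so equal inputs give byte-equal
  outputs.
* Site positions are 1-based and must be strictly increasing within a
  chromosome; unsorted input is rejected rather than silently
  mis-windowed.

## Known limitations

Reverse auditing is exact only in the L = 0 regime and is compute-bound in
the subset size and pool; panel-scale audits need to sample small site
subsets, as the exposure experiment does. The DPLL solver has no clause
learning — ample for the instance sizes here, but heavy suppression on
dense pair sets can hit the conflict budget and fall back to retries. The
attribute-inference experiment measures leakage of the *generation halves*,
not of single individuals; per-individual guarantees come from the exposure
audit instead.
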