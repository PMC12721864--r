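# logicgen

Privacy-tunable synthetic haplotypes by logic solving.

## The problem

Sharing real genomic cohorts is heavily restricted because even a handful of
rare variants can identify an individual. Synthetic cohorts are the usual
workaround, but statistical and deep generative models tend to *hallucinate*
allele combinations never seen in any real person, and — worse — to leak the
rare combinations that are seen in exactly one person. `logicgen` is for
researchers who need to generate phased haplotype cohorts whose fidelity and
privacy can be reasoned about *deductively*, and to audit how much any
synthetic haplotype logically reveals about the individuals it was built
from.

## The method

Each haplotype is a 0/1 vector over biallelic SNP sites. To generate one
synthetic haplotype from a cohort of real haplotypes:

1. **Cluster.** Build overlapping clusters of size *N*: each real haplotype
   together with its *N* − 1 Hamming-nearest neighbours. Pick one cluster at
   random.
2. **Constrain.** For a random fraction 1 − *L* of site pairs (i, j), count
   the four joint allele patterns (0,0), (0,1), (1,0), (1,1) among the
   cluster members. Draw a randomized threshold
   *Z* = ⌊Uniform[0, α + 1)⌋ per pair and forbid — as a two-literal CNF
   clause over one Boolean variable per site — every pattern whose observed
   frequency is ≤ *Z*. At α = 0 exactly the unobserved patterns are
   forbidden, so nothing can be hallucinated; larger α also suppresses
   rare, potentially identifying patterns.
3. **Solve.** A randomized SAT solver returns an assignment satisfying all
   constraints: the synthetic haplotype.

Because generation is purely logical it can be inverted. For a synthetic
haplotype generated with *L* = 0, every one of its pair patterns must have
had frequency ≥ 1 in the source cluster. The **reverse** problem encodes,
with one selection variable per cohort row and an exactly-*M* cardinality
constraint, all *M*-subsets that could have served as the cluster.
Individuals present in *every* feasible subset (the backbone) are logically
exposed; the *exposure risk* is the probability, over random site/individual
draws, that anyone is exposed.

Accuracy is scored by sliced Wasserstein distances (on PCA projections and
on the raw data) and by windowed LD r² square error with bootstrap bands;
proxy privacy by attribute-inference leakage (in-data vs out-data median
nearest-neighbour Hamming distance) and by private/fictitious quadruplet
revelation. A self-contained simulator (Balding–Nichols population
structure, founder-copied LD blocks, 1/f site-frequency spectrum) makes the
whole package testable offline.

## Worked example

```r
library(logicgen)

sim    <- simulate_cohort(n_samples = 100, n_sites = 150, n_pops = 2,
                          fst = 0.15, seed = 42)
cohort <- sim$haplotypes
#> haplotype_matrix: 200 haplotypes x 150 biallelic sites

params <- genomator_params(cluster_size = 40, exclusion_prob = 0,
                           privacy_alpha = 0.5, seed = 7)
synth  <- generate_haplotypes(cohort, params, count = 50)

pca <- pca_fit_project(cohort, synth)
sliced_wasserstein(pca$real_proj, pca$synth_proj, seed = 1)
#> [1] 0.3040427
raw_wasserstein_percent(cohort, synth)
#> [1] 4.08  (percent of the maximal per-haplotype displacement)

ld_square_error(cohort, synth, window_grid = seq(10000, 50000, length.out = 3),
                n_boot = 200, seed = 2)
#>   window_bp n_pairs     mse   ci_lo   ci_hi
#> 1     10000     372 0.00481 0.00364 0.00644
#> 2     30000    1060 0.00487 0.00335 0.00681
#> 3     50000    1631 0.00422 0.00324 0.00575

exposure_risk_experiment(cohort, n_snps = 10, subset_size = 8,
                         privacy_alpha = 0.5, iterations = 30,
                         n_reconstructions = 100, pool_size = 24, seed = 3)
#> exposure_report: risk 0.067 (90% CI 0.012-0.195) over 30 iterations
```

The PCA score and LD error say how closely the synthetic cloud tracks the
real population structure and local correlation (0 would be a perfect
match); the exposure report says that in ~7% of audit draws at α = 0.5 some
individual's cluster membership was logically deducible from a single
synthetic haplotype — at α = 0 the same cohort gives risks around 0.3, at
α = 2.5 near 0.

A command-line interface wrapping the same functions lives at
`inst/cli/logicgen.R` (`simulate`, `convert`, `filter`, `generate`,
`reverse`, `eval`); all commands are byte-reproducible under a fixed
`--seed`.

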