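#' Simulate a structured haplotype cohort
#'
#' A self-contained fixture generator reproducing the data features the
#' package's statistics measure: population structure,
#' linkage-disequilibrium blocks, and a rare-allele-skewed site frequency
#' spectrum. Ancestral allele frequencies are drawn log-uniformly from
#' `maf_range` (density proportional to 1/f, emulating the neutral
#' frequency spectrum's excess of rare variants, which is what makes
#' pairwise patterns informative about individuals);
#' population-specific frequencies follow the
#' Balding-Nichols construction, `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`
#' at differentiation `fst` (at `fst = 0` all populations share the
#' ancestral frequencies). Sites are partitioned into consecutive blocks of
#' Poisson-distributed length (mean `block_len`); within each block and
#' population, a small pool of founder block-haplotypes is drawn from the
#' population frequencies and every haplotype copies one founder per block,
#' then mutates each site independently with probability `mutation_rate`.
#' This yields r-squared > 0 within blocks and ~ 0 between blocks.
#' Positions are spaced 1000 bp apart on one chromosome.
#'
#' @param n_samples diploid sample count (2 haplotype rows each).
#' @param n_sites number of biallelic sites.
#' @param n_pops number of populations; samples are split evenly.
#' @param fst differentiation in `[0, 1)`.
#' @param block_len mean block length in sites.
#' @param maf_range ancestral-frequency interval, a sub-interval of
#'   `(0, 0.5]`.
#' @param n_founders founder block-haplotypes per population per block.
#' @param mutation_rate per-site copy-error probability.
#' @param seed integer seed, or `NULL` for the current RNG state.
#' @return List with `haplotypes` (a [haplotype_matrix()]), `pop` (factor of
#'   per-row population labels), `ancestral_freq` (the drawn ancestral
#'   alternate-allele frequencies) and `pop_freq` (population-by-site
#'   frequency matrix).
#' @export
simulate_cohort <- function(n_samples = 100L, n_sites = 200L, n_pops = 2L,
                            fst = 0.1, block_len = 20L,
                            maf_range = c(0.01, 0.5), n_founders = 6L,
                            mutation_rate = 0.01, seed = NULL) {
  stopifnot(n_samples >= 1L, n_sites >= 1L, n_pops >= 1L,
            fst >= 0, fst < 1, block_len >= 1L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2L * n_samples
  pop_of_sample <- rep_len(seq_len(n_pops), n_samples)
  pop <- rep(pop_of_sample, each = 2L)

  p_anc <- exp(runif(n_sites, log(maf_range[1]), log(maf_range[2])))
  p_pop <- matrix(p_anc, n_pops, n_sites, byrow = TRUE)
  if (fst > 0 && n_pops > 1L) {
    shape <- (1 - fst) / fst
    for (k in seq_len(n_pops))
      p_pop[k, ] <- rbeta(n_sites, p_anc * shape, (1 - p_anc) * shape)
    ## keep sites polymorphic in expectation
    p_pop <- pmin(pmax(p_pop, 1e-3), 1 - 1e-3)
  }

  ## consecutive blocks of ~ block_len sites
  lens <- integer(0)
  while (sum(lens) < n_sites)
    lens <- c(lens, max(1L, rpois(1L, block_len)))
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n_sites)
  lens <- lens[lens > 0L]
  block_of <- rep(seq_along(lens), lens)

  ## at fst = 0 the populations are undifferentiated: they share one founder
  ## pool per block, so population labels carry no signal at all
  shared_pool <- fst == 0 || n_pops == 1L
  haps <- matrix(0L, n_hap, n_sites)
  for (blk in seq_along(lens)) {
    cols <- which(block_of == blk)
    if (shared_pool)
      founders <- matrix(
        as.integer(runif(n_founders * length(cols)) <
                     rep(p_anc[cols], each = n_founders)),
        n_founders, length(cols))
    for (k in seq_len(n_pops)) {
      rows <- which(pop == k)
      if (!shared_pool)
        founders <- matrix(
          as.integer(runif(n_founders * length(cols)) <
                       rep(p_pop[k, cols], each = n_founders)),
          n_founders, length(cols))
      pick <- sample.int(n_founders, length(rows), replace = TRUE)
      haps[rows, cols] <- founders[pick, , drop = FALSE]
    }
  }
  if (mutation_rate > 0) {
    flip <- runif(length(haps)) < mutation_rate
    haps[flip] <- 1L - haps[flip]
  }
  labels <- paste0("pop", pop, "_", rep(paste0("s", seq_len(n_samples)),
                                        each = 2L),
                   "_", rep(1:2, n_samples))
  list(haplotypes = haplotype_matrix(haps, row_labels = labels),
       pop = factor(paste0("pop", pop)),
       ancestral_freq = p_anc, pop_freq = p_pop)
}

#' Plant a uniquely identifying allele quadruplet
#'
#' Selects 4 sites and an allele pattern carried by zero rows and writes it
#' into exactly one randomly chosen row, creating a *private* quadruplet
#' (real count exactly 1). When possible, the chosen pattern contains a
#' site *pair* sub-pattern that was also absent, so that after planting the
#' carrier is the unique supporter of that pair pattern -- the configuration
#' under which pairwise-constraint generation can logically expose the
#' carrier.
#'
#' @param x a [haplotype_matrix()] with >= 4 sites and >= 2 rows.
#' @param max_draws attempts at finding an absent pattern (default 1000).
#' @return List with `haplotypes` (modified matrix), `row` (the carrier),
#'   `sites`, `alleles`, and `private_pair`: a list with `sites`/`alleles`
#'   of a pair pattern now unique to the carrier, or `NULL` if none was
#'   found.
#' @export
plant_unique_quadruplet <- function(x, max_draws = 1000L) {
  stopifnot(inherits(x, "haplotype_matrix"),
            ncol(x$haps) >= 4L, nrow(x$haps) >= 2L)
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  fallback <- NULL
  for (d in seq_len(max_draws)) {
    sites <- sort(sample.int(ncol(x$haps), 4L))
    cnt4 <- apply(pats, 1L, function(a) count_pattern(x, sites, a))
    absent <- which(cnt4 == 0L)
    if (!length(absent)) next
    ## prefer a pattern containing an absent pair sub-pattern
    best <- NULL
    for (pi in sample(absent)) {
      a <- pats[pi, ]
      sub <- combn(4L, 2L)
      for (ci in sample(ncol(sub))) {
        ss <- sites[sub[, ci]]
        aa <- a[sub[, ci]]
        if (count_pattern(x, ss, aa) == 0L) {
          best <- list(alleles = a, pair = list(sites = ss, alleles = aa))
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best) && is.null(fallback))
      fallback <- list(sites = sites, alleles = pats[sample(absent, 1L), ])
    if (!is.null(best)) {
      row <- sample.int(nrow(x$haps), 1L)
      x$haps[row, sites] <- as.integer(best$alleles)
      return(list(haplotypes = x, row = row, sites = sites,
                  alleles = as.integer(best$alleles),
                  private_pair = best$pair))
    }
  }
  if (!is.null(fallback)) {
    row <- sample.int(nrow(x$haps), 1L)
    x$haps[row, fallback$sites] <- as.integer(fallback$alleles)
    return(list(haplotypes = x, row = row, sites = fallback$sites,
                alleles = as.integer(fallback$alleles), private_pair = NULL))
  }
  stop("no absent quadruplet pattern found within ", max_draws, " draws",
       call. = FALSE)
}
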