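# Fixtures and independent oracles shared across test files.

# random Bernoulli haplotype matrix
rand_hm <- function(n, s, seed, p = 0.3) {
  set.seed(seed)
  haplotype_matrix(matrix(as.integer(runif(n * s) < p), n, s))
}

# position-by-position Hamming oracle
hamming_oracle <- function(a, b) sum(a != b)

# naive row-scan oracle for pattern counting
count_pattern_oracle <- function(hm, sites, alleles) {
  hits <- 0L
  for (r in seq_len(nrow(hm$haps)))
    if (all(hm$haps[r, sites] == alleles)) hits <- hits + 1L
  hits
}

all_site_pairs <- function(n) logicgen:::all_site_pairs(n)

# check every row of `haps` against a 2-literal clause list; returns the
# number of (row, clause) violations
count_clause_violations <- function(haps, clauses) {
  if (!length(clauses)) return(0L)
  l1 <- vapply(clauses, `[`, 0L, 1L)
  l2 <- vapply(clauses, `[`, 0L, 2L)
  sat1 <- haps[, abs(l1), drop = FALSE] ==
    matrix(as.integer(l1 > 0), nrow(haps), length(l1), byrow = TRUE)
  sat2 <- haps[, abs(l2), drop = FALSE] ==
    matrix(as.integer(l2 > 0), nrow(haps), length(l2), byrow = TRUE)
  sum(!(sat1 | sat2))
}

# all-pairs membership oracle: number of site pairs at which `target`'s
# pattern is absent from the given rows (hallucinated pairs)
count_hallucinated_pairs <- function(haps_rows, target) {
  pairs <- all_site_pairs(length(target))
  counts <- logicgen:::pattern_count_matrix(haps_rows, pairs)
  pat <- 2L * target[pairs[, 1]] + target[pairs[, 2]] + 1L
  sum(counts[cbind(seq_len(nrow(pairs)), pat)] == 0L)
}

# brute-force family of feasible subsets of size m for a reconstruction
# target (frequency >= 1 at every pair), as a character-key set
brute_force_feasible <- function(hm, target, m) {
  pairs <- all_site_pairs(ncol(hm$haps))
  subs <- combn(nrow(hm$haps), m, simplify = FALSE)
  keys <- character(0)
  for (ss in subs) {
    h <- hm$haps[ss, , drop = FALSE]
    ok <- all(vapply(seq_len(nrow(pairs)), function(k) {
      any(h[, pairs[k, 1]] == target[pairs[k, 1]] &
            h[, pairs[k, 2]] == target[pairs[k, 2]])
    }, TRUE))
    if (ok) keys <- c(keys, paste(ss, collapse = ","))
  }
  keys
}

set_key <- function(s) paste(sort(s), collapse = ",")

# mean silhouette over points with 2 groups, Euclidean, for PCA checks
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  vals <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(tapply(d[i, !own], droplevels(factor(labels[!own])), mean))
    (b - a) / max(a, b)
  }, 0.0)
  mean(vals)
}

# minimal phased VCF writer for hand-built fixtures
write_vcf_fixture <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}
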