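test_that("pattern counting matches a naive row scan and is monotone", {
  x <- rand_hm(30, 20, seed = 201, p = 0.3)
  expect_equal(count_pattern(x, integer(0), integer(0)), 30L)  # vacuous match
  expect_gte(count_pattern(x, 1:4, x$haps[7, 1:4]), 1L)        # own pattern
  set.seed(1)
  for (rep in 1:20) {
    sites <- sample.int(20, 4)
    alleles <- sample(0:1, 4, replace = TRUE)
    expect_equal(count_pattern(x, sites, alleles),
                 count_pattern_oracle(x, sites, alleles))
  }
  # appending sites can only shrink the match count
  sites <- sample.int(20, 6)
  alleles <- x$haps[3, sites]
  counts <- vapply(1:6, function(k)
    count_pattern(x, sites[1:k], alleles[1:k]), 0L)
  expect_true(all(diff(counts) <= 0L))
  expect_error(count_pattern(x, c(1L, 99L), c(0L, 1L)), "range")
  expect_error(count_pattern(x, c(2L, 2L), c(0L, 1L)), "distinct")
})

test_that("sampled quadruplet labels are exact against the recount oracle", {
  x <- rand_hm(40, 30, seed = 203, p = 0.2)
  set.seed(2)
  q <- sample_labelled_quadruplets(x, quota_private = 100,
                                   quota_fictitious = 100)
  expect_equal(sum(q$label == "private"), 100L)
  expect_equal(sum(q$label == "fictitious"), 100L)
  keys <- apply(q[, 1:8], 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  for (i in seq_len(nrow(q))) {
    cnt <- count_pattern_oracle(x, unlist(q[i, 1:4]), unlist(q[i, 5:8]))
    expect_equal(cnt, q$real_count[i])
    expect_equal(q$label[i], if (cnt == 1L) "private" else "fictitious")
  }
  # unreachable quota warns and returns a partial result
  tiny <- haplotype_matrix(matrix(0L, 2, 4))
  expect_warning(
    qq <- sample_labelled_quadruplets(tiny, quota_private = 5,
                                      quota_fictitious = 5, max_draws = 50),
    "quotas")
  expect_lte(sum(qq$label == "private"), 5L)
})

test_that("revelation likelihoods match a double-loop recount", {
  x <- rand_hm(25, 15, seed = 205, p = 0.3)
  set.seed(3)
  q <- sample_labelled_quadruplets(x, quota_private = 60, quota_fictitious = 60)
  synth <- lapply(1:5, function(s) rand_hm(20, 15, seed = 300 + s, p = 0.3))
  rep <- quadruplet_revelation(q, synth)
  # oracle: loop over quadruplets and datasets
  any_occ <- rate <- setNames(numeric(2), c("private", "fictitious"))
  for (lab in names(any_occ)) {
    rows <- which(q$label == lab)
    occ <- sapply(rows, function(i)
      vapply(synth, function(d)
        count_pattern_oracle(d, unlist(q[i, 1:4]), unlist(q[i, 5:8])) >= 1L,
        TRUE))
    any_occ[lab] <- mean(colSums(occ) > 0L)
    rate[lab] <- mean(occ)
  }
  expect_equal(rep$likelihood, any_occ)
  expect_equal(rep$per_dataset_rate, rate)
  # self-match: the real cohort as the only synthetic dataset reveals every
  # private quadruplet
  rep_self <- quadruplet_revelation(q, list(x))
  expect_equal(unname(rep_self$likelihood["private"]), 1)
  # all-zero synthetic reveals no quadruplet containing a 1 allele
  zeros <- haplotype_matrix(matrix(0L, 10, 15))
  has_one <- rowSums(q[, 5:8]) > 0
  rep_z <- quadruplet_revelation(q[has_one, ], list(zeros))
  expect_equal(max(rep_z$likelihood, na.rm = TRUE), 0)
})

test_that("a memorizing generator shows zero in-distance and positive leakage", {
  sim <- simulate_cohort(n_samples = 40, n_sites = 60, n_pops = 2, fst = 0.2,
                         seed = 207)
  x <- sim$haplotypes
  memorizer <- function(half, count)
    haplotype_matrix(half$haps[rep_len(seq_len(nrow(half$haps)), count), ,
                               drop = FALSE], sites = half$sites)
  set.seed(4)
  r <- attribute_inference_experiment(x, n_synthetic_per_half = 40,
                                      generator = memorizer)
  expect_equal(r$in_median, 0)
  expect_gt(r$leakage, 0)
})

test_that("a cohort-independent generator leaks nothing beyond permutation noise", {
  sim <- simulate_cohort(n_samples = 40, n_sites = 60, n_pops = 1, fst = 0,
                         seed = 209)
  x <- sim$haplotypes
  external <- function(half, count)
    haplotype_matrix(matrix(as.integer(runif(count * 60) < 0.3), count, 60),
                     sites = half$sites)
  set.seed(5)
  r <- attribute_inference_experiment(x, n_synthetic_per_half = 30,
                                      generator = external)
  # permutation band: re-split the rows many times and recompute the
  # leakage from the fixed distance vectors
  n_half <- sum(r$split == 0L)
  d_in <- r$in_distances; d_out <- r$out_distances
  perm <- replicate(500, {
    flip <- sample(c(TRUE, FALSE), length(d_in), replace = TRUE)
    md_in <- median(ifelse(flip, d_out, d_in))
    md_out <- median(ifelse(flip, d_in, d_out))
    md_out - md_in
  })
  band <- quantile(perm, c(0.005, 0.995))
  expect_gte(r$leakage, band[1])
  expect_lte(r$leakage, band[2])
})

test_that("swapping the halves negates leakage for a deterministic generator", {
  x <- rand_hm(30, 40, seed = 211, p = 0.3)
  # two fixed synthetic sets, assigned by call order: swapping the halves
  # swaps which set plays the in-data role
  m1 <- rand_hm(10, 40, seed = 212, p = 0.3)
  m2 <- rand_hm(10, 40, seed = 213, p = 0.3)
  make_gen <- function() {
    calls <- 0L
    function(half, count) {
      calls <<- calls + 1L
      if (calls == 1L) m1 else m2
    }
  }
  split <- rep(c(0L, 1L), 15)
  r1 <- attribute_inference_experiment(x, n_synthetic_per_half = 10,
                                       generator = make_gen(), split = split)
  r2 <- attribute_inference_experiment(x, n_synthetic_per_half = 10,
                                       generator = make_gen(),
                                       split = 1L - split)
  expect_equal(r1$leakage, -r2$leakage)
  expect_equal(r1$in_median, r2$out_median)
})
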