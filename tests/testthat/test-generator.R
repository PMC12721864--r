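test_that("privacy threshold draws follow the floor-uniform law", {
  set.seed(1)
  expect_true(all(draw_z(1000, 0) == 0L))
  z <- draw_z(1e5, 0.5)
  expect_true(all(z %in% 0:1))
  expect_lt(abs(mean(z == 1L) - 1 / 3), 0.02)
  z2 <- draw_z(1e5, 2)
  expect_true(all(z2 %in% 0:2))
  for (v in 0:2) expect_lt(abs(mean(z2 == v) - 1 / 3), 0.02)
  expect_error(draw_z(1, -0.1), "privacy_alpha")
})

test_that("clusters are seed plus Hamming-nearest rows with index tie-breaks", {
  x <- rand_hm(8, 20, seed = 31)
  cl_all <- build_clusters(x, 8)
  for (c in cl_all) expect_equal(c$members, 1:8)
  cl_one <- build_clusters(x, 1)
  for (i in 1:8) expect_equal(cl_one[[i]]$members, i)
  expect_error(build_clusters(x, 9), "exceeds")

  cl <- build_clusters(x, 3)
  for (i in 1:8) {
    d <- vapply(1:8, function(j) hamming_oracle(x$haps[i, ], x$haps[j, ]), 0L)
    ord <- order(d, 1:8)                 # stable tie-break oracle
    ord <- c(i, setdiff(ord, i))
    expect_equal(cl[[i]]$members, sort(ord[1:3]))
    expect_true(i %in% cl[[i]]$members)
  }
})

test_that("pair universe sampling hits its binomial law and edge cases", {
  set.seed(2)
  expect_equal(nrow(sample_pair_universe(10, 0)), choose(10, 2))
  expect_equal(nrow(sample_pair_universe(10, 1)), 0L)
  n <- nrow(sample_pair_universe(100, 0.99))
  mu <- 4950 * 0.01
  expect_lt(abs(n - mu), 3 * sqrt(4950 * 0.01 * 0.99))
  expect_error(sample_pair_universe(1, 0.5), "2 sites")
})

test_that("pattern frequencies enumerate the four joint patterns", {
  x <- haplotype_matrix(rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  expect_equal(pattern_frequencies(x, 1:3, c(1L, 2L)),
               c(`00` = 1L, `01` = 1L, `10` = 0L, `11` = 1L))
  expect_equal(sum(pattern_frequencies(x, 2L, c(1L, 2L))), 1L)
  y <- haplotype_matrix(matrix(1L, 5, 2))
  expect_equal(pattern_frequencies(y, 1:5, c(1L, 2L)),
               c(`00` = 0L, `01` = 0L, `10` = 0L, `11` = 5L))
})

test_that("constraints forbid exactly the at-or-below-z patterns", {
  x <- rand_hm(30, 30, seed = 41, p = 0.25)
  cl <- list(seed_row = 1L, members = 1:20)
  pairs <- all_site_pairs(30)
  set.seed(7)
  prob <- build_constraints(x, cl, pairs, privacy_alpha = 1)
  # recount oracle: recompute every pair's pattern frequencies and apply
  # "forbidden iff freq <= z" with the recorded z draws
  audit_key <- with(prob$audit, paste(site_i, site_j, pattern))
  expected <- character(0)
  for (k in seq_len(nrow(pairs))) {
    fr <- pattern_frequencies(x, cl$members, pairs[k, ])
    z <- prob$z[k]
    forb <- names(fr)[fr <= z]
    if (length(forb) == 4L) forb <- setdiff(forb, names(which.max(fr)))
    if (length(forb))
      expected <- c(expected, paste(pairs[k, 1], pairs[k, 2], forb))
  }
  expect_setequal(audit_key, expected)
  expect_true(all(prob$audit$freq <= prob$audit$z))

  # alpha = 0: exactly the frequency-0 patterns
  prob0 <- build_constraints(x, cl, pairs, privacy_alpha = 0)
  expect_true(all(prob0$audit$freq == 0L))
  expect_true(all(prob0$audit$z == 0L))
})

test_that("the all-four-patterns safeguard keeps the modal pattern", {
  x <- haplotype_matrix(rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L)))
  prob <- build_constraints(x, list(members = 1:3), cbind(1L, 2L), z = 5L)
  expect_equal(nrow(prob$audit), 3L)            # 3 forbidden, 11 kept
  expect_false("11" %in% prob$audit$pattern)
  # the kept pattern must remain satisfiable
  sol <- solve_constraints(prob, seed = 1)
  expect_equal(sol$assignment, c(1L, 1L))

  # lexicographic tie-break: 00 and 11 tie at count 1; 00 must be kept
  y <- haplotype_matrix(rbind(c(0L, 0L), c(1L, 1L)))
  prob2 <- build_constraints(y, list(members = 1:2), cbind(1L, 2L), z = 2L)
  expect_setequal(prob2$audit$pattern, c("01", "10", "11"))
})

test_that("raising every z yields a superset of forbidden patterns", {
  x <- rand_hm(25, 20, seed = 51, p = 0.3)
  cl <- list(members = 1:15)
  pairs <- all_site_pairs(20)
  z <- draw_z(nrow(pairs), 1.5)
  p1 <- build_constraints(x, cl, pairs, z = z)
  p2 <- build_constraints(x, cl, pairs, z = z + 1L)
  k1 <- with(p1$audit, paste(site_i, site_j, pattern))
  k2 <- with(p2$audit, paste(site_i, site_j, pattern))
  # monotone before the safeguard: any pattern forbidden at z but not z+1
  # must be the safeguard-kept modal pattern of a fully-forbidden pair
  lost <- setdiff(k1, k2)
  if (length(lost)) {
    full <- names(which(table(with(p2$audit, paste(site_i, site_j))) == 3L))
    lost_pair <- sub(" [01]+$", "", lost)
    expect_true(all(lost_pair %in% full))
  }
  expect_gte(nrow(p2$audit), nrow(p1$audit) - length(lost))
})

test_that("the SAT solver returns verified models and detects conflicts", {
  # forced pair: forbid 01, 10, 11 at sites (1, 2)
  x <- haplotype_matrix(rbind(c(0L, 0L, 1L), c(0L, 0L, 0L)))
  prob <- build_constraints(x, list(members = 1:2), cbind(1L, 2L), z = 0L)
  for (s in 1:5) {
    sol <- solve_constraints(prob, seed = s)
    expect_true(sol$satisfiable)
    expect_equal(sol$assignment[1:2], c(0L, 0L))
  }
  # a random 50-var cluster problem: model passes the independent checker
  y <- rand_hm(40, 50, seed = 61, p = 0.2)
  prob2 <- build_constraints(y, list(members = 1:12), all_site_pairs(50),
                             privacy_alpha = 0)
  sol2 <- solve_constraints(prob2, seed = 3)
  expect_true(sol2$satisfiable)
  expect_equal(count_clause_violations(matrix(sol2$assignment, 1), prob2$clauses), 0L)
  # determinism for a fixed seed
  expect_identical(solve_constraints(prob2, seed = 9)$assignment,
                   solve_constraints(prob2, seed = 9)$assignment)
  # an unsatisfiable CNF is reported, not crashed on
  res <- logicgen:::sat_solve(2, list(c(1L), c(-1L)))
  expect_false(res$satisfiable)
  expect_equal(res$status, "unsat")
})

test_that("every cluster member is a model of its alpha = 0 CNF", {
  x <- rand_hm(30, 40, seed = 71, p = 0.25)
  cl <- build_clusters(x, 12)
  pairs <- all_site_pairs(40)
  for (c in cl[seq(1, 30, by = 3)]) {
    prob <- build_constraints(x, c, pairs, z = rep(0L, nrow(pairs)))
    expect_equal(count_clause_violations(x$haps[c$members, , drop = FALSE],
                                         prob$clauses), 0L)
  }
})

test_that("generation is hallucination-free at alpha = 0, L = 0", {
  sim <- simulate_cohort(n_samples = 30, n_sites = 80, n_pops = 2,
                         fst = 0.1, seed = 81)
  x <- sim$haplotypes
  params <- genomator_params(cluster_size = 20, exclusion_prob = 0,
                             privacy_alpha = 0, seed = 13)
  syn <- generate_haplotypes(x, params, count = 5)
  prov <- attr(syn, "provenance")
  cl <- build_clusters(x, 20)
  for (k in 1:5) {
    members <- cl[[prov$cluster_seed_row[k]]]$members
    expect_equal(count_hallucinated_pairs(x$haps[members, , drop = FALSE],
                                          syn$haps[k, ]), 0L)
  }
})

test_that("generation is deterministic under a fixed seed and count 0 is empty", {
  sim <- simulate_cohort(n_samples = 25, n_sites = 60, seed = 91)
  x <- sim$haplotypes
  params <- genomator_params(cluster_size = 15, exclusion_prob = 0.9,
                             privacy_alpha = 0.5, seed = 17)
  a <- generate_haplotypes(x, params, count = 4)
  b <- generate_haplotypes(x, params, count = 4)
  expect_identical(a$haps, b$haps)
  expect_identical(attr(a, "provenance"), attr(b, "provenance"))

  e <- generate_haplotypes(x, params, count = 0)
  expect_equal(nrow(e$haps), 0L)
  expect_equal(nrow(attr(e, "provenance")), 0L)
})
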