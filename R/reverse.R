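#' Build the input-reconstruction SAT problem for a synthetic haplotype
#'
#' Encodes, with one Boolean selection variable per cohort row, which
#' subsets of exactly `subset_size` rows could have served as the generation
#' cluster of `target` in the no-pair-exclusion regime (L = 0): a subset is
#' feasible iff, for every considered site pair, at least one selected row
#' exhibits the target's allele pattern there. This is the certain logical
#' consequence of generation -- a pattern present in the output cannot have
#' had frequency zero in the cluster -- and deliberately requires only
#' frequency >= 1, since the per-pair privacy thresholds actually drawn are
#' unknown to an auditor.
#'
#' The exactly-`subset_size` cardinality constraint uses a sequential-counter
#' encoding (auxiliary register variables, linear size).
#'
#' @param cohort a [haplotype_matrix()]: the pool an attacker reconstructs
#'   against.
#' @param target 0/1 vector, one synthetic haplotype over the cohort's sites.
#' @param subset_size M, the assumed cluster size.
#' @param pairs two-column matrix of site pairs to constrain on (default:
#'   all pairs, the L = 0 regime).
#' @return An object of class `reconstruction_problem` with fields
#'   `n_rows`, `subset_size`, `n_vars`, `clauses`, `sel_vars`, `feasible`
#'   (`FALSE` when some target pattern is supported by no cohort row, in
#'   which case `infeasible_pair` names the first such pair).
#' @export
build_reconstruction_problem <- function(cohort, target, subset_size,
                                         pairs = NULL) {
  stopifnot(inherits(cohort, "haplotype_matrix"))
  target <- as.integer(target)
  n <- nrow(cohort$haps)
  s <- ncol(cohort$haps)
  if (length(target) != s)
    stop("target length (", length(target), ") does not match site count (",
         s, ")", call. = FALSE)
  subset_size <- as.integer(subset_size)
  if (subset_size < 1L || subset_size > n)
    stop("subset_size must lie in [1, ", n, "]", call. = FALSE)
  if (is.null(pairs)) pairs <- all_site_pairs(s)

  ## support clause per pair: rows matching the target's pattern there
  match_i <- cohort$haps[, pairs[, 1], drop = FALSE] ==
    matrix(target[pairs[, 1]], n, nrow(pairs), byrow = TRUE)
  match_j <- cohort$haps[, pairs[, 2], drop = FALSE] ==
    matrix(target[pairs[, 2]], n, nrow(pairs), byrow = TRUE)
  support <- match_i & match_j                  # rows x pairs
  ok <- colSums(support) > 0L
  if (!all(ok)) {
    bad <- which(!ok)[1]
    return(structure(list(n_rows = n, subset_size = subset_size,
                          n_vars = n, clauses = list(), sel_vars = seq_len(n),
                          feasible = FALSE,
                          infeasible_pair = pairs[bad, ]),
                     class = "reconstruction_problem"))
  }
  support_clauses <- lapply(seq_len(nrow(pairs)),
                            function(p) which(support[, p]))
  ## dedupe identical support clauses (many pairs share supporters)
  support_clauses <- unique(support_clauses)

  card <- exactly_k_clauses(n, subset_size)
  structure(list(n_rows = n, subset_size = subset_size,
                 n_vars = card$n_vars,
                 clauses = c(support_clauses, card$clauses),
                 sel_vars = seq_len(n),
                 feasible = TRUE, infeasible_pair = NULL),
            class = "reconstruction_problem")
}

## Sequential-counter encoding of "exactly k of vars 1..n are true".
## Auxiliary variable s(i, j) = n + (i - 1) * k + j  <=>  at least j of the
## first i selection variables are true.
exactly_k_clauses <- function(n, k) {
  sv <- function(i, j) n + (i - 1L) * k + j
  cls <- vector("list", 4L * n * k + n + 1L)
  m <- 0L
  add <- function(cl) { m <<- m + 1L; cls[[m]] <<- as.integer(cl) }
  ## i = 1
  add(c(-sv(1L, 1L), 1L)); add(c(-1L, sv(1L, 1L)))
  if (k >= 2L) for (j in 2L:k) add(-sv(1L, j))
  if (n >= 2L) for (i in 2L:n) {
    for (j in 1L:k) {
      add(c(-sv(i - 1L, j), sv(i, j)))                    # carry forward
      if (j == 1L) {
        add(c(-i, sv(i, 1L)))                             # x_i counts
        add(c(-sv(i, 1L), sv(i - 1L, 1L), i))             # completeness
      } else {
        add(c(-i, -sv(i - 1L, j - 1L), sv(i, j)))
        add(c(-sv(i, j), sv(i - 1L, j), i))
        add(c(-sv(i, j), sv(i - 1L, j), sv(i - 1L, j - 1L)))
      }
    }
    add(c(-i, -sv(i - 1L, k)))                            # at most k
  }
  add(sv(n, k))                                           # at least k
  list(n_vars = n + n * k, clauses = cls[seq_len(m)])
}

#' Enumerate plausible input subsets
#'
#' Repeatedly solves the reconstruction problem with re-randomized decision
#' polarity, blocking each found subset, until `count` distinct subsets are
#' found or the solution space is exhausted.
#'
#' @param problem a [build_reconstruction_problem()] result.
#' @param count requested number of distinct subsets (default 500).
#' @param seed integer seed for the solver's randomness.
#' @return List with `sets` (list of sorted integer row-index vectors) and
#'   `complete` (`TRUE` if the whole solution space was enumerated).
#' @export
enumerate_reconstructions <- function(problem, count = 500L, seed = 1L) {
  stopifnot(inherits(problem, "reconstruction_problem"))
  if (!problem$feasible) return(list(sets = list(), complete = TRUE))
  res <- sat_enumerate(problem$n_vars, problem$clauses, seed = seed,
                       max_models = count, block_vars = problem$sel_vars)
  sets <- lapply(res$models, function(m) which(m[problem$sel_vars] == 1L))
  stopifnot(all(lengths(sets) == problem$subset_size))
  list(sets = sets, complete = res$complete)
}

#' Members common to all reconstructions
#'
#' The sampled-intersection exposure test: individuals present in every
#' reconstructed input subset are labelled exposed.
#'
#' @param reconstructions non-empty list of row-index sets.
#' @return Sorted integer vector (possibly empty).
#' @export
exposed_members <- function(reconstructions) {
  if (!length(reconstructions))
    stop("exposure is undefined for an empty reconstruction list", call. = FALSE)
  sort(Reduce(intersect, reconstructions))
}

#' Certify that a member occurs in every feasible subset
#'
#' Exact backbone test: forces the member's selection variable false and
#' checks unsatisfiability. Strengthens the sampled intersection of
#' [exposed_members()], which can only over-approximate the backbone.
#'
#' @param problem a feasible [build_reconstruction_problem()] result.
#' @param member cohort row index.
#' @param seed solver seed.
#' @return `TRUE` iff no feasible subset excludes `member`.
#' @export
certify_exposure <- function(problem, member, seed = 1L) {
  stopifnot(inherits(problem, "reconstruction_problem"), problem$feasible)
  res <- sat_solve(problem$n_vars, problem$clauses, seed = seed,
                   assumptions = -as.integer(member))
  !res$satisfiable
}

#' Exposure-risk experiment
#'
#' Estimates the probability that a synthetic haplotype logically exposes an
#' input individual. Per iteration: `n_snps` sites are sampled, a pool of
#' `pool_size` rows is sampled from the cohort, `subset_size` pool rows form
#' the generation cluster, one synthetic haplotype is generated from them
#' (L = 0, cluster size = `subset_size`, the given `privacy_alpha`), the
#' reconstruction problem over the same sites is built against the pool, up
#' to `n_reconstructions` plausible subsets are enumerated, and the
#' iteration scores 1 if their intersection is non-empty. The risk is the
#' mean score; the confidence interval is exact binomial (Clopper-Pearson).
#'
#' @param cohort a [haplotype_matrix()].
#' @param n_snps G, number of sites sampled per iteration.
#' @param subset_size M, generation-cluster and reconstruction subset size.
#' @param privacy_alpha generator privacy parameter.
#' @param iterations number of iterations.
#' @param n_reconstructions subsets enumerated per iteration (default 500).
#' @param pool_size rows the auditor reconstructs against; must be >=
#'   `subset_size`. Default `min(rows, 3 * subset_size)`.
#' @param ci_level confidence level (default 0.90).
#' @param seed integer seed, or `NULL` for the current RNG state.
#' @return An `exposure_report` list: `risk`, `ci_bounds`, `iterations`,
#'   `n_failed`, `exposed_sets` (per-iteration exposed members), plus the
#'   experiment settings.
#' @export
exposure_risk_experiment <- function(cohort, n_snps, subset_size,
                                     privacy_alpha, iterations = 50L,
                                     n_reconstructions = 500L,
                                     pool_size = NULL, ci_level = 0.90,
                                     seed = NULL) {
  stopifnot(inherits(cohort, "haplotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$haps)
  s <- ncol(cohort$haps)
  stopifnot(n_snps <= s, subset_size <= n)
  if (is.null(pool_size)) pool_size <- min(n, 3L * subset_size)
  stopifnot(pool_size >= subset_size, pool_size <= n)
  params <- genomator_params(cluster_size = subset_size, exclusion_prob = 0,
                             privacy_alpha = privacy_alpha, seed = NULL)
  hits <- logical(0)
  exposed_sets <- list()
  n_failed <- 0L
  for (it in seq_len(iterations)) {
    sites <- sort(sample.int(s, n_snps))
    pool <- sort(sample.int(n, pool_size))
    cluster_in_pool <- sort(sample.int(pool_size, subset_size))
    pool_m <- subset_haplotypes(cohort, rows = pool, cols = sites)
    cluster_m <- subset_haplotypes(pool_m, rows = cluster_in_pool)
    synth <- generate_haplotypes(cluster_m, params, count = 1L)
    prob <- build_reconstruction_problem(pool_m, synth$haps[1L, ],
                                         subset_size = subset_size)
    if (!prob$feasible) { n_failed <- n_failed + 1L; next }
    rec <- enumerate_reconstructions(prob, count = n_reconstructions,
                                     seed = sample.int(.Machine$integer.max, 1L))
    if (!length(rec$sets)) { n_failed <- n_failed + 1L; next }
    ex <- exposed_members(rec$sets)
    hits <- c(hits, length(ex) > 0L)
    exposed_sets[[length(exposed_sets) + 1L]] <- pool[ex]
  }
  n_ok <- length(hits)
  if (n_ok == 0L) stop("all iterations failed", call. = FALSE)
  ci <- binom.test(sum(hits), n_ok, conf.level = ci_level)$conf.int
  structure(list(risk = mean(hits), ci_bounds = as.numeric(ci),
                 ci_level = ci_level, iterations = iterations,
                 n_failed = n_failed, exposed_sets = exposed_sets,
                 n_snps = n_snps, subset_size = subset_size,
                 pool_size = pool_size, privacy_alpha = privacy_alpha,
                 n_reconstructions = n_reconstructions),
            class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf("exposure_report: risk %.3f (%.0f%% CI %.3f-%.3f) over %d iterations\n",
              x$risk, 100 * x$ci_level, x$ci_bounds[1], x$ci_bounds[2],
              x$iterations - x$n_failed))
  cat(sprintf("  G = %d SNPs, M = %d of pool %d, privacy_alpha = %g, %d reconstructions\n",
              x$n_snps, x$subset_size, x$pool_size, x$privacy_alpha,
              x$n_reconstructions))
  invisible(x)
}
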