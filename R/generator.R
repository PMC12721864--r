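#' Generation parameters
#'
#' The tuning triple of the generator plus run controls. `cluster_size` (N)
#' sets how many Hamming-nearest real haplotypes inform each synthetic one;
#' larger clusters see more pattern diversity and constrain the output less.
#' `exclusion_prob` (L) is the probability that a site pair is *ignored* when
#' building constraints, so only a fraction `1 - L` of all pairs is encoded.
#' `privacy_alpha` parameterizes the randomized suppression threshold Z drawn
#' per pair as `floor(Uniform[0, alpha + 1))`: observed patterns with
#' in-cluster frequency at or below Z are forbidden, attenuating rare,
#' potentially identifying combinations. At `alpha = 0.5`, Z is 1 with
#' probability 1/3 and 0 otherwise.
#'
#' @param cluster_size positive integer N (default 150).
#' @param exclusion_prob L in `[0, 1]` (default 0.99).
#' @param privacy_alpha alpha >= 0 (default 0.5).
#' @param seed integer seed for the whole generation run, or `NULL` to use
#'   the current RNG state.
#' @param max_retries solver retries with fresh randomness before the
#'   privacy threshold is relaxed (default 5).
#' @param freeze_pairs if `TRUE`, the random pair universe is drawn once per
#'   run instead of per synthetic haplotype.
#' @return An object of class `genomator_params`.
#' @export
genomator_params <- function(cluster_size = 150L, exclusion_prob = 0.99,
                             privacy_alpha = 0.5, seed = NULL,
                             max_retries = 5L, freeze_pairs = FALSE) {
  if (cluster_size < 1L) stop("cluster_size must be positive", call. = FALSE)
  if (exclusion_prob < 0 || exclusion_prob > 1)
    stop("exclusion_prob must lie in [0, 1]", call. = FALSE)
  if (privacy_alpha < 0) stop("privacy_alpha must be >= 0", call. = FALSE)
  if (max_retries < 1L) stop("max_retries must be positive", call. = FALSE)
  structure(list(cluster_size = as.integer(cluster_size),
                 exclusion_prob = exclusion_prob,
                 privacy_alpha = privacy_alpha,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_retries = as.integer(max_retries),
                 freeze_pairs = isTRUE(freeze_pairs)),
            class = "genomator_params")
}

#' Draw the randomized privacy threshold Z
#'
#' Z is the floor of a uniform draw on `[0, alpha + 1)`, so its support is
#' `{0, ..., floor(alpha)}` plus possibly `ceiling(alpha)`. Integer `alpha`
#' gives `alpha + 1` equiprobable values; `alpha = 0.5` gives Z = 1 with
#' probability 1/3.
#'
#' @param n number of draws.
#' @param privacy_alpha alpha >= 0.
#' @return Integer vector of `n` non-negative thresholds.
#' @export
draw_z <- function(n, privacy_alpha) {
  if (privacy_alpha < 0) stop("privacy_alpha must be >= 0", call. = FALSE)
  as.integer(floor(runif(n, 0, privacy_alpha + 1)))
}

#' Overlapping Hamming clusters
#'
#' One cluster per cohort haplotype: the seed row together with its
#' `cluster_size - 1` nearest rows by Hamming distance, ties broken in favor
#' of the lower row index. Deterministic given the matrix.
#'
#' @param x a [haplotype_matrix()].
#' @param cluster_size N, at most the row count.
#' @return List of clusters, each a list with `seed_row` and sorted integer
#'   `members` (length N, containing `seed_row`).
#' @export
build_clusters <- function(x, cluster_size) {
  stopifnot(inherits(x, "haplotype_matrix"))
  n <- nrow(x$haps)
  cluster_size <- as.integer(cluster_size)
  if (cluster_size > n)
    stop("cluster_size (", cluster_size, ") exceeds haplotype count (", n, ")",
         call. = FALSE)
  d <- hamming_matrix(x$haps)
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))   # stable: ties to lower index
    ord <- c(i, setdiff(ord, i))       # seed always first
    list(seed_row = i, members = sort(ord[seq_len(cluster_size)]))
  })
}

#' Random site-pair universe
#'
#' Each of the `choose(n_sites, 2)` unordered site pairs is retained
#' independently with probability `1 - exclusion_prob`.
#'
#' @param n_sites number of sites (>= 2).
#' @param exclusion_prob L in `[0, 1]`.
#' @return Two-column integer matrix of retained pairs (`i < j`), possibly
#'   with zero rows.
#' @export
sample_pair_universe <- function(n_sites, exclusion_prob) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  if (exclusion_prob < 0 || exclusion_prob > 1)
    stop("exclusion_prob must lie in [0, 1]", call. = FALSE)
  all_pairs <- all_site_pairs(n_sites)
  if (exclusion_prob == 0) return(all_pairs)
  keep <- runif(nrow(all_pairs)) >= exclusion_prob
  all_pairs[keep, , drop = FALSE]
}

all_site_pairs <- function(n_sites) {
  i <- rep.int(seq_len(n_sites - 1L), (n_sites - 1L):1L)
  j <- sequence((n_sites - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Pairwise allele-pattern frequencies in a cluster
#'
#' @param x a [haplotype_matrix()].
#' @param members integer vector of row indices.
#' @param pair length-2 integer vector of site indices.
#' @return Named integer vector of counts for patterns `00`, `01`, `10`,
#'   `11` (first allele at `pair[1]`); counts sum to `length(members)`.
#' @export
pattern_frequencies <- function(x, members, pair) {
  stopifnot(inherits(x, "haplotype_matrix"), length(pair) == 2L)
  a <- x$haps[members, pair[1], drop = TRUE]
  b <- x$haps[members, pair[2], drop = TRUE]
  idx <- 2L * a + b
  counts <- tabulate(idx + 1L, nbins = 4L)
  names(counts) <- c("00", "01", "10", "11")
  counts
}

# pattern counts for many pairs at once: returns m x 4 matrix (00,01,10,11)
pattern_count_matrix <- function(haps, pairs) {
  one <- crossprod(haps)                 # 11
  a0 <- 1L - haps
  n10 <- crossprod(haps, a0)             # row site = 1, col site = 0
  n00 <- crossprod(a0)
  idx <- pairs
  cbind(`00` = n00[idx], `01` = t(n10)[idx], `10` = n10[idx], `11` = one[idx])
}

PATTERNS <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))

#' Build the pairwise-pattern CNF for one cluster
#'
#' For each retained site pair, a privacy threshold `z` is drawn (or taken
#' from `z`), and every allele pattern whose frequency among the cluster
#' members is at most `z` is forbidden by a two-literal clause. If that
#' would forbid all four patterns of a pair, the highest-frequency pattern
#' (ties: lexicographically smallest of 00 < 01 < 10 < 11) is left allowed so
#' no pair is contradictory on its own.
#'
#' @param x a [haplotype_matrix()].
#' @param cluster a cluster from [build_clusters()] (or any list with a
#'   `members` field).
#' @param pairs two-column matrix of site pairs, e.g. from
#'   [sample_pair_universe()].
#' @param privacy_alpha alpha for [draw_z()]; ignored when `z` is supplied.
#' @param z optional integer vector of per-pair thresholds (for audits and
#'   reproducibility studies).
#' @return An object of class `constraint_problem`: list with `n_vars`
#'   (site count), `clauses` (list of 2-literal integer vectors) and `audit`
#'   (data frame: `site_i`, `site_j`, `pattern`, `freq`, `z` per forbidden
#'   pattern).
#' @export
build_constraints <- function(x, cluster, pairs, privacy_alpha = 0.5, z = NULL) {
  stopifnot(inherits(x, "haplotype_matrix"))
  members <- if (is.list(cluster)) cluster$members else cluster
  m <- nrow(pairs)
  if (m == 0L) {
    warning("empty pair universe: constraint problem has no clauses")
    return(structure(list(n_vars = ncol(x$haps), clauses = list(),
                          audit = empty_audit()),
                     class = "constraint_problem"))
  }
  if (is.null(z)) z <- draw_z(m, privacy_alpha)
  stopifnot(length(z) == m)
  counts <- pattern_count_matrix(x$haps[members, , drop = FALSE], pairs)
  forbid <- counts <= z                     # m x 4 logical
  all4 <- rowSums(forbid) == 4L
  if (any(all4)) {
    keep <- max.col(counts[all4, , drop = FALSE], ties.method = "first")
    forbid[cbind(which(all4), keep)] <- FALSE
  }
  w <- which(forbid, arr.ind = TRUE)
  if (nrow(w) == 0L) {
    audit <- empty_audit()
    clauses <- list()
  } else {
    pr <- w[, 1]; pat <- w[, 2]
    i <- pairs[pr, 1]; j <- pairs[pr, 2]
    ai <- PATTERNS[pat, 1]; aj <- PATTERNS[pat, 2]
    # forbid (x_i = ai & x_j = aj)  <=>  clause (x_i != ai | x_j != aj)
    l1 <- ifelse(ai == 1L, -i, i)
    l2 <- ifelse(aj == 1L, -j, j)
    ord <- order(pr, pat)
    clauses <- mapply(function(a, b) c(a, b), l1[ord], l2[ord],
                      SIMPLIFY = FALSE)
    audit <- data.frame(site_i = i[ord], site_j = j[ord],
                        pattern = colnames(counts)[pat][ord],
                        freq = counts[cbind(pr, pat)][ord],
                        z = z[pr][ord],
                        stringsAsFactors = FALSE)
  }
  structure(list(n_vars = ncol(x$haps), clauses = clauses, audit = audit,
                 pairs = pairs, z = z),
            class = "constraint_problem")
}

empty_audit <- function() {
  data.frame(site_i = integer(0), site_j = integer(0),
             pattern = character(0), freq = integer(0), z = integer(0),
             stringsAsFactors = FALSE)
}

#' Solve a pairwise-pattern CNF
#'
#' Runs the randomized DPLL solver; decision order and polarity are drawn
#' from `seed`, so different seeds can yield different models and a fixed
#' seed is reproducible. The returned assignment is re-checked clause by
#' clause before being returned.
#'
#' @param problem a `constraint_problem` from [build_constraints()].
#' @param seed integer solver seed.
#' @param max_conflicts search budget per attempt; 0 (default) searches to
#'   completion. When exceeded, `status` is `"unknown"` and the caller may
#'   retry with a different seed (randomized restart).
#' @return List with `satisfiable` (logical), `status`
#'   (`"sat"`/`"unsat"`/`"unknown"`), `assignment` (0/1 integer vector over
#'   sites, or `NULL`), and `audit` (the problem's audit table, for
#'   diagnosis when unsatisfiable).
#' @export
solve_constraints <- function(problem, seed = 1L, max_conflicts = 0) {
  stopifnot(inherits(problem, "constraint_problem"))
  res <- sat_solve(problem$n_vars, problem$clauses, seed = seed,
                   max_conflicts = max_conflicts)
  if (!res$satisfiable)
    return(list(satisfiable = FALSE, status = res$status, assignment = NULL,
                audit = problem$audit))
  stopifnot(sat_check_model(res$model, problem$clauses))
  list(satisfiable = TRUE, status = res$status,
       assignment = as.integer(res$model), audit = problem$audit)
}

#' Generate synthetic haplotypes
#'
#' For each synthetic haplotype: a cluster is chosen uniformly at random, a
#' fresh pair universe is sampled (unless `freeze_pairs`), the pairwise
#' pattern CNF is built with freshly drawn per-pair privacy thresholds, and
#' a randomized SAT model becomes the synthetic haplotype. If a problem is
#' unsatisfiable (possible only for `privacy_alpha > 0`), it is retried with
#' fresh randomness up to `max_retries` times, after which `privacy_alpha`
#' is halved (reaching 0 within a few steps, where satisfiability is
#' guaranteed: every cluster member is itself a model).
#'
#' @param x a [haplotype_matrix()] of real haplotypes.
#' @param params a [genomator_params()].
#' @param count number of synthetic haplotypes to produce.
#' @return A [haplotype_matrix()] of `count` synthetic haplotypes carrying
#'   the input's site metadata, with attribute `provenance`: a data frame
#'   with one row per output (`index`, `cluster_seed_row`, `retries`,
#'   `effective_alpha`, `n_clauses`).
#' @export
generate_haplotypes <- function(x, params = genomator_params(), count) {
  stopifnot(inherits(x, "haplotype_matrix"), inherits(params, "genomator_params"))
  if (nrow(x$haps) < params$cluster_size)
    stop("cohort has fewer haplotypes (", nrow(x$haps),
         ") than cluster_size (", params$cluster_size, ")", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  count <- as.integer(count)
  prov <- data.frame(index = integer(0), cluster_seed_row = integer(0),
                     retries = integer(0), effective_alpha = numeric(0),
                     n_clauses = integer(0))
  out <- matrix(0L, nrow = count, ncol = ncol(x$haps))
  if (count == 0L) {
    res <- haplotype_matrix(out, sites = x$sites, row_labels = character(0))
    attr(res, "provenance") <- prov
    return(res)
  }
  clusters <- build_clusters(x, params$cluster_size)
  frozen_pairs <- if (params$freeze_pairs)
    sample_pair_universe(ncol(x$haps), params$exclusion_prob) else NULL
  for (k in seq_len(count)) {
    ci <- sample.int(length(clusters), 1L)
    cl <- clusters[[ci]]
    alpha <- params$privacy_alpha
    retries <- 0L
    repeat {
      pairs <- if (params$freeze_pairs) frozen_pairs else
        sample_pair_universe(ncol(x$haps), params$exclusion_prob)
      prob <- suppressWarnings(
        build_constraints(x, cl, pairs, privacy_alpha = alpha))
      ## budgeted search: a hard instance is abandoned and retried with
      ## fresh randomness rather than searched to completion
      sol <- solve_constraints(prob, seed = sample.int(.Machine$integer.max, 1L),
                               max_conflicts = if (alpha > 0) 20000 else 0)
      if (sol$satisfiable) break
      if (sol$status == "unsat" && alpha == 0)
        stop("unsatisfiable at privacy_alpha = 0; this indicates a bug",
             call. = FALSE)
      retries <- retries + 1L
      if (retries %% params$max_retries == 0L)
        alpha <- if (alpha < 0.25) 0 else alpha / 2
    }
    out[k, ] <- sol$assignment
    prov <- rbind(prov, data.frame(index = k, cluster_seed_row = cl$seed_row,
                                   retries = retries, effective_alpha = alpha,
                                   n_clauses = length(prob$clauses)))
  }
  res <- haplotype_matrix(out, sites = x$sites,
                          row_labels = paste0("synth", seq_len(count)))
  attr(res, "provenance") <- prov
  res
}
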