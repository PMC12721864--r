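#' Count haplotypes carrying an allele pattern
#'
#' @param x a [haplotype_matrix()].
#' @param sites integer vector of distinct site indices (may be empty, in
#'   which case every row matches vacuously).
#' @param alleles 0/1 vector of the same length.
#' @return Number of rows matching all given alleles at the given sites.
#' @export
count_pattern <- function(x, sites, alleles) {
  stopifnot(inherits(x, "haplotype_matrix"), length(sites) == length(alleles))
  if (!length(sites)) return(nrow(x$haps))
  sites <- as.integer(sites)
  if (any(sites < 1L) || any(sites > ncol(x$haps)))
    stop("site index out of range", call. = FALSE)
  if (anyDuplicated(sites)) stop("site indices must be distinct", call. = FALSE)
  m <- x$haps[, sites, drop = FALSE]
  sum(rowSums(m == matrix(as.integer(alleles), nrow(m), length(sites),
                          byrow = TRUE)) == length(sites))
}

#' Sample private and fictitious allele quadruplets
#'
#' Draws 4 distinct sites uniformly and 4 alleles uniformly, labels the
#' quadruplet *private* if exactly one real haplotype carries it and
#' *fictitious* if none does, and keeps sampling (without duplicates) until
#' both quotas are met or `max_draws` candidate draws are spent, in which
#' case a partial result is returned with a warning.
#'
#' @param x the real cohort, a [haplotype_matrix()] with >= 4 sites.
#' @param quota_private,quota_fictitious numbers of labelled quadruplets
#'   wanted per category (defaults 10000, the scale used for cohort-level
#'   revelation scans).
#' @param max_draws cap on candidate draws (default 100 times the total
#'   quota).
#' @return Data frame with columns `s1..s4` (site indices), `a1..a4`
#'   (alleles), `label` (`"private"`/`"fictitious"`), `real_count`.
#' @export
sample_labelled_quadruplets <- function(x, quota_private = 10000L,
                                        quota_fictitious = 10000L,
                                        max_draws = NULL) {
  stopifnot(inherits(x, "haplotype_matrix"))
  s <- ncol(x$haps)
  if (s < 4L) stop("need at least 4 sites", call. = FALSE)
  if (is.null(max_draws))
    max_draws <- 100L * (quota_private + quota_fictitious)
  got_p <- 0L; got_f <- 0L
  keep <- vector("list", quota_private + quota_fictitious)
  nkeep <- 0L
  seen <- new.env(hash = TRUE)
  draws <- 0L
  while ((got_p < quota_private || got_f < quota_fictitious) &&
         draws < max_draws) {
    batch <- min(1000L, max_draws - draws)
    for (b in seq_len(batch)) {
      draws <- draws + 1L
      sites <- sort(sample.int(s, 4L))
      alleles <- sample(0:1, 4L, replace = TRUE)
      key <- paste(c(sites, alleles), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cnt <- count_pattern(x, sites, alleles)
      if (cnt == 1L && got_p < quota_private) {
        got_p <- got_p + 1L
      } else if (cnt == 0L && got_f < quota_fictitious) {
        got_f <- got_f + 1L
      } else next
      nkeep <- nkeep + 1L
      keep[[nkeep]] <- c(sites, alleles, cnt)
    }
  }
  if (got_p < quota_private || got_f < quota_fictitious)
    warning(sprintf(
      "quotas not met within %d draws (private %d/%d, fictitious %d/%d)",
      max_draws, got_p, quota_private, got_f, quota_fictitious))
  m <- do.call(rbind, keep[seq_len(nkeep)])
  if (is.null(m)) m <- matrix(integer(0), ncol = 9L)
  out <- as.data.frame(m)
  names(out) <- c("s1", "s2", "s3", "s4", "a1", "a2", "a3", "a4", "real_count")
  out$label <- ifelse(out$real_count == 1L, "private", "fictitious")
  out
}

#' Quadruplet revelation across synthetic datasets
#'
#' For each labelled quadruplet, checks whether it occurs (count >= 1) in
#' each synthetic dataset. The headline likelihood per label is the
#' fraction of quadruplets appearing in at least one dataset; the mean
#' per-dataset occurrence rate is reported separately.
#'
#' @param quadruplets a data frame from [sample_labelled_quadruplets()].
#' @param synthetic_datasets list of [haplotype_matrix()] objects with the
#'   same site indexing as the real cohort.
#' @return A `revelation_report` list: `n_quadruplets` (per label),
#'   `n_datasets`, `likelihood` (per label, any-dataset), `per_dataset_rate`
#'   (per label, mean over datasets), and the per-quadruplet `revealed`
#'   indicator.
#' @export
quadruplet_revelation <- function(quadruplets, synthetic_datasets) {
  stopifnot(is.data.frame(quadruplets), length(synthetic_datasets) >= 1L)
  s <- ncol(synthetic_datasets[[1]]$haps)
  for (d in synthetic_datasets)
    if (ncol(d$haps) != s)
      stop("synthetic datasets disagree on site count", call. = FALSE)
  if (nrow(quadruplets) &&
      max(quadruplets[, c("s1", "s2", "s3", "s4")]) > s)
    stop("quadruplet site index exceeds synthetic site count", call. = FALSE)
  nq <- nrow(quadruplets)
  occ <- matrix(FALSE, nq, length(synthetic_datasets))
  for (di in seq_along(synthetic_datasets)) {
    d <- synthetic_datasets[[di]]
    for (qi in seq_len(nq)) {
      q <- quadruplets[qi, ]
      occ[qi, di] <- count_pattern(d, unlist(q[c("s1", "s2", "s3", "s4")]),
                                   unlist(q[c("a1", "a2", "a3", "a4")])) >= 1L
    }
  }
  revealed <- rowSums(occ) > 0L
  lab <- quadruplets$label
  lik <- function(l) if (any(lab == l)) mean(revealed[lab == l]) else NA_real_
  rate <- function(l) if (any(lab == l))
    mean(colMeans(occ[lab == l, , drop = FALSE])) else NA_real_
  structure(list(
    n_quadruplets = c(private = sum(lab == "private"),
                      fictitious = sum(lab == "fictitious")),
    n_datasets = length(synthetic_datasets),
    likelihood = c(private = lik("private"), fictitious = lik("fictitious")),
    per_dataset_rate = c(private = rate("private"),
                         fictitious = rate("fictitious")),
    revealed = revealed), class = "revelation_report")
}

#' Attribute-inference leakage experiment
#'
#' Emulates an inference attack in which an adversary fills in a target's
#' missing alleles from the nearest synthetic haplotype. The cohort is
#' split into two random halves and synthetic data is generated from each;
#' every real row's nearest-neighbor Hamming distance is computed to the
#' synthetic set from its own half (*in*) and from the other half (*out*).
#' `leakage = out_median - in_median`: a positive value means synthetic data
#' is systematically closer to the individuals it was built from, i.e.
#' information about them leaks.
#'
#' @param x the real cohort, a [haplotype_matrix()].
#' @param params a [genomator_params()] for the default generator; its
#'   `cluster_size` must not exceed a half's row count.
#' @param n_synthetic_per_half synthetic haplotypes per half (default 120).
#' @param generator generation backend: a `function(half_matrix, count)`
#'   returning a `haplotype_matrix`, so any method can be scored. Default
#'   wraps [generate_haplotypes()] with `params`.
#' @param split optional 0/1 assignment of rows to halves (for paired
#'   designs); default random equal split (an odd trailing row is dropped).
#' @return An `attribute_inference_report` list: `in_median`, `out_median`,
#'   `leakage`, per-row distance vectors, and the split used.
#' @export
attribute_inference_experiment <- function(x, params = genomator_params(),
                                           n_synthetic_per_half = 120L,
                                           generator = NULL, split = NULL) {
  stopifnot(inherits(x, "haplotype_matrix"))
  n <- nrow(x$haps)
  n_use <- n - (n %% 2L)
  if (is.null(split)) {
    split <- integer(n_use)
    split[sample.int(n_use, n_use %/% 2L)] <- 1L
  } else {
    split <- as.integer(split)
    stopifnot(length(split) == n_use, sum(split) == n_use %/% 2L)
  }
  half_a <- subset_haplotypes(x, rows = which(split == 0L))
  half_b <- subset_haplotypes(x, rows = which(split == 1L))
  if (is.null(generator)) {
    if (nrow(half_a$haps) < params$cluster_size)
      stop("half size (", nrow(half_a$haps), ") is below cluster_size (",
           params$cluster_size, ")", call. = FALSE)
    generator <- function(half, count) generate_haplotypes(half, params, count)
  }
  synth_a <- generator(half_a, n_synthetic_per_half)
  synth_b <- generator(half_b, n_synthetic_per_half)
  nn <- function(real, synth)
    apply(hamming_cross(real$haps, synth$haps), 1L, min)
  in_d <- c(nn(half_a, synth_a), nn(half_b, synth_b))
  out_d <- c(nn(half_a, synth_b), nn(half_b, synth_a))
  structure(list(in_median = median(in_d), out_median = median(out_d),
                 leakage = median(out_d) - median(in_d),
                 in_distances = in_d, out_distances = out_d,
                 split = split, n_synthetic_per_half = n_synthetic_per_half),
            class = "attribute_inference_report")
}

#' @export
print.attribute_inference_report <- function(x, ...) {
  cat(sprintf(
    "attribute_inference_report: in-data median %g, out-data median %g, leakage %g\n",
    x$in_median, x$out_median, x$leakage))
  invisible(x)
}
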