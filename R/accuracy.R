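#' PCA fit on real data with synthetic projection
#'
#' Principal components are fit on the real haplotype matrix only (rows
#' centered, unscaled); both real and synthetic rows are then projected onto
#' those components, so the synthetic cloud is judged in the real data's
#' coordinate system.
#'
#' @param real,synthetic [haplotype_matrix()] objects over the same sites.
#' @param n_components number of components (default 2).
#' @return A `pca_report` list: `rotation` (loadings), `center`,
#'   `real_proj`, `synth_proj` (score matrices), `sdev`.
#' @export
pca_fit_project <- function(real, synthetic, n_components = 2L) {
  stopifnot(inherits(real, "haplotype_matrix"),
            inherits(synthetic, "haplotype_matrix"))
  if (ncol(real$haps) != ncol(synthetic$haps))
    stop("site counts differ (", ncol(real$haps), " vs ",
         ncol(synthetic$haps), ")", call. = FALSE)
  p <- prcomp(real$haps, center = TRUE, scale. = FALSE, rank. = n_components)
  synth_proj <- scale(synthetic$haps, center = p$center, scale = FALSE) %*%
    p$rotation
  structure(list(rotation = p$rotation, center = p$center,
                 real_proj = p$x[, seq_len(n_components), drop = FALSE],
                 synth_proj = synth_proj, sdev = p$sdev),
            class = "pca_report")
}

#' Sliced Wasserstein distance between point clouds
#'
#' Averages, over random unit projection directions, the 1-D Wasserstein-1
#' distance between the projected samples. For equal sample sizes the 1-D
#' distance is the mean absolute difference of the sorted projections; for
#' unequal sizes the quantile-function (CDF-integral) form is used.
#' Symmetric in its arguments and zero iff the clouds agree as multisets
#' along every drawn direction.
#'
#' @param a,b numeric matrices, points in rows, equal column count.
#' @param n_projections number of random directions (default 100).
#' @param directions optional matrix of fixed unit directions in rows
#'   (overrides `n_projections`; used for deterministic checks).
#' @param seed integer seed for the direction draw, or `NULL`.
#' @return Non-negative scalar.
#' @export
sliced_wasserstein <- function(a, b, n_projections = 100L, directions = NULL,
                               seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty point cloud", call. = FALSE)
  if (ncol(a) != ncol(b)) stop("dimension mismatch", call. = FALSE)
  if (is.null(directions)) {
    if (!is.null(seed)) set.seed(seed)
    directions <- matrix(stats::rnorm(n_projections * ncol(a)),
                         nrow = n_projections)
    directions <- directions / sqrt(rowSums(directions^2))
  } else {
    directions <- as.matrix(directions)
    stopifnot(ncol(directions) == ncol(a))
  }
  pa <- a %*% t(directions)   # points x directions
  pb <- b %*% t(directions)
  mean(vapply(seq_len(ncol(pa)),
              function(k) wasserstein_1d(pa[, k], pb[, k]), 0.0))
}

# 1-D Wasserstein-1 distance between empirical distributions
wasserstein_1d <- function(u, v) {
  u <- sort(u); v <- sort(v)
  if (length(u) == length(v)) return(mean(abs(u - v)))
  ## CDF-integral form on the merged grid
  grid <- sort(c(u, v))
  fu <- findInterval(grid, u) / length(u)
  fv <- findInterval(grid, v) / length(v)
  sum(abs(fu - fv)[-length(grid)] * diff(grid))
}

#' Raw-data Wasserstein percentage error
#'
#' Wasserstein distance computed across all site dimensions in the
#' axis-decomposed form: the sum over sites of the 1-D Wasserstein-1
#' distance between the real and synthetic allele distributions at that
#' site (for 0/1 alleles this is the absolute allele-frequency difference),
#' normalized by the site count -- the maximum possible per-haplotype
#' displacement -- and expressed as a percentage. Identical cohorts score
#' 0%; the bitwise complement of a constant cohort scores 100%. The
#' normalization choice is recorded in the result, and the statistic is
#' deterministic.
#'
#' @param real,synthetic [haplotype_matrix()] objects over the same sites.
#' @return Scalar percentage with attribute `normalization = "site_count"`.
#' @export
raw_wasserstein_percent <- function(real, synthetic) {
  stopifnot(inherits(real, "haplotype_matrix"),
            inherits(synthetic, "haplotype_matrix"))
  if (ncol(real$haps) != ncol(synthetic$haps))
    stop("site counts differ", call. = FALSE)
  per_site <- vapply(seq_len(ncol(real$haps)), function(j)
    wasserstein_1d(real$haps[, j], synthetic$haps[, j]), 0.0)
  structure(100 * sum(per_site) / ncol(real$haps),
            normalization = "site_count")
}

#' Pairwise linkage-disequilibrium r-squared within a window
#'
#' On phased haplotypes the Rogers-Huff estimator reduces to the squared
#' Pearson correlation of the 0/1 allele indicators, which is what is
#' computed here. Pairs are restricted to sites within `max_window_bp` base
#' pairs of each other; pairs involving a monomorphic site have undefined
#' r-squared and are reported as `NA`.
#'
#' @param x a [haplotype_matrix()] with sorted positions.
#' @param max_window_bp maximum base-pair separation.
#' @return Data frame: `site_i`, `site_j`, `dist_bp`, `r2`.
#' @export
ld_r2_pairs <- function(x, max_window_bp) {
  stopifnot(inherits(x, "haplotype_matrix"))
  pos <- x$sites$pos
  chrom <- x$sites$chrom
  if (is.unsorted(pos[chrom == chrom[1]]) || length(unique(chrom)) > 1 &&
      any(tapply(pos, chrom, is.unsorted)))
    stop("site positions must be sorted within chromosome", call. = FALSE)
  r2m <- suppressWarnings(cor(x$haps))^2
  pairs <- all_site_pairs(ncol(x$haps))
  same_chrom <- chrom[pairs[, 1]] == chrom[pairs[, 2]]
  d <- abs(pos[pairs[, 2]] - pos[pairs[, 1]])
  keep <- same_chrom & d <= max_window_bp
  data.frame(site_i = pairs[keep, 1], site_j = pairs[keep, 2],
             dist_bp = d[keep], r2 = r2m[pairs[keep, , drop = FALSE]])
}

#' Windowed LD square error with bootstrap bands
#'
#' For each window size, averages `(r2_real - r2_synth)^2` over all site
#' pairs within the window, skipping pairs undefined (monomorphic) in either
#' dataset, and attaches a percentile bootstrap confidence interval
#' resampling SNP pairs.
#'
#' @param real,synthetic [haplotype_matrix()] objects over matched sites.
#' @param window_grid base-pair window sizes (default five equal increments
#'   from 50000 to 250000).
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @return An `ld_report` data frame: `window_bp`, `n_pairs`, `mse`,
#'   `ci_lo`, `ci_hi` (NA with a warning where a window has no valid pair).
#' @export
ld_square_error <- function(real, synthetic,
                            window_grid = seq(50000, 250000, length.out = 5),
                            n_boot = 1000L, ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(real, "haplotype_matrix"),
            inherits(synthetic, "haplotype_matrix"))
  if (ncol(real$haps) != ncol(synthetic$haps))
    stop("site counts differ", call. = FALSE)
  if (!isTRUE(all.equal(real$sites$pos, synthetic$sites$pos)))
    stop("site positions differ between real and synthetic", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  wmax <- max(window_grid)
  pr <- ld_r2_pairs(real, wmax)
  ps <- ld_r2_pairs(synthetic, wmax)
  stopifnot(nrow(pr) == nrow(ps))
  sqerr <- (pr$r2 - ps$r2)^2
  valid <- !is.na(sqerr)
  alpha <- (1 - ci_level) / 2
  rows <- lapply(window_grid, function(w) {
    sel <- which(pr$dist_bp <= w & valid)
    if (!length(sel)) {
      warning("no valid site pair within window ", w, " bp")
      return(data.frame(window_bp = w, n_pairs = 0L, mse = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    e <- sqerr[sel]
    boots <- vapply(seq_len(n_boot), function(b)
      mean(e[sample.int(length(e), replace = TRUE)]), 0.0)
    data.frame(window_bp = w, n_pairs = length(sel), mse = mean(e),
               ci_lo = unname(quantile(boots, alpha)),
               ci_hi = unname(quantile(boots, 1 - alpha)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ld_report", class(out))
  out
}
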