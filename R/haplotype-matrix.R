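#' Construct a haplotype matrix
#'
#' The universal cohort container: a binary matrix with one row per phased
#' haplotype (a diploid sample contributes two adjacent rows) and one column
#' per biallelic variant site, 0 coding the reference allele and 1 the
#' alternate. Site metadata rides along as a data frame.
#'
#' @param haps integer or logical matrix of 0/1 entries, haplotypes in rows.
#' @param sites data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   one row per matrix column. If `NULL`, synthetic metadata is created
#'   (chromosome `"1"`, positions `1000 * column index`, alleles A/G).
#' @param row_labels character vector of per-haplotype labels. Defaults to
#'   `hap1, hap2, ...`.
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `haps` (integer matrix), `sites` (data frame), `row_labels`.
#' @export
haplotype_matrix <- function(haps, sites = NULL, row_labels = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (length(haps) && !all(haps %in% c(0L, 1L)))
    stop("haplotype entries must be 0 or 1", call. = FALSE)
  if (is.null(sites)) sites <- default_sites(ncol(haps))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(needed %in% names(sites)))
    stop("sites must have columns chrom, pos, id, ref, alt", call. = FALSE)
  if (nrow(sites) != ncol(haps))
    stop("number of site records (", nrow(sites), ") does not match matrix columns (",
         ncol(haps), ")", call. = FALSE)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("site positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  if (is.null(row_labels)) row_labels <- paste0("hap", seq_len(nrow(haps)))
  if (length(row_labels) != nrow(haps))
    stop("row_labels length must equal haplotype count", call. = FALSE)
  dimnames(haps) <- NULL
  structure(list(haps = haps, sites = sites, row_labels = as.character(row_labels)),
            class = "haplotype_matrix")
}

default_sites <- function(n) {
  data.frame(chrom = rep("1", n),
             pos = if (n) 1000L * seq_len(n) else integer(0),
             id = rep(".", n),
             ref = rep("A", n),
             alt = rep("G", n),
             stringsAsFactors = FALSE)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", nrow(x$haps), " haplotypes x ", ncol(x$haps),
      " biallelic sites\n", sep = "")
  if (ncol(x$haps)) {
    f <- colMeans(x$haps)
    cat("  alt-allele frequency range: [", sprintf("%.3f", min(f)), ", ",
        sprintf("%.3f", max(f)), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$haps)

n_haplotypes <- function(x) nrow(x$haps)
n_sites <- function(x) ncol(x$haps)

#' Subset a haplotype matrix
#'
#' @param x a [haplotype_matrix()].
#' @param rows,cols integer indices of haplotype rows / variant sites to keep
#'   (default: all).
#' @return A `haplotype_matrix` restricted to the selection.
#' @export
subset_haplotypes <- function(x, rows = seq_len(nrow(x$haps)),
                              cols = seq_len(ncol(x$haps))) {
  stopifnot(inherits(x, "haplotype_matrix"))
  haplotype_matrix(x$haps[rows, cols, drop = FALSE],
                   sites = x$sites[cols, , drop = FALSE],
                   row_labels = x$row_labels[rows])
}

#' Filter sites by minor allele frequency
#'
#' Retains sites whose minor allele frequency `min(f, 1 - f)`, with `f` the
#' alternate-allele fraction over haplotype rows, is at least `min_maf`.
#' Site order is preserved. The comparison is done on allele counts so the
#' boundary case (e.g. 1 alternate allele in 100 rows at `min_maf = 0.01`)
#' is retained exactly.
#'
#' @param x a [haplotype_matrix()].
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @return The filtered `haplotype_matrix` (possibly with zero sites).
#' @export
filter_by_maf <- function(x, min_maf = 0.01) {
  stopifnot(inherits(x, "haplotype_matrix"))
  if (nrow(x$haps) == 0L) stop("empty haplotype matrix", call. = FALSE)
  if (min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5]", call. = FALSE)
  ac <- colSums(x$haps)
  mac <- pmin(ac, nrow(x$haps) - ac)
  keep <- mac >= min_maf * nrow(x$haps) - 1e-9
  subset_haplotypes(x, cols = which(keep))
}

#' Hamming distances from one query to every haplotype row
#'
#' @param x a [haplotype_matrix()].
#' @param query either a single row index into `x` or an external 0/1 vector
#'   whose length equals the site count.
#' @return Integer vector: entry `i` is the number of sites at which row `i`
#'   differs from the query (0 for the query row itself).
#' @export
hamming_distances <- function(x, query) {
  stopifnot(inherits(x, "haplotype_matrix"))
  if (length(query) == 1L && query == as.integer(query) &&
      query >= 1 && query <= nrow(x$haps)) {
    q <- x$haps[as.integer(query), ]
  } else {
    q <- as.integer(query)
    if (length(q) != ncol(x$haps))
      stop("query length (", length(q), ") does not match site count (",
           ncol(x$haps), ")", call. = FALSE)
  }
  as.integer(x$haps %*% (1L - q) + (1L - x$haps) %*% q)
}

# full pairwise Hamming matrix (rows x rows), used for clustering
hamming_matrix <- function(haps) {
  h <- haps %*% t(1L - haps)
  h + t(h)
}

# cross Hamming: rows of A x rows of B
hamming_cross <- function(a, b) {
  a %*% t(1L - b) + (1L - a) %*% t(b)
}
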