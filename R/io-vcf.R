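#' Read a phased VCF into a haplotype matrix
#'
#' Loads a VCF file, restricts it to biallelic single-nucleotide variants,
#' and transcribes the phased GT fields into a binary haplotype matrix with
#' two rows per diploid sample (adjacent, `sample_1` then `sample_2`).
#' Haploid GT fields (a bare `0`/`1`) are accepted and yield one row per
#' sample; ploidy must be consistent across the file.
#'
#' Multiallelic records and indels are skipped and counted. Sites containing
#' missing (`.`) or unphased (`/`) genotypes are an error under
#' `on_missing = "reject"` (naming the first offending site and sample) or
#' are dropped and counted under `on_missing = "drop_site"`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param on_missing `"reject"` (default) or `"drop_site"`.
#' @return A [haplotype_matrix()] with attribute `io_log`, a list with counts
#'   `n_records`, `n_multiallelic`, `n_not_snp`, `n_dropped_missing`.
#' @export
read_phased_vcf <- function(path, on_missing = c("reject", "drop_site")) {
  on_missing <- match.arg(on_missing)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n_records <- nrow(fix)
  if (n_records == 0L) stop("no variant records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- matrix(as.character(gt), nrow = n_records,
               dimnames = list(NULL, colnames(gt)))
  samples <- colnames(gt)

  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- !multi & fix$REF %in% bases & fix$ALT %in% bases
  log <- list(n_records = n_records,
              n_multiallelic = sum(multi),
              n_not_snp = sum(!snp & !multi),
              n_dropped_missing = 0L)
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  if (nrow(fix) == 0L)
    stop("no biallelic SNP records remain after filtering", call. = FALSE)

  missing <- is.na(gt) | grepl(".", gt, fixed = TRUE)
  unphased <- grepl("/", gt, fixed = TRUE)
  bad <- missing | unphased
  if (any(bad)) {
    if (on_missing == "reject") {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop("missing or unphased genotype at ", fix$CHROM[w[1]], ":",
           fix$POS[w[1]], " sample ", samples[w[2]],
           " (use on_missing = \"drop_site\" to discard such sites)",
           call. = FALSE)
    }
    drop <- unique(which(bad, arr.ind = TRUE)[, 1])
    log$n_dropped_missing <- length(drop)
    fix <- fix[-drop, , drop = FALSE]
    gt <- gt[-drop, , drop = FALSE]
    if (nrow(fix) == 0L)
      stop("no sites remain after dropping missing/unphased genotypes",
           call. = FALSE)
  }

  phased <- grepl("|", gt, fixed = TRUE)
  if (all(phased)) {
    alle <- strsplit(as.vector(gt), "|", fixed = TRUE)
    if (any(lengths(alle) != 2L))
      stop("only diploid phased genotypes (a|b) are supported", call. = FALSE)
    a <- matrix(as.integer(vapply(alle, `[`, "", 1L)), nrow = nrow(gt))
    b <- matrix(as.integer(vapply(alle, `[`, "", 2L)), nrow = nrow(gt))
    haps <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gt))
    haps[seq(1L, by = 2L, length.out = length(samples)), ] <- t(a)
    haps[seq(2L, by = 2L, length.out = length(samples)), ] <- t(b)
    labels <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  } else if (!any(phased)) {
    if (!all(gt %in% c("0", "1")))
      stop("haploid GT fields must be 0 or 1", call. = FALSE)
    haps <- t(matrix(as.integer(gt), nrow = nrow(gt)))
    labels <- samples
  } else {
    stop("mixed haploid and diploid GT fields are not supported", call. = FALSE)
  }
  if (any(!haps %in% c(0L, 1L)))
    stop("allele codes other than 0/1 found; input must be biallelic",
         call. = FALSE)

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  sites$id[is.na(sites$id)] <- "."
  out <- haplotype_matrix(haps, sites = sites, row_labels = labels)
  attr(out, "io_log") <- log
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' Under `pairing = "consecutive"`, rows `2k - 1` and `2k` become sample `k`'s
#' phased genotype `a|b` (the row count must be even). Under
#' `pairing = "none"` every haplotype becomes a haploid sample with a bare
#' allele in its GT field. The 0/1 matrix round-trips exactly through
#' [read_phased_vcf()]. No date is written into the header so identical
#' matrices produce byte-identical files.
#'
#' @param x a [haplotype_matrix()].
#' @param path output file path.
#' @param pairing `"consecutive"` (default) or `"none"`.
#' @param sample_prefix prefix for generated sample names.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path, pairing = c("consecutive", "none"),
                             sample_prefix = "SAMPLE") {
  stopifnot(inherits(x, "haplotype_matrix"))
  pairing <- match.arg(pairing)
  n <- nrow(x$haps)
  if (pairing == "consecutive" && n %% 2L != 0L)
    stop("consecutive pairing requires an even number of haplotype rows (got ",
         n, ")", call. = FALSE)
  if (pairing == "consecutive") {
    ns <- n %/% 2L
    a <- x$haps[seq(1L, by = 2L, length.out = ns), , drop = FALSE]
    b <- x$haps[seq(2L, by = 2L, length.out = ns), , drop = FALSE]
    gt <- matrix(paste0(t(a), "|", t(b)), nrow = ncol(x$haps))
  } else {
    ns <- n
    gt <- t(x$haps)
    mode(gt) <- "character"
  }
  sample_names <- sprintf("%s%d", sample_prefix, seq_len(ns))
  header <- c("##fileformat=VCFv4.2",
              "##source=logicgen",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- cbind(x$sites$chrom, x$sites$pos, x$sites$id, x$sites$ref,
                x$sites$alt, ".", "PASS", ".", "GT", gt)
  lines <- c(header, apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain 0/1 haplotype table
#'
#' A whitespace-separated text format: one row of 0/1 tokens per haplotype,
#' all rows the same length. An optional first line of base-pair positions
#' (any token outside `{0, 1}` marks it as a header) supplies site
#' coordinates; otherwise positions default to `1000 * column index`.
#'
#' @param path path to the table file.
#' @return A [haplotype_matrix()] with synthetic site metadata.
#' @export
read_haplotype_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty haplotype table: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  pos <- NULL
  if (!all(toks[[1]] %in% c("0", "1"))) {
    pos <- suppressWarnings(as.integer(toks[[1]]))
    if (any(is.na(pos)))
      stop("header line must contain integer positions", call. = FALSE)
    toks <- toks[-1]
    if (!length(toks)) stop("no data rows after header", call. = FALSE)
  }
  len <- lengths(toks)
  if (any(len != len[1]))
    stop("ragged row: line ", which(len != len[1])[1] + !is.null(pos),
         " has ", len[which(len != len[1])[1]], " tokens, expected ", len[1],
         call. = FALSE)
  flat <- unlist(toks, use.names = FALSE)
  if (!all(flat %in% c("0", "1"))) {
    bad <- which(!vapply(toks, function(t) all(t %in% c("0", "1")), TRUE))[1]
    stop("non-binary token in data row ", bad, call. = FALSE)
  }
  haps <- matrix(as.integer(flat), nrow = length(toks), byrow = TRUE)
  sites <- default_sites(ncol(haps))
  if (!is.null(pos)) {
    if (length(pos) != ncol(haps))
      stop("header has ", length(pos), " positions but rows have ",
           ncol(haps), " sites", call. = FALSE)
    sites$pos <- pos
  }
  haplotype_matrix(haps, sites = sites)
}

#' Write a plain 0/1 haplotype table
#'
#' @param x a [haplotype_matrix()].
#' @param path output path.
#' @param header write the site positions as a first line?
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path, header = TRUE) {
  stopifnot(inherits(x, "haplotype_matrix"))
  lines <- apply(x$haps, 1L, paste, collapse = " ")
  if (header) lines <- c(paste(x$sites$pos, collapse = " "), lines)
  writeLines(lines, path)
  invisible(path)
}
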