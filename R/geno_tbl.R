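#' Genotype table
#'
#' The central container for joint-genotyped calls at variant *and* invariant
#' sites. Genotypes are stored as two allele-index matrices (`0` = reference,
#' `1..k` = alternate alleles, `NA` = uncalled) plus a per-genotype depth
#' matrix, with site records and sample metadata as tibbles. Keeping the calls
#' in matrices makes the filtering cascade and the pairwise statistics cheap;
#' every analysis function returns an ordinary tibble.
#'
#' @param gt1,gt2 Integer matrices (samples x sites) of allele indices, `NA`
#'   for uncalled genotypes. An uncalled genotype must be `NA` in both.
#' @param dp Integer matrix (samples x sites) of per-genotype sequencing
#'   depth; `NA` allowed where uncalled.
#' @param sites Tibble with columns `contig`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated alternate alleles, `NA` for invariant sites), `qual`,
#'   and optionally `sex_linked` (logical).
#' @param samples Tibble with columns `sample`, `deme`, and optionally `lon`,
#'   `lat`, `sex`, `year`.
#'
#' @return An object of class `geno_tbl`.
#' @export
geno_tbl <- function(gt1, gt2, dp, sites, samples) {
  stopifnot(is.matrix(gt1), is.matrix(gt2), is.matrix(dp))
  if (!identical(dim(gt1), dim(gt2)) || !identical(dim(gt1), dim(dp))) {
    abort("gt1, gt2 and dp must share dimensions (samples x sites).")
  }
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  if (nrow(samples) != nrow(gt1)) {
    abort("nrow(samples) must equal nrow(gt1) (one row per sample).")
  }
  if (nrow(sites) != ncol(gt1)) {
    abort("nrow(sites) must equal ncol(gt1) (one row per site).")
  }
  if (anyDuplicated(samples$sample)) abort("sample ids must be unique.")
  if (any(sites$pos < 1)) abort("site positions are 1-based; pos >= 1 required.")
  ord_ok <- all(unlist(lapply(
    split(sites$pos, factor(sites$contig, levels = unique(sites$contig))),
    function(p) all(diff(p) > 0)
  )))
  if (!ord_ok) abort("sites must be strictly increasing in pos within contig.")
  miss_mismatch <- xor(is.na(gt1), is.na(gt2))
  if (any(miss_mismatch)) abort("uncalled genotypes must be NA in both gt1 and gt2.")
  dimnames(gt1) <- dimnames(gt2) <- dimnames(dp) <-
    list(samples$sample, NULL)
  structure(
    list(gt1 = gt1, gt2 = gt2, dp = dp, sites = sites, samples = samples),
    class = "geno_tbl"
  )
}

#' @export
print.geno_tbl <- function(x, ...) {
  nv <- sum(n_alt_alleles(x) > 0)
  cat(sprintf(
    "<geno_tbl> %d samples x %d sites (%d variant, %d invariant), %d contigs\n",
    n_samples(x), n_sites(x), nv, n_sites(x) - nv,
    length(unique(x$sites$contig))
  ))
  cat(sprintf("  call rate: %.3f\n", mean(is_called(x))))
  if ("deme" %in% names(x$samples)) {
    tab <- table(x$samples$deme)
    cat("  demes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Dimensions of a genotype table
#' @param x A [geno_tbl()].
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$gt1)

#' @rdname n_samples
#' @export
n_sites <- function(x) ncol(x$gt1)

#' Number of alternate alleles per site
#' @param x A [geno_tbl()].
#' @return Integer vector, 0 for invariant sites.
#' @export
n_alt_alleles <- function(x) {
  alt <- x$sites$alt
  out <- integer(length(alt))
  has <- !is.na(alt) & alt != "" & alt != "."
  out[has] <- lengths(strsplit(alt[has], ",", fixed = TRUE))
  out
}

#' Called-genotype indicator matrix
#' @param x A [geno_tbl()].
#' @return Logical matrix (samples x sites).
#' @export
is_called <- function(x) !is.na(x$gt1)

#' Heterozygous-genotype indicator matrix
#' @param x A [geno_tbl()].
#' @return Logical matrix, `NA` where uncalled.
#' @export
is_het <- function(x) x$gt1 != x$gt2

#' Alternate-allele dosage matrix for biallelic sites
#'
#' Codes called genotypes at biallelic (single-ALT) sites as 0/1/2 copies of
#' the alternate allele. Columns for invariant or multiallelic sites are NA.
#'
#' @param x A [geno_tbl()].
#' @return Numeric matrix (samples x sites).
#' @export
alt_dosage <- function(x) {
  d <- x$gt1 + x$gt2
  d[, n_alt_alleles(x) != 1L] <- NA_real_
  storage.mode(d) <- "double"
  d
}

#' Subset a genotype table
#'
#' @param x A [geno_tbl()].
#' @param samples Logical/integer/character index into samples (optional).
#' @param sites Logical or integer index into sites (optional).
#' @return A `geno_tbl`.
#' @export
gt_subset <- function(x, samples = NULL, sites = NULL) {
  si <- seq_len(n_samples(x))
  li <- seq_len(n_sites(x))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample) else si[samples]
    if (anyNA(si)) abort("unknown sample id in subset.")
  }
  if (!is.null(sites)) li <- li[sites]
  geno_tbl(
    x$gt1[si, li, drop = FALSE], x$gt2[si, li, drop = FALSE],
    x$dp[si, li, drop = FALSE],
    x$sites[li, , drop = FALSE], x$samples[si, , drop = FALSE]
  )
}

#' Deme assignment helper
#' @param x A [geno_tbl()].
#' @return Factor of deme labels, one per sample.
#' @export
deme_of <- function(x) {
  if (!"deme" %in% names(x$samples)) abort("samples tibble has no 'deme' column.")
  factor(x$samples$deme)
}

#' Summarise a genotype table as a tibble
#'
#' One row per sample with call counts, useful at the head of a pipe.
#'
#' @param x A [geno_tbl()].
#' @param ... Unused.
#' @return A tibble: sample, deme, n_called, n_missing, missingness.
#' @export
#' @method as_tibble geno_tbl
as_tibble.geno_tbl <- function(x, ...) {
  called <- rowSums(is_called(x))
  dplyr::mutate(
    x$samples,
    n_called = called,
    n_missing = n_sites(x) - called,
    missingness = 1 - called / n_sites(x)
  )
}
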