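#' Per-individual retention filter for heterozygosity
#'
#' Filtering is individual-specific: for one sample it drops missing calls,
#' calls at sites whose alternate alleles include the spanning-deletion
#' symbol `*` (or whose genotype references it), and calls with depth below
#' `min_dp` or above `max_dp` (a call at exactly either bound is kept).
#'
#' @param table A [geno_tbl()].
#' @param sample A sample id present in the table.
#' @param min_dp,max_dp Per-genotype depth window (defaults 15 and 95).
#' @return Tibble of retained calls for that sample: `site` (index),
#'   `contig`, `pos`, `depth`, `n_records` (after atomization), `n_het`
#'   (heterozygous records).
#' @export
per_individual_site_filter <- function(table, sample, min_dp = 15,
                                       max_dp = 95) {
  i <- match(sample, table$samples$sample)
  if (is.na(i)) abort(sprintf("unknown sample id '%s'.", sample))
  keep <- individual_retention_mask(table, min_dp, max_dp)[i, ]
  rec <- atomized_record_counts(table)
  idx <- which(keep)
  tibble(
    site = idx,
    contig = table$sites$contig[idx],
    pos = table$sites$pos[idx],
    depth = table$dp[i, idx],
    n_records = rec$n_records[idx],
    n_het = rec$het_records[i, idx]
  )
}

# samples x sites logical retention under the per-individual rules
individual_retention_mask <- function(table, min_dp, max_dp,
                                      exclude_sites = NULL) {
  star <- !is.na(table$sites$alt) &
    vapply(strsplit(ifelse(is.na(table$sites$alt), "", table$sites$alt), ",",
                    fixed = TRUE),
           function(a) any(a == "*"), logical(1))
  keep <- is_called(table) &
    table$dp >= min_dp & table$dp <= max_dp
  keep[, star] <- FALSE
  if (!is.null(exclude_sites)) keep[, exclude_sites] <- FALSE
  keep[is.na(keep)] <- FALSE
  keep
}

#' Atomize a multiallelic site into biallelic records
#'
#' Mirrors the atomization convention of variant normalisers: a site with k
#' alternate alleles yields k records, one per alternate; in record `a`,
#' genotype alleles equal to `a` stay alternate and all others are recoded
#' to reference. A genotype made of two different alternate alleles is
#' therefore heterozygous in each of its records. Biallelic and invariant
#' sites pass through as a single record.
#'
#' @param table A [geno_tbl()].
#' @param site Site index.
#' @return Tibble with one row per (derived record, sample): `record_alt`
#'   (the alternate allele the record isolates), `sample`, `gt1`, `gt2`
#'   (recoded 0/1), `het`.
#' @export
atomize_multiallelic <- function(table, site) {
  nalt <- n_alt_alleles(table)[site]
  alts <- if (nalt > 0) {
    strsplit(table$sites$alt[site], ",", fixed = TRUE)[[1]]
  } else {
    NA_character_
  }
  a1 <- table$gt1[, site]; a2 <- table$gt2[, site]
  recs <- lapply(seq_len(max(1L, nalt)), function(a) {
    r1 <- ifelse(is.na(a1), NA_integer_, as.integer(a1 == a))
    r2 <- ifelse(is.na(a2), NA_integer_, as.integer(a2 == a))
    tibble(
      record_alt = if (nalt > 0) alts[a] else NA_character_,
      sample = table$samples$sample,
      gt1 = r1, gt2 = r2,
      het = r1 != r2
    )
  })
  dplyr::bind_rows(recs)
}

# closed form for the atomized record counts: a site with k alts gives
# max(1, k) records; a called genotype (a, b) is heterozygous in
# (a > 0) + (b > 0 & b != a) of them when a != b, none when a == b
atomized_record_counts <- function(table) {
  nalt <- n_alt_alleles(table)
  g1 <- table$gt1; g2 <- table$gt2
  het <- (g1 != g2) * ((g1 > 0) + (g2 > 0 & g2 != g1))
  het[is.na(het)] <- 0
  list(n_records = pmax(1L, nalt), het_records = het)
}

#' Per-individual autosomal heterozygosity
#'
#' Observed heterozygosity per individual over *all* retained records —
#' variant and invariant alike — so estimates are comparable across
#' individuals regardless of which sites segregate in the sample:
#' `H_O = heterozygous retained records / all retained records`, after the
#' per-individual filters of [per_individual_site_filter()] and atomization
#' of multiallelic sites.
#'
#' @param table A [geno_tbl()].
#' @param min_dp,max_dp Per-genotype depth window.
#' @param exclude_sites Optional site indices (or logical mask) removed for
#'   every individual, e.g. loci flagged by [sex_linkage_screen()].
#' @param samples Optional subset of sample ids.
#' @return Tibble: `sample`, `n_retained`, `n_het`, `h_o`.
#' @export
autosomal_het <- function(table, min_dp = 15, max_dp = 95,
                          exclude_sites = NULL, samples = NULL) {
  if (!is.null(samples)) table <- gt_subset(table, samples = samples)
  keep <- individual_retention_mask(table, min_dp, max_dp, exclude_sites)
  rec <- atomized_record_counts(table)
  n_retained <- as.vector(keep %*% rec$n_records)
  n_het <- rowSums(keep * rec$het_records)
  if (any(n_retained == 0)) {
    abort(sprintf(
      "no retained records for sample(s): %s",
      paste(table$samples$sample[n_retained == 0], collapse = ", ")
    ))
  }
  tibble(
    sample = table$samples$sample,
    n_retained = as.integer(n_retained),
    n_het = as.integer(round(n_het)),
    h_o = n_het / n_retained
  )
}

#' Per-deme inbreeding coefficient F_IS
#'
#' Within each deme, every biallelic locus polymorphic in that deme with at
#' least two called individuals contributes
#' `F_locus = 1 - H_obs / H_exp` with `H_exp = 2 p (1 - p)` at the deme
#' allele frequency; the deme's F_IS is the unweighted mean over
#' contributing loci. With `hexp_correction = TRUE` the small-sample
#' corrected `H_exp * 2n / (2n - 1)` is used instead.
#'
#' @param table A [geno_tbl()] with deme labels.
#' @param hexp_correction Apply the small-sample correction to H_exp.
#' @return Tibble: `deme`, `f_is`, `n_loci`, `n_samples`, `reliable`
#'   (FALSE when the deme has fewer than 2 samples; computed regardless).
#' @export
deme_fis <- function(table, hexp_correction = FALSE) {
  demes <- deme_of(table)
  d <- alt_dosage(table)
  out <- lapply(levels(demes), function(dm) {
    rows <- which(demes == dm)
    dd <- d[rows, , drop = FALSE]
    called <- !is.na(dd)
    n_called <- colSums(called)
    p <- colSums(dd, na.rm = TRUE) / (2 * n_called)
    h_obs <- colSums(dd == 1, na.rm = TRUE) / n_called
    h_exp <- 2 * p * (1 - p)
    if (hexp_correction) h_exp <- h_exp * 2 * n_called / (2 * n_called - 1)
    use <- n_called >= 2 & !is.na(h_exp) & h_exp > 0
    f <- 1 - h_obs[use] / h_exp[use]
    tibble(
      deme = dm,
      f_is = if (any(use)) mean(f) else NA_real_,
      n_loci = sum(use),
      n_samples = length(rows),
      reliable = length(rows) >= 2
    )
  })
  dplyr::bind_rows(out)
}

#' Heterozygosity profile along a concatenated pseudogenome
#'
#' Contigs are ordered by descending length (taken as the largest observed
#' site position per contig) and concatenated; non-overlapping windows of
#' `window_bp` tile the pseudogenome. Per window and individual, H_O is
#' computed with the same per-individual filters as [autosomal_het()];
#' windows whose retained-record count falls below `min_records` are
#' reported as absent (no row), never as zero.
#'
#' @param table A [geno_tbl()].
#' @param window_bp Window width in bp.
#' @param min_dp,max_dp Per-genotype depth window.
#' @param min_records Denominator floor below which a window is absent.
#' @return Tibble: `sample`, `window`, `start` (pseudogenome bp, 1-based),
#'   `n_records`, `n_het`, `h_o`.
#' @export
window_profile <- function(table, window_bp = 1e5, min_dp = 15, max_dp = 95,
                           min_records = 50) {
  stopifnot(window_bp > 0)
  contig_len <- tapply(table$sites$pos, table$sites$contig, max)
  ord <- names(sort(contig_len, decreasing = TRUE))
  offset <- setNames(cumsum(c(0, contig_len[ord][-length(ord)])), ord)
  pseudo_pos <- offset[table$sites$contig] + table$sites$pos
  win <- floor((pseudo_pos - 1) / window_bp)

  keep <- individual_retention_mask(table, min_dp, max_dp)
  rec <- atomized_record_counts(table)
  nrec_m <- sweep(keep + 0, 2, rec$n_records, "*")
  het_m <- keep * rec$het_records

  wf <- factor(win)
  n_by_win <- t(rowsum(t(nrec_m), wf))    # samples x windows
  h_by_win <- t(rowsum(t(het_m), wf))
  out <- tibble(
    sample = rep(table$samples$sample, times = ncol(n_by_win)),
    window = rep(as.integer(levels(wf)), each = n_samples(table)),
    n_records = as.integer(n_by_win),
    n_het = as.integer(h_by_win)
  )
  out <- dplyr::filter(out, .data$n_records >= min_records)
  dplyr::mutate(out,
                start = .data$window * window_bp + 1,
                h_o = .data$n_het / .data$n_records)
}

#' Regress heterozygosity on a covariate
#'
#' Ordinary least squares of H_O on one covariate (e.g. retained-site count
#' or sampling year), used to check that individual heterozygosity is not an
#' artefact of data quantity or collection time.
#'
#' @param results Tibble from [autosomal_het()] (needs `h_o`).
#' @param covariate A numeric vector aligned with `results`, or the name of
#'   a column in `results`.
#' @return One-row tibble: `slope`, `r_squared`, `p_value`, `n`.
#' @export
het_covariate_check <- function(results, covariate) {
  y <- results$h_o
  x <- if (is.character(covariate) && length(covariate) == 1) {
    results[[covariate]]
  } else {
    covariate
  }
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- y[ok]
  if (length(y) < 3) abort("need at least 3 individuals for the regression.")
  if (var(x) == 0) abort("covariate has zero variance.")
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = length(y)
  )
}
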