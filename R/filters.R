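#' Locus call-rate filter
#'
#' Retains loci whose call rate over all samples exceeds `overall_rate` and
#' whose within-deme call rate exceeds `per_deme_rate` in at least
#' `min_demes` demes (default: every deme, mirroring a populations-style
#' `-R/-r/-p` filter).
#'
#' @param table A [geno_tbl()] with a `deme` column in its samples.
#' @param overall_rate Call-rate threshold across all samples (strict `>`).
#' @param per_deme_rate Within-deme call-rate threshold (strict `>`).
#' @param min_demes Minimum demes that must clear `per_deme_rate`;
#'   `NULL` = all demes present.
#' @return List: `table` (filtered [geno_tbl()]) and `report` (one-row
#'   tibble; see [filter_report()]).
#' @export
locus_call_rate_filter <- function(table, overall_rate = 0.85,
                                   per_deme_rate = 0.5, min_demes = NULL) {
  stopifnot(overall_rate >= 0, overall_rate <= 1,
            per_deme_rate >= 0, per_deme_rate <= 1)
  if (anyNA(table$samples$deme)) {
    bad <- table$samples$sample[is.na(table$samples$deme)]
    abort(sprintf("sample(s) without a deme label: %s",
                  paste(bad, collapse = ", ")))
  }
  demes <- deme_of(table)
  if (is.null(min_demes)) min_demes <- nlevels(demes)
  called <- is_called(table)
  overall <- colMeans(called)
  per_deme <- rowsum(called + 0, demes) / as.vector(table(demes))
  n_pass_deme <- colSums(per_deme > per_deme_rate)
  keep <- overall > overall_rate & n_pass_deme >= min_demes
  out <- gt_subset(table, sites = keep)
  list(table = out,
       report = filter_report("locus_call_rate", table, out,
                              overall_rate = overall_rate,
                              per_deme_rate = per_deme_rate,
                              min_demes = min_demes))
}

#' Sample missingness filter
#'
#' Retains samples whose fraction of missing calls is strictly below
#' `max_missing` (a sample at exactly the threshold is dropped).
#'
#' @param table A [geno_tbl()].
#' @param max_missing Missingness cut-off in \[0, 1\].
#' @return List: `table`, `report`, and `retention` (a one-row tibble with
#'   samples in/out and the retention percentage rounded to integer percent).
#' @export
sample_missingness_filter <- function(table, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  missing_frac <- rowSums(!is_called(table)) / n_sites(table)
  keep <- missing_frac < max_missing
  out <- gt_subset(table, samples = keep)
  retention <- tibble(
    samples_in = n_samples(table),
    samples_out = sum(keep),
    retention_pct = round(100 * sum(keep) / n_samples(table))
  )
  list(table = out,
       report = filter_report("sample_missingness", table, out,
                              max_missing = max_missing),
       retention = retention)
}

#' Minor-allele-count filter
#'
#' Retains loci whose minor allele count over called genotypes is at least
#' `min_mac`. Counts every allele index (multiallelic loci use the count of
#' the rarest observed allele as MAC if two or more alleles are present;
#' a locus where a single allele is observed has MAC 0). Invariant sites
#' are removed whenever `min_mac >= 1`.
#'
#' @param table A [geno_tbl()].
#' @param min_mac Minimum minor allele count.
#' @return A filtered [geno_tbl()].
#' @export
mac_filter <- function(table, min_mac = 3) {
  stopifnot(min_mac >= 0)
  keep <- locus_mac(table) >= min_mac
  gt_subset(table, sites = keep)
}

#' @rdname mac_filter
#' @return `locus_mac()`: integer vector of per-locus minor allele counts.
#' @export
locus_mac <- function(table) {
  nalt <- n_alt_alleles(table)
  alt_cnt <- colSums(table$gt1 > 0, na.rm = TRUE) +
    colSums(table$gt2 > 0, na.rm = TRUE)
  tot <- 2L * colSums(is_called(table))
  mac <- pmin(alt_cnt, tot - alt_cnt)
  mac[tot == 0] <- 0L
  # multiallelic loci: MAC is the total minus the count of the commonest allele
  for (l in which(nalt > 1)) {
    a <- c(table$gt1[, l], table$gt2[, l])
    a <- a[!is.na(a)]
    if (length(a) == 0) { mac[l] <- 0L; next }
    tab <- table(a)
    mac[l] <- if (length(tab) < 2) 0L else as.integer(sum(tab) - max(tab))
  }
  as.integer(mac)
}

#' Mean-depth window filter
#'
#' Retains loci whose mean depth over called genotypes lies inside
#' `[min_mean_dp, max_mean_dp]` (inclusive). A locus with no called
#' genotypes fails. The upper bound can be derived from the data with
#' [li_max_depth()].
#'
#' @param table A [geno_tbl()].
#' @param min_mean_dp,max_mean_dp Bounds on the per-locus mean depth.
#' @return A filtered [geno_tbl()].
#' @export
depth_window_filter <- function(table, min_mean_dp = 5, max_mean_dp = 95) {
  stopifnot(min_mean_dp >= 0, min_mean_dp < max_mean_dp)
  called <- is_called(table)
  dp <- table$dp
  dp[!called] <- NA_integer_
  mean_dp <- colMeans(dp, na.rm = TRUE)
  keep <- !is.nan(mean_dp) & mean_dp >= min_mean_dp & mean_dp <= max_mean_dp
  gt_subset(table, sites = keep)
}

#' Maximum read-depth rule
#'
#' Rule-of-thumb ceiling for mean sequencing depth: `d + coefficient *
#' sqrt(d)` for genome-wide mean depth `d`, beyond which excess depth tends
#' to mark collapsed repeats and mapping artefacts.
#'
#' @param mean_depth Genome-wide mean depth (> 0).
#' @param coefficient Multiplier on `sqrt(mean_depth)`; default 4.
#' @return The depth ceiling (numeric scalar).
#' @export
li_max_depth <- function(mean_depth, coefficient = 4) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("mean_depth must be positive.")
  }
  mean_depth + coefficient * sqrt(mean_depth)
}

#' Site-quality filter
#'
#' Retains loci whose site quality is at least `min_qual` (a stand-in for a
#' caller's hard-filter battery when only a single QUAL scalar is carried).
#'
#' @param table A [geno_tbl()].
#' @param min_qual Minimum site quality.
#' @return A filtered [geno_tbl()].
#' @export
site_quality_filter <- function(table, min_qual = 30) {
  q <- table$sites$qual
  keep <- !is.na(q) & q >= min_qual
  gt_subset(table, sites = keep)
}

#' Distance thinning of loci
#'
#' Greedy left-to-right walk per contig: the first site is kept, and each
#' subsequent site only if it lies at least `min_distance_bp` beyond the
#' last *kept* site. Contigs are independent. Input must already be
#' position-sorted (the constructor enforces this); an unsorted table is an
#' error, never silently sorted.
#'
#' @param table A [geno_tbl()].
#' @param min_distance_bp Minimum spacing between kept sites, bp.
#' @return A thinned [geno_tbl()].
#' @export
thin_loci <- function(table, min_distance_bp = 10000) {
  stopifnot(min_distance_bp >= 0)
  contig <- factor(table$sites$contig, levels = unique(table$sites$contig))
  pos <- table$sites$pos
  if (any(unlist(lapply(split(pos, contig), function(p) any(diff(p) <= 0))))) {
    abort("sites are not position-sorted within contig; refusing to sort silently.")
  }
  keep <- logical(n_sites(table))
  for (idx in split(seq_along(pos), contig)) {
    last_kept <- -Inf
    for (i in idx) {
      if (pos[i] - last_kept >= min_distance_bp) {
        keep[i] <- TRUE
        last_kept <- pos[i]
      }
    }
  }
  gt_subset(table, sites = keep)
}

#' Stage report for a filtering step
#'
#' @param stage Stage name.
#' @param before,after The [geno_tbl()] before and after the stage.
#' @param ... Named thresholds applied, recorded as a `params` string.
#' @return One-row tibble: stage, sites/samples in and out, params.
#' @export
filter_report <- function(stage, before, after, ...) {
  ps <- list(...)
  tibble(
    stage = stage,
    sites_in = n_sites(before), sites_out = n_sites(after),
    samples_in = n_samples(before), samples_out = n_samples(after),
    params = paste(names(ps), vapply(ps, function(x)
      paste(format(x), collapse = "/"), character(1)),
      sep = "=", collapse = ", ")
  )
}

#' Run the full locus/sample filtering cascade
#'
#' Stage order: site quality, first-pass locus call rate, sample
#' missingness, second-pass (stricter) locus call rate, minor allele count,
#' mean-depth window, optional distance thinning. Defaults follow a
#' RADseq-style pipeline: call rates 0.70 then 0.85 overall with 0.50 in
#' every deme, <10% per-sample missingness, MAC 3, mean depth in \[5, 95\],
#' thinning off (enable with `thin_bp = 10000` for linkage-sensitive
#' analyses).
#'
#' @param table A [geno_tbl()].
#' @param min_qual Site-quality floor (`NULL` skips the stage).
#' @param first_overall_rate,overall_rate First- and second-pass overall
#'   call-rate thresholds.
#' @param per_deme_rate,min_demes Within-deme call-rate rule.
#' @param max_missing Per-sample missingness cut-off.
#' @param min_mac Minimum minor allele count.
#' @param min_mean_dp,max_mean_dp Mean-depth window.
#' @param thin_bp Thinning distance in bp, or `NULL` to skip.
#' @return List: `table` (filtered) and `report` (tibble of per-stage rows).
#' @export
filter_cascade <- function(table,
                           min_qual = 30,
                           first_overall_rate = 0.70,
                           overall_rate = 0.85,
                           per_deme_rate = 0.5,
                           min_demes = NULL,
                           max_missing = 0.10,
                           min_mac = 3,
                           min_mean_dp = 5,
                           max_mean_dp = 95,
                           thin_bp = NULL) {
  reports <- list()
  push <- function(stage, before, after, ...) {
    reports[[length(reports) + 1]] <<- filter_report(stage, before, after, ...)
  }
  cur <- table
  if (!is.null(min_qual)) {
    nxt <- site_quality_filter(cur, min_qual)
    push("site_quality", cur, nxt, min_qual = min_qual)
    cur <- nxt
  }
  step <- locus_call_rate_filter(cur, first_overall_rate, 0, min_demes = 0)
  reports[[length(reports) + 1]] <- step$report
  cur <- step$table
  step <- sample_missingness_filter(cur, max_missing)
  reports[[length(reports) + 1]] <- step$report
  cur <- step$table
  step <- locus_call_rate_filter(cur, overall_rate, per_deme_rate, min_demes)
  reports[[length(reports) + 1]] <- step$report
  cur <- step$table
  nxt <- mac_filter(cur, min_mac)
  push("mac", cur, nxt, min_mac = min_mac)
  cur <- nxt
  nxt <- depth_window_filter(cur, min_mean_dp, max_mean_dp)
  push("depth_window", cur, nxt, min_mean_dp = min_mean_dp,
       max_mean_dp = max_mean_dp)
  cur <- nxt
  if (!is.null(thin_bp)) {
    nxt <- thin_loci(cur, thin_bp)
    push("thin", cur, nxt, thin_bp = thin_bp)
    cur <- nxt
  }
  list(table = cur, report = dplyr::bind_rows(reports))
}
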