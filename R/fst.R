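#' Weir-Cockerham variance components for one deme pair
#'
#' Per biallelic locus with at least `min_called` called individuals in each
#' deme, computes the among-population (a), among-individual (b) and
#' within-individual (c) variance components of the Weir & Cockerham (1984)
#' estimator with unequal sample sizes (two-population case).
#'
#' @param table A [geno_tbl()] with deme labels.
#' @param deme_a,deme_b Deme labels.
#' @param min_called Minimum called individuals per deme per locus.
#' @return Tibble: `site`, `a`, `b`, `c` for each contributing locus.
#' @keywords internal
wc_components <- function(table, deme_a, deme_b, min_called = 2) {
  demes <- as.character(deme_of(table))
  rows_a <- which(demes == deme_a)
  rows_b <- which(demes == deme_b)
  if (length(rows_a) == 0) abort(sprintf("deme '%s' is empty.", deme_a))
  if (length(rows_b) == 0) abort(sprintf("deme '%s' is empty.", deme_b))
  d <- alt_dosage(table)
  da <- d[rows_a, , drop = FALSE]
  db <- d[rows_b, , drop = FALSE]

  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- colSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(da == 1, na.rm = TRUE) / n1
  h2 <- colSums(db == 1, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  use <- n1 >= min_called & n2 >= min_called & !is.na(pbar) &
    pbar > 0 & pbar < 1
  tibble(site = which(use), a = a[use], b = b[use], c = cc[use])
}

#' Multilocus Weir-Cockerham F_ST for one deme pair
#'
#' Ratio of sums over loci, `theta = sum(a) / sum(a + b + c)` — not the mean
#' of per-locus ratios. Loci with zero total variance contribute nothing.
#'
#' @inheritParams wc_components
#' @return One-row tibble: `deme_a`, `deme_b`, `theta`, `n_loci`.
#' @export
wc_theta <- function(table, deme_a, deme_b, min_called = 2) {
  comp <- wc_components(table, deme_a, deme_b, min_called)
  nz <- comp$a + comp$b + comp$c != 0
  tibble(
    deme_a = deme_a, deme_b = deme_b,
    theta = sum(comp$a[nz]) / sum((comp$a + comp$b + comp$c)[nz]),
    n_loci = sum(nz)
  )
}

#' Pairwise F_ST with locus-bootstrap significance
#'
#' For each deme pair (all pairs by default), computes multilocus
#' Weir-Cockerham theta and a locus bootstrap: loci are resampled with
#' replacement `n_boot` times, giving a percentile confidence interval and a
#' one-sided p-value (the fraction of bootstrap thetas at or below zero —
#' differentiation is only meaningful in the positive direction). Pairs are
#' flagged significant at the Bonferroni-corrected per-test level
#' `alpha_tablewide / n_pairs`.
#'
#' @param table A [geno_tbl()] with deme labels.
#' @param pairs Optional two-column data frame of deme pairs; default all
#'   unordered pairs of demes present.
#' @param n_boot Bootstrap replicates (>= 100 recommended; fewer runs with a
#'   warning).
#' @param alpha_tablewide Table-wide alpha shared across pairs (default
#'   0.01).
#' @param min_called Minimum called individuals per deme per locus.
#' @return A tibble of class `fst_matrix`: `deme_a`, `deme_b`, `theta`,
#'   `ci_lo`, `ci_hi` (2.5/97.5 bootstrap percentiles), `p`, `significant`,
#'   `n_loci`. Attribute `alpha_per_test` records the corrected level.
#' @export
fst_bootstrap <- function(table, pairs = NULL, n_boot = 10000,
                          alpha_tablewide = 0.01, min_called = 2) {
  if (n_boot < 100) {
    warn(sprintf("n_boot = %d is below 100; intervals will be coarse.", n_boot))
  }
  if (is.null(pairs)) {
    dl <- levels(deme_of(table))
    idx <- utils::combn(length(dl), 2)
    pairs <- tibble(deme_a = dl[idx[1, ]], deme_b = dl[idx[2, ]])
  }
  pairs <- as_tibble(pairs)
  names(pairs)[1:2] <- c("deme_a", "deme_b")
  alpha_per_test <- alpha_tablewide / nrow(pairs)

  out <- purrr::pmap(pairs, function(deme_a, deme_b, ...) {
    comp <- wc_components(table, deme_a, deme_b, min_called)
    a <- comp$a
    abc <- comp$a + comp$b + comp$c
    theta <- sum(a) / sum(abc)
    L <- length(a)
    boot <- vapply(seq_len(n_boot), function(k) {
      idx <- sample.int(L, L, replace = TRUE)
      sum(a[idx]) / sum(abc[idx])
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    p <- mean(boot <= 0)
    tibble(
      deme_a = deme_a, deme_b = deme_b, theta = theta,
      ci_lo = ci[1], ci_hi = ci[2], p = p,
      significant = p < alpha_per_test, n_loci = L
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "alpha_per_test") <- alpha_per_test
  class(res) <- c("fst_matrix", class(res))
  res
}

#' Lower-triangle F_ST table with deme means
#'
#' Reshapes a [fst_bootstrap()] result into the conventional lower-triangle
#' matrix layout with a per-deme mean pairwise F_ST column.
#'
#' @param fst A `fst_matrix` tibble.
#' @return Tibble: one row per deme, pairwise columns (lower triangle) and
#'   `mean_fst`.
#' @export
fst_table <- function(fst) {
  demes <- unique(c(fst$deme_a, fst$deme_b))
  m <- matrix(NA_real_, length(demes), length(demes),
              dimnames = list(demes, demes))
  for (k in seq_len(nrow(fst))) {
    m[fst$deme_b[k], fst$deme_a[k]] <- fst$theta[k]
    m[fst$deme_a[k], fst$deme_b[k]] <- fst$theta[k]
  }
  mean_fst <- rowMeans(m, na.rm = TRUE)
  low <- m
  low[upper.tri(low, diag = TRUE)] <- NA_real_
  dplyr::bind_cols(tibble(deme = demes), as_tibble(low),
                   tibble(mean_fst = mean_fst))
}

#' Private alleles per deme
#'
#' An allele (at any locus, reference or alternate) is private to a deme
#' when it is observed in called genotypes of that deme and of no other.
#'
#' @param table A [geno_tbl()] with deme labels.
#' @return Tibble: `deme`, `private_alleles`.
#' @export
private_alleles <- function(table) {
  demes <- deme_of(table)
  dl <- levels(demes)
  max_allele <- max(c(table$gt1, table$gt2), na.rm = TRUE)
  # presence[d, (site, allele)] flattened over alleles 0..max_allele
  presence <- vapply(0:max_allele, function(a) {
    hit <- (table$gt1 == a) | (table$gt2 == a)
    hit[is.na(hit)] <- FALSE
    rowsum(hit + 0, demes) > 0
  }, matrix(TRUE, length(dl), n_sites(table)))
  n_demes_with <- apply(presence, c(2, 3), sum)
  counts <- vapply(seq_along(dl), function(d) {
    sum(presence[d, , ][n_demes_with == 1])
  }, numeric(1))
  tibble(deme = dl, private_alleles = as.integer(counts))
}
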