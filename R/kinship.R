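#' Moment-estimator kinship screen
#'
#' For every unordered sample pair, computes the robust within-pair moment
#' kinship estimate and a frequency-normalised estimate of the probability
#' of sharing no alleles identical by descent (K0), over biallelic
#' polymorphic loci called in both samples:
#'
#' * `K = (N_het.both - 2 * N_opp.hom) / (N_het.i + N_het.j)`, where
#'   `N_het.both` counts loci heterozygous in both, `N_opp.hom` loci where
#'   the pair are opposite homozygotes, and `N_het.i`/`N_het.j` the
#'   heterozygote counts of each member over the shared loci.
#' * `K0 = N_opp.hom / sum_l 2 p_l^2 (1-p_l)^2`, the opposite-homozygote
#'   count normalised by its expectation for an unrelated pair at the pooled
#'   allele frequencies, clamped to \[0, 1\].
#'
#' K0 near 0 marks parent-offspring pairs; full and half siblings sit at
#' 0.25 or higher; unrelated pairs near 1. Duplicated samples approach
#' K = 0.5, K0 = 0.
#'
#' @param table A [geno_tbl()] with at least 2 samples; at least 100
#'   polymorphic loci are recommended for stable estimates.
#' @param thresholds Classification rule, a list with elements
#'   `k_first = c(0.177, 0.354)` (first-degree K window),
#'   `k_half = c(0.088, 0.177)` (half-sibling window) and `k0_po = 0.1`
#'   (K0 below which a first-degree pair is called parent-offspring).
#' @return Tibble with one row per unordered pair: `sample_i`, `sample_j`,
#'   `n_shared` (loci used), `k`, `k0`, `class` (`"parent-offspring"`,
#'   `"full-sib"`, `"half-sib"` or `"unrelated"`).
#' @export
kinship_screen <- function(table,
                           thresholds = list(k_first = c(0.177, 0.354),
                                             k_half = c(0.088, 0.177),
                                             k0_po = 0.1)) {
  if (n_samples(table) < 2) abort("kinship_screen needs at least 2 samples.")
  d <- alt_dosage(table)
  n_called <- colSums(!is.na(d))
  p_all <- colSums(d, na.rm = TRUE) / (2 * pmax(1, n_called))
  poly <- which(n_called > 0 & p_all > 0 & p_all < 1)
  if (length(poly) == 0) {
    abort("no biallelic polymorphic loci; kinship is undefined.")
  }
  d <- d[, poly, drop = FALSE]
  called <- !is.na(d)
  p <- p_all[poly]

  H <- (d == 1); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  A0 <- (d == 0); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A2 <- (d == 2); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  C <- called + 0

  het_both <- tcrossprod(H)
  opp <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  het_shared <- tcrossprod(H, C)          # [i,j] = het in i & called in j
  e <- 2 * p^2 * (1 - p)^2
  e_shared <- tcrossprod(sweep(C, 2, e, "*"), C)
  n_shared <- tcrossprod(C)

  n <- n_samples(table)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  denom <- het_shared[cbind(i, j)] + het_shared[cbind(j, i)]
  k <- (het_both[cbind(i, j)] - 2 * opp[cbind(i, j)]) / denom
  k0 <- pmin(1, pmax(0, opp[cbind(i, j)] / e_shared[cbind(i, j)]))

  cls <- rep("unrelated", length(k))
  first <- !is.na(k) & k >= thresholds$k_first[1] & k <= thresholds$k_first[2]
  cls[first & k0 < thresholds$k0_po] <- "parent-offspring"
  cls[first & k0 >= thresholds$k0_po] <- "full-sib"
  cls[!is.na(k) & k >= thresholds$k_half[1] & k < thresholds$k_first[1]] <- "half-sib"

  ids <- table$samples$sample
  tibble(
    sample_i = ids[i], sample_j = ids[j],
    n_shared = as.integer(n_shared[cbind(i, j)]),
    k = k, k0 = k0, class = cls
  )
}
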