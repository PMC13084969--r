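#' Great-circle distance matrices
#'
#' Haversine distances on the sphere with mean Earth radius 6371.0088 km,
#' plus the natural-log matrix used for isolation-by-distance regression.
#' Pairs at distance zero cannot enter a log-distance Mantel test; their log
#' entries are `NA` and they are reported in the `excluded_pairs` attribute.
#'
#' @param coords Data frame with columns `lon`, `lat` in degrees and
#'   optionally `sample` (used for dimnames).
#' @param log_base Base of the log matrix: `"natural"` (default) or `"10"`.
#' @return List: `km` (symmetric matrix), `log_km` (with `NA` at
#'   zero-distance pairs), `excluded_pairs` (tibble of such pairs).
#' @export
geo_distances <- function(coords, log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  lon <- coords$lon
  lat <- coords$lat
  if (any(abs(lon) > 180, na.rm = TRUE) || any(abs(lat) > 90, na.rm = TRUE)) {
    abort("coordinates outside valid degree ranges.")
  }
  km <- haversine_matrix(lon, lat)
  ids <- coords[["sample"]] %||% as.character(seq_along(lon))
  dimnames(km) <- list(ids, ids)
  zero <- which(km == 0 & upper.tri(km), arr.ind = TRUE)
  log_km <- km
  log_km[km == 0] <- NA_real_
  log_km <- if (log_base == "natural") log(log_km) else log10(log_km)
  diag(log_km) <- NA_real_
  list(
    km = km,
    log_km = log_km,
    excluded_pairs = tibble(sample_i = ids[zero[, 1]],
                            sample_j = ids[zero[, 2]])
  )
}

# haversine on the mean Earth radius
haversine_matrix <- function(lon, lat, radius_km = 6371.0088) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  h <- pmin(pmax(h, 0), 1)
  2 * radius_km * asin(sqrt(h))
}

#' Rousset's a-hat individual pairwise genetic distance
#'
#' Identity-probability form of the multilocus estimator, a ratio of sums
#' over the loci shared by a pair:
#' `a_ij = sum_l (Qw_l - Qij_l) / sum_l (1 - Qw_l)`, where `Qw_l` is the
#' probability of allelic identity of the two genes within an individual at
#' locus l, averaged over the reference sample (the analysis scope), and
#' `Qij_l` the identity probability for one gene drawn from each of i and j
#' (the mean of the four cross-comparisons of their alleles). The reference
#' scope matters: pass the deme's samples for within-deme isolation by
#' distance, the region's or everyone for larger scopes.
#'
#' @param table A [geno_tbl()].
#' @param scope Optional character vector of sample ids defining both the
#'   pairs evaluated and the reference sample for `Qw`; default all samples.
#' @return Tibble: `sample_i`, `sample_j`, `a_hat`, `n_shared`,
#'   `degenerate` (TRUE when the denominator is zero — e.g. a scope with no
#'   heterozygosity — in which case `a_hat` is `NA`).
#' @export
rousset_a <- function(table, scope = NULL) {
  if (!is.null(scope)) table <- gt_subset(table, samples = scope)
  n <- n_samples(table)
  if (n < 2) abort("need at least 2 samples in scope.")
  called <- is_called(table)
  hom <- (table$gt1 == table$gt2) + 0
  hom[!called] <- 0
  qw <- colSums(hom) / pmax(1, colSums(called))   # scope-average within-individual identity
  any_called <- colSums(called) > 0

  g1 <- table$gt1; g2 <- table$gt2
  ids <- table$samples$sample
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    shared <- called[i, ] & called[j, ] & any_called
    if (!any(shared)) {
      abort(sprintf("samples '%s' and '%s' share no called loci.",
                    ids[i], ids[j]))
    }
    qij <- ((g1[i, shared] == g1[j, shared]) + (g1[i, shared] == g2[j, shared]) +
              (g2[i, shared] == g1[j, shared]) + (g2[i, shared] == g2[j, shared])) / 4
    num <- sum(qw[shared] - qij)
    den <- sum(1 - qw[shared])
    tibble(
      sample_i = ids[i], sample_j = ids[j],
      a_hat = if (den > 0) num / den else NA_real_,
      n_shared = sum(shared),
      degenerate = den <= 0
    )
  })
  dplyr::bind_rows(res)
}

#' Turn a pairwise tibble into a symmetric matrix
#'
#' @param df Tibble with `sample_i`, `sample_j` and a value column.
#' @param value Name of the value column.
#' @param ids Optional id ordering; default the ids in order of appearance.
#' @return Symmetric matrix with `NA` diagonal.
#' @export
pairwise_matrix <- function(df, value, ids = NULL) {
  ids <- ids %||% unique(c(df$sample_i, df$sample_j))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(df$sample_i, ids)
  j <- match(df$sample_j, ids)
  m[cbind(i, j)] <- df[[value]]
  m[cbind(j, i)] <- df[[value]]
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper-triangle entries, with a
#' one-sided (positive association) permutation p-value under simultaneous
#' row/column permutation of the second matrix:
#' `p = (1 + #[r_perm >= r_obs]) / (n_perm + 1)`. Cells that are `NA` in
#' either matrix (e.g. log distance of co-located pairs) are excluded from
#' each correlation, including under permutation.
#'
#' @param mat_a,mat_b Square symmetric matrices in the same order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @return One-row tibble of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `n_pairs`.
#' @export
mantel <- function(mat_a, mat_b, n_perm = 999, seed = NULL) {
  stopifnot(is.matrix(mat_a), is.matrix(mat_b),
            nrow(mat_a) == ncol(mat_a),
            identical(dim(mat_a), dim(mat_b)))
  if (n_perm < 99) abort("n_perm must be at least 99.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mat_a)
  ut <- upper.tri(mat_a)
  r_of <- function(perm) {
    b <- mat_b[perm, perm]
    x <- mat_a[ut]; y <- b[ut]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok]))
  }
  r_obs <- r_of(seq_len(n))
  if (is.na(r_obs)) abort("correlation undefined (constant or empty matrix).")
  r_perm <- vapply(seq_len(n_perm), function(k) r_of(sample.int(n)),
                   numeric(1))
  p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  out <- tibble(r = r_obs, p = p, n_perm = as.integer(n_perm),
                n_pairs = sum(is.finite(mat_a[ut]) & is.finite(mat_b[ut])))
  class(out) <- c("mantel_result", class(out))
  out
}

#' Isolation-by-distance Mantel tests at several scopes
#'
#' For each requested scope — every deme, each of two regions, and globally
#' — computes Rousset's a-hat with the scope as reference sample, the
#' natural-log great-circle distance, and a one-sided Mantel test.
#'
#' @param table A [geno_tbl()] whose samples carry `deme`, `lon`, `lat` and
#'   (for region scopes) `region`.
#' @param scopes Character subset of `c("deme", "region", "global")`.
#' @param n_perm Permutations per test.
#' @param seed Integer seed (one stream, tests run in a fixed order).
#' @param min_samples Scopes with fewer samples are skipped.
#' @return Tibble: `scope`, `unit`, `n_samples`, `r`, `p`, `n_perm`.
#' @export
ibd_mantel <- function(table, scopes = c("deme", "region", "global"),
                       n_perm = 999, seed = NULL, min_samples = 5) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  units <- list()
  if ("deme" %in% scopes) {
    for (d in levels(deme_of(table))) {
      units[[length(units) + 1]] <- list(scope = "deme", unit = d,
        ids = table$samples$sample[table$samples$deme == d])
    }
  }
  if ("region" %in% scopes && "region" %in% names(table$samples)) {
    for (r in unique(table$samples$region)) {
      units[[length(units) + 1]] <- list(scope = "region", unit = r,
        ids = table$samples$sample[table$samples$region == r])
    }
  }
  if ("global" %in% scopes) {
    units[[length(units) + 1]] <- list(scope = "global", unit = "all",
                                       ids = table$samples$sample)
  }
  out <- lapply(units, function(u) {
    if (length(u$ids) < min_samples) return(NULL)
    sub <- gt_subset(table, samples = u$ids)
    gen <- pairwise_matrix(rousset_a(sub), "a_hat", ids = u$ids)
    geo <- geo_distances(sub$samples)$log_km
    res <- try(mantel(gen, geo, n_perm = n_perm), silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    tibble(scope = u$scope, unit = u$unit, n_samples = length(u$ids),
           r = res$r, p = res$p, n_perm = res$n_perm)
  })
  dplyr::bind_rows(out)
}
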