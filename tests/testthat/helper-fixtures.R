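# Hand-built genotype tables and brute-force oracles used across tests.

# Build a geno_tbl from compact genotype strings ("0/0", "0/1", "./.", ...).
# geno: character matrix or vector (samples x sites); depth defaults to 30.
make_geno <- function(geno, dp = NULL, demes = NULL, alt = NULL,
                      contig = NULL, pos = NULL, qual = 60,
                      lon = NULL, lat = NULL, sex = NULL, year = NULL) {
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = 1)
  n <- nrow(geno); L <- ncol(geno)
  parse1 <- function(g, which) {
    a <- strsplit(g, "[/|]")[[1]][which]
    if (is.na(a) || a == ".") NA_integer_ else as.integer(a)
  }
  gt1 <- apply(geno, c(1, 2), parse1, which = 1)
  gt2 <- apply(geno, c(1, 2), parse1, which = 2)
  if (is.null(dp)) dp <- matrix(30L, n, L)
  if (!is.matrix(dp)) dp <- matrix(dp, n, L, byrow = TRUE)
  if (is.null(alt)) {
    alt <- ifelse(apply(gt1, 2, function(x) any(x > 0, na.rm = TRUE)) |
                    apply(gt2, 2, function(x) any(x > 0, na.rm = TRUE)),
                  "T", NA_character_)
  }
  sites <- tibble::tibble(
    contig = contig %||% "chr1",
    pos = pos %||% (seq_len(L) * 100L),
    ref = "A",
    alt = alt,
    qual = qual
  )
  samples <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    deme = demes %||% "d1"
  )
  if (!is.null(lon)) samples$lon <- lon
  if (!is.null(lat)) samples$lat <- lat
  if (!is.null(sex)) samples$sex <- sex
  if (!is.null(year)) samples$year <- year
  geno_tbl(gt1, gt2, dp, sites, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random table with controllable missingness for filter property tests
random_geno <- function(n = 50, L = 200, n_demes = 4, miss = 0.1,
                        p_range = c(0.05, 0.95), seed = 1) {
  set.seed(seed)
  p <- runif(L, p_range[1], p_range[2])
  gt1 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
  gt2 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
  drop <- matrix(runif(n * L) < miss, n, L)
  gt1[drop] <- NA_integer_; gt2[drop] <- NA_integer_
  dp <- matrix(as.integer(rpois(n * L, 40)), n, L)
  sites <- tibble::tibble(
    contig = rep(sprintf("c%02d", 1:10), each = L / 10),
    pos = rep(sort(sample.int(1e5, L / 10)), times = 10) +
      rep(0:9 * 0, times = rep(L / 10, 10)),
    ref = "A", alt = "G", qual = round(runif(L, 10, 90), 1)
  )
  # ensure strictly increasing positions within contig
  sites$pos <- as.integer(ave(seq_len(L), sites$contig, FUN = function(i)
    sort(sample.int(5e5, length(i)))))
  samples <- tibble::tibble(
    sample = sprintf("s%03d", seq_len(n)),
    deme = rep_len(sprintf("d%d", seq_len(n_demes)), n)
  )
  geno_tbl(gt1, gt2, dp, sites, samples)
}

# ---- brute-force oracles -------------------------------------------------

oracle_call_rate_keep <- function(tb, overall, per_deme, min_demes) {
  demes <- unique(tb$samples$deme)
  vapply(seq_len(n_sites(tb)), function(l) {
    called <- !is.na(tb$gt1[, l])
    ok_overall <- mean(called) > overall
    n_ok <- 0
    for (d in demes) {
      in_d <- tb$samples$deme == d
      if (mean(called[in_d]) > per_deme) n_ok <- n_ok + 1
    }
    ok_overall && n_ok >= min_demes
  }, logical(1))
}

oracle_mac <- function(tb) {
  vapply(seq_len(n_sites(tb)), function(l) {
    a <- c(tb$gt1[, l], tb$gt2[, l]); a <- a[!is.na(a)]
    if (length(a) == 0) return(0L)
    tab <- table(a)
    if (length(tab) < 2) 0L else as.integer(sum(tab) - max(tab))
  }, integer(1))
}

oracle_mean_depth_keep <- function(tb, lo, hi) {
  vapply(seq_len(n_sites(tb)), function(l) {
    called <- !is.na(tb$gt1[, l])
    if (!any(called)) return(FALSE)
    m <- mean(tb$dp[called, l])
    m >= lo && m <= hi
  }, logical(1))
}

oracle_thin_keep <- function(contig, pos, min_bp) {
  keep <- logical(length(pos))
  for (cg in unique(contig)) {
    idx <- which(contig == cg)
    last <- -Inf
    for (i in idx) {
      if (pos[i] - last >= min_bp) { keep[i] <- TRUE; last <- pos[i] }
    }
  }
  keep
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# full-system ordinary kriging at given nodes (no neighbourhood search)
oracle_krige_full <- function(obs_lon, obs_lat, values, model, node_lon,
                              node_lat) {
  hv <- function(lon1, lat1, lon2, lat2) {
    p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
    dl <- (lon2 - lon1) * pi / 180
    h <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
    2 * 6371.0088 * asin(sqrt(pmin(pmax(h, 0), 1)))
  }
  n <- length(values)
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    C[i, j] <- model$psill * exp(-hv(obs_lon[i], obs_lat[i],
                                     obs_lon[j], obs_lat[j]) / model$range_km)
  }
  diag(C) <- model$nugget + model$psill
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  vapply(seq_along(node_lon), function(g) {
    c0 <- vapply(1:n, function(i) {
      model$psill * exp(-hv(obs_lon[i], obs_lat[i], node_lon[g],
                            node_lat[g]) / model$range_km)
    }, numeric(1))
    sol <- solve(A, c(c0, 1))
    sum(sol[1:n] * values)
  }, numeric(1))
}
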