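#' Draw hierarchical deme allele frequencies
#'
#' Balding-Nichols hierarchy: for each variable site an ancestral alternate
#' allele frequency `p` is drawn uniformly on \[0.05, 0.95\]; each region's
#' frequency is Beta(p(1-t)/t, (1-p)(1-t)/t) around `p` with t =
#' `theta_region`; each deme's frequency is drawn likewise around its region
#' frequency with t = `theta_deme`. Invariant sites (ancestral frequency 0,
#' or 1 for a small fraction fixed for the alternate allele) propagate
#' unchanged. The expected Weir-Cockerham F_ST between two demes of one
#' region is approximately `theta_deme`.
#'
#' Draws from the current RNG state; seed beforehand (or use
#' [simulate_dataset()], which seeds from the config).
#'
#' @param config A [sim_config()].
#' @return A list of class `deme_freqs`: `sites` tibble (contig, pos, ref,
#'   alt, ancestral_p, variable, sex_linked), `deme` frequency matrix
#'   (demes x sites), `region` frequency matrix (2 x sites).
#' @export
draw_hierarchical_frequencies <- function(config) {
  validate_sim_config(config)
  L <- config$n_sites
  n_var <- round(L * config$prop_variable)
  sites <- sim_site_positions(config)

  variable <- rep(FALSE, L)
  variable[sample.int(L, n_var)] <- TRUE

  p_anc <- numeric(L)
  # a sliver of invariant sites are fixed for the alternate allele: still
  # monomorphic in the sample, but carry an ALT relative to the reference
  p_anc[!variable] <- ifelse(runif(L - n_var) < 0.02, 1, 0)
  p_anc[variable] <- runif(n_var, 0.05, 0.95)

  bn_draw <- function(p, theta) {
    out <- p
    mid <- p > 0 & p < 1
    out[mid] <- rbeta(
      sum(mid),
      p[mid] * (1 - theta) / theta,
      (1 - p[mid]) * (1 - theta) / theta
    )
    out
  }

  region <- matrix(0, nrow = 2, ncol = L)
  for (r in 1:2) region[r, ] <- bn_draw(p_anc, config$theta_region)
  deme <- matrix(0, nrow = config$n_demes, ncol = L)
  region_of_deme <- integer(config$n_demes)
  region_of_deme[config$region_split[[1]]] <- 1L
  region_of_deme[config$region_split[[2]]] <- 2L
  for (d in seq_len(config$n_demes)) {
    deme[d, ] <- bn_draw(region[region_of_deme[d], ], config$theta_deme)
  }
  rownames(deme) <- config$deme_names

  sex_linked <- rep(FALSE, L)
  if (config$n_sexlinked > 0) {
    sex_linked[sample(which(variable), config$n_sexlinked)] <- TRUE
  }
  sites$ancestral_p <- p_anc
  sites$variable <- variable
  sites$sex_linked <- sex_linked
  structure(
    list(sites = sites, deme = deme, region = region,
         region_of_deme = region_of_deme),
    class = "deme_freqs"
  )
}

# RAD-like layout: many short contigs of heterogeneous length, sites placed
# uniformly within each, count proportional to length
sim_site_positions <- function(config) {
  len <- sort(round(config$contig_length * runif(config$n_contigs, 0.1, 1)),
              decreasing = TRUE)
  contig <- sprintf("contig%04d", seq_len(config$n_contigs))
  n_per <- as.vector(stats::rmultinom(1, config$n_sites, prob = len / sum(len)))
  bases <- c("A", "C", "G", "T")
  recs <- lapply(seq_len(config$n_contigs), function(i) {
    if (n_per[i] == 0) return(NULL)
    pos <- sort(sample.int(len[i], min(n_per[i], len[i])))
    tibble(contig = contig[i], pos = pos, contig_length = len[i])
  })
  sites <- dplyr::bind_rows(recs)
  # multinomial may overfill a short contig; top up on the longest one
  deficit <- config$n_sites - nrow(sites)
  if (deficit > 0) {
    free <- setdiff(seq_len(len[1]), sites$pos[sites$contig == contig[1]])
    extra <- tibble(contig = contig[1], pos = sort(sample(free, deficit)),
                    contig_length = len[1])
    sites <- dplyr::arrange(dplyr::bind_rows(sites, extra),
                            .data$contig, .data$pos)
  }
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites$ref <- ref
  sites$alt_base <- unname(alt)
  sites
}

#' Scatter individuals around their deme centroids
#'
#' Individuals are placed with isotropic Gaussian noise of `scatter_sd` km
#' around the deme centroid and the km offsets converted to degrees at the
#' centroid's latitude. The eastward offset (standardised by `scatter_sd`)
#' is kept so the genotype sampler can impose a within-deme allele-frequency
#' gradient, which induces isolation by distance when `ibd_slope > 0`.
#'
#' @param config A [sim_config()].
#' @return Tibble: sample, deme, region, lon, lat, east_std.
#' @export
place_coordinates <- function(config) {
  validate_sim_config(config)
  region_name <- character(config$n_demes)
  region_name[config$region_split[[1]]] <- names(config$region_split)[1] %||% "region1"
  region_name[config$region_split[[2]]] <- names(config$region_split)[2] %||% "region2"
  rows <- lapply(seq_len(config$n_demes), function(d) {
    n <- config$deme_sizes[d]
    east <- rnorm(n, 0, config$scatter_sd)
    north <- rnorm(n, 0, config$scatter_sd)
    lat0 <- config$deme_centroids$lat[d]
    tibble(
      deme = config$deme_names[d],
      region = region_name[d],
      lon = config$deme_centroids$lon[d] + east / (111.320 * cos(lat0 * pi / 180)),
      lat = lat0 + north / 110.574,
      east_std = if (config$scatter_sd > 0) east / config$scatter_sd else east * 0
    )
  })
  out <- dplyr::bind_rows(rows)
  out$sample <- sprintf("%s_%02d", out$deme,
                        unlist(lapply(config$deme_sizes, seq_len)))
  dplyr::select(out, "sample", "deme", "region", "lon", "lat", "east_std")
}

#' Sample diploid genotypes with individual inbreeding
#'
#' Each individual draws an inbreeding coefficient F_i uniformly from its
#' deme's interval; at a site with deme alternate-allele frequency p its
#' genotype is heterozygous with probability 2p(1-p)(1-F_i), and the
#' homozygote classes receive p^2 + F_i p(1-p) and (1-p)^2 + F_i p(1-p).
#' Planted full-sibling and parent-offspring dyads are generated by explicit
#' Mendelian transmission from simulated parents. X-linked loci give males a
#' single allele, reported as a homozygous diploid call. With
#' `ibd_slope > 0` and coordinates supplied, each variable site gets a fixed
#' gradient direction and individual-specific frequencies shifted on the
#' logit scale by `ibd_slope * east_std`, creating within-deme isolation by
#' distance.
#'
#' @param freqs A `deme_freqs` from [draw_hierarchical_frequencies()].
#' @param config The same [sim_config()].
#' @param coords Optional tibble from [place_coordinates()]; required when
#'   `ibd_slope > 0`.
#' @return List: `table` (noise-free [geno_tbl()]) and `truth` (`sim_truth`:
#'   individuals, planted pairs, per-locus flags, deme frequency matrix).
#' @export
sample_individuals <- function(freqs, config, coords = NULL) {
  validate_sim_config(config)
  if (config$ibd_slope > 0 && is.null(coords)) {
    abort("coords from place_coordinates() are required when ibd_slope > 0.")
  }
  if (is.null(coords)) coords <- place_coordinates(config)
  L <- config$n_sites
  N <- sum(config$deme_sizes)
  deme_idx <- rep(seq_len(config$n_demes), config$deme_sizes)

  f_true <- numeric(N)
  for (d in seq_len(config$n_demes)) {
    fr <- config$f_range_per_deme[[d]]
    f_true[deme_idx == d] <- runif(config$deme_sizes[d], fr[1], fr[2])
  }
  sex <- sample(c("F", "M"), N, replace = TRUE)
  year <- sample(2008:2011, N, replace = TRUE)

  grad_dir <- rnorm(L) * as.numeric(freqs$sites$variable)

  gt1 <- matrix(NA_integer_, N, L)
  gt2 <- matrix(NA_integer_, N, L)
  for (d in seq_len(config$n_demes)) {
    rows <- which(deme_idx == d)
    p <- freqs$deme[d, ]
    for (i in rows) {
      p_i <- p
      if (config$ibd_slope > 0) {
        v <- freqs$sites$variable
        p_i[v] <- plogis(qlogis(p[v]) +
                           config$ibd_slope * grad_dir[v] * coords$east_std[i])
      }
      g <- draw_genotype_vector(p_i, f_true[i])
      gt1[i, ] <- g$a1
      gt2[i, ] <- g$a2
    }
  }

  # planted dyads by Mendelian transmission from simulated parents
  pairs <- plant_dyads(gt1, gt2, freqs, config, deme_idx, coords$sample)
  gt1 <- pairs$gt1; gt2 <- pairs$gt2
  f_true[pairs$replaced] <- NA_real_

  # X-linked loci: males hemizygous, reported as homozygous diploid calls
  xl <- which(freqs$sites$sex_linked)
  if (length(xl) > 0) {
    males <- which(sex == "M")
    for (i in males) {
      a <- as.integer(runif(length(xl)) < freqs$deme[deme_idx[i], xl])
      gt1[i, xl] <- a
      gt2[i, xl] <- a
    }
  }

  sites <- tibble(
    contig = freqs$sites$contig,
    pos = freqs$sites$pos,
    ref = freqs$sites$ref,
    alt = ifelse(freqs$sites$ancestral_p > 0 | freqs$sites$variable,
                 freqs$sites$alt_base, NA_character_),
    qual = round(stats::rgamma(L, shape = 4, scale = 15), 1),
    sex_linked = freqs$sites$sex_linked
  )
  # a site can be monomorphic reference in every deme yet "variable"
  # ancestrally; keep its ALT so the record mirrors a real joint-call VCF
  samples <- dplyr::mutate(coords, sex = sex, year = year)
  samples <- dplyr::select(samples, "sample", "deme", "region", "lon", "lat",
                           "sex", "year")
  # noise-free table carries a flat nominal depth; add_noise_and_depth()
  # replaces it with overdispersed draws
  dp <- matrix(as.integer(round(config$mean_depth)), N, L)
  table <- geno_tbl(gt1, gt2, dp, sites, samples)

  truth <- structure(list(
    individuals = dplyr::mutate(samples, f_true = f_true),
    pairs = pairs$pairs,
    sites = dplyr::select(freqs$sites, "contig", "pos", "variable",
                          "sex_linked", "ancestral_p"),
    deme_freqs = freqs$deme
  ), class = "sim_truth")
  list(table = table, truth = truth)
}

# vectorised single-individual genotype draw across all sites
draw_genotype_vector <- function(p, f) {
  L <- length(p)
  q <- 1 - p
  p_het <- 2 * p * q * (1 - f)
  p_alt <- p^2 + f * p * q
  u <- runif(L)
  a1 <- integer(L)
  a2 <- integer(L)
  het <- u < p_het
  alt2 <- !het & (u < p_het + p_alt)
  a1[het] <- 0L; a2[het] <- 1L
  a1[alt2] <- 1L; a2[alt2] <- 1L
  list(a1 = a1, a2 = a2)
}

plant_dyads <- function(gt1, gt2, freqs, config, deme_idx, sample_ids) {
  n_pairs <- config$n_sib_pairs + config$n_po_pairs
  empty <- tibble(sample_i = character(), sample_j = character(),
                  relationship = character(), deme = character())
  if (n_pairs == 0) {
    return(list(gt1 = gt1, gt2 = gt2, pairs = empty, replaced = integer()))
  }
  eligible <- which(config$deme_sizes >= 2)
  if (2 * n_pairs > sum(config$deme_sizes[eligible])) {
    abort("not enough individuals to host the planted dyads.")
  }
  kinds <- c(rep("full-sib", config$n_sib_pairs),
             rep("parent-offspring", config$n_po_pairs))
  home <- rep(eligible, length.out = n_pairs)
  used <- integer(0)
  recs <- vector("list", n_pairs)
  draw_parent <- function(d) {
    fr <- config$f_range_per_deme[[d]]
    draw_genotype_vector(freqs$deme[d, ], runif(1, fr[1], fr[2]))
  }
  mendel_child <- function(pa, pb) {
    L <- length(pa$a1)
    from_a <- ifelse(runif(L) < 0.5, pa$a1, pa$a2)
    from_b <- ifelse(runif(L) < 0.5, pb$a1, pb$a2)
    list(a1 = as.integer(from_a), a2 = as.integer(from_b))
  }
  for (k in seq_len(n_pairs)) {
    d <- home[k]
    slots <- setdiff(which(deme_idx == d), used)
    if (length(slots) < 2) {
      d <- eligible[which.max(vapply(eligible, function(e) {
        length(setdiff(which(deme_idx == e), used))
      }, numeric(1)))]
      slots <- setdiff(which(deme_idx == d), used)
    }
    ij <- slots[1:2]
    used <- c(used, ij)
    pa <- draw_parent(d); pb <- draw_parent(d)
    if (kinds[k] == "full-sib") {
      c1 <- mendel_child(pa, pb); c2 <- mendel_child(pa, pb)
      gt1[ij[1], ] <- c1$a1; gt2[ij[1], ] <- c1$a2
      gt1[ij[2], ] <- c2$a1; gt2[ij[2], ] <- c2$a2
    } else {
      child <- mendel_child(pa, pb)
      gt1[ij[1], ] <- pa$a1; gt2[ij[1], ] <- pa$a2
      gt1[ij[2], ] <- child$a1; gt2[ij[2], ] <- child$a2
    }
    recs[[k]] <- tibble(sample_i = sample_ids[ij[1]],
                        sample_j = sample_ids[ij[2]],
                        relationship = kinds[k],
                        deme = config$deme_names[d])
  }
  list(gt1 = gt1, gt2 = gt2, pairs = dplyr::bind_rows(recs), replaced = used)
}

#' Add depth, genotype error and missingness
#'
#' Depth per genotype is negative binomial with mean `mean_depth` and size
#' `depth_dispersion` (Poisson in the `Inf` limit). With probability
#' `error_rate` one allele copy of a called genotype is redrawn from the
#' site's pooled alternate-allele frequency. Genotypes are then set missing
#' independently with probability `missing_rate`.
#'
#' @param table A noise-free [geno_tbl()].
#' @param config A [sim_config()].
#' @return A [geno_tbl()] with depth filled in and missingness applied.
#' @export
add_noise_and_depth <- function(table, config) {
  validate_sim_config(config)
  N <- n_samples(table); L <- n_sites(table)
  n <- N * L
  dp <- if (is.finite(config$depth_dispersion)) {
    rnbinom(n, size = config$depth_dispersion, mu = config$mean_depth)
  } else {
    stats::rpois(n, config$mean_depth)
  }
  dp <- matrix(as.integer(dp), N, L)
  gt1 <- table$gt1; gt2 <- table$gt2

  if (config$error_rate > 0) {
    p_site <- colMeans((gt1 > 0) + (gt2 > 0), na.rm = TRUE) / 2
    hit <- which(matrix(runif(n) < config$error_rate, N, L) & !is.na(gt1))
    if (length(hit) > 0) {
      site_of <- ((hit - 1) %/% N) + 1
      new_allele <- as.integer(runif(length(hit)) < p_site[site_of])
      first_copy <- runif(length(hit)) < 0.5
      gt1[hit[first_copy]] <- new_allele[first_copy]
      gt2[hit[!first_copy]] <- new_allele[!first_copy]
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n) < config$missing_rate, N, L)
    gt1[drop] <- NA_integer_
    gt2[drop] <- NA_integer_
    dp[drop] <- 0L
  }
  geno_tbl(gt1, gt2, dp, table$sites, table$samples)
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from `config$seed`, then draws frequencies, coordinates,
#' genotypes, and noise. The same config always yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `deme_sim`: `table` ([geno_tbl()] with noise),
#'   `clean` (noise-free table), `truth` (`sim_truth`), `freqs`
#'   (`deme_freqs`), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  freqs <- draw_hierarchical_frequencies(config)
  coords <- place_coordinates(config)
  drawn <- sample_individuals(freqs, config, coords)
  noisy <- add_noise_and_depth(drawn$table, config)
  structure(
    list(table = noisy, clean = drawn$table, truth = drawn$truth,
         freqs = freqs, config = config),
    class = "deme_sim"
  )
}
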