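#' Simulation configuration
#'
#' Describes a synthetic study: a set of demes nested in two regions, each
#' deme diverged from its region and the regions from an ancestral pool under
#' a hierarchical Balding-Nichols model; per-individual inbreeding
#' coefficients; within-deme isolation by distance; planted relative dyads;
#' optional sex-linked loci; RAD-like sites spread over many short contigs
#' with overdispersed depth and missingness.
#'
#' The defaults mirror the study design the package was built around: seven
#' demes of sizes 18, 9, 7, 6, 22, 13, 10 (85 diploid individuals) split into
#' a northern and a southern region, 5,000 variable among 50,000 callable
#' sites, and per-individual inbreeding varying roughly two-fold in its
#' effect on heterozygosity.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_demes Number of demes.
#' @param deme_sizes Integer vector of diploid individuals per deme.
#' @param deme_names Character labels, one per deme.
#' @param region_split List of two integer vectors partitioning
#'   `seq_len(n_demes)` into two regions.
#' @param theta_region Balding-Nichols divergence of each region from the
#'   ancestral pool, in (0, 1).
#' @param theta_deme Divergence of each deme from its region, in (0, 1).
#' @param n_contigs Number of contigs the sites are spread over.
#' @param contig_length Contig length in bp (positions drawn within it).
#' @param n_sites Total callable sites (variant + invariant).
#' @param prop_variable Fraction of sites polymorphic in the ancestral pool.
#' @param f_range_per_deme List (length `n_demes`) of `c(f_lo, f_hi)`
#'   intervals for the individual inbreeding coefficient F_i, or a single
#'   interval recycled to all demes.
#' @param deme_centroids Data frame / tibble with columns `lon`, `lat`
#'   (degrees), one row per deme.
#' @param scatter_sd Isotropic scatter of individuals around their centroid,
#'   km.
#' @param ibd_slope Strength of the within-deme allele-frequency gradient
#'   (per standardised km of eastward offset) that induces isolation by
#'   distance; 0 disables it.
#' @param n_sib_pairs,n_po_pairs Planted full-sibling and parent-offspring
#'   dyads (each dyad within one deme).
#' @param n_sexlinked Number of X-linked loci among the variable sites.
#' @param mean_depth Expected per-genotype depth.
#' @param depth_dispersion Negative-binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param missing_rate Probability a genotype is uncalled.
#' @param error_rate Probability a called genotype has one allele copy
#'   redrawn from the deme frequency.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_demes = 7L,
                       deme_sizes = c(18L, 9L, 7L, 6L, 22L, 13L, 10L),
                       deme_names = c("NW", "TW", "TE", "NE", "DW", "DE", "TP"),
                       region_split = list(north = 1:4, south = 5:7),
                       theta_region = 0.05,
                       theta_deme = 0.10,
                       n_contigs = 200L,
                       contig_length = 4e5,
                       n_sites = 50000L,
                       prop_variable = 0.1,
                       f_range_per_deme = list(c(0, 0.35)),
                       deme_centroids = NULL,
                       scatter_sd = 15,
                       ibd_slope = 0,
                       n_sib_pairs = 2L,
                       n_po_pairs = 0L,
                       n_sexlinked = 0L,
                       mean_depth = 40,
                       depth_dispersion = 5,
                       missing_rate = 0.03,
                       error_rate = 0) {
  if (is.null(deme_centroids)) {
    deme_centroids <- tibble(
      lon = c(145.20, 146.90, 147.30, 147.90, 147.00, 147.45, 147.85),
      lat = c(-41.05, -41.35, -41.30, -41.10, -42.75, -42.70, -43.05)
    )[seq_len(n_demes), , drop = FALSE]
  }
  deme_centroids <- as_tibble(deme_centroids)
  if (length(f_range_per_deme) == 1L) {
    f_range_per_deme <- rep(f_range_per_deme, n_demes)
  }
  cfg <- list(
    seed = as.integer(seed), n_demes = as.integer(n_demes),
    deme_sizes = as.integer(deme_sizes), deme_names = as.character(deme_names),
    region_split = region_split, theta_region = theta_region,
    theta_deme = theta_deme, n_contigs = as.integer(n_contigs),
    contig_length = contig_length, n_sites = as.integer(n_sites),
    prop_variable = prop_variable, f_range_per_deme = f_range_per_deme,
    deme_centroids = deme_centroids, scatter_sd = scatter_sd,
    ibd_slope = ibd_slope, n_sib_pairs = as.integer(n_sib_pairs),
    n_po_pairs = as.integer(n_po_pairs), n_sexlinked = as.integer(n_sexlinked),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    missing_rate = missing_rate, error_rate = error_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(deme_sizes) != n_demes) abort("deme_sizes must have n_demes entries.")
    if (length(deme_names) != n_demes) abort("deme_names must have n_demes entries.")
    if (sum(deme_sizes) < 2) abort("deme_sizes must sum to at least 2.")
    if (theta_region <= 0 || theta_region >= 1) {
      abort("theta_region must lie strictly in (0, 1).")
    }
    if (theta_deme <= 0 || theta_deme >= 1) {
      abort("theta_deme must lie strictly in (0, 1).")
    }
    if (!setequal(unlist(region_split), seq_len(n_demes)) ||
        length(region_split) != 2L) {
      abort("region_split must partition the demes into exactly two regions.")
    }
    for (p in c(prop_variable, missing_rate, error_rate)) {
      if (p < 0 || p > 1) abort("probabilities must lie in [0, 1].")
    }
    for (fr in f_range_per_deme) {
      if (length(fr) != 2L || fr[1] > fr[2] || fr[1] < 0 || fr[2] > 1) {
        abort("each f_range must be an interval within [0, 1].")
      }
    }
    if (nrow(deme_centroids) != n_demes) {
      abort("deme_centroids must have one row per deme.")
    }
    if (n_sexlinked > floor(n_sites * prop_variable)) {
      abort("n_sexlinked cannot exceed the number of variable sites.")
    }
    if (mean_depth <= 0) abort("mean_depth must be positive.")
  })
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$deme_centroids)) {
    raw$deme_centroids <- as_tibble(raw$deme_centroids)
  }
  if (!is.null(raw$f_range_per_deme)) {
    raw$f_range_per_deme <- lapply(raw$f_range_per_deme, unlist)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$deme_centroids <- as.list(as.data.frame(config$deme_centroids))
  yaml::write_yaml(out, path)
  invisible(path)
}
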