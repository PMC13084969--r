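test_that("hierarchical frequency draws respect limits and propagate invariant sites", {
  cfg <- sim_config(seed = 1, n_sites = 400, prop_variable = 0.25)
  set.seed(1)
  fr <- draw_hierarchical_frequencies(cfg)
  expect_equal(nrow(fr$sites), 400)
  expect_equal(sum(fr$sites$variable), 100)
  # invariant sites propagate unchanged through both levels
  inv0 <- !fr$sites$variable & fr$sites$ancestral_p == 0
  expect_true(all(fr$deme[, inv0] == 0))
  inv1 <- !fr$sites$variable & fr$sites$ancestral_p == 1
  if (any(inv1)) expect_true(all(fr$deme[, inv1] == 1))
  # theta -> 0 limit: deme frequencies concentrate at the region frequency
  cfg0 <- sim_config(seed = 1, n_sites = 200, prop_variable = 1,
                     theta_deme = 1e-6)
  set.seed(2)
  fr0 <- draw_hierarchical_frequencies(cfg0)
  for (d in seq_len(cfg0$n_demes)) {
    r <- fr0$region_of_deme[d]
    expect_lt(max(abs(fr0$deme[d, ] - fr0$region[r, ])), 0.01)
  }
  expect_error(sim_config(theta_deme = 0), "theta_deme")
  expect_error(sim_config(theta_deme = 1), "theta_deme")
})

test_that("inbreeding coefficient controls heterozygosity as 2p(1-p)(1-F)", {
  # F = 1: no heterozygous calls at all
  cfg1 <- sim_config(seed = 2, n_demes = 2, deme_sizes = c(3L, 3L),
                     deme_names = c("A", "B"), region_split = list(1, 2),
                     n_sites = 2000, prop_variable = 1,
                     f_range_per_deme = list(c(1, 1)),
                     deme_centroids = data.frame(lon = c(147, 147.5),
                                                 lat = c(-42, -42.5)),
                     n_sib_pairs = 0L, missing_rate = 0, error_rate = 0)
  sim1 <- simulate_dataset(cfg1)
  expect_equal(sum(is_het(sim1$clean)), 0)

  # F = 0 vs F = 0.5 on a near-identical frequency spectrum: H_O ratio 2
  cfg <- sim_config(seed = 3, n_demes = 2, deme_sizes = c(12L, 12L),
                    deme_names = c("A", "B"), region_split = list(1, 2),
                    theta_region = 1e-9, theta_deme = 1e-9,
                    n_sites = 10000, prop_variable = 1,
                    f_range_per_deme = list(c(0, 0), c(0.5, 0.5)),
                    deme_centroids = data.frame(lon = c(147, 147.5),
                                                lat = c(-42, -42.5)),
                    n_sib_pairs = 0L, missing_rate = 0, error_rate = 0)
  sim <- simulate_dataset(cfg)
  het <- autosomal_het(sim$clean)
  m <- tapply(het$h_o, sim$clean$samples$deme, mean)
  expect_equal(unname(m[["A"]] / m[["B"]]), 2, tolerance = 0.05)
})

test_that("depth noise approaches the Poisson limit and trivial rates behave", {
  cfg <- sim_config(seed = 4, n_demes = 2, deme_sizes = c(20L, 20L),
                    deme_names = c("A", "B"), region_split = list(1, 2),
                    n_sites = 2500, prop_variable = 0.2,
                    deme_centroids = data.frame(lon = c(147, 147.5),
                                                lat = c(-42, -42.5)),
                    mean_depth = 30, depth_dispersion = Inf,
                    missing_rate = 0, error_rate = 0, n_sib_pairs = 0L)
  sim <- simulate_dataset(cfg)
  dp <- as.vector(sim$table$dp)   # 40 x 2500 = 1e5 draws
  expect_equal(mean(dp), 30, tolerance = 0.02)
  expect_equal(var(dp), 30, tolerance = 0.05)

  # error_rate = 0: noise-free genotypes unchanged
  expect_identical(sim$table$gt1, sim$clean$gt1)
  expect_identical(sim$table$gt2, sim$clean$gt2)

  # missing_rate = 1: everything uncalled
  cfg_m <- cfg; cfg_m$missing_rate <- 1
  sim_m <- simulate_dataset(cfg_m)
  expect_true(all(is.na(sim_m$table$gt1)))
})

test_that("region_split must be a two-part partition", {
  expect_error(
    sim_config(n_demes = 2, deme_sizes = c(5L, 5L), deme_names = c("A", "B"),
               region_split = list(1, integer(0)),
               deme_centroids = data.frame(lon = c(147, 147.5),
                                           lat = c(-42, -42.5))),
    "partition")
})

test_that("coordinate placement matches the centroid geometry", {
  cfg0 <- sim_config(seed = 5, scatter_sd = 0)
  set.seed(5)
  co <- place_coordinates(cfg0)
  for (d in seq_len(cfg0$n_demes)) {
    rows <- co$deme == cfg0$deme_names[d]
    expect_true(all(co$lon[rows] == cfg0$deme_centroids$lon[d]))
    expect_true(all(co$lat[rows] == cfg0$deme_centroids$lat[d]))
  }
  # two centroids 100 km apart, scatter 5 km: between-deme pairs all > 80 km
  cfg2 <- sim_config(seed = 6, n_demes = 2, deme_sizes = c(8L, 8L),
                     deme_names = c("A", "B"), region_split = list(1, 2),
                     scatter_sd = 5,
                     deme_centroids = data.frame(lon = c(147, 147),
                                                 lat = c(-42, -42 + 100 / 110.574)))
  set.seed(6)
  co2 <- place_coordinates(cfg2)
  km <- geo_distances(co2)$km
  between <- km[co2$deme == "A", co2$deme == "B"]
  expect_true(all(between > 80))
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- sim_config(seed = 7, n_sites = 600, prop_variable = 0.2,
                    n_sexlinked = 5, ibd_slope = 0.3)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table$gt1, b$table$gt1)
  expect_identical(a$table$dp, b$table$dp)
  expect_identical(a$truth$individuals, b$truth$individuals)
})

test_that("planted X-linked loci leave males without heterozygous calls", {
  cfg <- sim_config(seed = 8, n_sites = 1200, prop_variable = 0.5,
                    n_sexlinked = 40, missing_rate = 0, error_rate = 0)
  sim <- simulate_dataset(cfg)
  males <- sim$clean$samples$sex == "M"
  xl <- which(sim$clean$sites$sex_linked)
  expect_length(xl, 40)
  expect_equal(sum(is_het(sim$clean)[males, xl], na.rm = TRUE), 0)
  females <- !males
  expect_gt(sum(is_het(sim$clean)[females, xl], na.rm = TRUE), 0)
})

test_that("planted dyads are recorded and genuinely related", {
  cfg <- sim_config(seed = 9, n_sites = 3000, prop_variable = 0.5,
                    n_sib_pairs = 2L, n_po_pairs = 1L,
                    missing_rate = 0, error_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$pairs), 3)
  expect_setequal(unique(sim$truth$pairs$relationship),
                  c("full-sib", "parent-offspring"))
  # a parent-offspring pair never shows opposite homozygotes
  po <- sim$truth$pairs[sim$truth$pairs$relationship == "parent-offspring", ]
  i <- match(po$sample_i, sim$clean$samples$sample)
  j <- match(po$sample_j, sim$clean$samples$sample)
  d <- alt_dosage(sim$clean)
  expect_equal(sum(abs(d[i, ] - d[j, ]) == 2, na.rm = TRUE), 0)
})

test_that("stronger deme divergence raises realized pairwise F_ST", {
  theta_of <- function(theta, seed) {
    cfg <- sim_config(seed = seed, n_demes = 2, deme_sizes = c(20L, 20L),
                      deme_names = c("A", "B"), region_split = list(1, 2),
                      theta_region = 1e-9, theta_deme = theta,
                      n_sites = 1500, prop_variable = 1,
                      deme_centroids = data.frame(lon = c(147, 147.5),
                                                  lat = c(-42, -42.5)),
                      n_sib_pairs = 0L, missing_rate = 0, error_rate = 0)
    sim <- simulate_dataset(cfg)
    wc_theta(sim$clean, "A", "B")$theta
  }
  lo <- vapply(1:4, function(s) theta_of(0.03, s), numeric(1))
  hi <- vapply(1:4, function(s) theta_of(0.15, s + 100), numeric(1))
  expect_gt(mean(hi), mean(lo))
})
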