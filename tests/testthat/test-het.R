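test_that("per-individual retention drops missing, star, and out-of-window calls", {
  geno <- matrix(c(
    # s01: 1 star site, 2 missing, 1 low depth, 1 high depth, 5 clean
    "0/1", "./.", "0/0", "./.", "0/1", "0/0", "0/1", "1/1", "0/0", "0/1"
  ), 1, 10)
  dp <- matrix(c(30L, 30L, 14L, 30L, 96L, 15L, 95L, 30L, 30L, 30L), 1, 10)
  alt <- c("T,*", "T", "T", "T", "T", "T", "T", "T", NA, "T")
  tb <- make_geno(geno, dp = dp, alt = alt)
  ret <- per_individual_site_filter(tb, "s01", min_dp = 15, max_dp = 95)
  # dropped: site1 (star), sites 2 & 4 (missing), site3 (depth 14 < 15),
  # site5 (depth 96 > 95); kept: 6..10 with boundary depths 15 and 95 kept
  expect_equal(ret$site, 6:10)
  expect_error(per_individual_site_filter(tb, "nope"), "unknown sample")
})

test_that("atomization follows the one-record-per-alternate convention", {
  tb <- make_geno(rbind("1/2", "0/0", "1/1", "0/2"), alt = "T,G")
  rec <- atomize_multiallelic(tb, 1)
  expect_equal(nrow(rec), 8)   # 2 records x 4 samples
  r1 <- rec[rec$record_alt == "T", ]
  r2 <- rec[rec$record_alt == "G", ]
  # genotype alt1/alt2 is heterozygous in both derived records
  expect_true(r1$het[r1$sample == "s01"] && r2$het[r2$sample == "s01"])
  # ref/ref homozygous in both
  expect_false(r1$het[r1$sample == "s02"] || r2$het[r2$sample == "s02"])
  # alt1/alt1: hom-alt in record 1, hom-ref in record 2
  expect_false(r1$het[r1$sample == "s03"] || r2$het[r2$sample == "s03"])
  expect_equal(unname(r1$gt1[r1$sample == "s03"]), 1L)
  expect_equal(unname(r2$gt1[r2$sample == "s03"]), 0L)
  # biallelic passes through unchanged
  bi <- make_geno(rbind("0/1", "0/0"), alt = "T")
  rec_bi <- atomize_multiallelic(bi, 1)
  expect_equal(nrow(rec_bi), 2)
  expect_equal(unname(rec_bi$het), c(TRUE, FALSE))
})

test_that("H_O is het records over all retained records, invariants included", {
  geno <- matrix(c(rep("0/1", 3), rep("0/0", 7)), 1, 10)
  tb <- make_geno(geno, alt = c(rep("T", 3), rep(NA, 7)))
  res <- autosomal_het(tb)
  expect_equal(res$n_retained, 10L)
  expect_equal(res$n_het, 3L)
  expect_equal(res$h_o, 0.3)
  # all homozygous: exactly zero
  res0 <- autosomal_het(make_geno(matrix("0/0", 1, 8)))
  expect_equal(res0$h_o, 0)
  # zero retained records is an explicit error, not a silent zero
  none <- make_geno(matrix("./.", 1, 5))
  expect_error(autosomal_het(none), "no retained records")
})

test_that("multiallelic records enter numerator and denominator per record", {
  tb <- make_geno(matrix(c("1/2", "0/0"), 1, 2), alt = c("T,G", NA))
  res <- autosomal_het(tb)
  # site 1 atomizes to 2 records, both het; site 2 is 1 invariant record
  expect_equal(res$n_retained, 3L)
  expect_equal(res$n_het, 2L)
})

test_that("simulated inbreeding is recovered through the closed form", {
  # F = 0.25, 20,000 sites, 10% variable at p = 0.5:
  # E[H_O] = 0.1 * 0.5 * 0.75 = 0.0375
  set.seed(51)
  L <- 20000
  variable <- seq_len(L) <= 2000
  f <- 0.25
  p_het <- ifelse(variable, 2 * 0.5 * 0.5 * (1 - f), 0)
  is_h <- rbinom(L, 1, p_het) == 1
  gt1 <- matrix(0L, 1, L); gt2 <- matrix(ifelse(is_h, 1L, 0L), 1, L)
  tb <- geno_tbl(gt1, gt2, matrix(30L, 1, L),
                 tibble::tibble(contig = "c", pos = seq_len(L), ref = "A",
                                alt = ifelse(variable, "T", NA), qual = 60),
                 tibble::tibble(sample = "s1", deme = "d1"))
  res <- autosomal_het(tb)
  se <- sqrt(0.0375 * (1 - 0.0375) / L)
  expect_lt(abs(res$h_o - 0.0375), 3 * se)
})

test_that("H_O scales exactly with added invariant records and ignores other samples", {
  base <- make_geno(rbind(c("0/1", "0/1", "0/0", "0/0"),
                          c("0/0", "0/1", "0/1", "0/0")))
  r1 <- autosomal_het(base)
  # adding 4 invariant retained records halves H_O exactly
  wide <- make_geno(rbind(c("0/1", "0/1", rep("0/0", 6)),
                          c("0/0", "0/1", "0/1", rep("0/0", 5))),
                    alt = c("T", "T", "T", rep(NA, 5)))
  r2 <- autosomal_het(wide)
  expect_equal(r2$h_o, r1$h_o * 4 / 8)
  # removing the other sample leaves an individual's H_O unchanged
  solo <- autosomal_het(gt_subset(base, samples = "s01"))
  expect_equal(solo$h_o, r1$h_o[r1$sample == "s01"])
})

test_that("F_IS hits its fixed points and recovers simulated inbreeding", {
  # exact HWE at p = 0.5 with half the individuals het: F_IS = 0
  hwe <- make_geno(matrix(rep(c("0/0", "0/1", "0/1", "1/1"), 3),
                          nrow = 4, ncol = 3), demes = "d1")
  expect_equal(deme_fis(hwe)$f_is, 0)
  # no heterozygotes at p = 0.5: F = 1
  fixed <- make_geno(matrix(c("0/0", "1/1", "0/0", "1/1"), 4, 2),
                     demes = "d1")
  expect_equal(deme_fis(fixed)$f_is, 1)

  # uniform F = 0.2 over 2000 loci, 30 individuals
  set.seed(52)
  n <- 30; L <- 2000; f <- 0.2
  p <- runif(L, 0.2, 0.8)
  cls <- vapply(seq_len(L), function(l) {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - p[l])^2 + f * p[l] * (1 - p[l]),
                    2 * p[l] * (1 - p[l]) * (1 - f),
                    p[l]^2 + f * p[l] * (1 - p[l])))
  }, integer(n))
  gt1 <- pmin(cls, 1L); gt2 <- pmax(cls - 1L, 0L)
  tb <- geno_tbl(gt1, gt2, matrix(30L, n, L),
                 tibble::tibble(contig = "c", pos = seq_len(L), ref = "A",
                                alt = "T", qual = 60),
                 tibble::tibble(sample = sprintf("s%02d", 1:n), deme = "d1"))
  est <- deme_fis(tb, hexp_correction = TRUE)
  expect_lt(abs(est$f_is - 0.2), 0.03)
  # a single-sample deme is computed but marked unreliable
  lone <- deme_fis(gt_subset(tb, samples = 1))
  expect_false(lone$reliable)
})

test_that("window profile is consistent with the genome-wide estimate", {
  cfg <- sim_config(seed = 53, n_sites = 2000, prop_variable = 0.3,
                    n_contigs = 5, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  # one window spanning everything reproduces autosomal_het
  prof <- window_profile(sim$clean, window_bp = 1e9, min_records = 1)
  full <- autosomal_het(sim$clean)
  joined <- merge(prof, full, by = "sample")
  expect_equal(joined$h_o.x, joined$h_o.y)
  expect_equal(joined$n_records, joined$n_retained)
  # thin windows fall below the record floor and are absent, never zero
  thin <- window_profile(sim$clean, window_bp = 200, min_records = 50)
  expect_true(all(thin$n_records >= 50))
})

test_that("covariate regression returns R^2 with sane null behaviour", {
  set.seed(54)
  het <- tibble::tibble(sample = sprintf("s%d", 1:40),
                        h_o = runif(40, 0.01, 0.03))
  perfect <- suppressWarnings(het_covariate_check(het, het$h_o))
  expect_equal(perfect$r_squared, 1)
  expect_error(het_covariate_check(het, rep(1, 40)), "zero variance")
  expect_error(het_covariate_check(het[1:2, ], c(1, 2)), "at least 3")
  # independent covariate: null R^2 is Beta(1/2, (n-2)/2); check the mean
  r2 <- vapply(1:300, function(i) {
    het_covariate_check(het, rnorm(40))$r_squared
  }, numeric(1))
  # E[R^2] = 1/(n-1) under the null
  expect_equal(mean(r2), 1 / 39, tolerance = 0.35)
})
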