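test_that("empirical semivariogram matches hand arithmetic and a pair-loop oracle", {
  set.seed(91)
  co <- tibble::tibble(lon = runif(12, 146, 148), lat = runif(12, -43, -41))
  # constant field: zero semivariance in every non-empty bin
  emp0 <- empirical_semivariogram(co, rep(0.5, 12), n_bins = 6)
  expect_true(all(emp0$gamma[emp0$n_pairs > 0] == 0))
  expect_equal(sum(emp0$n_pairs), 12 * 11 / 2)

  # seeded Gaussian field equals a brute-force pair loop
  v <- rnorm(12)
  emp <- empirical_semivariogram(co, v, n_bins = 5)
  km <- demescope:::haversine_matrix(co$lon, co$lat)
  max_lag <- max(km[upper.tri(km)])
  width <- max_lag / 5
  for (b in 1:5) {
    s <- 0; cnt <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      if (km[i, j] > (b - 1) * width && km[i, j] <= b * width) {
        s <- s + (v[i] - v[j])^2; cnt <- cnt + 1
      }
    }
    if (cnt == 0) {
      expect_true(is.na(emp$gamma[b]))
    } else {
      expect_equal(emp$gamma[b], s / (2 * cnt))
      expect_equal(emp$n_pairs[b], cnt)
    }
  }
})

test_that("single-bin semivariance is half the mean squared difference", {
  co <- tibble::tibble(lon = c(147, 147.5, 147.25, 147.1, 146.9, 147.6,
                               147.3, 146.8, 147.45, 147.05),
                       lat = seq(-42, -41.1, 0.1))
  v <- c(1, 3, rep(1, 8))
  emp <- empirical_semivariogram(co, v, n_bins = 1)
  expect_equal(emp$n_pairs, 45L)
  # two points alone: single pair, gamma = (1/2) * (v1 - v2)^2 = 2
  g2 <- sum((outer(v, v, "-")[upper.tri(outer(v, v, "-"))])^2) / (2 * 45)
  expect_equal(emp$gamma, g2)
})

test_that("exponential model fit recovers known parameters", {
  # empirical points generated from gamma(h) = 0 + 1 * (1 - exp(-h / 50))
  lag <- seq(5, 200, by = 5)
  emp <- tibble::tibble(lag = lag,
                        gamma = 1 - exp(-lag / 50),
                        n_pairs = rep(50L, length(lag)))
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_exponential(emp)
  expect_true(fit$converged)
  expect_lt(abs(fit$range_km - 50) / 50, 0.2)
  expect_lt(fit$nugget, 0.05 * fit$psill)
  expect_equal(variogram_gamma(fit, 0), fit$nugget)

  # flat empirical variogram collapses to a pure-nugget model
  flat <- tibble::tibble(lag = lag, gamma = rep(0.8, length(lag)),
                         n_pairs = rep(30L, length(lag)))
  class(flat) <- c("empirical_variogram", class(flat))
  fit_flat <- suppressWarnings(fit_exponential(flat))
  expect_equal(fit_flat$psill, 0)
  expect_equal(fit_flat$nugget, 0.8, tolerance = 0.01)
})

test_that("kriging is exact at observations and reproduces a constant field", {
  set.seed(92)
  pts <- tibble::tibble(lon = runif(25, 146, 148), lat = runif(25, -43, -41))
  v <- rnorm(25)
  model <- variogram_model(nugget = 0, psill = 1, range_km = 60)
  s <- krige(pts, v, model, grid = pts, k_neighbors = 36)
  expect_lt(max(abs(s$prediction - v)), 1e-8)
  expect_true(all(s$variance >= -1e-10))

  const <- krige(pts, rep(0.7, 25), model,
                 grid = tibble::tibble(lon = runif(10, 146, 148),
                                       lat = runif(10, -43, -41)),
                 k_neighbors = 10)
  expect_equal(const$prediction, rep(0.7, 10), tolerance = 1e-10)
})

test_that("neighbourhood kriging equals the full system when k >= n", {
  set.seed(93)
  pts <- tibble::tibble(lon = runif(30, 146, 148), lat = runif(30, -43, -41))
  v <- rnorm(30, 0.02, 0.005)
  model <- variogram_model(nugget = 0.1, psill = 1, range_km = 80)
  nodes <- tibble::tibble(lon = runif(8, 146, 148), lat = runif(8, -43, -41))
  s36 <- krige(pts, v, model, grid = nodes, k_neighbors = 36)
  s30 <- krige(pts, v, model, grid = nodes, k_neighbors = 30)
  expect_equal(s36$prediction, s30$prediction, tolerance = 1e-12)
  oracle <- oracle_krige_full(pts$lon, pts$lat, v, model,
                              nodes$lon, nodes$lat)
  expect_equal(s36$prediction, oracle, tolerance = 1e-8)
})

test_that("shrinking the neighbourhood toward n reduces the discrepancy", {
  set.seed(94)
  pts <- tibble::tibble(lon = runif(40, 146, 148), lat = runif(40, -43, -41))
  v <- rnorm(40)
  model <- variogram_model(nugget = 0.05, psill = 1, range_km = 70)
  nodes <- tibble::tibble(lon = runif(12, 146, 148),
                          lat = runif(12, -43, -41))
  full <- krige(pts, v, model, grid = nodes, k_neighbors = 40)$prediction
  errs <- vapply(c(5, 15, 30, 40), function(k) {
    max(abs(krige(pts, v, model, grid = nodes,
                  k_neighbors = k)$prediction - full))
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 1e-12)
  expect_equal(errs[4], 0, tolerance = 1e-12)
})

test_that("duplicate observation points are averaged, not singular", {
  pts <- tibble::tibble(lon = c(147, 147, 147.5, 147.8, 146.9),
                        lat = c(-42, -42, -42.2, -41.8, -42.4))
  v <- c(1, 3, 2, 2, 2)
  model <- variogram_model(0, 1, 50)
  expect_message(
    s <- krige(pts, v, model,
               grid = tibble::tibble(lon = 147, lat = -42), k_neighbors = 4),
    "co-located")
  expect_equal(s$prediction, 2, tolerance = 1e-8)   # the average of 1 and 3
})

test_that("z-scored surfaces are plain standardisation of predictions", {
  set.seed(95)
  pts <- tibble::tibble(lon = runif(15, 146, 148), lat = runif(15, -43, -41))
  v <- rnorm(15, 0.02, 0.004)
  model <- variogram_model(0, 1, 50)
  s <- krige(pts, v, model,
             grid = tibble::tibble(lon = runif(6, 146, 148),
                                   lat = runif(6, -43, -41)),
             k_neighbors = 15)
  z <- zscore_surface(s, v)
  expect_equal(z$z, (s$prediction - mean(v)) / sd(v))
  expect_error(zscore_surface(s, rep(0.5, 15)), "zero standard deviation")
  # prediction at the mean maps to z = 0, one s.d. above to z = 1
  fake <- s
  fake$prediction <- c(mean(v), mean(v) + sd(v), rep(mean(v), 4))
  zf <- zscore_surface(fake, v)
  expect_equal(zf$z[1:2], c(0, 1))
})
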