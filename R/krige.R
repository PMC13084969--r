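#' Empirical semivariogram
#'
#' Classical (Matheron) estimator on equal-width lag bins:
#' `gamma(bin) = sum (v_i - v_j)^2 / (2 N_bin)` over pairs whose
#' great-circle separation falls in the bin. Bins with no pairs are kept in
#' the output with `NA` semivariance (empty, not zero).
#'
#' @param coords Data frame with `lon`, `lat` (degrees).
#' @param values Numeric vector aligned with `coords`.
#' @param n_bins Number of equal-width lag bins.
#' @param max_lag Largest lag considered, km; default the maximum pairwise
#'   distance.
#' @return Tibble of class `empirical_variogram`: `lag` (bin center, km),
#'   `gamma`, `n_pairs`.
#' @export
empirical_semivariogram <- function(coords, values, n_bins = 12,
                                    max_lag = NULL) {
  if (length(values) < 10) abort("need at least 10 points.")
  km <- haversine_matrix(coords$lon, coords$lat)
  ut <- upper.tri(km)
  d <- km[ut]
  max_lag <- max_lag %||% max(d)
  if (max_lag > max(d)) abort("max_lag exceeds the maximum pairwise distance.")
  sq <- outer(values, values, "-")^2
  g <- sq[ut]
  use <- d <= max_lag & d > 0
  bin <- ceiling(d[use] / (max_lag / n_bins))
  bin[bin < 1] <- 1
  gamma <- rep(NA_real_, n_bins)
  n_pairs <- integer(n_bins)
  agg_s <- tapply(g[use], bin, sum)
  agg_n <- tapply(rep(1L, sum(use)), bin, sum)
  idx <- as.integer(names(agg_s))
  n_pairs[idx] <- as.integer(agg_n)
  gamma[idx] <- agg_s / (2 * n_pairs[idx])
  out <- tibble(
    lag = (seq_len(n_bins) - 0.5) * max_lag / n_bins,
    gamma = gamma,
    n_pairs = n_pairs
  )
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Fit an exponential semivariogram model
#'
#' Weighted least squares (weights = pair counts) fit of
#' `gamma(h) = nugget + psill * (1 - exp(-h / range))` with non-negativity
#' constraints, via Levenberg-Marquardt. Starting values: nugget at the
#' smallest non-empty bin's semivariance, partial sill at the spread up to
#' the largest, range at a third of the maximum lag. A degenerate fit
#' (partial sill collapsing toward zero) returns a pure-nugget model with a
#' warning.
#'
#' @param empirical An [empirical_semivariogram()] result.
#' @return A `variogram_model` list: `nugget`, `psill`, `range_km`, `model
#'   = "exponential"`, `converged`.
#' @export
fit_exponential <- function(empirical) {
  d <- dplyr::filter(as_tibble(empirical), !is.na(.data$gamma),
                     .data$n_pairs > 0)
  if (nrow(d) < 3) abort("need at least 3 non-empty bins to fit.")
  g_lo <- d$gamma[which.min(d$lag)]
  g_hi <- max(d$gamma)
  start <- list(nugget = max(1e-12, g_lo),
                psill = max(1e-12, g_hi - g_lo),
                range_km = max(d$lag) / 3)
  fit <- try(minpack.lm::nlsLM(
    gamma ~ nugget + psill * (1 - exp(-lag / range_km)),
    data = d, start = start, weights = d$n_pairs,
    lower = c(0, 0, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  mean_gamma <- sum(d$gamma * d$n_pairs) / sum(d$n_pairs)
  if (inherits(fit, "try-error")) {
    warn("variogram fit failed to converge; returning a pure-nugget model.")
    return(variogram_model(mean_gamma, 0, max(d$lag), converged = FALSE))
  }
  cf <- coef(fit)
  if (cf[["psill"]] <= 1e-10 * max(cf[["nugget"]], 1e-12)) {
    warn("partial sill collapsed to zero; returning a pure-nugget model.")
    return(variogram_model(mean_gamma, 0, max(d$lag), converged = FALSE))
  }
  variogram_model(cf[["nugget"]], cf[["psill"]], cf[["range_km"]],
                  converged = TRUE)
}

#' @rdname fit_exponential
#' @param nugget,psill,range_km Model parameters (nugget and partial sill in
#'   value-variance units, range in km).
#' @param converged Whether the optimiser converged.
#' @export
variogram_model <- function(nugget, psill, range_km, converged = TRUE) {
  stopifnot(nugget >= 0, psill >= 0, range_km > 0)
  structure(list(nugget = nugget, psill = psill, range_km = range_km,
                 model = "exponential", converged = converged),
            class = "variogram_model")
}

#' Evaluate a variogram model
#' @param model A `variogram_model`.
#' @param h Distances, km.
#' @return Semivariance at `h`.
#' @export
variogram_gamma <- function(model, h) {
  model$nugget + model$psill * (1 - exp(-h / model$range_km))
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> exponential: nugget %.3g, psill %.3g, range %.1f km%s\n",
              x$nugget, x$psill, x$range_km,
              if (x$converged) "" else " (degenerate fit)"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variogram_model <- function(x, ...) {
  tibble(term = c("nugget", "psill", "range_km"),
         estimate = c(x$nugget, x$psill, x$range_km))
}

#' Ordinary kriging onto a lon/lat grid
#'
#' For each grid node, selects the `k_neighbors` nearest observations by
#' great-circle distance and solves the ordinary-kriging system (weights
#' constrained to sum to one via a Lagrange multiplier) under the
#' exponential covariance `C(h) = psill * exp(-h / range)` with the nugget
#' added on the diagonal. With a zero nugget the predictor is exact at
#' observation locations. Duplicated observation locations are averaged
#' before solving.
#'
#' @param coords Data frame with `lon`, `lat` for the observations.
#' @param values Observed values aligned with `coords`.
#' @param model A `variogram_model`.
#' @param grid Either `NULL` (bounding box of the observations padded 10%,
#'   `n_x` x `n_y` cells) or a data frame of `lon`, `lat` nodes.
#' @param k_neighbors Neighbourhood size (default 36; capped at the number
#'   of distinct observation locations).
#' @param n_x,n_y Grid resolution when `grid` is `NULL`.
#' @return Tibble of class `kriged_surface`: `lon`, `lat`, `prediction`,
#'   `variance`. Attributes keep the model and observed values so
#'   [zscore_surface()] can standardise.
#' @export
krige <- function(coords, values, model, grid = NULL, k_neighbors = 36,
                  n_x = 100, n_y = 100) {
  stopifnot(k_neighbors >= 1)
  obs <- tibble(lon = coords$lon, lat = coords$lat, value = values)
  dup <- duplicated(obs[, c("lon", "lat")]) |
    duplicated(obs[, c("lon", "lat")], fromLast = TRUE)
  if (any(dup)) {
    inform(sprintf("averaging %d co-located observations before kriging.",
                   sum(dup)))
    obs <- dplyr::summarise(dplyr::group_by(obs, .data$lon, .data$lat),
                            value = mean(.data$value), .groups = "drop")
  }
  n <- nrow(obs)
  k <- min(k_neighbors, n)
  if (is.null(grid)) {
    pad_x <- diff(range(obs$lon)) * 0.1
    pad_y <- diff(range(obs$lat)) * 0.1
    grid <- expand.grid(
      lon = seq(min(obs$lon) - pad_x, max(obs$lon) + pad_x, length.out = n_x),
      lat = seq(min(obs$lat) - pad_y, max(obs$lat) + pad_y, length.out = n_y)
    )
  }
  grid <- as_tibble(grid)

  cov_of <- function(h) model$psill * exp(-h / model$range_km)
  sill <- model$nugget + model$psill
  d_obs <- haversine_matrix(obs$lon, obs$lat)
  C_full <- cov_of(d_obs)
  diag(C_full) <- sill

  phi_o <- obs$lat * pi / 180
  lam_o <- obs$lon * pi / 180
  pred <- numeric(nrow(grid))
  kvar <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    phi <- grid$lat[g] * pi / 180
    lam <- grid$lon[g] * pi / 180
    h <- sin((phi_o - phi) / 2)^2 + cos(phi) * cos(phi_o) * sin((lam_o - lam) / 2)^2
    d0 <- 2 * 6371.0088 * asin(sqrt(pmin(1, pmax(0, h))))
    nb <- order(d0)[seq_len(k)]
    A <- rbind(cbind(C_full[nb, nb, drop = FALSE], 1), c(rep(1, k), 0))
    b <- c(cov_of(d0[nb]), 1)
    sol <- solve(A, b)
    w <- sol[seq_len(k)]
    mu <- sol[k + 1]
    pred[g] <- sum(w * obs$value[nb])
    kvar[g] <- max(0, sill - sum(w * b[seq_len(k)]) - mu)
  }
  out <- dplyr::mutate(grid, prediction = pred, variance = kvar)
  attr(out, "model") <- model
  attr(out, "observed") <- values
  class(out) <- c("kriged_surface", class(out))
  out
}

#' Standardise a kriged surface against the observed values
#'
#' Adds `z = (prediction - mean(values)) / sd(values)`, the predicted
#' deviation from the global observed mean in standard-deviation units.
#'
#' @param surface A [krige()] result.
#' @param values The observed values; defaults to those stored on the
#'   surface.
#' @return The surface tibble with a `z` column.
#' @export
zscore_surface <- function(surface, values = NULL) {
  values <- values %||% attr(surface, "observed")
  if (is.null(values)) abort("no observed values available.")
  s <- sd(values)
  if (s == 0) abort("observed values have zero standard deviation.")
  out <- dplyr::mutate(surface, z = (.data$prediction - mean(values)) / s)
  class(out) <- unique(c("kriged_surface", class(out)))
  attr(out, "model") <- attr(surface, "model")
  attr(out, "observed") <- values
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.kriged_surface <- function(object, fill = NULL, ...) {
  fill <- fill %||% if ("z" %in% names(object)) "z" else "prediction"
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = fill)
}
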