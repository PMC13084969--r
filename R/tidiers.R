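#' @exportS3Method generics::tidy
tidy.fst_matrix <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.fst_matrix <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    mean_theta = mean(x$theta),
    n_significant = sum(x$significant),
    alpha_per_test = attr(x, "alpha_per_test")
  )
}

#' @exportS3Method generics::tidy
tidy.mantel_result <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.variogram_model <- function(x, ...) {
  tibble(nugget = x$nugget, psill = x$psill, range_km = x$range_km,
         sill = x$nugget + x$psill, converged = x$converged)
}

#' Heatmap of pairwise F_ST
#' @param object A `fst_matrix` from [fst_bootstrap()].
#' @param ... Passed to [ggplot2::geom_tile()].
#' @exportS3Method ggplot2::autoplot
autoplot.fst_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$deme_a, .data$deme_b,
                                   fill = .data$theta)) +
    ggplot2::geom_tile(...) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f%s", .data$theta,
                      ifelse(.data$significant, "*", "")))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "F_ST")
}

#' Heterozygosity along the concatenated pseudogenome
#'
#' @param profile Tibble from [window_profile()].
#' @param highlight Optional sample ids drawn in colour over the grey bulk.
#' @return A ggplot.
#' @export
plot_window_profile <- function(profile, highlight = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(.data$start / 1e6, .data$h_o,
                                    group = .data$sample)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3)
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(profile, .data$sample %in% highlight),
      ggplot2::aes(colour = .data$sample), linewidth = 0.6)
  }
  p + ggplot2::labs(x = "pseudogenome position (Mb)", y = "window H_O") +
    ggplot2::theme_minimal()
}

#' Scatter of individual heterozygosity by deme
#' @param het Tibble from [autosomal_het()] with a `deme` column.
#' @return A ggplot.
#' @export
plot_het_by_deme <- function(het) {
  ggplot2::ggplot(het, ggplot2::aes(.data$deme, .data$h_o)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = "deme", y = "individual autosomal H_O") +
    ggplot2::theme_minimal()
}
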