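#' Principal component scores of genotype dosages
#'
#' Centers the 0/1/2 alternate-allele dosage matrix over biallelic
#' polymorphic loci (missing genotypes imputed by the locus mean) and
#' eigen-decomposes it. Scores are the sample projections; explained
#' variance fractions are eigenvalue shares.
#'
#' @param table A [geno_tbl()].
#' @param n_components Number of components to keep.
#' @return Object of class `geno_pca`: list with `scores` (tibble of sample
#'   metadata plus `PC1..PCk`), `explained` (variance fractions), `sdev`,
#'   `n_loci`.
#' @export
pca_scores <- function(table, n_components = 10) {
  d <- alt_dosage(table)
  mono <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || all(x == x[1])
  })
  d <- d[, !mono, drop = FALSE]
  if (ncol(d) < n_components) {
    abort(sprintf("only %d polymorphic loci for %d components.",
                  ncol(d), n_components))
  }
  mu <- colMeans(d, na.rm = TRUE)
  for (l in seq_len(ncol(d))) d[is.na(d[, l]), l] <- mu[l]
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    table$samples,
    as_tibble(pc$x[, seq_len(k), drop = FALSE])
  )
  structure(
    list(scores = scores, explained = explained[seq_len(k)],
         sdev = pc$sdev, n_loci = ncol(d)),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d loci; explained: %s\n",
              nrow(x$scores), x$n_loci,
              paste(sprintf("%.1f%%", 100 * head(x$explained, 5)),
                    collapse = " ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geno_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.geno_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_loci = x$n_loci,
    pc1_frac = x$explained[1],
    pc2_frac = x$explained[2]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.geno_pca <- function(object, x = 1, y = 2, colour = "deme", ...) {
  xs <- paste0("PC", x)
  ys <- paste0("PC", y)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[xs]], .data[[ys]],
                               colour = .data[[colour]])) +
    ggplot2::geom_point(...) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, 100 * object$explained[x]),
      y = sprintf("%s (%.1f%%)", ys, 100 * object$explained[y])
    ) +
    ggplot2::theme_minimal()
}
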