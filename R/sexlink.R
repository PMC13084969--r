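#' Screen loci for sex-linked genotype patterns
#'
#' Two exact tests per testable locus (at least `min_per_sex` individuals of
#' each sex with calls): a Fisher test on the 2x2 heterozygote /
#' non-heterozygote table by sex, and a Fisher test on the called / missing
#' table by sex. After Bonferroni correction at family-wise `alpha`, a locus
#' is flagged `"x_linked"` when the heterozygosity test is significant with
#' the male heterozygote rate below the female rate (X-hemizygous males are
#' reported homozygous, so their het rate collapses to ~0), and `"yw_like"`
#' when the call-rate test is significant with one sex largely uncalled.
#' Samples with missing sex are ignored; loci that are untestable after
#' that are skipped and counted in the `n_skipped` attribute.
#'
#' @param table A [geno_tbl()].
#' @param sexes Optional character vector ("M"/"F") aligned with samples;
#'   defaults to `table$samples$sex`.
#' @param alpha Family-wise error rate for the Bonferroni correction.
#' @param min_per_sex Minimum called individuals of each sex for a locus to
#'   be testable.
#' @return Tibble of testable loci: `site` (index into the table), `contig`,
#'   `pos`, per-sex het and call rates, raw `p_het` / `p_call`, and `flag`
#'   (`NA`, `"x_linked"` or `"yw_like"`). Attribute `n_skipped` counts
#'   untestable loci.
#' @export
sex_linkage_screen <- function(table, sexes = NULL, alpha = 0.05,
                               min_per_sex = 5) {
  sexes <- sexes %||% table$samples$sex
  if (is.null(sexes)) abort("no sex labels available.")
  known <- !is.na(sexes) & sexes %in% c("M", "F")
  male <- known & sexes == "M"
  female <- known & sexes == "F"
  called <- is_called(table)
  het <- is_het(table)

  m_called <- colSums(called[male, , drop = FALSE])
  f_called <- colSums(called[female, , drop = FALSE])
  m_het <- colSums(het[male, , drop = FALSE], na.rm = TRUE)
  f_het <- colSums(het[female, , drop = FALSE], na.rm = TRUE)
  n_m <- sum(male); n_f <- sum(female)

  # the heterozygosity contrast needs calls in both sexes at the locus; the
  # call-rate contrast only needs enough individuals of each sex in the cohort
  het_testable <- m_called >= min_per_sex & f_called >= min_per_sex
  call_testable <- rep(n_m >= min_per_sex & n_f >= min_per_sex,
                       n_sites(table))
  testable <- which(het_testable | call_testable)
  n_skipped <- n_sites(table) - length(testable)
  if (length(testable) == 0) {
    out <- tibble(site = integer(), contig = character(), pos = integer(),
                  male_het = numeric(), female_het = numeric(),
                  male_call = numeric(), female_call = numeric(),
                  p_het = numeric(), p_call = numeric(), flag = character())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  p_het <- vapply(testable, function(l) {
    if (!het_testable[l]) return(NA_real_)
    fisher.test(matrix(c(m_het[l], m_called[l] - m_het[l],
                         f_het[l], f_called[l] - f_het[l]), 2))$p.value
  }, numeric(1))
  p_call <- vapply(testable, function(l) {
    fisher.test(matrix(c(m_called[l], n_m - m_called[l],
                         f_called[l], n_f - f_called[l]), 2))$p.value
  }, numeric(1))

  cut_het <- alpha / max(1, sum(het_testable))
  cut_call <- alpha / length(testable)
  mh <- m_het[testable] / m_called[testable]
  fh <- f_het[testable] / f_called[testable]
  mc <- m_called[testable] / n_m
  fc <- f_called[testable] / n_f
  flag <- rep(NA_character_, length(testable))
  flag[p_call < cut_call & abs(mc - fc) > 0.5] <- "yw_like"
  flag[!is.na(p_het) & p_het < cut_het & mh < fh] <- "x_linked"

  out <- tibble(
    site = testable,
    contig = table$sites$contig[testable],
    pos = table$sites$pos[testable],
    male_het = mh, female_het = fh,
    male_call = mc, female_call = fc,
    p_het = p_het, p_call = p_call,
    flag = flag
  )
  attr(out, "n_skipped") <- n_skipped
  out
}
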