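#' Convert a genotype table to a vcfR object
#'
#' Invariant records get a missing ALT per the VCF standard; per-genotype
#' depth goes to the per-sample DP field; positions are 1-based.
#'
#' @param x A [geno_tbl()].
#' @return A [vcfR::vcfR] object.
#' @export
as_vcfR <- function(x) {
  L <- n_sites(x)
  fix <- cbind(
    CHROM = as.character(x$sites$contig),
    POS = as.character(x$sites$pos),
    ID = NA_character_,
    REF = as.character(x$sites$ref),
    ALT = ifelse(is.na(x$sites$alt) | x$sites$alt == "", NA_character_,
                 x$sites$alt),
    QUAL = as.character(x$sites$qual %||% rep(NA_real_, L)),
    FILTER = "PASS",
    INFO = NA_character_
  )
  called <- is_called(x)
  gt_str <- matrix("./.", n_samples(x), L)
  gt_str[called] <- paste0(x$gt1[called], "/", x$gt2[called])
  dp <- x$dp
  dp[is.na(dp)] <- 0L
  body <- matrix(paste0(gt_str, ":", dp), n_samples(x), L)
  gt <- cbind("GT:DP", t(body))
  colnames(gt) <- c("FORMAT", x$samples$sample)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=demescope",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  methods::new("vcfR", meta = meta, fix = fix, gt = gt)
}

#' Read a joint-genotyped VCF (with invariant sites) into a genotype table
#'
#' @param vcf_path Path to a VCF (plain or bgzip/gzip).
#' @param meta Optional path to a sample metadata CSV with columns `sample`,
#'   `deme` and optionally `lon`, `lat`, `sex`, `year`; or a data frame.
#'   Samples absent from the metadata keep `NA` fields; metadata rows are
#'   matched by sample id.
#' @return A [geno_tbl()].
#' @export
read_geno_vcf <- function(vcf_path, meta = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  a1 <- sub("^([0-9.]+)([/|].*)?$", "\\1", gt_chr)
  a2 <- sub("^([0-9.]+)[/|]([0-9.]+)(:.*)?$", "\\2", gt_chr)
  a2[!grepl("[/|]", gt_chr)] <- a1[!grepl("[/|]", gt_chr)]
  to_int <- function(m) {
    m[m == "." | is.na(m)] <- NA
    out <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m)))
    out
  }
  gt1 <- t(to_int(a1))
  gt2 <- t(to_int(a2))
  # half-missing calls count as uncalled
  half <- xor(is.na(gt1), is.na(gt2))
  gt1[half] <- NA_integer_
  gt2[half] <- NA_integer_
  dpm <- t(dp)
  storage.mode(dpm) <- "integer"
  sites <- tibble(
    contig = vcf@fix[, "CHROM"],
    pos = as.integer(vcf@fix[, "POS"]),
    ref = vcf@fix[, "REF"],
    alt = dplyr::na_if(vcf@fix[, "ALT"], "."),
    qual = suppressWarnings(as.numeric(vcf@fix[, "QUAL"]))
  )
  samples <- tibble(sample = colnames(vcf@gt)[-1])
  if (!is.null(meta)) {
    md <- if (is.character(meta)) {
      as_tibble(read.csv(meta, stringsAsFactors = FALSE))
    } else {
      as_tibble(meta)
    }
    if (!"sample" %in% names(md)) abort("metadata must have a 'sample' column.")
    samples <- dplyr::left_join(samples, md, by = "sample")
  }
  geno_tbl(gt1, gt2, dpm, sites, samples)
}

#' Write a simulated study to disk
#'
#' Emits the genotype table as VCF (gzipped), sample metadata and ground
#' truth as CSV, and the generating config as YAML, so a run can be
#' reproduced or consumed by external tools.
#'
#' @param sim A `deme_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "deme_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf.gz"),
    meta = file.path(dir, "samples.csv"),
    truth_individuals = file.path(dir, "truth_individuals.csv"),
    truth_pairs = file.path(dir, "truth_pairs.csv"),
    truth_sites = file.path(dir, "truth_sites.csv"),
    truth_deme_freqs = file.path(dir, "truth_deme_freqs.csv"),
    config = file.path(dir, "config.yaml")
  )
  ok <- try(vcfR::write.vcf(as_vcfR(sim$table), file = paths$vcf),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("failed writing VCF to '%s': %s", paths$vcf,
                  attr(ok, "condition")$message))
  }
  write.csv(sim$table$samples, paths$meta, row.names = FALSE)
  write.csv(sim$truth$individuals, paths$truth_individuals, row.names = FALSE)
  write.csv(sim$truth$pairs, paths$truth_pairs, row.names = FALSE)
  write.csv(sim$truth$sites, paths$truth_sites, row.names = FALSE)
  freqs <- as.data.frame(t(sim$truth$deme_freqs))
  write.csv(cbind(sim$truth$sites[, c("contig", "pos")], freqs),
            paths$truth_deme_freqs, row.names = FALSE)
  write_sim_config(sim$config, paths$config)
  invisible(paths)
}
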