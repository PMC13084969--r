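#' Pipeline run configuration
#'
#' Bundles every stage's parameters with a single global seed. Either a
#' [sim_config()] (synthetic input) or a VCF + metadata pair must be given.
#' Stage parameters default to the package-wide conventions: call rates
#' 0.70/0.85 overall and 0.50 in all demes, <10% sample missingness, MAC 3,
#' locus mean depth in \[5, 95\], per-individual depth in \[15, 95\],
#' 10,000 bootstraps at table-wide alpha 0.01, 999 Mantel permutations, and
#' exponential kriging with 36 neighbours.
#'
#' @param sim A [sim_config()], or `NULL` to read `vcf`/`meta`.
#' @param vcf,meta Input paths when `sim` is `NULL`.
#' @param stages Character vector of stages to run, in fixed order
#'   `simulate`, `filter`, `het`, `structure`, `krige`, `report`.
#' @param seed Global seed; per-stage seeds derive from it (see
#'   [stage_seed()]).
#' @param filter,het,structure,krige Named lists overriding stage defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            vcf = NULL, meta = NULL,
                            stages = c("simulate", "filter", "het",
                                       "structure", "krige", "report"),
                            seed = 1L,
                            filter = list(), het = list(),
                            structure = list(), krige = list()) {
  if (is.null(sim) && is.null(vcf)) {
    abort("either a sim_config or a vcf path is required.", class = "config_error")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  defaults <- list(
    filter = list(min_qual = 30, first_overall_rate = 0.70,
                  overall_rate = 0.85, per_deme_rate = 0.5, min_demes = NULL,
                  max_missing = 0.10, min_mac = 3, min_mean_dp = 5,
                  max_mean_dp = 95, thin_bp = NULL),
    het = list(min_dp = 15, max_dp = 95, window_bp = 1e5, min_records = 50),
    structure = list(n_boot = 10000, alpha_tablewide = 0.01, n_perm = 999,
                     n_components = 5),
    krige = list(k_neighbors = 36, n_x = 100, n_y = 100, n_bins = 12)
  )
  merge1 <- function(base, over) utils::modifyList(base, over)
  out <- list(sim = sim, vcf = vcf, meta = meta, stages = stages,
              seed = as.integer(seed),
              filter = merge1(defaults$filter, filter),
              het = merge1(defaults$het, het),
              structure = merge1(defaults$structure, structure),
              krige = merge1(defaults$krige, krige))
  class(out) <- "pipeline_config"
  out
}

#' Per-stage seed derivation
#'
#' Deterministic expansion of the global seed so a stage can be rerun in
#' isolation with the same stream: `(seed + 1000003 * stage_index) mod
#' (2^31 - 1)`, with stages indexed in their fixed order.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  order <- c("simulate", "filter", "het", "structure", "krige", "report")
  i <- match(stage, order)
  if (is.na(i)) abort(sprintf("unknown stage '%s'.", stage))
  as.integer((as.numeric(seed) + 1000003 * i) %% (2^31 - 1))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> filtering cascade (with kinship and sex-linkage
#' screens) -> per-individual heterozygosity, per-deme F_IS and the
#' pseudogenome window profile -> pairwise F_ST with bootstrap, private
#' alleles, PCA, isolation-by-distance Mantel tests -> variogram fit and
#' ordinary kriging of H_O -> summary report. Every artefact is written as
#' CSV (plus the VCF for simulated data and a serialized config) into
#' `out_dir`; a stage failure halts the run with the stage named, keeping
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of class `demescope_run` with every stage
#'   result and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = out_dir)
  emit <- function(df, name) {
    write.csv(df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  }
  run_stage <- function(stage, expr) {
    inform(sprintf("[demescope] stage %s", stage))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "stage_error")
    })
  }
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(serialize_pipeline_config(config), cfg_path)

  if ("simulate" %in% config$stages) {
    table <- run_stage("simulate", {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_dataset(sim_cfg)
      write_sim_outputs(sim, file.path(out_dir, "simulated"))
      res$sim <- sim
      sim$table
    })
  } else {
    table <- run_stage("simulate", read_geno_vcf(config$vcf, config$meta))
  }
  res$input <- table
  inform(sprintf("[demescope] input: %d samples x %d sites",
                 n_samples(table), n_sites(table)))

  if ("filter" %in% config$stages) {
    run_stage("filter", {
      set.seed(stage_seed(config$seed, "filter"))
      fc <- do.call(filter_cascade, c(list(table), config$filter))
      res$filtered <- fc$table
      res$filter_report <- fc$report
      emit(fc$report, "filter_report")
      kin <- kinship_screen(fc$table)
      res$kinship <- kin
      emit(kin, "kinship")
      if ("sex" %in% names(table$samples) &&
          any(!is.na(table$samples$sex))) {
        sl <- sex_linkage_screen(fc$table)
        res$sex_linkage <- sl
        emit(sl, "sex_linkage")
      }
      inform(sprintf("[demescope] filter: %d -> %d sites, %d -> %d samples",
                     n_sites(table), n_sites(fc$table),
                     n_samples(table), n_samples(fc$table)))
    })
  }

  if ("het" %in% config$stages) {
    run_stage("het", {
      hp <- config$het
      flagged <- if (!is.null(res$sex_linkage)) {
        # screen indexes the filtered SNP table; map back by contig+pos
        key <- paste(res$sex_linkage$contig[!is.na(res$sex_linkage$flag)],
                     res$sex_linkage$pos[!is.na(res$sex_linkage$flag)])
        which(paste(table$sites$contig, table$sites$pos) %in% key)
      } else NULL
      het <- autosomal_het(table, min_dp = hp$min_dp, max_dp = hp$max_dp,
                           exclude_sites = flagged)
      res$het <- dplyr::left_join(
        het, table$samples[, intersect(c("sample", "deme", "lon", "lat",
                                         "year"), names(table$samples))],
        by = "sample")
      emit(res$het, "het_individuals")
      res$fis <- deme_fis(table)
      emit(res$fis, "fis_demes")
      res$window_profile <- window_profile(
        table, window_bp = hp$window_bp, min_dp = hp$min_dp,
        max_dp = hp$max_dp, min_records = hp$min_records)
      emit(res$window_profile, "window_profile")
    })
  }

  if ("structure" %in% config$stages) {
    run_stage("structure", {
      if (is.null(res$filtered)) abort("structure stage needs the filter stage.")
      sp <- config$structure
      set.seed(stage_seed(config$seed, "structure"))
      snps <- res$filtered
      res$fst <- fst_bootstrap(snps, n_boot = sp$n_boot,
                                alpha_tablewide = sp$alpha_tablewide)
      emit(res$fst, "fst_pairs")
      emit(fst_table(res$fst), "fst_table")
      res$private <- private_alleles(snps)
      emit(res$private, "private_alleles")
      res$pca <- pca_scores(snps, n_components = sp$n_components)
      emit(tidy(res$pca), "pca_scores")
      if (all(c("lon", "lat") %in% names(snps$samples))) {
        res$mantel <- ibd_mantel(snps, n_perm = sp$n_perm)
        emit(res$mantel, "mantel")
      }
    })
  }

  if ("krige" %in% config$stages) {
    run_stage("krige", {
      if (is.null(res$het)) abort("krige stage needs the het stage.")
      if (!all(c("lon", "lat") %in% names(res$het))) {
        abort("no coordinates available for kriging.")
      }
      kp <- config$krige
      set.seed(stage_seed(config$seed, "krige"))
      emp <- empirical_semivariogram(res$het, res$het$h_o,
                                     n_bins = kp$n_bins)
      model <- fit_exponential(emp)
      surf <- krige(res$het, res$het$h_o, model,
                    k_neighbors = kp$k_neighbors,
                    n_x = kp$n_x, n_y = kp$n_y)
      res$variogram <- model
      res$surface <- zscore_surface(surf, res$het$h_o)
      emit(res$surface, "kriged_surface")
    })
  }

  if ("report" %in% config$stages && !is.null(res$het)) {
    run_stage("report", {
      res$summary <- summary_report(res$het)
      writeLines(format(res$summary), file.path(out_dir, "summary.txt"))
      emit(res$summary$deme_table, "summary_demes")
    })
  }
  class(res) <- "demescope_run"
  invisible(res)
}

serialize_pipeline_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) {
    sim <- unclass(out$sim)
    sim$deme_centroids <- as.list(as.data.frame(sim$deme_centroids))
    out$sim <- sim
  }
  out
}

#' Heterozygosity summary battery
#'
#' The deme-level summary of individual H_O: extremes and their demes,
#' per-deme mean/min/max and max/min ratio, a single-factor ANOVA of H_O
#' across demes (df k-1 and n-k), and OLS R-squared of H_O against the
#' retained-site count and, when present, the sampling year.
#'
#' @param het Tibble from [autosomal_het()], with a `deme` column (and
#'   optionally `year`).
#' @return List of class `het_summary`: `extremes`, `deme_table`, `anova`,
#'   `covariates`.
#' @export
summary_report <- function(het) {
  stopifnot(all(c("h_o", "deme") %in% names(het)))
  extremes <- tibble(
    which = c("min", "max"),
    sample = het$sample[c(which.min(het$h_o), which.max(het$h_o))],
    deme = het$deme[c(which.min(het$h_o), which.max(het$h_o))],
    h_o = c(min(het$h_o), max(het$h_o))
  )
  deme_table <- dplyr::summarise(
    dplyr::group_by(het, .data$deme),
    n = dplyr::n(),
    mean_h_o = mean(.data$h_o),
    min_h_o = min(.data$h_o),
    max_h_o = max(.data$h_o),
    ratio_max_min = max(.data$h_o) / min(.data$h_o),
    .groups = "drop"
  )
  k <- length(unique(het$deme))
  anova_row <- if (k < 2) {
    tibble(f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
           p = NA_real_, note = "single deme; ANOVA skipped")
  } else if (var(het$h_o) == 0) {
    # degenerate flat response: no among-deme signal by definition
    tibble(f = 0, df1 = k - 1L, df2 = nrow(het) - k,
           p = 1, note = "zero variance in H_O")
  } else {
    fit <- aov(h_o ~ factor(deme), data = het)
    tab <- summary(fit)[[1]]
    tibble(f = tab[["F value"]][1],
           df1 = as.integer(tab[["Df"]][1]),
           df2 = as.integer(tab[["Df"]][2]),
           p = tab[["Pr(>F)"]][1],
           note = NA_character_)
  }
  covs <- list()
  if (nrow(het) >= 3 && var(het$n_retained) > 0) {
    covs$retained_sites <- het_covariate_check(het, "n_retained")
  }
  if (nrow(het) >= 3 && "year" %in% names(het) &&
      length(unique(het$year)) > 1) {
    covs$year <- het_covariate_check(het, "year")
  }
  covariates <- dplyr::bind_rows(covs, .id = "covariate")
  structure(list(extremes = extremes, deme_table = deme_table,
                 anova = anova_row, covariates = covariates),
            class = "het_summary")
}

#' @export
format.het_summary <- function(x, ...) {
  lines <- c(
    "== Individual autosomal heterozygosity summary ==",
    sprintf("  lowest  H_O: %.3e (%s, deme %s)", x$extremes$h_o[1],
            x$extremes$sample[1], x$extremes$deme[1]),
    sprintf("  highest H_O: %.3e (%s, deme %s)", x$extremes$h_o[2],
            x$extremes$sample[2], x$extremes$deme[2]),
    "",
    "  per-deme:",
    sprintf("    %-6s n=%-3d mean=%.3e min=%.3e max=%.3e max/min=%.2f",
            x$deme_table$deme, x$deme_table$n, x$deme_table$mean_h_o,
            x$deme_table$min_h_o, x$deme_table$max_h_o,
            x$deme_table$ratio_max_min),
    ""
  )
  if (!is.na(x$anova$f)) {
    lines <- c(lines, sprintf("  ANOVA across demes: F_%d,%d = %.3f, p = %.3f",
                              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  } else {
    lines <- c(lines, paste0("  ", x$anova$note))
  }
  lines <- c(lines, sprintf(
    "  H_O ~ %s: R^2 = %.3f (slope %.3e)",
    x$covariates$covariate, x$covariates$r_squared, x$covariates$slope))
  lines
}

#' @export
print.het_summary <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
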