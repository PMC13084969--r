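# demescope

Conservation-genomics analysis for small, geographically structured
populations ("demes"), starting from a jointly genotyped VCF that keeps
**invariant sites**. The motivating setting is a threatened vertebrate
sampled across a fragmented range — a few dozen individuals in a handful of
demes split over two regions — where the questions are: how differentiated
are the demes, is similarity decaying with distance, and *which individuals*
carry low genome-wide heterozygosity, and where?

The package implements, as plain R functions over tibbles:

* **Per-individual autosomal heterozygosity** with invariant-site
  denominators: `H_O = heterozygous retained records / all retained
  records`, filtered *per individual* (missing calls, spanning-deletion
  `*` alleles, depth outside [15, 95]) with multiallelic sites atomized
  into one biallelic record per alternate — so estimates are comparable
  across individuals and unbiased by sample composition. Plus per-deme
  Wright's F_IS and a window profile along a size-concatenated
  pseudogenome.
* **A RADseq-style filtering cascade** (site quality, locus call rate
  overall and per deme, per-sample missingness, minor allele count,
  mean-depth window with the `d + 4√d` ceiling, greedy distance thinning),
  each stage reporting counts, plus moment-estimator kinship (K, K0) and
  exact-test sex-linkage screens.
* **Differentiation statistics**: pairwise Weir–Cockerham
  θ = Σaₗ / Σ(aₗ+bₗ+cₗ) (ratio of sums over loci, unequal sample sizes)
  with locus-bootstrap confidence intervals and Bonferroni-corrected
  significance; private allele counts; PCA of genotype dosages.
* **Isolation by distance**: Rousset's â in identity-probability form,
  â = Σ(Q_w − Q_ij) / Σ(1 − Q_w) over shared loci with an explicit
  reference scope, against natural-log great-circle distance via one-sided
  permutation Mantel tests at deme, region and global scope.
* **Ordinary kriging of H_O** with a WLS-fitted exponential semivariogram
  and 36-nearest-neighbour search, output as deviations from the global
  mean in s.d. units (`z`), with `autoplot()` maps.
* **A synthetic-data generator** (`sim_config()` / `simulate_dataset()`)
  producing VCF + metadata + ground truth under hierarchical
  Balding–Nichols divergence, per-individual inbreeding, planted sibling /
  parent–offspring dyads, optional X-linked loci and within-deme
  isolation-by-distance gradients, with negative-binomial depth and
  missingness — the test bed for everything above.

`vignettes/demescope-methods.Rmd` documents the estimators, defaults and
design decisions in detail.

## Worked example

```r
library(demescope)
library(dplyr)

cfg <- sim_config(seed = 42, n_sites = 20000, prop_variable = 0.1,
                  ibd_slope = 0.4, n_sexlinked = 25)
sim <- simulate_dataset(cfg)
sim$table
#> <geno_tbl> 85 samples x 20000 sites (2351 variant, 17649 invariant), 200 contigs
#>   call rate: 0.970
#>   demes: DE(13) DW(22) NE(6) NW(18) TE(7) TP(10) TW(9)

het <- autosomal_het(sim$table) |> left_join(sim$table$samples, by = "sample")
summary_report(het)
#> == Individual autosomal heterozygosity summary ==
#>   lowest  H_O: 1.907e-02 (DE_10, deme DE)
#>   highest H_O: 3.136e-02 (NE_02, deme NE)
#> ...
#>   ANOVA across demes: F_6,78 = 1.363, p = 0.240
#>   H_O ~ retained_sites: R^2 = 0.001 (slope -2.991e-06)
```

Each individual's `h_o` is its heterozygous fraction over ~18,000 retained
records; the ANOVA (df 6 and 78 for 7 demes, 85 individuals) asks whether
demes differ in mean H_O — here, as in the motivating data, within-deme
spread (max/min ratios of 1.3–1.6) swamps the among-deme signal.

```r
snps <- filter_cascade(sim$table)$table       # 20,000 sites -> ~1,700 SNPs
fst <- fst_bootstrap(snps, n_boot = 1000)
glance(fst)
#> # A tibble: 1 × 4
#>   n_pairs mean_theta n_significant alpha_per_test
#> 1      21      0.118            21       0.000476

ibd_mantel(snps, scopes = "global", n_perm = 999, seed = 1)
#> # A tibble: 1 × 6
#>   scope  unit  n_samples     r     p n_perm
#> 1 global all          85 0.668 0.001    999
```

All 21 deme pairs are significantly differentiated at the Bonferroni
per-test level 0.01/21, with mean pairwise θ ≈ 0.12 (the generator's
hierarchical divergence), and the planted within-deme gradient surfaces as
a strong global isolation-by-distance signal (Mantel r = 0.67 between â and
log distance). A kriged map of individual heterozygosity is then:

```r
emp <- empirical_semivariogram(het, het$h_o)
surf <- krige(het, het$h_o, fit_exponential(emp), k_neighbors = 36) |>
  zscore_surface(het$h_o)
autoplot(surf)   # blue: above-mean H_O, red: basins of low heterozygosity
```

`run_pipeline(pipeline_config(...), out_dir)` chains all stages
(simulate/load → filter + screens → heterozygosity → structure → kriging →
report) with one global seed and writes every artefact as CSV;
`inst/cli/demescope.R` wraps it for shell use
(`Rscript inst/cli/demescope.R run-all --config sim.yaml --out run/`).

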