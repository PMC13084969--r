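---
title: "Methods: individual heterozygosity, differentiation and spatial structure in demes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual heterozygosity, differentiation and spatial structure in demes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

demescope analyses conservation-genomic data for small, geographically
structured populations ("demes") starting from a jointly genotyped variant
file that retains **invariant sites**. This vignette documents the models and
estimators, the choices made where conventions genuinely diverge, and what
the synthetic-data generator does and does not emulate.

## Why invariant sites are the backbone

Per-individual observed heterozygosity is estimated as

$$H_O^{(i)} = \frac{\text{heterozygous retained records}_i}
                   {\text{all retained records}_i},$$

where the denominator counts every confidently genotyped record for
individual $i$ — polymorphic or not. Conditioning the denominator only on
sites that happen to segregate in the sample would tie the scale of $H_O$ to
the sample composition; with invariant sites included, removing or adding
other individuals leaves $H_O^{(i)}$ unchanged (a property the test suite
asserts exactly). Filters are applied **per individual**: missing calls,
calls at sites carrying the spanning-deletion (`*`) allele, and calls with
depth outside $[15, 95]$ are dropped for that individual only, so samples of
uneven quality remain comparable. Multiallelic sites are atomized into one
biallelic record per alternate allele before counting; a genotype composed
of two different alternates is heterozygous in each derived record, and each
derived record counts once in both numerator and denominator. The depth
bounds are inclusive: the rules are "less than 15×" and "more than 95×"
removed, so 15 and 95 themselves are retained.

## The filtering cascade

Locus and sample filters run in a fixed order, each stage reporting counts
in and out: site quality (QUAL ≥ 30, standing in for a caller's hard-filter
battery since the generator emits a single quality scalar), a first-pass
locus call-rate screen (> 0.70 overall), per-sample missingness (strictly
below 10% to stay in; a sample at exactly the threshold is dropped), a
stricter second pass (> 0.85 overall and > 0.50 within every deme), minor
allele count ≥ 3, a locus mean-depth window of $[5, 95]$, and optional
greedy distance thinning (first site kept, then each site at least 10,000 bp
beyond the last *kept* site, contigs independent) for linkage-sensitive
analyses. The mean-depth ceiling can be derived from the data as
$\bar d + 4\sqrt{\bar d}$ (`li_max_depth()`), the usual guard against
collapsed repeats. Every stage is mirrored by a brute-force recount oracle
in the tests.

Two screens accompany the cascade. The **kinship screen** uses the robust
within-pair moment estimator
$K = (N_{\text{het,both}} - 2N_{\text{opp}}) / (N_{\text{het},i} +
N_{\text{het},j})$ together with $K_0 = N_{\text{opp}} / \sum_l 2p_l^2(1-p_l)^2$,
the opposite-homozygote count normalised by its unrelated-pair expectation
and clamped to $[0,1]$. $K_0$ estimates the probability of sharing zero
alleles identical by descent directly: parent–offspring pairs sit near 0,
siblings near 0.25, unrelated pairs near 1. Classification windows are
$K \in [0.177, 0.354]$ for first-degree pairs (parent–offspring if
$K_0 < 0.1$, full siblings otherwise) and $K \in [0.088, 0.177)$ for half
siblings. These are the standard powers-of-$2^{-1/2}$ windows; with strong
population structure the pooled-frequency normalisation of $K_0$ is
conservative, so first-degree dyads in structured data may straddle the
parent–offspring/full-sibling boundary — the screen is for flagging, not
pedigree reconstruction. The **sex-linkage screen** runs two Fisher exact
tests per locus — heterozygote-by-sex and called-by-sex 2×2 tables — with
Bonferroni control at family-wise 0.05. X-linked loci show male
heterozygosity collapsing toward zero (hemizygous males are reported as
homozygous diploid calls); Y/W-like loci show one sex largely uncalled. The
het contrast needs five called individuals of each sex at the locus; the
call-rate contrast only needs five individuals of each sex in the cohort,
since a fully sex-missing locus is exactly the pattern sought.

## Differentiation and isolation by distance

Pairwise $F_{ST}$ uses the Weir–Cockerham (1984) variance components
$a, b, c$ for two populations with unequal, per-locus sample sizes (called
genotypes only), combined across loci as a **ratio of sums**
$\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)$ — not a mean of
per-locus ratios, a distinction the tests pin down on a two-locus fixture.
Significance comes from resampling loci with replacement (10,000 bootstraps
by default): the percentile interval and a one-sided $p$, the fraction of
bootstrap $\theta^*$ at or below zero, since negative differentiation is
estimation noise. With 21 deme pairs the Bonferroni per-test level is the
table-wide $\alpha' = 0.01$ divided by 21.

Individual genetic distance is Rousset's $\hat a$ in its identity-probability
form: with $Q_w$ the within-individual probability of allelic identity
averaged over the reference sample and $Q_{ij}$ the cross-individual
identity (mean of the four allele comparisons),
$\hat a_{ij} = \sum_l (Q_{w,l} - Q_{ij,l}) / \sum_l (1 - Q_{w,l})$ over the
loci both individuals have called. The reference scope matters and is
explicit: within-deme tests use the deme as reference, region and global
tests their own scope. A scope with no heterozygosity drives the denominator
to zero; the estimator then returns a degenerate flag rather than a number.

Isolation by distance is tested by Mantel correlation between $\hat a$ and
the **natural log** of great-circle distance (haversine, mean Earth radius
6371.0088 km; base-10 is available as an option — the choice rescales the
regressor and leaves $r$ unchanged). The permutation test permutes rows and
columns of one matrix simultaneously, one-sided for positive association,
with the add-one rule $p = (1 + \#\{r^* \ge r\})/(n_{\text{perm}} + 1)$.
Co-located pairs have no log distance and are excluded from every
correlation, including under permutation. PCA operates on mean-imputed
0/1/2 dosages of polymorphic biallelic loci via `prcomp()`.

## Kriging individual heterozygosity

The spatial surface is ordinary kriging of individual $H_O$ with an
exponential structure, $k = 36$ nearest observations per node, reported as
deviations from the global mean in standard-deviation units
($z = (\hat y - \bar{H_O}) / s_{H_O}$). The upstream GIS products that
popularised this display do not disclose their variogram fitting, so the
package makes it explicit and reproducible: a Matheron empirical
semivariogram on equal-width lag bins (empty bins reported as absent, never
zero), then weighted least squares (weights = pair counts) for
$\gamma(h) = \text{nugget} + \text{psill}\,(1 - e^{-h/\text{range}})$ under
non-negativity constraints via Levenberg–Marquardt, starting from the first
bin's semivariance (nugget), the spread to the maximum (partial sill) and a
third of the maximum lag (range). A collapsing partial sill returns a pure
nugget model with a warning. The kriging system uses the covariance
$C(h) = \text{psill}\,e^{-h/\text{range}}$ with the nugget on the diagonal
and a Lagrange multiplier constraining weights to sum to one; with zero
nugget the predictor is exact at observations (asserted to $10^{-8}$), and
the 36-neighbour solution equals the full system whenever $n \le 36$.
Distances stay on the sphere (no projection): at deme scale the error is
negligible and it keeps the surface free of projection choices. The default
grid is the observation bounding box padded 10%, 100×100 cells; duplicated
observation locations are averaged before solving rather than left to make
the system singular. No coastline masking is applied — the surface is a
statistical object, and masking is a display decision left to the caller.

## The synthetic generator

The generator writes standard VCF (invariant records with missing ALT,
depth in the per-sample DP field) plus metadata and ground-truth CSVs, and
emulates, in order of importance to the analyses:

* **Hierarchical divergence** — ancestral alternate frequencies uniform on
  $[0.05, 0.95]$ for variable sites; regions drawn Balding–Nichols around
  the ancestral pool ($\theta_{\text{region}}$, default 0.05) and demes
  around their region ($\theta_{\text{deme}}$, default 0.10), giving
  closed-form expectations for $F_{ST}$ recovery tests. Invariant sites
  propagate unchanged (a ~2% sliver is fixed for the alternate allele, as
  happens in real joint calls against a divergent reference).
* **Individual inbreeding** — each individual draws $F_i$ uniformly from its
  deme's interval (default $[0, 0.35]$, making the expected two-fold
  within-deme spread of heterozygosity attainable); genotypes follow
  $P(\text{het}) = 2p(1-p)(1-F_i)$ with the homozygote classes receiving
  $p^2 + F_i p(1-p)$ and $(1-p)^2 + F_i p(1-p)$.
* **Relatives** — full-sibling and parent–offspring dyads planted by
  explicit Mendelian transmission from simulated parents, always within one
  deme (default: two sibling pairs, echoing the handful of sibling dyads a
  field sample of this kind contains).
* **Space** — individuals scatter isotropically (15 km s.d. by default)
  around seven deme centroids laid out like the two-region study geography,
  with sizes 18, 9, 7, 6, 22, 13, 10 (85 individuals). With `ibd_slope > 0`
  each variable site gets a fixed random gradient direction and
  individual-specific frequencies shifted on the logit scale by
  `ibd_slope` × standardised eastward offset, which yields positive
  within-deme Mantel correlations in expectation. How much within-deme
  signal exists relative to deme divergence is not known for the real
  system, so `ibd_slope` is a free knob (default 0) rather than a
  calibrated quantity.
* **Noise** — depth negative binomial (mean 40, size 5; RAD depth is
  overdispersed, with the Poisson limit at `depth_dispersion = Inf`),
  genotypes set missing independently (3%), and an optional error model
  that redraws one allele copy from the site's pooled frequency, chosen so
  `error_rate = 0` reproduces the clean table bit-for-bit.
* **Sex linkage** — optional X-linked loci at which males carry a single
  allele reported as a homozygous diploid call, so the screen has planted
  positives to find.

It does **not** emulate read-level reality (no FASTQ, alignment or
genotype-likelihood machinery), linkage disequilibrium beyond physical
thinning structure, recombination maps, selection, or coalescent
genealogies. Passing tests therefore demonstrate that the estimators
recover the parameters of this generative model at realistic scale — not
that any particular wet-lab artefact is handled.

A default simulation is 85 individuals × 50,000 sites (10% variable) on 200
contigs: large enough that multilocus estimators operate in their intended
regime, small enough to run on a desk machine. The test suite and the
acceptance script scale some scenarios down further (stated per test):
$F_{ST}$ recovery uses 50 replicates of 2×30 individuals at 2,000 loci, the
Mantel calibration 500 null replicates of 12 points at 999 permutations,
and the inbred-deme kriging scenario 4,000 sites on a 40×40 grid.

## Numerical and design choices

* **F_IS** per deme is the unweighted mean over polymorphic loci of
  $1 - H_{\text{obs}}/H_{\text{exp}}$ at the deme allele frequency, the
  per-site coefficient convention of the common callers; whether to average
  per-site coefficients or pool counts is genuinely open, so the
  small-sample-corrected $H_{\text{exp}} \cdot 2n/(2n-1)$ variant is a
  toggle (`hexp_correction`), and recovery tests use it.
* **Window profile** — contigs ordered by descending observed length and
  concatenated; windows below 50 retained records are reported absent, not
  zero, because a ratio on a tiny denominator is noise masquerading as
  signal.
* **Private alleles** count every allele (reference included) observed in
  exactly one deme's called genotypes.
* **Degenerate inputs** are contracts, not crashes: zero retained records
  for an individual is an error (never a silent $H_O = 0$), a constant
  matrix fails the Mantel correlation explicitly, zero observed variance
  fails z-scoring, monomorphic-only tables fail the kinship screen, and a
  flat ANOVA (all $H_O$ equal) reports $F = 0$ rather than 0/0.
* **Reproducibility** — one global seed expands into per-stage seeds by a
  fixed affine hash (`stage_seed()`), so stages can be toggled without
  perturbing each other's streams; two runs from the same config are
  byte-identical, which the pipeline tests verify by checksum.

## Limitations

The kinship classifier uses pooled allele frequencies; under strong
structure its $K_0$ normalisation is biased downward and classes should be
read as flags. The bootstrap treats loci as exchangeable, which physical
thinning supports only approximately. Kriging assumes second-order
stationarity and isotropy of $H_O$ over the study extent; with few dozen
observations the variogram fit is itself noisy, and the reported kriging
variance understates that uncertainty. Runs of homozygosity, model-based
clustering, migration-rate and bottleneck inference are intentionally out
of scope.
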