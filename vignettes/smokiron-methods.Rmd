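---
title: "Methods: linking smoking to striatal iron at phenotypic, genetic and causal levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking smoking to striatal iron at phenotypic, genetic and causal levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokiron)
```

# The scientific problem

Smokers show elevated iron in the striatum on susceptibility-weighted MRI.
Two markers capture it with opposite sign conventions: T2\* (shortened by
iron, so more iron means *lower* values) and QSM (tissue magnetic
susceptibility, *higher* with more iron), each measured bilaterally in the
putamen, caudate and accumbens — twelve region-level traits in all.
`smokiron` implements the full analytical chain that connects a smoking
exposure to these traits:

1. **Phenotypic**: de-confounded ordinary-least-squares associations between
   six smoking variables and the twelve traits, with FDR control, a
   left–right asymmetry test, a former-smoker cessation model and
   robustness metrics.
2. **Genetic**: genome-wide genetic correlation by bivariate LD-score
   regression, and gene-level cross-GWAS coherence tests under an LD-aware
   null.
3. **Causal**: bidirectional two-sample Mendelian randomisation with the
   standard sensitivity battery, and a gene-level directional ratio test.

Individual-level biobank data and full-scale GWAS summary statistics are
access-restricted, so the package ships generators for synthetic cohorts
and synthetic paired GWAS with *known* truth. Every operating
characteristic claimed below is measured on those generators by the test
suite; nothing is asserted that the tests do not compute.

# Phenotypic stage

## Cleaning and transformation cascade

`pheno_preprocess()` applies, in order:

* **Imputation** of covariates: group mean for continuous, mode for
  categorical variables (ties broken by the first level in sorted order).
  The "group" is the whole analysis sample; no subgroup rule is defined.
* **Outlier exclusion** on brain traits beyond five *unscaled* median
  absolute deviations from the median: `MAD = median(|x - median|)` without
  the 1.4826 consistency factor, reading "five absolute median deviations"
  literally. When MAD is zero the rule degenerates to keeping exact-median
  values. Filtering happens *before* any transformation.
* **Log transforms** for skewed variables: pack-years get `ln(x + 1)`
  (zeros are meaningful), deprivation-index-like variables get
  `ln(x + 1 - min(x))` so the minimum maps to zero.
* **De-confounding**: each brain trait *and* each smoking variable is
  regressed on the full covariate set (age, age², sex and their
  interactions, deprivation, income, education, alcohol, blood pressures,
  BMI, and opaque imaging covariates) and replaced by its residuals. The
  same covariates are used on both sides, which is what makes the
  downstream bivariate regressions interpretable as de-confounded
  associations.
* **Rank-based inverse normal transformation** of continuous variables
  using Blom offsets, `qnorm((rank - 3/8)/(n + 1/4))` with average ranks
  for ties, then z-scoring. Binary smoking contrasts are residualised but
  not rank-transformed (a rank transform of a binary variable is an affine
  map, so nothing would be gained).

## The regression battery

Six smoking variables — ever smoked, currently smoking, current vs never,
current vs former, former vs never (each contrast excluding the omitted
group), and pack-years — are each regressed against the twelve traits;
Benjamini–Hochberg FDR is applied across the 72 main-effect tests. Among
former smokers only, years since cessation, pack-years and their
interaction enter one joint model per trait, with both predictors
rank-transformed inside the subset so the fit is invariant to monotone
shifts (e.g. redefining the cessation reference date).

The left–right asymmetry z-test compares hemispheric coefficients with
`z = (bL - bR)/sqrt(seL^2 + seR^2)` and reports the **one-sided** upper-tail
probability: at z = 1.74 the upper tail is 0.041 and the two-sided value
would be 0.082, so only the one-sided convention reproduces the reported
rounding to 0.04. The formula ignores the L–R covariance because no
covariance information survives in reported per-hemisphere fits; since the
hemispheres are positively correlated this overstates the denominator and
the test is conservative. Both points are deliberate conventions, recorded
here as such.

Robustness between two analysis variants is summarised by the Pearson
correlation of aligned effect estimates and the Jaccard index of
FDR-significant sets, reported missing when neither analysis finds
anything (0/0 is undefined, not 1).

# Genetic correlation stage

## LD scores and LD-score regression

For SNP j, `ld_scores()` computes
\(\ell_j = \sum_k r^2_{adj}(j,k)\) over panel SNPs within a window, with
\(r^2_{adj} = r^2 - (1-r^2)/(n_{panel}-2)\) so null pairs contribute zero
in expectation. `fit_univariate()` regresses \(z_j^2\) on
\(n\ell_j/M\): the slope estimates the SNP heritability \(h^2\) and the
intercept captures confounding inflation. Weights follow the published
two-step scheme: an unweighted first pass fixes the conditional mean, the
second pass weights by \(1/[\max(\ell_j,1) \cdot 2(E[z_j^2])^2]\) (LD
redundancy times the chi-square variance). `fit_bivariate()` does the same
for the product \(z_{1j} z_{2j}\); its slope gives the genetic covariance
and its intercept estimates the cross-trait test-statistic correlation
\(\rho_{ov}\) induced by overlapping participants — the quantity the
gene-level tests consume. Standard errors come from a delete-one jackknife
over 20 contiguous SNP blocks; 200 blocks would be meaningless on a
2 000-SNP toy genome. The genetic correlation
\(r_g = \rho_g/\sqrt{h^2_1 h^2_2}\) is clipped to \([-1.5, 1.5]\) because
small-sample noise can push the raw ratio outside the parameter space, and
is reported missing when either heritability estimate is non-positive.

Two design points matter on toy genomes and are choices of this package,
not of the estimator. First, the LD-score window should match the true LD
extent (100 kb here): widening it only adds null-pair sampling noise to the
regressor, which attenuates the slope (errors-in-variables). Second, the
toy genome must contain *LD-score variation* — blocks of heterogeneous
AR(ρ) in {0, 0.4, 0.7, 0.9} spreading \(\ell\) over roughly 1–5 —
otherwise the regression has no leverage and the intercept is an
extrapolation far outside the design. The recovery experiments use a
2 000-SNP genome, a 4 000-haplotype panel, \(h^2 = 0.4\), n = 20 000 for
heritability and correlation, and n = 10 000 with modest background
(\(h^2 = 0.1\)) for overlap-intercept recovery, where the per-SNP
polygenic term would otherwise swamp the intercept.

## Gene-level coherence test

SNP magnitudes are first **rank-normalised genome-wide**:
\(u_i = (rank(p_i) - 1/2)/M\) and \(z_i = sign(\beta_i)\,
\Phi^{-1}(1 - u_i/2)\). This discards the (possibly mis-calibrated) tails
of the input p-values while keeping direction; the cost is a ceiling of
\(\Phi^{-1}(1 - 1/(2M))\) on any single SNP's contribution. SNPs with
minor allele frequency below 0.01 are removed first, and the second study
is allele-harmonised to the first before signs are read.

For each gene, a window of ±50 kb around the transcribed span (1-based,
inclusive, strand-symmetric — no strand-specific rule exists to encode)
collects the analysed SNPs and their panel LD correlation matrix
\(\Sigma\), regularised as \((1-\epsilon)\Sigma + \epsilon I\) with
\(\epsilon = 10^{-3}\) because thresholded-Gaussian panels can be
near-singular. The statistic is \(D = \sum_i z^A_i z^B_i\). Under the null
the two score vectors are jointly Gaussian, each \(N(0, \Sigma)\), with
cross-covariance \(\rho_{ov}\Sigma\); this is the minimal model consistent
with correcting for LD and for sample overlap through the LD-score
intercept. On the eigen-basis \(\Sigma = Q\Lambda Q^T\),
\(D = \sum_k \lambda_k a_k b_k\) with \(corr(a_k, b_k) = \rho_{ov}\), and
each product splits as
\(a b = \tfrac{1+\rho}{2} U - \tfrac{1-\rho}{2} V\) with independent
\(U, V \sim \chi^2_1\) (from \(ab = [(a+b)^2 - (a-b)^2]/4\) and
\(Var(a \pm b) = 2(1 \pm \rho)\)). The coherence p-value is the upper tail
of this indefinite weighted chi-square form at D; anti-coherence is the
upper tail of −D under the same null, and negating one trait's scores
swaps the two exactly. Flipping a trait (`trait_sign = -1`, used to put
T2\* on the iron scale) also flips the sign of its overlap correlation,
since shared-participant correlation is a property of the measured trait.

Eigenvalues below \(10^{-8}\) are truncated before the tail evaluation.
\(\rho_{ov}\) is taken from the bivariate LD-score intercept and clipped
to (−0.99, 0.99).

## Directional ratio test

The ratio statistic \(R = \sum_i z^A_i z^B_i / \sum_i (z^B_i)^2\)
normalises the cross-product by the outcome's own signal, so a gene scores
highly only when the exposure's effects are large relative to the
outcome's — a summary-statistic analogue of the strong-instrument
requirement, sensitive to broad polygenic alignment rather than only
genome-wide-significant loci. Because the denominator is positive,
\(P(R \ge r) = P(w^T A(r) w \ge 0)\) for the stacked vector
\(w = (z^A, z^B)\), \(A(r) = [[0, I/2], [I/2, -rI]]\) and joint covariance
\(\Omega = [[\Sigma, \rho\Sigma], [\rho\Sigma, \Sigma]]\); the eigenvalues
of \(\Omega^{1/2} A \Omega^{1/2}\) feed the same tail engine at zero. The
block square root \(\Omega^{1/2}\) is assembled from \(\Sigma^{1/2}\) with
\(\pm\sqrt{(1\pm\rho)/2}\) mixing, avoiding a 2m × 2m eigendecomposition
of \(\Omega\) itself.

## The weighted-chi-square tail engine

Both tests reduce to
\(P(\sum_k w^+_k U_k - \sum_k w^-_k V_k \ge x)\). The engine inverts the
characteristic function numerically (Imhof's method) with adaptive
quadrature on \((0, \infty)\). The integrand decays like
\(u^{-(k/2+1)}\) where k is the number of weights, so for k < 6 — e.g. a
single-SNP window, whose statistic is a product of two normals with an
unbounded density — no quadrature reaches the target absolute error of
\(10^{-10}\); those cases, and any quadrature that fails its error check,
fall back to a streaming Monte-Carlo sampler (10^6 draws, p floored at
\(1/(draws+1)\) so downstream \(-\log_{10}\) stays finite). The method
used is recorded on every result. The analytic path is validated against
an *independent* 10^7-draw Monte-Carlo oracle to within three Monte-Carlo
standard errors across random LD configurations.

## Multiple testing and reporting

Gene scans use Bonferroni over the genes actually tested (0.05/18 344 ≈
2.73 × 10⁻⁶ genome-wide; 0.05/5 = 0.01 in five-gene candidate mode).
Significant genes whose 50-kb windows overlap are reported as clusters
(connected components of the window-overlap graph): within a cluster the
window is too large relative to the gene spacing to attribute the signal
to a single member. A sensitivity mode drops genes previously associated
with likely confounders (alcohol use, serum iron) before thresholding.

# Causal stage: two-sample Mendelian randomisation

Instruments are exposure SNPs with p < 5 × 10⁻⁸, greedily clumped by
ascending p against panel r² > 0.001; when fewer than five survive, the
threshold relaxes to 10⁻⁵ (recorded in the output, since the weaker set
may carry weak-instrument bias). Clumping at r² = 0.001 only makes sense
when the panel's null-pair r² noise (≈ 1/n_haplotypes) is below the
threshold; the synthetic panels used for MR therefore carry at least 2 000
haplotypes. Harmonisation aligns outcome alleles to the exposure's effect
allele, flipping betas for swapped records and dropping palindromic (A/T,
C/G) SNPs whose allele frequency is within 0.08 of 0.5 (the 0.42 rule) in
either study; remaining palindromes align by frequency.

Estimators: IVW (weighted regression through the origin, multiplicative
random-effects standard error inflated by \(\max(1, \sqrt{Q/(n-1)})\)),
MR-Egger (free intercept; the intercept estimates directional pleiotropy),
weighted median and weighted mode (normal-kernel smoothed, Silverman-type
bandwidth), plus Cochran's Q, per-instrument F-statistics
\((\beta/se)^2\), leave-one-out IVW, and confounder-SNP exclusion.
Bootstrap-based standard errors record their seed. BH-FDR is applied to
the IVW family only (all trait pairs × both directions in a run); the
other estimators are sensitivity analyses and are reported nominally.

# The synthetic-data generators

**Panels** threshold a blockwise AR(ρ) latent Gaussian at each SNP's
sampled MAF quantile; blocks are independent, giving clean LD structure
with known boundaries that the summary simulator reuses. Monomorphic draws
are patched by flipping one haplotype. **Paired summary statistics** draw
true standardised effects per gene class — null, coherent (identical
vectors), anticoherent (negated), causal (one trait's effects are γ times
the other's), and private to one trait — on top of an optional polygenic
background whose cross-trait correlation `bg_cross_corr` *is* the true
genome-wide genetic correlation when genes are null (this field exists
precisely to give LDSC a closed-form recovery target). The marginal model
is \(z = \sqrt{n}\,\Sigma b + \epsilon\), \(\epsilon \sim N(0, \Sigma)\)
per block, with cross-trait noise covariance \(\rho_{ov}\Sigma\),
\(\rho_{ov} = overlap_n \cdot \rho_e / \sqrt{n_1 n_2}\) — overlap enters
only through the noise, mirroring the LD-score intercept model, never
through shared effects. Betas are reported per standard deviation with
\(se = 1/\sqrt{n}\), which makes recovery targets n-independent.

The `private_1`/`private_2` classes are an extension beyond the minimal
class set: a forward-causal world with a *testably null* reverse direction
requires the outcome to carry its own genetics, otherwise reverse MR is
either uninstrumentable or instrumented by inherited exposure loci whose
Wald ratios are 1/γ.

**Cohorts** default to the study conditions: 3.3% current / 33.9% former /
62.8% never smokers, 52.9% female, age 64.2 ± 7.7 (truncated to the
imaging age range). Covariates are drawn first; smoking status follows a
multinomial logit that can load on an age/deprivation confounder index;
pack-years come from cigarettes/day and years smoked by the standard
formula; former smokers get years since cessation. Brain traits are linear
in the configured effects plus unit Gaussian noise, then shifted into
marker-typical units (T2\* ~ 30 ± 4 ms-scale, QSM ~ 0.03 ± 0.012
arbitrary susceptibility units); missingness (2%) and gross outliers
(0.2%, ±10 SD) are injected last so the imputation and MAD machinery have
real work to do.

What the generators deliberately do **not** emulate: real human LD maps
and allele-frequency spectra, genome-scale SNP counts, assortative mating
or population stratification, non-linear covariate effects, informative
missingness, and biobank field encodings. Passing tests therefore
demonstrate the estimators' operating characteristics under their own
model assumptions at toy scale — parameter recovery, calibration, FDR
control, directionality — not that real-data effect sizes would be
reproduced.

# Operating characteristics the tests measure

With the study-condition defaults, the suite verifies: type-I error of
the coherence and ratio tests within [0.04, 0.06] at α = 0.05 over 5 000
null genes with AR(0.8) LD, with and without ρ_ov = 0.3 overlap;
agreement of the analytic tail with a 10^7-draw Monte-Carlo oracle within
3 MC standard errors; recovery of \(r_g = 0.5\) within ±0.15 (20 seeds),
γ = 0.1 by IVW within ±0.015 mean bias (50 seeds), and a standardised
phenotypic effect of 0.3 within ±0.1 (n = 5 000); forward/reverse
discrimination of a γ = 0.2 causal link in ≥ 80% of seeds; and any-discovery
rates ≤ 0.07 for full-null phenotypic and MR pipelines. Problem sizes
(toy genomes of 600–50 000 SNPs, panels of 400–10 000 haplotypes, cohorts
of 1 000–5 000) were chosen as the smallest at which these operating
characteristics are stable.

# Known limitations

* The gene-test null treats rank-normalised scores as jointly Gaussian
  with the panel's LD; rank normalisation makes this only approximately
  true, and its magnitude ceiling costs power at very strong loci.
* The asymmetry test's independence assumption is conservative (see
  above).
* LDSC on toy genomes needs the matched-window, heterogeneous-LD design
  described here; the package does not attempt 1.2-million-SNP scale.
* The cross-GWAS scorer follows the published *description* of the
  coherence and ratio tests, not any particular implementation's
  internals; exact per-gene p-values may differ from other software even
  on identical inputs.
* MAD filtering and imputation treat the whole sample as one group; no
  per-subgroup variant is provided.
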