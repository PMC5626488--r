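---
title: "Estimating and partitioning the heritability of a case-control trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and partitioning the heritability of a case-control trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwherit)
```

# The model

`gwherit` estimates the proportion of variance in a binary disease trait
attributable to genotyped SNPs, and asks where in the genome that
variance sits. Three pieces of machinery interlock.

**The GRM.** For individuals $j,k$ and $N$ SNPs with A1 dosages $x_{ij}$
and A1 frequencies $p_i$ estimated from the analysis sample,

$$A_{jk} = \frac{1}{N_{jk}} \sum_i
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1 - p_i)},$$

where $N_{jk}$ counts the SNPs non-missing in both samples
(pairwise-complete handling; imputing zeros would bias diagonals).
Because frequencies come from the sample itself, the standardized
dosages are exactly mean-centred, which ties the off-diagonal mean to
$-\overline{A_{jj}}/(n-1)$ — an identity the test suite asserts.

**REML.** Case-control status $y \in \{0,1\}$ enters the mixed model
$y = X\beta + \sum_r g_r + \varepsilon$ with
$\mathrm{var}(y) = \sum_r A_r \sigma_r^2 + I\sigma_\varepsilon^2$, one
random effect per GRM. `fit_reml()` maximizes the restricted
log-likelihood by average-information updates,
$\sigma_{new} = \sigma + \mathrm{AI}^{-1} s$ with score
$s_r = -\tfrac12[\mathrm{tr}(PA_r) - y'PA_rPy]$ and
$\mathrm{AI}_{rs} = \tfrac12 y'PA_rPA_sPy$. The first three iterations
use the slower but monotone EM step
$\sigma_r + \sigma_r^2(y'PA_rPy - \mathrm{tr}(PA_r))/n$ to survive poor
starting values; components are floored at $10^{-8}$ of the phenotypic
variance; convergence is declared when successive log-likelihoods differ
by less than $10^{-8}$ (at most 100 iterations, flagged otherwise).
With a single GRM the model is rotated into the GRM's eigenbasis, where
$V$ is diagonal and each iteration costs $O(np^2)$ — this is what makes
label-permutation tests with hundreds of refits cheap. Standard errors
come from the inverse AI matrix at the optimum; per-component $h^2$
standard errors by the delta method.

**The liability scale.** An ascertained case-control sample (case
fraction $P$) over-represents the upper tail of the latent liability,
so the observed-scale $h^2$ is mapped through the threshold model with
population prevalence $K$:

$$h^2_{liab} = h^2_{obs}\,
  \frac{K^2(1-K)^2}{z^2\,P(1-P)}, \qquad z = \varphi(\Phi^{-1}(1-K)).$$

At $K = P = 1/2$ the factor is exactly $\pi/2$ (the suite checks this to
$10^{-9}$); at $K = 0.02, P = 0.66$ — a melanoma-like regime — it is
$0.7303$. The conversion is applied after REML; the GRM calibration
(below) is applied before. The two corrections commute only
approximately, and this ordering is the package's fixed convention.

# Partitioned architecture

`partition_snps()` labels autosomal SNPs by chromosome, by six MAF bins
$[0.01,0.05], (0.05,0.1], \ldots, (0.4,0.5]$ (a MAF of exactly 0.05
falls in the first bin; bin edges follow the convention that the printed
lower bound is inclusive only for the first bin), by genic/intergenic
status, by cis-eQTL status at a chosen significance threshold, or by
inclusion in $\pm w$ kb windows around a list of index SNPs (listed SNPs
absent from the panel are counted and reported, mirroring how known risk
variants missing from a genotyping array are handled). One GRM per label
is fitted jointly, so each component is conditional on the rest; on
simulated data the per-chromosome components sum to within one joint SE
of the single-GRM estimate, which the acceptance suite verifies at
$n = m = 2000$. If the joint fit fails (e.g. collinear GRMs), the
orchestrator falls back to sequential single-GRM fits with a prominent
flag.

`h2_length_regression()` regresses per-chromosome $h^2$ on physical
length — linear under a polygenic architecture with risk spread evenly
along the genome — and calls chromosomes outside the pointwise 95%
confidence band of the fitted line outliers. Chromosome length defaults
to the genotyped span (max − min position); assembly lengths can be
supplied instead. The band is derived from the slope/intercept
covariance; this is one reading of "confidence interval of the
regression line" and is recorded here as the package's choice.

**Rare-variant model and GRM calibration.** When causal variants are
assumed rare (MAF at or below an explicit ceiling — the ceiling is never
defaulted because 0.1 and 0.01 are both defensible and give different
analyses), the GRM built from the rare subset under-captures relatedness
at causal loci. Following the regression-calibration idea, the
off-diagonals of the subset GRM $G$ are regressed on the full-panel GRM
$A$; the slope satisfies $\beta = 1 - (c + 1/N)\mathrm{var}(A_{jk})$,
giving $c = (1-\beta)/\mathrm{var}(A_{jk}) - 1/N$. `adjust_grm()` then
rescales off-diagonals by $1/(1 - (c + 1/N)\mathrm{var}(A_{jk}))$ and
maps diagonals as $1 + (A_{jj}-1)$ times the same factor, so $c = 0$
with large $N$ approaches the identity. Negative estimated $c$ (pure
sampling noise) is clamped to zero with a warning, and adjusting an
already-adjusted GRM is refused. A caveat the tests make explicit: the
$c$ estimator multiplies the sampling noise of $\hat\beta$ by
$1/\mathrm{var}(A_{jk})$, which is $O(m)$; at panel sizes below
$\sim 10^5$ SNPs the estimate is numerically meaningless, so the suite
validates the machinery by a controlled attenuation round-trip (shrink a
GRM by the factor a known $c$ implies, recover $c$ exactly, invert the
attenuation) rather than by stochastic recovery.

# Association and enrichment

`gwas_logistic()` fits, per SNP, a logistic regression of status on the
additive 0/1/2 dosage plus covariates (age, sex, ancestry PCs, and
optionally the ordinal 1–10 skin-color score; samples missing skin color
are dropped only from the adjusted model). The scan is a Newton
iteration vectorized across SNPs, validated coefficient-for-coefficient
against `stats::glm`; for the intercept-only design the per-SNP 2×2
systems are solved in closed form, which is the hot path of permutation
scans. Wald two-sided p-values are reported; separated or non-converged
SNPs fall back to an efficient-score test and are flagged rather than
given fabricated Wald values; monomorphic SNPs are flagged untested.
The genomic inflation factor is the median association chi-square over
0.4549.

`eqtl_enrichment()` counts flagged (cis-eQTL) SNPs among the top-$k$
association signals — ties broken deterministically by smaller p, larger
absolute estimate, then SNP id — and compares that count with its
distribution over full scans on label-shuffled data. Shuffling labels
while keeping genotypes fixed preserves LD among SNPs; keeping
covariates attached to samples preserves the covariate structure while
breaking genotype–phenotype association. The empirical p-value counts
ties as exceedances by default: the strict "more than observed" rule is
available but is anti-conservative in degenerate cases (if every SNP is
flagged, every permutation ties the observed count and the strict rule
returns 0 where 1 is the only defensible answer). The same tie
convention, with the same rationale, applies to
`h2_permutation_test()`, which shuffles labels and refits REML on a
fixed eigendecomposition.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, and defines the
conditions under which the estimators are validated:

* **Genotypes.** Per-SNP MAFs uniform on [0.01, 0.5] by default (or
  supplied explicitly); dosages are two allele draws from a Gaussian
  copula. Within an LD block of `ld_block_size` SNPs the allele latents
  share a block factor with pairwise correlation `ld_r` (default 0.8),
  then are thresholded at $\Phi^{-1}(p_i)$, so marginal frequencies are
  exact and adjacent SNPs are positively correlated. This
  block-exchangeable structure is deliberately simple: it exercises the
  GRM, its calibration and LD-preserving permutations, but does not
  reproduce human recombination maps, allele-frequency/LD coupling or
  demography — passing tests say nothing about those features.
* **Phenotype.** Liability = per-partition genetic scores + normal
  residual. Effects are drawn i.i.d. normal on standardized genotypes
  and rescaled so each partition's realized genetic variance equals its
  target exactly, removing Monte-Carlo drift from recovery tests. Cases
  are liabilities above $\Phi^{-1}(1-K)$. Default $K$ is 2% and the
  default target case fraction 66%, the melanoma study regime; the
  default single-partition $h^2$ is 0.18, the liability-scale estimate
  reported for melanoma, with a causal fraction of 5% (a polygenic but
  not infinitesimal architecture — the paper-scale value is unknown, and
  this choice is fixed here once).
* **Ascertainment.** A super-population is simulated and subsampled to
  exactly `round(n * target_case_fraction)` cases. Its size defaults to
  1.25× the binding requirement, `need_cases / K` or
  `need_controls / (1-K)`: a fixed multiple (one could default to 20×)
  cannot supply 66% cases at 2% prevalence, which needs ≈ 66× — the
  adaptive default makes runtimes predictable across regimes. At the
  default regime a 2,000-sample cohort implies a ≈ 85,000-sample
  super-population; desk-scale tests therefore use higher $K$ or smaller
  cohorts.
* **Skin color.** `round(5.5 + Σ effect · (dosage − 1) + noise)` clipped
  to 1–10 — any monotone construction suffices for an ordinal covariate.
  The generative link between skin color and disease liability is *not*
  fixed by the generator: it is a free parameter of the study design
  (designate pigmentation loci, or construct confounded phenotypes
  directly), because the analysis being emulated treats that link as the
  open scientific question.
* **Annotations.** Genic labels at a 49% rate and nested cis-eQTL flag
  sets at 23% / 10% / 6% for thresholds 0.01 / 0.001 / 0.0001, the
  fractions reported for skin eQTL annotation of a GWAS panel; a
  synthetic per-SNP eQTL p-value consistent with the flags supports
  threshold-based round-trips.

Every operation draws from a named substream of a single root seed
(`derive_seed`), so stages are independently reproducible and identical
seeds give bit-identical cohorts.

# Numerical choices and degenerate inputs

* HWE: exact enumeration test when any expected genotype class is below
  5, 1-df chi-square otherwise; both exposed. The two agree to ~0.01 in
  the median at GWAS-scale counts but can differ by a few hundredths on
  extreme tables even at $n = 5000$ — the probability-ordered exact tail
  and the chi-square tail classify boundary tables differently — so
  exact is the default where it matters (rare genotype classes).
* Differential missingness: Fisher's exact test when any expected cell
  of the 2×2 missing-by-status table is ≤ 5, chi-square otherwise;
  zero-margin tables return p = 1.
* Filter order is fixed and logged (autosomes → missingness → MAF → HWE
  → differential missingness); thresholds use the strict inequalities as
  printed (MAF < 0.01 removes; 0.01 survives); rerunning QC on filtered
  output is a no-op. Relatedness pruning is greedy with deterministic
  tie-breaking (drop the later-ordered member of the worst pair).
* Eigenvector signs are fixed by making each component's
  largest-magnitude loading positive; PCA on an identity-like GRM raises
  a degeneracy flag instead of returning arbitrary axes.
* Constant phenotypes, rank-deficient designs, identity-like GRMs and
  duplicated GRMs raise identifiability errors rather than returning
  unstable estimates; permutation refits that fail are dropped and the
  effective number of permutations reported.
* LRT p-values for a variance component use the 50:50 boundary mixture,
  $p = \tfrac12 P(\chi^2_1 > \Lambda)$.

# Problem sizes and what the tests show

The acceptance suite runs the estimators at $n = m = 2000$
(quantitative, truth $h^2 = 0.5$) and $n = 1500$ ascertained
case-control cohorts (truth 0.4, $K = 0.1$, 50% cases), 20 replicates
each; permutation calibration uses 100 replicates at $B = 99$; the
REML optimizer is checked against an exhaustive 0.001-step grid search
of the restricted likelihood at $n = 30$. These sizes were chosen as the
smallest at which the asymptotic standard errors are trustworthy and
coverage statements (≥ 18/20 within 2 SE) are meaningful. What passing
shows: unbiasedness and calibration under the generator's assumptions —
unlinked or block-exchangeable LD, Gaussian effects, exact
standardization. What it does not show: behaviour under real LD
heterogeneity, assortative structure, cryptic relatedness or
genotyping-batch artifacts, which is precisely why the QC regime and the
PC covariates exist in the real pipeline.

# Known limitations

* The GRM calibration constant $c$ is not estimable at small panel sizes
  (see above); the implementation reports $\beta$, raw and clamped $c$
  so users can judge.
* The exact transform GCTA applies internally for GRM adjustment is not
  published; the rescaling here follows the printed $\beta$ relation and
  has not been verified equivalent to GCTA binaries.
* Observed-scale analysis of 0/1 traits with a linear mixed model is the
  standard GREML route but is an approximation; the liability conversion
  assumes the threshold model holds and $K$ is known, and errors in $K$
  propagate multiplicatively.
* The logistic scan drops samples listwise per SNP for missing calls;
  no dosage-probability or imputation-info handling is included.
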