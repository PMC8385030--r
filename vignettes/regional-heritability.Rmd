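---
title: "Regional heritability mapping: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhmap)
```

This vignette is the package's account of the statistics it implements:
the mixed models and their assumptions, the numerical choices inside the
REML machinery, the rationale for the simulator's design, and the limits
of what the test suite can certify.

## The two mixed models

A binary disease phenotype is analysed on the observed 0/1 scale with a
linear mixed model, as GREML does for case-control data. The null model
captures a genome-wide polygenic effect through the genomic relationship
matrix (GRM) $G$:

$$ y = X\beta + u + e, \qquad
   \mathrm{Var}(u) = G\sigma^2_u, \quad \mathrm{Var}(e) = I\sigma^2_e . $$

$X$ contains the intercept, sex, a genotyping-array indicator and the first
ten eigenvectors of $G$ (population-structure adjustment). The scan's
alternative model adds, for each window of adjacent SNPs, a regional random
effect with its own GRM $Q$ built from exactly the window's SNPs:

$$ y = X\beta + u + w + e, \qquad \mathrm{Var}(w) = Q\sigma^2_w . $$

Both GRMs use the same estimator,
$g_{jk} = \frac{1}{N}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$,
with $p_i$ the in-sample reference-allele frequency. Two consequences of
this choice matter downstream. First, regional GRMs over a partition of the
SNPs, weighted by their SNP counts, reconstruct the whole-genome GRM
exactly — the whole-genome model is literally the average of its regions.
Second, because allele frequencies are estimated in-sample, the columns of
the standardized genotype matrix are mean-centred, so $G$ annihilates the
ones vector: every GRM built this way is singular in the direction of the
intercept. The REML implementation is built around this fact (below).

Missing genotypes contribute zero to the GRM sum while the divisor stays
$N$; this is simple and unbiased toward zero relatedness. The per-pair
divisor used by some tools is not replicated; simulated data are complete,
and with the ≥98% call rates enforced by QC the difference is negligible.

## Testing a variance on its boundary

Each window is tested with $\mathrm{LRT} = -2\ln(L_0/L_1)$, comparing the
null fit (done once per dataset, not per window) with the window's fit.
Since $\sigma^2_w \ge 0$ and the null value sits on that boundary, the LRT
is asymptotically a 50–50 mixture of $\chi^2_0$ (a point mass at zero) and
$\chi^2_1$; the p-value is $0.5\,P(\chi^2_1 > \mathrm{LRT})$, with
$p = 0.5$ at $\mathrm{LRT} = 0$. The package's null-calibration tests
verify both halves empirically: across hundreds of null windows roughly
half the LRTs are exactly at the boundary, and the positive part passes a
Kolmogorov–Smirnov comparison against $\chi^2_1$.

Because consecutive windows overlap by 50%, the Bonferroni correction uses
half the number of tested windows as the effective test count:
$p_\mathrm{thr} = \alpha/(M/2)$, and the LRT threshold solves
$0.5\,S_{\chi^2_1}(x) = p_\mathrm{thr}$. $M$ counts only non-excluded
windows: windows whose fit fails to converge or produces extreme estimates
(any component beyond 10$\times$ the phenotypic variance — this multiplier
is this package's own operationalisation of "extreme") are flagged out of
the scan and out of $M$.

## AI-REML: the numerical core

`fit_reml()` maximises the restricted likelihood by the
average-information algorithm: one EM-REML step from the starting values
(robust far from the optimum), then AI updates (fast near it), with three
safeguards:

* **Step halving.** A proposed step that would decrease the likelihood is
  halved, up to 30 times. Thirty is deliberate: when two variance
  components are nearly unidentifiable (e.g. a GRM built from very many
  SNPs relative to the sample, so $G \approx I$), the AI matrix is
  near-singular and its solution can be enormous; 30 halvings shrink any
  such step below machine relevance, so the iteration degenerates
  gracefully into an accepted micro-step and a clean convergence signal
  instead of a spurious failure.
* **Boundary constraint with an active set.** Components falling below the
  floor ($10^{-6}\times$ the phenotypic variance) are held there and
  flagged; a floored component whose score points further downhill is
  dropped from the AI system, mirroring constrained GREML. Keeping
  components at a floor rather than removing them is what justifies the
  50–50 mixture null.
* **Error-contrast evaluation.** The likelihood is computed in the
  projected space: with $A$ an orthonormal basis of the complement of
  $\mathrm{col}(X)$,
  $\ell = -\tfrac12[\log|A'VA| + \log|X'X| + y^{*\prime}(A'VA)^{-1}y^*]$,
  algebraically identical to the textbook
  $-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ form. The projected form is
  not a stylistic preference: at the residual boundary
  ($\sigma^2_e \to$ floor) the unprojected $V$ is nearly singular in the
  ones direction that every in-sample GRM annihilates. That direction lies
  inside $\mathrm{col}(X)$ and cancels analytically, but in floating point
  the cancellation fails and the likelihood surface turns into noise of
  order $10^{-1}$ — enough to strand the optimizer. Projection removes the
  offending direction before any factorization. A test pins the projected
  value against the naive determinant formula at interior points.

Convergence is declared when the log-likelihood moves by less than
$10^{-4}$; each iteration costs one Cholesky factorization of the
$(n-p)\times(n-p)$ projected covariance, with scores, the AI matrix and
the delta-method covariance of heritability ratios all assembled from that
single factorization. Standard errors come from the inverse AI matrix at
the optimum. Window fits start from the null fit's estimates with the
regional component at $10\times$ the floor; a start-invariance test checks
that the optimum does not depend on this warm start. Whether the original
GCTA-based analyses warm-started window fits is not documented anywhere we
know of; warm starts stabilise scans of many windows and the invariance
test shows the choice is immaterial to the optimum.

## Liability-scale conversion

Observed-scale heritabilities (ratios $\sigma^2_w/\sigma^2_P$ or
$\sigma^2_u/\sigma^2_P$ of the 0/1 analysis) are converted with the
ascertainment-corrected case-control transformation

$$ h^2_\mathrm{liab} = h^2_\mathrm{obs}\,
   \frac{K^2(1-K)^2}{z^2\,P(1-P)} , $$

with $K$ the population prevalence, $P$ the sample case proportion and $z$
the standard normal density at the threshold $t = \Phi^{-1}(1-K)$. Where a
study names only "prevalence estimates", this is the standard choice for
ascertained case-control GREML; the uncorrected ($P = K$) version is its
special case. Standard errors scale by the same factor (the transformation
is linear in $h^2_\mathrm{obs}$). Scan records carry both scales because
reported regional heritabilities in the literature are typically
liability-scale while the model itself operates on the observed scale.

## What the simulator emulates — and what it does not

The generator exists so that every stage of the pipeline can be exercised
with known truth. Its design choices:

* **LD by founder haplotypes.** Within each block of `ld_block_size` SNPs,
  every individual draws two haplotypes (with replacement) from a pool of
  `n_founder_haplotypes` founders whose alleles are Bernoulli draws at
  per-SNP MAFs uniform on `maf_range`; blocks recombine freely. Small
  pools give strong multi-SNP tagging — the structure that makes a
  multi-QTL window detectable as a region while individual SNPs stay
  sub-significant. This is the simplest construct with a tunable LD dial;
  it is not a coalescent and makes no attempt at realistic LD decay,
  recombination hotspots or allele-frequency spectra.
* **Liability threshold with exact variance bookkeeping.** Liability is a
  sum of standardized-genotype effects (equal variance share per causal
  SNP within a component, random signs), covariate shifts and a normal
  residual sized so the target components sum to one; cases exceed
  $\Phi^{-1}(1-K)$. The recorded truth is therefore analytic, not
  estimated.
* **Ascertainment by rejection.** Batches of individuals are drawn until
  the requested cases and controls accrue, so the emitted cohort has
  exactly the requested case fraction while the population prevalence is
  $K$ — the oversampling design of real case-control studies. A cap on
  batches turns impossible prevalences into a clean error rather than an
  endless loop; prevalences below roughly $10^{-3}$ are impractical by
  rejection, which is why test cohorts use $K \approx 0.1$ rather than a
  rare-disease value, relying on the transformation (linear in the
  correction factor) to bridge the scales. Genotype effects are
  standardized batch-wise; batch sizes equal the cohort size, so the
  batch-to-batch wobble in realized effect scaling is $O(1/\sqrt{n})$.
* **Covariates without confounding.** Sex and array are Bernoulli(0.5),
  independent of genotype, with zero liability effect by default: the
  models adjust for them, and the simulator deliberately does not build
  confounding into them. Unrelated individuals only: how ascertainment
  interacts with relatedness in real cohorts is not modelled.

Passing tests on these cohorts certify the estimator's internal
consistency (parameter recovery, calibration, power ranking) under ideal
polygenic-liability assumptions. They say nothing about array artefacts,
imputation error, population stratification beyond what ten PCs absorb, or
real LD — all out of scope.

## Quality control conventions

Filters run in a fixed, logged order: sample call rate, SNP call rate,
MAF, Hardy–Weinberg exact test, LD pruning, relatedness; each step's
removals reconcile exactly with the dimension changes, and every filter is
idempotent. Conventions where common practice varies:

* The HWE exact test (two-sided by probability mass, full enumeration over
  heterozygote counts in log space) is computed on all samples — the
  controls-only variant is not assumed, and the report header says so.
* LD pruning removes, from each offending pair, the lower-MAF member (tie:
  the later position), sliding a 50-SNP window by 5; only the pruning
  *flags* are conventional, the removal rule is stated here because tools
  differ.
* Relatedness filtering thresholds GRM off-diagonals (default 0.1) rather
  than method-of-moments IBD pi-hat: for the unrelated/related dichotomy
  at these thresholds the two coincide in expectation, and it avoids
  re-implementing IBS-based IBD machinery. The pair member with the higher
  mean relatedness is removed first, iteratively — minimal removal on
  cliques.
* Missing calls are excluded pairwise in MAF, HWE and $r^2$ computations.

## Window bookkeeping

Windows start every `shift` SNPs per chromosome and never span
chromosomes; the final window of a chromosome is clipped rather than
dropped (tail coverage) and flagged. When a chromosome is shorter than the
shift, one window covers it. A clipped window can be a strict subset of
its predecessor; it is still emitted, matching the start-index rule, and
the overlap-aware $M/2$ correction absorbs the redundancy.

## Scale of the validation experiments

The test-suite experiment sizes were chosen to make each check
statistically meaningful at desk scale: null-scan calibration uses a
500-individual, 4000-SNP cohort (160 windows); the mixture-null
distribution pools 510 non-overlapping windows across three independent
150-individual cohorts; parameter recovery uses 2000 individuals, 4000
SNPs and a true liability heritability of 0.3 under $K = 0.1$
ascertainment; the power contrast runs twenty replicates of a
1000-individual cohort with a 5-QTL region at liability variance 0.05.
The grid-and-refine oracle that certifies REML optima runs at $n \le 30$,
where exhaustive search over variance ratios is cheap.

## Known limitations

* Observed-scale linear mixed models for binary traits are an
  approximation; no logistic/probit mixed model is provided.
* Dense $O(n^3)$ algebra throughout: cohorts beyond a few thousand
  individuals need the production tools this package deliberately mirrors
  rather than replaces.
* The rejection-sampling ascertainment cannot reach rare-disease
  prevalences; studies of that regime must rely on the liability
  transformation rather than direct simulation.
* X-chromosome handling, dosages, imputation and allele harmonisation
  across arrays are out of scope.
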