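---
title: "Polygenic, genomic and combined models for genomic selection with mixture priors"
author: "gsmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic, genomic and combined models for genomic selection with mixture priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmix)
```

## The models

`gsmix` compares three ways of estimating breeding values from a population
of full-sib families with SNP genotypes:

* **Polygenic animal model** (`modelSpec("polygenic")`):
  \(y = \mu + X_1 b + X_2 c + Z u + e\), with cage effects
  \(c \sim N(0, I\sigma^2_c)\), polygenic values
  \(u \sim N(0, A\sigma^2_u)\) where \(A\) is the pedigree additive
  relationship matrix, and residuals \(e \sim N(0, I\sigma^2_e)\). This is
  the classical mixed model used for pedigree-based evaluation.
* **Genomic multi-marker model** (`"genomic"`):
  \(y = \mu + X_1 b + X_2 c + Q a s + e\), where \(Q\) is the design matrix
  linking animals to marker alleles, \(a \sim N(0, I)\) are standard-normal
  base effects and \(s\) is a per-marker *scaling factor* carrying all of
  the marker-scale adaptation. In the non-mixture model the scaling factors
  have a positive truncated-normal prior \(s \sim TN_{\ge 0}(0,
  \sigma^2_{g})\), \(\sigma^2_g\) being interpretable as the expected
  average fitted variance per marker. In the mixture models a known
  fraction \(\pi_1\) of markers is allowed a *substantial* effect,
  \(s \sim TN_{\ge 0}(0, \sigma^2_{g1})\), while the remaining fraction
  \(\pi_0 = 1 - \pi_1\) falls in a near-zero component
  \(s \sim N(0, \sigma^2_{g0})\) whose variance is **fixed** at 1% of the
  phenotypic variance divided by the number of markers. \(\pi_1\) is
  treated as known per run (typical settings are 100, 70, 40, 10, 7.5, 5
  and 2.5%); estimating it from data is out of scope.
* **Combined model** (`"combined"`): both genetic terms,
  \(y = \mu + X_1 b + X_2 c + Q a s + Z u + e\), where \(u\) picks up
  genetic variance the markers cannot explain.

Only the product \(\beta_j = s_j a_j\) is identifiable (the sign and scale
split between \(s\) and \(a\) is not), so all reported quantities —
genomic values \(g = Q\beta\), the genomic variance, inclusion
probabilities — are functions of \(\beta\), \(g\) and the indicators.

## The Gibbs sampler

`fitBayes()` runs a single-chain Gibbs sampler (compiled core, all
randomness through R's RNG so chains are bit-reproducible from the seed):

1. \(\mu\) and the fixed-effect/covariate coefficients from normal full
   conditionals under flat priors (factors are treatment-coded against
   their first observed level; covariates are centred on the observed
   mean, the offset being absorbed in \(\mu\));
2. cage effects from normal full conditionals;
3. polygenic values single-site, using the sparse inverse of \(A\) built
   by Henderson's rules with inbreeding;
4. per marker, a joint \((\delta_j, s_j)\) block: the mixture indicator is
   drawn with \(s_j\) integrated analytically within each component — the
   substantial component's marginal likelihood includes the
   truncated-normal normalising factor \(2\Phi(m_1/\sqrt{v_1})\) — after
   which \(s_j\) is drawn from its component full conditional (normal for
   the near-zero component, positive truncated normal via the inverse CDF
   with an exponential-rejection fallback deep in the tail) and the base
   effects \(a\) from normal full conditionals with prior variance 1
   exactly. A pure conditional-on-\(s\) indicator update mixes poorly;
   the analytic integration is what makes small-\(\pi_1\) runs usable.
5. \(\sigma^2_c\), \(\sigma^2_u\), \(\sigma^2_e\) from scaled-inverse-
   chi-square full conditionals that are flat on the variance
   (\(\nu = -2\), i.e. \(SS/\chi^2_{q-2}\)), bounded below by \(10^{-10}\).
   These components always have ample degrees of freedom.
6. \(\sigma^2_{g1}\) from a scaled-inverse-chi-square full conditional
   under a **weakly informative** prior (\(\nu_0 = 4\), scale equal to its
   starting value \(0.5\,\widehat{\sigma^2_p}/(\pi_1 m)\), i.e. half the
   phenotypic variance spread over the expected number of substantial
   markers). A flat prior is an absorbing state here: once fewer than a
   handful of markers occupy the substantial component the flat draw has
   \(\le 1\) degree of freedom, \(\sigma^2_{g1}\) diverges, and the
   marginal-likelihood penalty then keeps the component empty for the rest
   of the chain. The upstream software's exact prior for this variance is
   not documented, so this choice is the package's own; with the
   substantial component well occupied its influence is negligible.

Animals with `NA` phenotypes contribute no residual term but keep their
polygenic link through \(A\) and their genomic value from \(Q\) — this is
how validation animals are predicted in cross-validation.

Defaults are 50,000 iterations, 10,000 burn-in, thinning 10. The tests and
the acceptance script use shorter chains at desk scale (stated below).

### Diagnostic controls

`chainControl()` exposes three switches used by the test suite and useful
for validating any change to the sampler: `fixVariances` (compare against
the direct mixed-model-equations solve), `sFixed`/`deltaFixed` (the model
collapses to ridge regression with penalty \(\sigma^2_e/s_0^2\)), and
`priorOnly` (the chain must reproduce \(E[\delta] = \pi_1\) and the
half-normal mean \(E[s \mid \delta = 1] = \sigma_{g1}\sqrt{2/\pi}\)).

## Reported quantities

`summarizeDraws()` computes, per stored sample, the genomic variance
\(\sigma^2_a\) as the empirical variance across animals of \(g = Q\beta\) —
identically the quadratic form \(\beta^\top C \beta\) with \(C\) the
empirical covariance of the encoding columns, so all LD covariances and
allele frequencies enter automatically. The phenotypic variance is the
per-sample sum \(\sigma^2_a + \sigma^2_u + \sigma^2_c + \sigma^2_e\)
(absent components contribute 0), so the heritabilities
\(h^2_u = \sigma^2_u/\sigma^2_p\) and \(h^2_a = \sigma^2_a/\sigma^2_p\) are
bounded in \([0,1]\) by construction and
\(h^2_u + h^2_a + (\sigma^2_c + \sigma^2_e)/\sigma^2_p = 1\) holds exactly
per sample. Intervals are central 95% posterior quantiles (not HPD): the
choice is deterministic given the draws; the source tables do not define
their interval type.

`markerInclusionProb()` is the per-marker mean of \(\delta\) over the \(S\)
stored samples, clamped to \([1/(2S), 1 - 1/(2S)]\) so that the
prior-to-posterior odds ratio
\[\mathrm{PPOR}_j = \frac{\hat p_1/(1-\hat p_1)}{\pi_1/(1-\pi_1)}\]
is always finite (the unclamped estimate and the clamp width are reported
alongside). Evidence classes use strict thresholds: substantial for
\(3.2 < \mathrm{PPOR} \le 10\), strong for \(10 < \mathrm{PPOR} \le 100\),
decisive above 100; boundary values fall in the lower class.

## Cross-validation design

`makeSplits()` builds ten train/validation pairs: the animals from
families with at least two phenotyped members (the *eligible* set) are
split into five disjoint validation groups, twice independently, giving a
1:5 validation-to-training ratio. *Within-family* mode deals each family's
shuffled members round-robin over the groups so every family keeps at
least one training member; *between-family* mode assigns whole families,
largest first onto the currently smallest group (ties broken by the seeded
shuffle), so no family ever spans both sets. Predictive ability is the
Pearson correlation between the predicted breeding value (\(u\), \(g\) or
\(u+g\) by model class) and the validation phenotype corrected for the
*training* fit's general mean, fixed effects and covariates — training-only
correction avoids leaking validation information; cage and genetic terms
are deliberately not removed. Each split refits the model with validation
phenotypes masked as missing; one chain per split, seeds `seed + split`.

## The synthetic-data generator

`simConfig()`/`simulatePopulation()` emulate the statistical structure the
analysis assumes, not any particular real dataset:

* eight founder strains (each strain fixed for one allele per marker),
  crossed and taken through 50 generations of pseudo-random mating among
  200 breeders — this burn-in generates the linkage disequilibrium;
* a recorded three-generation pedigree: 175 full-sib families, each with
  two parents descending from four distinct recorded grandparents; the
  recorded founders are produced by one extra round of random mating from
  the burn-in population, so they carry its LD without being clones;
* family sizes Poisson(11) truncated at 2 (about 12 offspring per family);
  cages per family \(1 + \mathrm{Poisson}(2.1)\) (mean 3.1), cages never
  spanning families;
* recombination by the Haldane map function at 0.5 cM/Mb on 5 chromosomes
  of 100 Mb carrying 1,000 markers by default (a desk-scale panel; the
  marker count, map and LD scale are configurable);
* the trait: general mean 50, sex effect 5, one continuous covariate with
  slope 2, cage effects drawn per cage, QTL effects at sampled markers
  (reflected-gamma, shape 0.4, mimicking few-large/many-small
  architectures; a normal option exists) rescaled so the realized genomic
  variance among offspring matches the target \(h^2_{QTL}\sigma^2_p\), a
  polygenic deviation simulated by pedigree gene flow (founders
  \(N(0,\sigma^2_u)\), offspring half the parent average plus Mendelian
  sampling \(N(0,\sigma^2_u/2)\)) independent of the marker panel by
  construction, and a normal residual; \(\sigma^2_p = 100\) by default.

Because the polygenic deviation never touches the markers, "genomic" and
"polygenic" variance are separable by construction, which is what makes
the combined model's partitioning testable. What the generator does *not*
emulate: genotyping error, sex chromosomes, real mouse haplotype
structure, selection during the burn-in, non-Gaussian traits, and family
sizes/cage sizes beyond their means. Passing tests therefore demonstrate
correctness of the machinery and reproduction of the method's qualitative
behaviour on data satisfying the model's assumptions — not performance on
any real dataset.

## Numerical choices and degenerate inputs

* Dosage encoding centres each marker column on twice the panel allele
  frequency; for a panel restricted to the analysed animals the columns
  are exactly mean-zero, decoupling markers from \(\mu\). Per-allele and
  third-allele (missing-as-allele) codings are uncentred, their offsets
  absorbed by \(\mu\); for biallelic markers dosage and per-allele codings
  span the same column space up to the intercept.
* Monomorphic marker columns have zero sums of squares; their full
  conditionals degenerate gracefully to the prior.
* Hardy-Weinberg imputation draws each unobserved allele slot as a
  Bernoulli trial at the observed alternate-allele frequency (the
  genotype-level draw is then exactly the \(p^2/2pq/q^2\) trinomial); at
  \(p = 0.5\) the draw is symmetric, so no tie-break is needed. Markers
  with no observed calls must be dropped first (`dropUninformative()`).
* Pedigrees are topologically reordered on construction; cycles are
  reported with an explicit path. The A-inverse uses Mendelian-sampling
  variances adjusted for parental inbreeding.
* One global seed drives everything; pipeline stages derive their own
  seeds as \((\mathrm{seed}\cdot 10007 + k) \bmod (2^{31}-1)\).

## Problem sizes used by the tests and the acceptance script

The checks run at sizes chosen to be statistically decisive at a desk
scale: oracle comparisons on 200-400 animals with 10,000-20,000
iterations; prior reproduction on 150 markers with 3,000 stored samples;
heritability recovery on five full-scale populations (175 families,
roughly 1,900 phenotyped offspring each, 15,000 iterations); the
cross-validation direction checks on five populations of 60 families
(about 720 offspring, 240 markers, 20 QTL, chains of 1,200); the mixture
sweep on 75 families at \(\pi_1 \in \{1, 0.4, 0.1, 0.025\}\). The same
populations can be regenerated at any size through `simConfig()`.

## Known limitations

* \(\pi_1\) is never estimated; model averaging over mixture settings is
  out of scope.
* Single-trait, Gaussian likelihood only; no multi-allelic markers beyond
  the synthetic missing-as-third-allele coding; no VCF input, phasing or
  genotype likelihoods.
* The genomic variance of a mixture fit depends on the encoding supplied
  to `summarizeDraws()`; supplying an encoding whose columns differ from
  the fit's is an error, but a *reordered* encoding is not detectable.
* Adjacent markers are not merged into QTL regions: a QTL's effect may be
  spread over several linked markers, and counts of flagged markers are
  counts of markers, not of QTLs.
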