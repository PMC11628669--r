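---
title: "Methods: karyotype-aware RDA for genotype-environment association"
author: "karyoRDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype-aware RDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`karyoRDA` scans a SNP panel — plus, optionally, the diploid chromosome
number treated as one more response column — for covariance with
environmental gradients.  The engine is redundancy analysis (RDA), i.e.
constrained ordination: with `Y` the column-centered samples × loci matrix
of minor-allele counts and `X` the column-standardized predictor matrix,
the least-squares fit `Yhat = X (X'X)^-1 X' Y` is decomposed by SVD,
`Yhat = U D V'`.  Constrained eigenvalues are `d_k^2 / (n-1)`; inertia is
the summed column variance of `Y` (divisor `n-1` throughout) and splits
exactly into constrained + unconstrained parts.  Any consistent divisor
cancels in per-axis proportions of variance (PVE) and in the pseudo-F
statistic, but users comparing raw eigenvalues with other ordination
software should expect scale differences when a different divisor is used
there.

Assumptions inherited from RDA as a GEA method: the genotype–environment
relationship is linear on the allele-count scale; loci contribute
additively; samples are exchangeable under the permutation null (see
*Limitations*).  `Y` is centered but not standardized — 0/1/2 counts share
a scale, so per-locus standardization would inflate the influence of
low-MAF loci.  The karyotype pseudo-locus is the exception: a raw 2n column
on a 69–84 scale would carry variance far above any SNP column, so
`appendKaryotype()` centers and scales it to unit variance by default
(`scaling = "raw"` is retained for sensitivity analysis).  Unit variance is
still 2–3× a typical SNP column's variance; the null-calibration tests
confirm this does not inflate the pseudo-locus's tail-flagging rate beyond
the nominal `2 * tail` per axis.

## Pipeline stages and their parameters

| stage | parameter | default | units / rationale |
|---|---|---|---|
| coverage filter | `minCalled` | 100 | samples with a non-missing call; protocol value |
| MAF filter | `mafMin` | 0.10 | allele-count fraction over non-missing calls |
| imputation | — | per-locus mode | keeps \{0,1,2\} support; count of imputed cells logged |
| predictor reduction | `cut` | 0.3 | distance `1 - |r|`; merges clusters with `|r| > 0.7` |
| collinearity check | `vifThreshold` | 10 | `VIF_j = 1/(1 - R^2_j)` |
| permutation tests | `nPerm` | 1000 | add-one p-value, floor `1/(nPerm+1)` |
| axis gate | `alpha` | 0.01 | forward stopping over nested axis tests |
| outlier scan | `tail` | 0.025 | per side, per significant axis |
| gene windows | `window` | 50000 | bp, strict upper bound on edge distance |

Filtering details.  The MAF and coverage filters act on SNP rows only; the
karyotype pseudo-locus is exempt but is treated identically to a SNP by
every downstream stage (it can be flagged, assigned a predictor, and
reported).  Filters commute because MAF is always computed on non-missing
calls.  Missing-call handling is a genuine design choice the upstream
protocol leaves open; we impute by the per-locus most common genotype
(mode), which is standard practice for RDA-based GEA since the ordination
requires a complete matrix, and we log the imputed-cell count so users can
judge the imputation load.  Mode imputation shrinks minor-allele variance
slightly at high missingness; at the ~5% missingness the generator
emulates, its effect on loadings is negligible.

Predictor reduction.  Correlations are Pearson, computed on per-sample rows
(population-level climate broadcast to samples) so that the reduction sees
exactly the design matrix the RDA will see.  The dendrogram comes from
complete-linkage clustering (`stats::hclust`) of `1 - |r|`; cluster
membership is read from merges at height strictly below the cut, honouring
the strict "distance lower than 0.3" protocol reading (library cut
functions merge at `height <= h`).  Within a cluster the representative is
chosen by (i) class preference quarterly > monthly > other, (ii) lowest
mean `|r|` with predictors outside the cluster, (iii) input column order.
Rules (ii)–(iii) are this package's own total order — reproducibility
requires one; rule (ii) prefers the member least entangled with other
clusters.  Complete linkage bounds within-cluster distances but chaining
can still leave two *retained* predictors with `|r| > 0.7` in pathological
geometries; the VIF gate is the backstop.

Permutation tests.  The statistic everywhere is pseudo-F,
`(constrained/p) / (unconstrained/(n-p-1))`.  The global test permutes
whole rows of `X`.  Term tests are marginal (each predictor given all
others) with residual permutation: `Y` and the focal column are
residualized on the remaining predictors and rows of the residualized
column are permuted.  Marginal rather than sequential testing keeps the
result invariant to predictor order.  Axis tests are sequential: axis `k`
conditions on the site scores of axes `1..k-1`, and testing stops at the
first non-significant axis because the hypotheses are nested.  A predictor
exactly duplicated by the others has zero residual; its F is identically 0
and its p-value 1 by the tie rule.  All p-values use the add-one formula
`(1 + #{F* >= F}) / (nPerm + 1)`, so no p-value can be 0.  A
`strata = "population"` option restricts permutations to within-population
exchanges for users who doubt sample-level exchangeability (see
*Limitations*).

Outlier scan.  Empirical per-axis quantiles (order statistics with linear
interpolation, R type 7) at `tail` and `1 - tail`; flagging is by strict
exceedance, so boundary ties are conservatively not flagged.  Loci flagged
on several axes are deduplicated to the axis of largest absolute loading,
with the per-axis rows preserved in an attribute.  The loadings used are
the raw right singular vectors (scaling-"none" species scores); per-axis
rescalings (correlation-style scores) are monotone per axis and would
select the same loci.

Annotation.  Gene windows use the edge distance in bp — 0 inside the gene
span, otherwise distance to the nearest span end measured from the SNP
position — with the `< 50 kbp` bound strict: 49,999 bp is reported, 50,000
is not.  Upstream/downstream is resolved from gene strand (upstream = 5'
side).

## Numerical choices

- Axis signs are fixed by making the largest-magnitude locus loading on
  each axis positive, so reports are reproducible across platforms; sign
  flips swap tail labels but never change the flagged set.
- Predictor bases are obtained by pivoted QR; rank-deficient design
  matrices are an error in `fitRDA` (naming the dependent columns) but are
  tolerated inside the permutation machinery, where residualization
  reduces rank by construction and the basis is trimmed to the pivoted
  rank.
- Inertia conservation (`constrained + unconstrained = total`) is enforced
  by the model validity check at `1e-8` relative tolerance; residual
  eigenvalues below `1e-12` of the leading one are dropped as numerical
  zeros.
- `fitRDA` accepts `n >= p + 1` so the saturated limit (`p = n-1`
  independent predictors, constrained inertia = total) is computable;
  pseudo-F additionally requires positive residual degrees of freedom.
- Degenerate inputs have defined behaviour: an all-equal loading vector
  flags nothing; a constant karyotype is rejected; an all-missing locus is
  an error (impossible after the coverage filter at any sensible
  threshold); a locus requested for predictor assignment with zero
  variance is an error; assignment ties break alphabetically with a
  message.

## The synthetic-data generator

`simulateLandscape()` emulates the statistical structure the analysis
assumes, with defaults fixed at the study conditions the package targets:
34 populations on a latitudinal gradient (31–55°), unbalanced sampling
(sizes clipped to 1–17, median ≈ 3, ≈ 150 samples in total), 700 biallelic
SNPs (650 neutral + 50 environment-associated), ≈ 5% missing calls, and a
chromosome-number series on 69–84.  Neutral differentiation follows the
Balding–Nichols model at FST = 0.15 — a realistic value for structured
plant populations at this geographic scale; environment-associated loci
take population allele frequencies `logistic(logit(p) + beta * z)` with
`beta = 1.5` per SD of the linked predictor; the karyotype is
`round(76.5 + 2.5 * z_BIO6 + N(0, 1.5))` clipped to 69–84, giving both a
strong minimum-temperature cline and within-population cytotype variation.
Eight bioclim-style predictors arrive in four collinear pairs
(within-pair `|r| ≈ 0.98`, between-pair `|r| < 0.5`) so the reduction
stage has real structure to collapse; class tags follow bioclim
conventions (BIO16/BIO17 quarterly, BIO6/BIO13/BIO14 monthly).  A truth
table records every locus's class, linked predictor and effect size.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium between loci (every locus
is drawn independently), isolation-by-distance beyond the shared
latitudinal gradient, admixture gradients between discrete clusters,
genotyping error, non-random missingness (real RAD dropout is
coverage- and allele-dependent), and any mechanistic model of chromosome
fission/fusion — the karyotype is a single integer trait, not a linkage
map.

## Limitations

- Sample-level permutation is anticonservative under strong population
  structure when predictors are constant within populations: the effective
  replication is closer to the number of populations than of samples, so
  under a no-effect simulation most axes still test significant, and about
  half of tail-flagged loci are neutral (the acceptance measurements
  report FDR ≈ 0.5 at the default conditions).  The per-axis flagging rate
  of the karyotype pseudo-locus itself stays at the nominal `2 * tail`.
  Users wanting within-population exchangeability should pass
  `strata = "population"`; the default mirrors the unstratified protocol.
- Adding the karyotype column necessarily perturbs the fitted SVD
  (a rank-one update), so the with- and without-karyotype variants agree
  on SNP results only up to loci at the tail-quantile boundary (observed
  Jaccard overlap 0.85–0.97 at the default conditions).  Exact agreement
  is impossible whenever the karyotype is informative enough to be
  flagged.
- The retained predictor set is data-dependent; only three of the four
  simulated cluster representatives are forced by the class-preference
  rule, the fourth resolves by the correlation tie-break.

## Problem sizes used by the test suite

The suite cross-checks the engine against a brute-force oracle (explicit
normal equations + dense eigendecomposition) on 100 random instances with
`n <= 40`, `L <= 60`, `p <= 5` at `1e-6` relative tolerance, and against
`vegan::rda` as an independent implementation.  Calibration of the global
permutation test uses 300 null replicates (`n = 50`, `L = 100`, `p = 4`,
199 permutations) against binomial 95% intervals at alpha 0.01 and 0.05.
Pipeline power and null behaviour are each measured over 50 simulation
seeds at the default study conditions with 199 and 99 permutations
respectively — sizes chosen to keep the whole suite in a couple of minutes
on a laptop while leaving Monte-Carlo error well below the asserted
margins.
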