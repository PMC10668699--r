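---
title: "A Bayesian threshold animal model for angular hoof deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian threshold animal model for angular hoof deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofgen)
```

## The problem

Angular hoof deviations — splay-footed and pigeon-toed stances of the fore
and rear limbs — are ordinal conformation defects scored during a horse's
once-in-a-lifetime morphological evaluation. Breeding decisions need two
kinds of quantities: descriptive epidemiology (how prevalent is each
defect, how does prevalence move with birth year and inbreeding, which
animals fail the breed's severity rule) and genetic parameters
(heritabilities, genetic correlations, breeding values) estimated from an
ordinal trait observed once per animal on a large pedigree.

`hoofgen` implements that full pipeline: pedigree algebra, a multi-trait
Bayesian threshold animal model estimated by Gibbs sampling, post-Gibbs
summaries and diagnostics, the descriptive layer, and a simulator that
generates pedigreed populations with known genetic parameters so every
stage can be validated end to end without access to studbook data.

## Model

For trait $t$ of animal $i$ the liability is

$$ l_{it} = x_i' b_t + u_{it} + e_{it}, \qquad
   u \sim N(0,\, G \otimes A), \qquad e_i \sim N(0,\, R), $$

where $A$ is the numerator relationship matrix from the pedigree, $G$ the
additive-genetic covariance among traits and $R$ the residual covariance
among traits within an animal. A Gaussian trait is observed as $y_{it} =
l_{it}$; an ordinal trait with $K$ categories is observed as the interval
of $l_{it}$ among thresholds $-\infty < t_1 < \dots < t_{K-1} < \infty$.
Fixed effects are sex and birth-stud size (treatment contrasts against the
alphabetically first level; the parameterisation is a package convention),
plus linear covariates for evaluation age and the inbreeding coefficient
$F$. An intercept is always included (covariates are centred, so it sits
at the covariate mean).

### Pedigree algebra

`inbreeding()` implements the Meuwissen–Luo recursion for Wright's $F$;
`relationship_matrix()` the tabular method (dense, capped at 5,000 animals
by default); `a_inverse()` assembles the sparse $A^{-1}$ in one pedigree
pass by Henderson's rules with the Quaas correction, using the
Mendelian-sampling variance $d_i = \tfrac12 - \tfrac14(F_s + F_d)$
($\tfrac34 - \tfrac14 F$ with one known parent, $1$ for founders). Unknown
parents are treated as unrelated non-inbred founders. The sampler only
ever consumes the sparse inverse, so dense $A$ is never formed for large
pedigrees. The suite cross-checks the three routes against each other and
against a gene-dropping Monte Carlo kinship oracle.

### Gibbs sampler

One iteration updates, in order: latent liabilities (truncated-normal
draws conditioned on the record's other traits through $R$; missing cells
are augmented unconstrained, which keeps the covariance updates
conjugate), location effects ($b$ by single-site draws, $u$ by per-animal
blocks across traits using the sparse $A^{-1}$ rows), interior thresholds
(uniform over the interval bounded by the adjacent categories'
liabilities), $G$ from its inverse-Wishart full conditional with scale
$S_g + U'A^{-1}U$, and $R$ (next paragraph). The chain is single and
seeded; identical configuration, data and seed reproduce the stored draws
bit for bit.

### Identification of the ordinal scale

An ordinal trait's liability scale and location are not identified by the
data: we fix $t_1 = 0$ and the ordinal residual variance at 1. Early
versions of the sampler left the residual scale free (proper priors only)
and rescaled draws at storage time; on realistic data the unidentified
scale direction behaves as a nearly neutral multiplicative random walk,
and over $10^4$–$10^5$ iterations its excursions distort the coupled
genetic variances of ordinal traits. Rescaling the state every iteration
is not a valid Gibbs move either — the inverse-Wishart conditionals
re-expand the scale each cycle, producing a systematic ratchet. The
sampler therefore identifies the model *during* sampling: the ordinal
block of $R$ is fixed at the identity (unit liability variances, zero
residual covariance among ordinal traits — the classical assumption for
once-scored categorical traits), and the ordinal-by-Gaussian covariances
plus the Gaussian block are drawn from the exact conditional
inverse-Wishart given that block. With $S' = S_r + \sum_i e_i e_i'$ and
$\nu' = \nu_r + n$, the Gaussian conditional covariance is
$\Omega \sim IW(\nu', S'_{gg \cdot o})$ and the regression block is
matrix-normal, so the update stays fully conjugate. Heritabilities of
ordinal traits are consequently liability-scale ratios
$G_{tt}/(G_{tt} + 1)$, and all residual variances reported for ordinal
traits are exactly 1.

The location effects receive a weakly informative normal prior
$b \sim N(0, \tau^2 R_{tt})$ with $\tau^2 = 100$ rather than a flat prior:
with a fixed unit liability scale this is simply $N(0, 100)$ per
coefficient — ten residual standard deviations — and carries no practical
information, while guaranteeing a proper joint posterior in every
configuration (including validation runs with no records).

### Priors

Defaults are inverse-Wishart with $\nu = T + 2$ degrees of freedom and
scales $0.2\,I$ for $G$ and $0.8\,I$ for $R$, i.e. prior means of 0.2 and
0.8 — a weakly informative prior centred at a liability heritability of
0.2, in the range reported for conformation traits in horses. The
degrees of freedom must exceed $T + 1$ so the prior is proper with a
finite mean. All prior settings are arguments of `model_config()`.

### Schedule

`model_config()` defaults to the long single chain conventional for these
models: 100,000 iterations, 20,000 burn-in, thinning 10, i.e. 8,000
stored draws. The package's own validation suite runs scaled-down
schedules (20,000/4,000/4 for the replicated recovery study; a few
thousand iterations for unit checks) — sizes chosen so the whole suite
runs on a single CPU in minutes while leaving Monte Carlo error well
below the tolerances being asserted.

## Post-Gibbs layer

`posterior_summary()` reports mean, median, sd, 95% highest-posterior-
density interval (exact shortest sorted window, leftmost on ties), Geweke
Z (first 10% vs last 50%, spectral variance at frequency zero via an
AR fit with AIC order selection) and the batch-means Monte Carlo standard
error ($\lfloor\sqrt{n}\rfloor$ batches) for every variance, slope,
heritability, genetic correlation (with the dominant-sign probability
$P_{\neq 0}$) and sampled threshold. The window and batch conventions are
common post-Gibbs practice; the diagnostics named in the literature this
package follows do not pin them down further. `compute_dic()` integrates
liabilities out marginally per record (normal CDF differences for ordinal
cells) and floors category probabilities at $10^{-12}$.
`ebv_percentile_overlap()` compares top-quintile breeding-value sets
between two fits; the denominator is the first fit's top set and ties
break by animal id so the set is deterministic.

## The simulator

`simulate_dataset()` generates non-overlapping generations with parents
sampled from the previous generation (or a repeated full-sib line, which
pushes $F$ past 0.25 within three generations, covering the upper
inbreeding bins of the descriptive layer), drops true breeding values
down the pedigree (founders $N(0,G)$; offspring mid-parent plus a
Mendelian deviation with covariance $d_i G$, so $\mathrm{Var}(u_i) =
(1+F_i)G$), and emits phenotypes by thresholding liabilities built from
sex, stud size, age, $F$, $u$ and a unit-variance residual. Thresholds
are either given or calibrated as inverse-CDF quantiles of the realised
liabilities to hit target category frequencies. Sex and age are assigned
independently of genotype; studs are assigned per mating so the stud-size
effect is estimable. The default six-trait panel reproduces the published
study conditions: the four hoof deviations with their reported category
prevalences, model-A liability heritabilities and genetic correlations,
and the two Gaussian conformation covariates (tendon score, 4.87 ± 1.083,
$h^2 = 0.076$; proportionality index, 99.80 ± 2.379, $h^2 = 0.348$);
correlations without a published value are zero. Missingness rates match
the per-trait record counts; the two Gaussian traits use a nominal 5%.
Fixed-effect and covariate magnitudes (e.g. males +0.25 liability units
for the splay-footed forelimb, inbreeding slopes of 0.3–0.5) are modest
liability-scale choices of this package, fixed once — the study reports
significance patterns, not liability-scale effect sizes.

What the simulator does *not* emulate: overlapping generations,
selection and culling, evaluator effects, age-structured scoring, or the
severity-rule feedback on matings. Passing recovery tests therefore show
that the estimator recovers parameters under the model's own assumptions
at realistic sizes — not that real studbook data meet those assumptions.

## Validation strategy

Three independent lines of evidence back the sampler, all in the test
suite:

1. **Conjugate oracle** — the Gaussian special case agrees with a
   hand-written single-trait conjugate Gibbs sampler on shared data.
2. **Prior recovery** — with no records, stored draws of $G$ match the
   analytic prior mean within Monte Carlo error.
3. **Joint-distribution (successive-conditional) validation** — with the
   data re-simulated from the current parameters each iteration, the
   stored draws must be distributed exactly as the prior; means of
   $G_{tt}$, $r_g$ and the residual functionals are required within
   3 combined Monte Carlo standard errors of prior Monte Carlo values.
   This check exercises every conditional jointly and catches sign,
   scale and bookkeeping errors that single-case tests miss.

During development these checks, plus an exact brute-force posterior
(orthant-probability grid) on a micro pedigree, were what exposed the
unidentified-scale drift described above.

## Numerical choices and degenerate inputs

Truncated normal draws invert the CDF in the body of the distribution and
fall back to exponential rejection in far tails. A liability exceeding
$10^6$ in magnitude aborts the run with a diagnostic rather than
continuing silently. Non-positive-definite covariance draws are rejected
and redrawn (never repaired by eigenvalue clipping); an empty interior
category leaves its threshold bounded by the adjacent thresholds, with a
logged fallback count. Empty fixed-effect levels are dropped with a
warning; a factor collapsing to one level is removed entirely. An empty
trait column in the descriptive layer yields an $N = 0$ row, not an
error. The co-occurrence and prevalence denominators are
pairwise-complete records. The inbreeding-bin endpoints follow the
published convention ($[0, 0.0625]$, $(0.25, 1)$ at the extremes); the
two interior boundaries are a package convention recorded in the output.

## Known limitations

- Residual covariances **among** ordinal traits are fixed at zero by the
  identification scheme; genetic correlations among them are unrestricted
  (these are the quantities of scientific interest here).
- One record per animal: no permanent-environment effects.
- Single-chain diagnostics only (Geweke, MCSE); no Gelman–Rubin.
- The dichotomous-vs-three-category model comparison via DIC compares
  fits to differently coded responses, as in the source methodology; DIC
  differences across codings should be read qualitatively.
- At the package's default schedule a six-trait, $10^5$-animal run is a
  matter of hours, not of the minutes the validation sizes take.
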