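---
title: "Pedigree variance components for quantitative bipolarity: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree variance components for quantitative bipolarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedherit)
```

## The scientific setting

`pedherit` analyses a self-reported bipolarity scale (the 25-item QBS,
items rated 0–3) in multigenerational pedigrees from founder
populations. Such cohorts pose two linked statistical questions:

1. **Genetic validity** — how much of the variation in the quantitative
   trait is attributable to additive genetic effects (`h2`), how much
   to shared household environment (`c2`), and does the trait share
   genetic variance with the categorical diagnosis (`rhoG`)?
2. **Clinical validity** — does the score separate diagnosis groups,
   with what sensitivity/specificity, and does it aggregate in
   families?

Because individual-level data from such studies are typically not
releasable, the package ships a synthetic-cohort generator with known
ground truth; every inferential claim the package makes is exercised as
a parameter-recovery, oracle-equivalence or calibration experiment on
that generator.

## The polygenic model

For trait vector $y$ on $n$ pedigree members,

$$y \sim \mathcal N\!\left(X\beta,\;
  \sigma^2_g\,2\Phi + \sigma^2_c H + \sigma^2_e I\right),$$

where $\Phi$ is the kinship matrix from the genealogy (so $2\Phi$ is
the additive relationship matrix, diagonal $1+f_i$ under inbreeding),
$H$ the 0/1 sibship-household incidence, and $X$ holds intercept, age
and sex. Heritability is $h^2 = \sigma^2_g/\sigma^2_p$ and the
household proportion $c^2 = \sigma^2_c/\sigma^2_p$ with
$\sigma^2_p = \sigma^2_g + \sigma^2_c + \sigma^2_e$.

Kinship is computed by the classical recursion in generation order,
$\phi_{ii} = \tfrac12(1 + \phi_{F_iM_i})$ and
$\phi_{ij} = \tfrac12(\phi_{F_ij} + \phi_{M_ij})$; inbreeding loops
need no special handling, which a Monte-Carlo gene-dropping oracle
verifies in the test suite (recursive and simulated kinship agree
within four Monte-Carlo standard errors on looped fixtures). The matrix
is stored dense: at a few hundred individuals there is nothing to gain
from sparse machinery.

### Estimation

The model is fitted by **maximum likelihood** (REML is available behind
a flag for sensitivity analyses; the default matches the convention of
the pedigree-genetics software lineage this model comes from).
Three reductions keep every likelihood evaluation cheap and the
optimization low-dimensional:

* $\beta$ is profiled out by GLS at each covariance evaluation;
* $\sigma^2_p$ is profiled in closed form, leaving only the variance
  *proportions*;
* when $H$ is absent, a one-off spectral rotation of $2\Phi$
  diagonalizes the covariance, giving an $O(n)$ likelihood per
  evaluation and a one-dimensional search over $h^2$ (dense grid at
  step 0.01 plus Brent polish, with an explicit boundary comparison at
  $h^2 = 0$).

With a household term the proportions live on the simplex and are
optimized through a softmax ("multinomial logit") parameterization with
multi-start Nelder–Mead (near-null, balanced, near-saturated and
mid-range starts) followed by a BFGS polish, relative tolerance
$10^{-10}$; internal parameters are clamped at $\pm 15$ and proportions
below $10^{-5}$ snapped to the boundary. The trait is standardized
internally, which makes the proportion estimates exactly
scale-equivariant. A brute-force oracle — a dense $50\times50$
$(h^2, c^2)$ grid with GLS — bounds the optimizer on small pedigrees
within $10^{-4}$ log-likelihood units in the tests.

Before fitting, the trait is passed through the **rank-based inverse
normal transform** $z_i = \Phi^{-1}\{(r_i - 3/8)/(n + 1/4)\}$ (Blom
offset; the offset is configurable since conventions differ), with
average ranks on ties. Covariates stay in the model rather than being
residualized before transformation; the alternative ordering can be
obtained by transforming manually first.

### Uncertainty and testing

Standard errors of $h^2$ and $c^2$ come from the numerically
differentiated observed information of the profile log-likelihood on
the proportion scale (with $\beta$ and $\sigma^2_p$ profiled out, this
equals the corresponding block of the full observed information). At a
boundary estimate the quadratic approximation is meaningless and the SE
is reported `NA` rather than a number nobody should trust.

Each variance component is tested by a likelihood-ratio test against
the model with that component removed. Because the null value lies on
the boundary of the parameter space, the reference distribution is the
$\tfrac12\chi^2_0 : \tfrac12\chi^2_1$ mixture, so
$p = \tfrac12 P(\chi^2_1 > \Lambda)$ and $\Lambda = 0$ gives
$p = 0.5$.

**A caution on calibration.** The mixture is an asymptotic result in
the number of effectively independent families. The test suite shows it
calibrates at the nominal 5% level on 150 independent sibships, but on
the deeply interconnected founder cohort (~40 founder lineages) the
same test is *conservative* (empirical type-I error well below
nominal, with $P(\hat h^2 > 0 \mid h^2 = 0)$ clearly below ½). Users
should read borderline household p-values in that light; the test never
becomes anticonservative in our experiments, which the suite also
asserts.

### Bivariate model

For two traits the $2n$-dimensional covariance is
$G \otimes 2\Phi + E \otimes I$ with

$$G = \begin{pmatrix}\sigma^2_{g1} & \rho_G\sigma_{g1}\sigma_{g2}\\
\cdot & \sigma^2_{g2}\end{pmatrix},$$

and $E$ analogous with $\rho_E$. A joint rotation by the eigenvectors
of $2\Phi$ factorizes the likelihood into $n$ independent $2\times2$
problems, with both traits' fixed effects profiled by GLS, so the
six-parameter optimization (log-variances, $\tanh^{-1}$ correlations)
is $O(n)$ per evaluation. Multi-start Nelder–Mead is seeded from the
univariate fits and the sign of the phenotypic correlation. The
$\rho_G = 0$ test is a non-boundary 1-df LRT (the correlation can take
either sign). A binary diagnosis is entered as a quantitative 0/1
trait, exactly as in the analysis convention this mirrors; an optional
post-hoc threshold-model conversion to the liability scale
(`liability_h2()`) is provided as a clearly labelled extension.

## The synthetic cohort

The generator's defaults encode the study conditions the package
emulates and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 40 | founder couples seeding the genealogy |
| `generations` | 3 | offspring generations below the founders |
| `sibship_probs` | mean ≈ 3.3 | sibship sizes 2–9, right-skewed |
| `kinship_ceiling` | 1/16 | maximum mate kinship (first cousins and closer excluded) |
| `p_marry`, `p_immigrant` | 0.85, 0.5 | within-cohort marriage and marrying-in rates |
| `n_participants` | 310 | phenotyped study participants |
| `participation_probs` | .5/.2/.3 | families contributing one / two / many members |
| `h2_true`, `c2_true` | 0.46, 0 | generating variance proportions |
| `rhoG_true`, `rhoE_true` | 0.55, 0 | generating cross-trait correlations |
| `beta_age`, `beta_sex` | 0.05 SD | small covariate effects (the study found covariates explained ≤5% of variance) |
| prevalences | .065/.197/.010/.084 | bipolar / MDD / psychotic / other |

Two design points deserve emphasis:

* **Participation is sparse by design.** The genealogy is ~650 members;
  the phenotyped cohort of ~310 is sampled family-wise (half the
  families contribute a single member; densely sampled households
  contribute one or both parents and up to four children). This
  reproduces the study-scale relative-pair composition (about 190
  phenotyped sibling pairs) and, crucially, the *information content*
  of such a cohort: a fully phenotyped 310-member pedigree would carry
  roughly twice as many close pairs and yield materially smaller
  standard errors than a real study of this size. Parent–child pairs
  remain somewhat over-represented relative to the emulated cohort
  because sampled participants span generations.
* **Two additive-value generators.** Genetic values are drawn either
  multivariate-normally from $2\Phi$ or by gene-dropping 60 independent
  founder-effect loci; both have exactly the covariance
  $2\Phi\sigma^2_g$ (the tests verify their sib correlations are
  statistically indistinguishable), and the second also serves as an
  independent check that the kinship machinery and the trait model
  agree.

Items are generated from the standardized latent trait with loading
0.9 and shared thresholds (0, 1, 2) — fixed constants, not estimated —
chosen so the scored total is right-skewed like a symptom scale in a
mostly healthy cohort while correlating above 0.9 with the latent
trait. Diagnoses come from a liability threshold on the genetically
correlated second trait (bipolar) plus multinomial assignment of the
other groups, with fixed latent offsets per group for the
clinical-validity scenario. What the generator does **not** emulate:
item-level factor structure (all items load on one latent), missing
responses, assortative mating, ascertainment through affected families,
and secular/cohort effects on age. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to those real-data features.

## Clinical-validity machinery

* **Group comparison** fits the score on diagnosis dummies plus age and
  sex with the polygenic random effect, then tests the group block with
  a Wald chi-square (df = groups − 1). The reported F applies the
  residual-df rescaling so that with $K = I$ it reproduces the
  ordinary least-squares ANOVA F exactly. Pairwise contrasts are
  reported unadjusted and Holm-adjusted. (The emulated study prints an
  omnibus df that does not match its own group count; we use
  groups − 1 and note the discrepancy rather than matching it.)
* **ROC** uses the `score >= cutoff` convention over all observed
  thresholds; the trapezoid AUC equals the tie-corrected Mann–Whitney
  statistic exactly (asserted against `wilcox.test` and `pROC`), with
  Hanley–McNeil SE, Wald 95% CI and a normal-approximation test of
  AUC = 0.5. The Youden cutoff takes the smallest maximizing threshold
  on ties, and is computed per comparison (a shared cutoff across
  comparisons can be read off the controls comparison if desired).
* **Familial aggregation** defines the index set as scores above
  mean + 1 SD, the exposure set as non-index individuals with at least
  one relative of kinship φ ≥ 0.125 (first/second degree,
  operationalized through kinship so pedigree loops cannot break
  relationship labels) in the index set, and Welch-tests the score
  between exposed and unexposed non-index individuals. Index
  individuals are excluded from both sides; the rule is configurable
  because the emulated analysis leaves it unstated. Welch (rather than
  pooled-variance) t-tests are used throughout since group variances
  in such data are conspicuously unequal.

## QBS scoring rules

Depression is items 3–8 (0–18), mania items 11–24 (0–42), mood
fluctuation items 1, 2, 9, 10 (0–12); the 25th, global item counts
toward the total (0–75) but no subscale, and a flag excludes it for
24-item sensitivity analyses since conventions in the screening-scale
literature differ. Missing items fail scoring by default; an explicit
prorate policy rescales each affected sum by set size over answered
items, rounding half-up to preserve the integer score contract.

## Problem sizes and determinism

The recovery studies average 200 simulated cohorts per scenario
(~310 participants each; 200-member subsets for the controls-only
scenario), the null calibration uses 500 replicates, and the optimizer
oracle runs on 20 random pedigrees of up to 15 members; these sizes
keep Monte-Carlo error on a mean-of-estimates near 0.01 while remaining
desk-scale. All generators and scripts are seeded; identical seeds give
identical pedigrees, cohorts and reports (the pipeline hashes its
analytic configuration into the report for provenance).

## Known limitations

* Only additive and sibship-household components: no dominance,
  epistasis, maternal effects, or more than two traits.
* The binary diagnosis is modelled on the observed 0/1 scale in the
  fits; the liability conversion is post hoc and ignores ascertainment.
* SEs are quadratic-approximation based and suppressed at boundaries;
  profile-likelihood intervals are not implemented.
* The boundary LRT is conservative on densely interrelated pedigrees
  (see above); p-values near the household-effect threshold should not
  be over-read.
* No ascertainment correction: the generator recruits families at
  random, whereas real studies often ascertain through affected
  members.
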