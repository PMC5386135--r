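---
title: "Maternal genetic instruments for intrauterine effects: model, estimators, and what the simulations establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal genetic instruments for intrauterine effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The problem

Mendelian randomization (MR) with *maternal* genetic instruments asks whether
a maternal pregnancy exposure $X_m$ (say, gestational BMI) causally affects a
postnatal offspring outcome $Y_o$. The instrument is a maternal allele score
$G_m$; the target estimand $\gamma$ is the change in $Y_o$ (in SD units) per
SD of $X_m$.

The design has a structural weakness that ordinary MR does not: the offspring
inherits exactly half of each maternal instrument. If the offspring's own
genotype $G_o$ affects $Y_o$ directly (inevitable when the maternal exposure
and offspring outcome are the same or similar traits), the instrument reaches
the outcome through a path that bypasses the exposure, and the exclusion
restriction fails. Adjusting for $G_o$ blocks that path but opens another:
$G_o$ is a collider between $G_m$ and the paternal genotype $G_p$, so
conditioning on it induces a spurious negative maternal-paternal association
and lets any paternal direct path leak into the estimate with a negative
sign.

`triomr` implements the machinery for studying and handling this situation:
a trio simulator with a variance-component parameterization, the four
estimation strategies whose contrast diagnoses the problem, non-transmitted
haplotype instruments, one-sample summary-statistic sensitivity estimators,
and a scenario-grid runner.

## The generative model

One replicate draws $n$ mother-father-offspring trios. At each of $m$
independent biallelic variants with effect-allele frequency $p_j$, the four
parental haplotypes are independent Bernoulli($p_j$) draws; the offspring
genotype is the sum of one labelled transmitted haplotype from each parent,
so transmission ground truth is carried in the cohort. Weighted allele
scores are standardized *analytically* - a full score by
$\sqrt{\sum_j w_j^2\, 2p_j(1-p_j)}$, a single-haplotype (transmitted or
non-transmitted) score by its own analytic SD - so unit variance holds by
construction rather than by in-sample rescaling, and the parent-offspring
score correlation is exactly $1/2$ in expectation.

Phenotypes follow a linear path model on the standardized scale:

$$X_m = \sqrt{q_x}\,G_m + c_x C + e_x, \qquad
  Y_o = \gamma X_m + \sqrt{v_o}\,G_o + \sqrt{v_p}\,G_p + c_y C +
        \textstyle\sum_j \delta_j (M_j - 2p_j) + e_y,$$

where $C$ is a shared standard-normal confounder, $\delta$ an optional
per-variant pleiotropy vector acting on the centred maternal dosage $M_j$,
and $e_x$, $e_y$ residuals whose variances are *solved* from the
model-implied covariance so that both phenotypes have unit variance. A
variance budget that cannot be satisfied (negative residual variance) is a
configuration error, never a silent rescale.

The convention that a score "explaining a proportion $v$ of variance" enters
with coefficient $\sqrt{v}$ is what makes the closed forms below reproduce
the reference simulation grid exactly, which is the strongest available
check on the parameterization.

### Closed-form companions

`model_implied_covariance()` path-traces the full covariance of
$\{G_m, G_o, G_p, G_{nt}, G_t, C, X_m, Y_o\}$; the simulator's empirical
covariance converges to it (tested at $n = 10^5$). Two probability limits
follow directly and are exposed as functions:

* unadjusted strategy: $\gamma + \tfrac12\sqrt{v_o/q_x}$
  (`expected_unadjusted_estimate()`) - the transmitted-path leak;
* offspring-adjusted strategy: $\gamma - \tfrac13\sqrt{v_p/q_x}$
  (`expected_offspring_adjusted_estimate()`) - the collider leak. The
  $1/3$ is the magnitude of the partial correlation of $G_m$ and $G_p$
  given $G_o$: $(0 - 0.25)/0.75 = -1/3$ when both marginal correlations
  with $G_o$ are $0.5$ and the spousal correlation is zero.

At the grid's instrument strength ($q_x = 0.02$) these forms give 0.79,
0.35, 0.90 for the unadjusted cells and $-0.53$, $-0.24$, $-0.14$ for the
offspring-adjusted cells, matching the grid's printed cells to their precision;
the package's golden-number tests re-derive the same cells by simulation.

## Estimation strategies

`estimate_all_strategies()` runs just-identified two-stage least squares
(TSLS) five ways: (1) instrument $G_m$, no covariates; (2) adding $G_o$ to
both stages; (3) adding $G_o$ and $G_p$; (4) instrumenting with the maternal
non-transmitted haplotype score $G_{nt}$, no covariates; and (5) the
transmitted-score comparator $G_t$. Covariates enter both stages
symmetrically - that is standard TSLS practice and is required for the
collider mechanism to manifest as it does in the causal diagram. Standard
errors use the homoskedastic IV formula with structural residuals formed
from the observed exposure (a robust sandwich option exists but is off by
default, since the reference results do not state robustness). Confidence
intervals are $\hat\beta \pm 1.96\,\widehat{se}$. The partial F statistic
for the excluded instrument is always reported.

Strategies (3) and (4) are unbiased at every grid cell; the package's
acceptance tests verify this grid-wide and reproduce the biased cells of
strategies (1) and (2) at their printed values.

## Transmission resolution

With unphased dosages, the maternal transmitted allele is determined
whenever mother or offspring is homozygous; a mother-offspring double
heterozygote is resolvable only if the father is homozygous, and is
otherwise *ambiguous*. `resolve_transmission()` implements this rule (and
flags Mendelian-inconsistent trios as a status, not an exception);
`build_nontransmitted_score()` builds standardized haplotype scores from
resolved cells only.

Two design choices here are the package's own:

* **Ambiguous cells are excluded, not imputed.** Imputing the transmitted
  allele at its expectation would shrink $G_{nt}$ toward the full maternal
  score and re-introduce exactly the transmitted component the instrument
  exists to remove.
* **Per-trio analytic standardization.** Each trio's score is centred and
  scaled by the analytic moments of its own resolved variant set, so
  retained scores have unit variance regardless of the resolution pattern;
  trios resolved on less than half of the panel's variance contribution
  (configurable) are dropped and counted.

Statistical phasing from flanking haplotypes - the practical remedy for
double heterozygotes when fathers are untyped - is out of scope; simulated
cohorts carry ground-truth labels (`transmission_truth()`), matching the
assumption of precisely known transmission that the simulation design makes.

## Summary-statistic sensitivity analyses

`per_variant_summaries()` produces per-variant exposure and outcome
associations, the outcome model optionally conditioning on the offspring's
dosage at the same variant. Conditioning matters: when mother and offspring
share the trait, every variant's direct (transmitted) effect is proportional
to its instrument strength, which is precisely a violation of the InSIDE
assumption - so MR-Egger's slope tracks $\gamma + 0.5$, not $\gamma$,
unless the offspring genotype is adjusted for. The package tests this
failure mode explicitly.

Estimators: `ivw()` (weighted through-origin regression, weights
$1/se_y^2$), `mr_egger()` (free intercept estimating average directional
pleiotropy; slope consistent under InSIDE), and `weighted_median()` (median
of the inverse-variance-weighted empirical distribution of per-variant
ratios, consistent while at least half the weight is valid; SE by seeded
parametric bootstrap, 1000 replicates by default). All three agree exactly
on degenerate equal-ratio inputs, which is tested. Numerical choices: IVW
and Egger standard errors carry a multiplicative overdispersion factor
bounded below by 1 (the convention in established summary-MR software; the
source material does not specify one); the weighted median interpolates the
weighted ECDF at probability one half with cumulative weights taken at bin
midpoints; ratio-scale weights use the first-order delta form
$(\beta_x/se_y)^2$.

One-sample caveats are surfaced rather than solved: estimators warn when the
mean per-variant F is below 10, because one-sample IVW/Egger performance
deteriorates quickly with weak instruments and internal weights, and no
simple correction exists.

`minus_half_correction()` implements the same-trait shortcut - subtract 0.5
from the unadjusted estimate and both CI bounds - as a pure shift. Its
applicability conditions (identical trait in mother and offspring, additive
linear model, large samples) cannot be verified from data, so the caller's
assertion is recorded in metadata, not enforced.

## Assortative mating

The source design names assortment as a bias mechanism but gives no
generative recipe, so the mechanism here is the package's choice: mothers
and fathers are rank-coupled on noisy copies of an exposure-relevant
phenotype (the father's being $\sqrt{q_x}\,G_p$ plus independent noise, with
no shared confounder), using a latent bivariate normal with the target
spousal correlation. With `assortment_rho = 0` the path is bypassed and the
output is bit-identical to the plain simulator. Assortment with a heritable
exposure induces a positive spousal score correlation and biases the
non-transmitted strategy upward when the offspring genotype affects the
outcome - both tested by direction, since the magnitude is
mechanism-dependent.

## What the synthetic data does and does not establish

The generator reproduces the stated world of the reference simulation design:
10,000 trios per replicate, a maternal instrument explaining 2% of exposure
variance, offspring/paternal direct paths explaining 0-5% of outcome
variance, zero net confounding in the headline grid, and (for the default
panel) 97 equally weighted variants with frequencies drawn once in
[0.1, 0.9], mirroring the 97-SNP score of the worked real-data example. It
deliberately omits: linkage disequilibrium within the panel, sex
chromosomes, imprinting, age-varying genetic effects, dynastic environments
beyond the single shared confounder, and distinct pre-conceptual (oocyte)
pathways, which are representable only through the generic per-variant
pleiotropy vector. A green test therefore establishes that the estimators
behave as claimed *under the stated linear, additive, LD-free world* - not
that any real cohort satisfies those conditions.

Replicate counts in the tests are desk-scaled (200-400 replicates versus
the reference design's 1000; the grid-wide unbiasedness sweep additionally reduces
to 2,000 trios and 15 variants, which is legitimate because unbiasedness of
strategies (3) and (4) does not depend on sample size). Golden-number
tolerances follow the Monte-Carlo convention
$2\,\widehat{sd}/\sqrt{R}$ plus the printed value's rounding half-width
(0.005) and its own Monte-Carlo error at 1000 replicates - margins fixed
from the analytic probability limits before the tests were first run.

## Reproducibility

Every source of randomness descends from one root seed per scenario;
replicate $i$ uses a stream derived deterministically from
$(\text{seed}, i)$, so any replicate is reproducible in isolation and grid
runs are byte-identical across re-runs (tested). Seeds are kept below
$2^{31}$.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(n_trios = 10000, q_x = 0.02, gamma = 0.10,
                       v_o = 0.05, v_p = 0.01, seed = 1)
cohort <- simulate_trio_cohort(cfg)
estimate_all_strategies(cohort)
expected_unadjusted_estimate(0.10, 0.02, 0.05)   # 0.89
```

## Known limitations

* Over-identified individual-level TSLS with per-variant instruments is not
  provided; the panel enters as a single weighted score, as in the design
  under study. LIML/GMM variants are out of scope.
* The minus-0.5 correction's full applicability criteria live outside the
  available material; the package implements the shift and records the
  caller's assertion.
* The assortment mechanism is one of several plausible ones; magnitudes of
  assortment-induced bias are mechanism-specific even when directions are
  not.
* Real-cohort ingestion is limited to rectangular dosage/phenotype tables;
  cohort-specific cleaning, relatedness and population structure are the
  user's responsibility.
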