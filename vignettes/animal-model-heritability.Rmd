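---
title: "Heritability of social behaviour in a vole colony: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of social behaviour in a vole colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voleherit)
```

## The scientific question

Laboratory prairie voles show striking individual variation in pair-bonding
behaviour: in a three-hour partner-preference test some males spend over two
hours in side-by-side contact with their mate, others essentially none. Is
that variation genetic? `voleherit` implements the quantitative-genetic
machinery to answer this for a pedigreed colony: it estimates the
narrow-sense heritability of behavioural traits and of vasopressin-1a
receptor (V1aR) density in two brain regions (ventral pallidum, VP;
retrosplenial cortex, RSC), using every relationship in the colony rather
than only parent-offspring pairs.

## The animal model

For a vector of trial records $y$ (one measurement of a focal male, tested
with a partner female and a stranger female) we fit

$$ y = \mathbf{1}\beta + Z_m m + Z_p p + Z_s s + e $$

where $\beta$ is the intercept, $m$, $p$ and $s$ are additive genetic
effects of the focal male, the partner and the stranger (the latter two are
*indirect* genetic effects: the social environment a female's genotype
provides), and $Z_m, Z_p, Z_s$ are 0/1 incidence matrices mapping trials to
animals. The genetic effects are multivariate normal with covariance
proportional to the numerator relationship matrix $A$ derived from the
colony pedigree — $m \sim N(0, A\sigma^2_m)$ and likewise for $p$ and $s$ —
and residuals are independent, $e \sim N(0, I\sigma^2_e)$. Heritability of
each effect is its share of the total phenotypic variance,
$h^2_x = \sigma^2_x / (\sigma^2_m + \sigma^2_p + \sigma^2_s + \sigma^2_e)$.

$A$ is built by the tabular method (`additive_relationship()`): processing
animals parents-first, $a_{ii} = 1 + \tfrac12 a_{sd}$ and
$a_{ij} = \tfrac12(a_{js} + a_{jd})$, with unknown parents contributing
zero. Unknown parents are treated as unrelated, non-inbred founders — the
standard convention. The inverse is taken densely via Cholesky: at colony
scale (hundreds of animals) dense inversion is exact and simpler than
Henderson's sparse rules, and the pedigree may contain inbred loops, which
the tabular method handles without special cases.

## Gibbs sampler

`gibbs_fit()` cycles the full conditionals:

1. $\beta$ from its normal conditional under a flat prior;
2. each effect vector as one block draw from its multivariate normal
   conditional with precision $Z'Z/\sigma^2_e + A^{-1}/\sigma^2_x$;
3. each genetic variance from a scaled-inverse-$\chi^2$ with degrees
   $q + \nu_0$ and scale $(u'A^{-1}u + \nu_0 S_0)/(q + \nu_0)$, where $q$
   is the number of pedigree animals;
4. the residual variance analogously from the residual sum of squares.

Block updates (one multivariate draw per effect per iteration) mix far
better than single-site updates at a few hundred animals. Numerically, each
effect is drawn in whitened coordinates: a one-off factorisation finds $U$
with $U'A^{-1}U = I$ and $U'Z'Z\,U = \Lambda$ diagonal (a generalised
eigenproblem solved via the Cholesky factor of $A^{-1}$), so the conditional
precision is diagonal in $v$-space, each iteration costs $O(N^2)$, and
$u'A^{-1}u = \sum v_i^2$ falls out for free. This is an exact
reparameterisation, not an approximation.

**Priors.** The source analysis does not state its priors; we default to a
proper but near-noninformative scaled-inverse-$\chi^2$ with
$\nu_0 = 0.002$, $S_0 = 1$ per component (`prior_spec()`), configurable.
With hundreds of animals and the residual informed by all records, the
prior's contribution to the posterior scale is negligible — the
conjugate-limit test quantifies this against the closed form.

**Chain schedule.** The production schedule is 280,000 iterations, 30,000
burn-in, thinning 25 — exactly 10,000 retained draws
(`gibbs_config_production()`). The package default is a desk-scale
28,000 / 3,000 / 25 schedule (1,000 draws) which finishes in well under two
minutes on one core at colony scale; all retained-draw bookkeeping is exact
by construction, `(n_iter - burn_in) / thin`.

**Point estimates.** Heritability is computed per retained draw and then
averaged (mean of ratios), with the posterior SD as the standard error. The
alternative — ratio of posterior means — differs only at second order but
mean-of-ratios is the standard posterior functional for a derived quantity
and is what `heritability_from_samples()` implements.

**Diagnostics.** `convergence_diagnostics()` reports, per parameter, the
effective sample size by the initial-positive-sequence estimator
(autocovariances summed in adjacent pairs, truncated at the first
non-positive pair sum), lag-1..10 autocorrelations, and the posterior
summary; a constant chain is flagged with an undefined ESS rather than an
error. The estimator's name is carried in the output so reports are
self-describing.

**Cross-check estimator.** `parent_offspring_regression()` implements the
classical single-parent regression ($h^2 = 2 \times$ slope, SE doubled
likewise). It uses only sire-son pairs and is much noisier than the animal
model — which is precisely why the relationship-matrix approach exists — but
on large simulated data with a male effect only, the two estimators agree
within joint Monte-Carlo error, and the package tests assert this.

## The synthetic colony

`generate_colony_pedigree()` reproduces the study's crossing scheme: per
founder block, two full-sib males (sons of one founder couple) are each
mated to one of two unrelated full-sib females (daughters of a fresh founder
couple); in each later generation, up to two male offspring per litter are
mated, again to fresh unrelated full-sib female pairs. Mate females enter as
new, unrelated sib pairs each generation because in the source colony the
females come from outside the male line.

The exact block count and litter size of the original colony are not
published, so they are free parameters. The defaults — 7 blocks, 2 offspring
generations, litters of 7 (sexes alternating, so 4 males / 3 females) — were
chosen once to land on the study's scale: 406 pedigree animals with 182
non-founder (phenotyped) males, versus the study's N = 368 colony and 180
tested males. A 60-male subsample mimicking the density cohort is simply the
first 60 phenotyped males when needed.

Phenotypes are generated by inverting the animal model
(`simulate_phenotypes()`): breeding values are drawn as
$u = \sqrt{\sigma^2}\,L z$ from a lower-triangular factor of $A$, residuals
independently, and each trial value assembled as
$\beta + m + p + s + e$. The hidden components are retained, so the
reconstruction identity holds exactly and recovery experiments can score
posterior estimates against known truth. Each male is measured once per
trait, as in the study. Every generator takes an explicit seed and is a pure
function of its arguments.

What the simulator deliberately does *not* emulate: behavioural time-series
structure, floor/ceiling effects and non-normality of durations, mating
failure or death censoring, maternal and common-litter environmental
effects, and genotype-by-environment interaction. Passing recovery tests
therefore demonstrate that the estimation machinery is correct under the
model's own assumptions — they do not certify the model against real-data
violations of those assumptions.

## Recovery experiment and what it shows

`run_recovery_experiment()` is the validation surface: for male-effect
heritability truths 0, 0.5 and 0.8 on the default colony with the desk
chain, posterior means land within ±0.15 of truth and the null case below
0.15. That reproduces, in silico, the study's qualitative contrast: partner
preference and other behaviours with heritability indistinguishable from
zero versus V1aR densities with high heritability (53% in VP, 80% in RSC).
Estimating three genetic variances from 182 records on 406 animals is
genuinely hard; posterior SDs of 0.1–0.2 for $h^2_m$ are expected and the
small upward bias of a boundary-constrained variance under the null (a few
percent) is visible but well inside the criterion.

## Behavioural statistics

The descriptive/inferential layer mirrors the study's analyses:

- `paired_before_after()` — classic paired *t*-tests on per-animal
  after − before differences for the 13 assay behaviours, with SE =
  SD/√n and Bonferroni control (`bonferroni_alpha(13)` ≈ 0.004 at one
  significant figure). The difference contrast is defined as
  after − before and stamped on the output. Two-sided p-values throughout.
  One behaviour (pup-directed aggression) is a frequency rather than a
  duration; it is analysed by the same paired *t* for fidelity to the source
  analysis even though a count is non-Gaussian.
- `spearman_test()` / `spearman_screen()` — rank correlations of each
  behaviour contrast (before, after, difference) against V1aR density per
  section (8 VP + 7 RSC) plus per-region total averages. Average ranks for
  ties; the two-sided p-value is exact by full enumeration of all $n!$ rank
  permutations for $n \le 7$ and *t*-approximate beyond. The screen's
  per-test level is configurable: the published threshold $7.5\times10^{-5}$
  can be set directly because its exact Bonferroni divisor is not
  recoverable from the text; the default divides 0.05 by the number of
  correlations actually computed.
- `partner_preference_summary()` — mean ± SE, range and 10-minute histogram
  bins of partner-contact time.

## Numerical and degenerate-input choices

- Relationship values are dyadic rationals computed without rounding, so
  unrelatedness checks (`a = 0`) and textbook values (0.5, 0.25, 1.25) are
  exact comparisons.
- `inverse_relationship()` refuses matrices with reciprocal condition
  number below $10^{-12}$, reporting the estimate.
- A constant difference vector in the paired test returns $t = 0, P = 1$
  (identical phases) or $\pm\infty, P = 0$ rather than erroring.
- Constant inputs to a rank correlation yield an undefined (missing) $R$.
- A zero genetic variance simulates exact-zero breeding values; a zero total
  variance draw aborts heritability computation with a degenerate-draw
  error.
- Eigenvalues of the whitened effect precision are floored at zero to
  absorb roundoff; the sampler aborts with the iteration index if any
  variance becomes non-finite.

## Problem sizes used in the shipped tests

The test suite and acceptance script run entirely from simulated data: the
default 406-animal colony for recovery (one fit per truth at
28,000 / 3,000 / 25), 10,000-draw conjugate checks on 40 records, 1,000
null replicates at n = 180 for the paired-*t* calibration, 50 random
pedigrees (≤ 30 animals) against the recursive-coancestry oracle, and full
permutation enumeration up to n = 7. The production schedule is used for
real-data fits (`analysis/05_osf_real_data.R`); fitting the deposited
study data requires downloading it from OSF and is not part of the shipped
tests.

## Known limitations

- Single-trait analyses only: no genetic correlations between traits, no
  bivariate models, no maternal-effect terms.
- No REML alternative; estimation is Bayesian by design.
- The trait scale is used untransformed, as in the source analysis;
  strongly skewed durations may warrant transformation before fitting.
- Partner/stranger effects are weakly identified when each female appears
  in only one trial; their posteriors then lean on the pedigree structure
  and the prior, which is faithful to the design but worth remembering when
  interpreting small indirect-effect variances.
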