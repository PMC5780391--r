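# voleherit

Quantitative-genetic analysis of social behaviour and brain receptor density
in a pedigreed laboratory prairie-vole colony.

## The problem

Male prairie voles vary enormously in pair bonding: in a three-hour
partner-preference test, some males spend over two hours in contact with
their mate, others almost none. Is that variation heritable? Answering this
in a breeding colony requires more than parent–offspring regression — the
colony is a web of full sibs, half sibs and deeper relatives, and with only
one sire phenotyped per family the regression estimator is hopelessly noisy.
`voleherit` implements the standard solution from animal breeding, the
**animal model**, for colonies of this design, plus the supporting
behavioural statistics (before/after-mating comparisons, partner-preference
summaries, and rank-correlation screens of behaviour against
vasopressin-1a-receptor (V1aR) density in the ventral pallidum and
retrosplenial cortex).

## The model

For trial records `y` (one focal male tested with a partner and a stranger
female),

```
y = 1 β + Z_m m + Z_p p + Z_s s + e
m ~ N(0, A σ²_m),  p ~ N(0, A σ²_p),  s ~ N(0, A σ²_s),  e ~ N(0, I σ²_e)
```

where `A` is the numerator relationship matrix derived from the pedigree
(tabular method; diagonal `1 + F`), `m` is the focal male's additive genetic
effect and `p`, `s` are *indirect* genetic effects of the two females.
Variance components get weak scaled-inverse-χ² priors and are estimated by a
Gibbs sampler that block-draws each effect vector from its multivariate
normal full conditional; heritabilities are per-draw variance shares,
summarised by posterior mean ± SD. A parent–offspring regression
(`h² = 2 × slope`) is included as the classical cross-check, and a
synthetic-colony simulator reproduces the study's crossing scheme (full-sib
founder males × unrelated full-sib females, two offspring generations,
~400 animals, ~180 phenotyped males) so the whole machinery is validated by
parameter recovery against known truth.

## Worked example

```r
library(voleherit)

ped    <- generate_colony_pedigree(seed = 1)        # 406 animals, crossing scheme
trips  <- assign_partners_strangers(ped, seed = 2)  # 182 unrelated triples
truth  <- variance_truth(beta = 10, var_m = 2, var_e = 2)  # h2_m = 0.5
dat    <- simulate_phenotypes(ped, trips, truth, seed = 3)

A   <- additive_relationship(ped)
fit <- gibbs_fit(dat$trials, A, config = gibbs_config(28000, 3000, 25, seed = 4))
heritability_from_samples(fit)
```

```
Posterior heritability estimates (mean-of-ratios over retained draws)
 component h2_mean h2_sd
      male   0.582 0.174
   partner   0.020 0.028
  stranger   0.033 0.059
  residual   0.364 0.179
```

The focal-male heritability posterior (0.58 ± 0.17) brackets the simulated
truth of 0.5; the partner and stranger indirect effects, simulated at zero,
come back near zero. `convergence_diagnostics(fit)` adds effective sample
sizes (initial-positive-sequence estimator) and autocorrelations per
parameter. The chain above is the desk schedule (1,000 retained draws);
`gibbs_config_production()` gives the production schedule of 280,000
iterations / 30,000 burn-in / thin 25 = 10,000 retained draws.

The behavioural layer works from long-format tables:

```r
bonferroni_alpha(13)              # 0.003846…  (≈ 0.004, the 13-behaviour family)
paired_before_after(measurements) # per-behaviour paired t with Bonferroni flags
spearman_screen(measurements, densities, alpha = 7.5e-5)
partner_preference_summary(minutes)  # mean ± SE, range, 10-min bins
```

Spearman p-values are exact (full permutation enumeration) for n ≤ 7.

## Analysis workflow

The `analysis/` scripts chain the package into the full study pipeline and
write their tables under `results/`:

1. `01_simulate_colony.R` — colony pedigree, trial assignments, phenotypes
   for a non-heritable behaviour-like trait and an h² = 0.5 density-like
   trait (CSV + truth JSON).
2. `02_fit_heritability.R` — animal-model fits per trait with diagnostics.
3. `03_behaviour_screen.R` — 13-behaviour paired table, partner-preference
   summary, V1aR Spearman screen (8 VP + 7 RSC sections, 60-male subsample).
4. `04_recovery_experiment.R` — bias/coverage table over heritability truths
   0 / 0.5 / 0.8.
5. `05_osf_real_data.R` — fits user-downloaded real colony data (see the
   script header for the expected CSV dialects); not run automatically.

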