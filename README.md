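# calfnet

Social-network and weaning-stress analysis for pair-housing experiments in
dairy calves, driven by spatial proximity-logger data.

## The problem

When dairy calves are reared individually or in pairs and later regrouped
in a barn, two questions arise for welfare scientists:

1. **Does early social contact buffer weaning stress** (measured through
   vocalisations, growth and intake around milk withdrawal)?
2. **Does early familiarity shape the social network** that forms after
   regrouping?

Proximity loggers answer the second question by recording, for every pair
of collared calves, when and for how long they were within ~1.5 m of each
other. But raw logger streams need care: 1-second records are unreliable
chatter, and loggers differ systematically in sensitivity, so the two
members of a dyad rarely report the same contact time.

`calfnet` implements the full analysis chain:

- **Cleaning and bias correction.** Directed totals `d[a,b]` (time logger
  *a* recorded partner *b*) are compared across each dyad; each logger's
  over-recording index is its mean signed percentage difference
  `100·(d_ab − d_ba)/mean(d_ab, d_ba)` against its partners, and every
  logger's durations are reduced by its bias relative to the most
  under-recorded logger. Corrected directed totals are averaged into a
  symmetric weekly association matrix **O**.
- **Network stability.** Spearman correlation of off-diagonal strengths
  between weekly matrices, with significance from node-label (QAP)
  permutations.
- **Social differentiation.** The heterogeneity statistic
  `S = Σ_i Σ_{j≠i} (O_ij − E_ij)² / (N(N−1))`, where `E` spreads the
  observed total association time uniformly over dyads, referred to nulls
  that redistribute the total seconds multinomially over dyads.
- **Assortment.** A Bayesian dyadic regression
  `log O_ab = μ + β·x_ab + u_a + u_b + ε` with a multi-membership calf
  random effect, fitted by Gibbs sampling; fixed effects are dyadic
  familiarity (days of prior full social contact) and a
  different-treatment indicator; models are compared by DIC.
- **Treatment contrasts.** Coefficient of variation in association
  strength, percentage of time with the ex-penmate, and weighted degree,
  pen-averaged and tested with permutation ANOVA (bootstrap CIs).
- **Pen-rearing battery.** Specific growth rate `100·(ln W2 − ln W1)/t`,
  health-score summaries, weaning-period vocalisation tests (Friedman,
  Kruskal-Wallis, Mann-Whitney) with two-stage sharpened FDR q-values.
- **Synthetic data.** A generator that emulates the staggered-entry
  experiment (40 calves, 8 blocks × {1 individually housed, 2 paired at
  day 5, 2 paired at day 28}), including familiarity-driven contact rates,
  per-logger recording bias, spurious 1-s records and rearing records, so
  every stage is testable end to end.

## Worked example

Simulate one association week, build the corrected network, and test for
differentiation and familiarity assortment:

```r
library(calfnet)

cfg <- sim_config(weeks = 1L, baseline_contact_rate = 0.05)
sched <- generate_schedule(cfg)
contacts <- generate_contact_stream(sched, cfg, seed = 1)
contacts <- filter_min_duration(contacts)          # drop 1-s chatter

win <- attr(contacts, "windows")
totals <- directed_totals(contacts, win[1], win[2], sched$calf_id,
                          window = "week1")
bias <- estimate_logger_bias(totals)
M <- symmetrise(apply_bias_correction(totals, bias))
M
#> Association matrix (40 individuals, window week1)
#> total dyadic association: 822122.1 s; mean dyadic strength: 1054 s

differentiation_null_test(M, n_perm = 4999, seed = 2)
#> Social differentiation permutation test (N = 40 )
#>   S observed = 4.364e+05; null median = 1050; null 95% quantile = 1140
#>   p = 0.0002 (4999 null networks)

fit <- fit_dyadic_model(build_dyad_table(M, sched),
                        n_iter = 3000, burn_in = 500, thin = 2, seed = 3)
fit
#> Dyadic multi-membership regression of log association strength
#>   fixed effects: familiarity + different_treatment
#>   1560 dyad rows, 40 calves; DIC = 2882.07
#>                     post_mean lower_95 upper_95  pMCMC
#> (Intercept)            6.5722   6.5010   6.6395 0.0016
#> familiarity            0.0242   0.0207   0.0277 0.0016
#> different_treatment    0.0274  -0.0338   0.0891 0.4048
```

Reading the output: the observed differentiation statistic dwarfs its
uniform-mixing nulls (p at the 0.0002 floor attainable with 4999
permutations), so calves associate non-uniformly. The dyadic model
recovers the familiarity effect planted by the generator (0.02 extra log
encounter rate per day of familiarity; its 95% credible interval excludes
zero) while the treatment-similarity effect is indistinguishable from
zero — the same qualitative pattern the method is designed to detect in
field data.

The file-based pipeline (`pipeline_simulate()`, `pipeline_networks()`,
`pipeline_analyse()`) chains these stages through CSV/JSON artefacts and
a run manifest; `inst/scripts/calfnet-cli.R` wraps them for shell use.

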