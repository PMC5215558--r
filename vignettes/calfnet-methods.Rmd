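---
title: "Methods: proximity-logger networks and weaning stress in pair-housed calves"
author: "calfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-logger networks and weaning stress in pair-housed calves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfnet)
```

## The study design this package models

`calfnet` analyses a staggered-entry pair-housing experiment. Forty
female calves are split over eight blocks of five; within each block one
calf is housed individually (treatment *I*), two are paired from day 5
(*P5*) and two from day 28 (*P28*). Blocks enter the trial three days
apart. On study day 55 each block's pens are merged, on day 60 the block
moves to a shared barn, and when the last block arrives ("the first day
of barn grouping", calendar day 81 under the defaults) the whole group of
forty is observed for four weeks through collar-mounted proximity
loggers. Before that, weaning (stepped milk withdrawal from day 48)
provides the stress phase: vocalisations are counted per pen for three
days before, during and after weaning, alongside daily health scores,
pen-level concentrate intake and three weighings.

Two kinds of inference hang off this design. During **pen rearing** the
pen is the experimental unit, so all calf-level values are averaged per
pen before testing (with one individually housed calf removed from the
emulated cohort this yields 7 + 8 + 8 = 23 units). During **barn
grouping** the network itself is the object of inference, and all tests
are permutation-based because dyadic observations are not independent.

## Familiarity

The central covariate of the assortment analysis is dyadic familiarity:
the number of days a pair of calves had been in full social contact
before the first day of barn grouping. Contact can begin at pen pairing
(for penmates), at the within-block pen merge (day 55), or when the later
of the two blocks enters the shared barn. Under the default timeline a
block-1 *P5* pair accrues 81 − 5 = 76 days, a block-1 *P28* pair 53 days,
same-block non-penmates 26 days, and any dyad involving the last block 0
days — so familiarity spans the full 0–76 day range.

Two timeline choices deserve comment, as the design was genuinely open:

* **Block spacing defaults to 3 days.** Field practice varies between
  three and five days; only the 3-day value makes the maximum familiarity
  equal 76 under the day-5 pairing and day-81 grouping used here, which
  is why it is the default. It is configurable
  (`sim_config(block_spacing_days = ...)`).
* **"First day of barn grouping" is the day the last block enters.**
  Observation of the complete group can only start then; blocks that
  share the barn earlier accrue familiarity for the overlap.

## Logger cleaning and recording-bias correction

Proximity loggers emit one *directed* record per encounter per device:
the logger's own ID, the partner ID, start time and duration. Records of
1 s are treated as unreliable chatter and dropped
(`filter_min_duration()`, threshold 2 s). Records are assigned wholly to
the week containing their start time, with half-open windows so adjacent
weeks never double-count; the alternative (truncating records at window
boundaries) changes weekly totals by well under a percent at the default
encounter scale and is not implemented.

Loggers differ in sensitivity, so the two directions of a dyad disagree.
The disagreement between loggers $a$ and $b$ is measured as
$100\,(d_{ab} - d_{ba})/\mathrm{mean}(d_{ab}, d_{ba})$ — the symmetric,
mean-based denominator makes the quantity antisymmetric and
scale-invariant, so per-logger means are interpretable. A logger's
over-recording index is the unweighted mean of this quantity over its
partners with data; the logger with the minimum index (ties broken by
ID) becomes the reference, and every other logger's row of the directed
matrix is reduced by its index relative to the reference — bias $b\%$
means multiplication by $(1 - b/100)$. Corrected directed totals are
combined by their arithmetic *mean* (not sum: both directions measure the
same encounter seconds) into the symmetric weekly association matrix
$O$.

The estimator is accurate to well under a percentage point for planted
biases of the ~10% magnitude loggers actually exhibit; for much larger
biases the mean-based percentage difference is no longer linear in the
bias ratio and the estimate is conservative. Dyads where both directions
are zero carry no information about relative bias and are skipped
(an entirely silent logger is an error, not a silent guess).

## Network statistics

**Stability** between weekly matrices is the Spearman rank correlation of
their off-diagonal strengths, tested by jointly permuting rows and
columns (node labels) of the second matrix — the quadratic assignment
procedure. The test is two-sided on $|\rho|$, since a negative
correlation would be just as noteworthy as a positive one. Which matrix
is permuted does not affect the null distribution.

**Differentiation** measures group-level heterogeneity:
$$S = \frac{\sum_i \sum_{j \ne i} (O_{ij} - E_{ij})^2}{N(N-1)},$$
where $E$ spreads the observed total association time uniformly over
ordered dyads. $S$ is zero exactly when all dyads are equal and scales
with the square of total time. Its null distribution redistributes the
total integer seconds uniformly at random over the $N(N-1)/2$ unordered
dyads (a multinomial draw, mirrored to a symmetric matrix). This is a
modelling choice — the direct operationalisation of "all individuals
associate uniformly" — and any exchangeable redistribution of seconds
would serve; calibration under this null is checked by simulation in the
test suite.

All permutation p-values use the add-one convention
$p = (k + 1)/(n_{\mathrm{perm}} + 1)$, whose attainable floor with 4999
permutations is exactly 0.0002.

**Treatment contrasts** (CV in association strength, percentage of
association time with the ex-penmate, weighted degree) are pen-averaged
and tested by one-way ANOVA with the F statistic referred to label
permutations; group means get nonparametric percentile bootstrap CIs.
The phrase "bootstrap permutations" in field usage conflates these two
operations; the only reading consistent with producing both p-values and
CIs is label permutation for the former and within-group bootstrap for
the latter, which is what `bootstrap_anova()` does. The CV uses the
sample (n−1) standard deviation. Eigenvector centrality is provided as a
redundancy check on weighted degree — on the dense, completely saturated
networks loggers produce, the two rank individuals near-identically
(rank correlation > 0.9 in the test battery) — and is not separately
tested.

## The dyadic assortment model

Association strengths are modelled on the log scale:
$$\log O_{ab} = \mu + \beta' x_{ab} + u_a + u_b + \varepsilon_{ab},$$
with fixed covariates any subset of {familiarity (days, uncentred),
different-treatment indicator} and a single **multi-membership** random
term: both members of every dyad draw from one pool of calf effects
$u \sim N(0, \sigma_u^2)$, which absorbs the non-independence of dyads
sharing a calf. The table holds each unordered dyad twice with roles
swapped, the standard layout making the fit invariant to the arbitrary
a/b labelling (verified in the tests).

Estimation is a Gibbs sampler with conjugate weakly-informative priors:
$\beta \sim N(0, 10^2)$, inverse-gamma(0.001, 0.001) on both variances.
Defaults are 6000 iterations, 1000 burn-in, thinning 5; effective sample
sizes are estimated from the autocorrelation function and a warning is
raised below 100. Reported per fixed effect: posterior mean, 95%
credible interval, and `pMCMC` — twice the smaller posterior tail mass
around zero, floored at 2/(kept samples), a pragmatic tail-area summary
for a "p"-style column. Model comparison uses the conditional-focus DIC
($2\bar D - D(\hat\theta)$ with the deviance evaluated at posterior
means of $\beta$, $u$ and $\sigma_e^2$); all four fixed-effect
combinations are fitted and the lowest DIC wins.

Zero strengths cannot occur in a saturated network but can in sparse
synthetic data; they enter as $\log(O + 1)$ and are counted in a table
attribute with a warning. With the random-effect variance pinned near
zero and flat priors the posterior means converge to least squares; on
fixtures the sampler agrees with GLS at the posterior-mean variance
components to within Monte-Carlo error.

## Pen-rearing statistics

Specific growth rate is $100 (\ln W_2 - \ln W_1)/t$ percent per day
(the defining property being that time-weighted averages over
consecutive intervals chain exactly). The respiratory score is the sum
of cough, nasal, eye and ear scores; a day is "impaired" when the faecal
score exceeds 1 or the respiratory score exceeds 0. Weaning summaries
are means over days 45–47, 48–50 and 51–53. Percentages are
arcsine-square-root transformed before parametric tests. A calf removed
from study contributes no data at all.

Multiple pairwise contrasts are corrected with the two-stage sharpened
FDR procedure (linear step-up at level $q/(1+q)$ to estimate the number
of true nulls, then a second step-up at the sharpened level); q-values
are the smallest nominal level at which the procedure rejects, found by
bisection (valid because the rejection sets are nested in $q$) and
checked against an independent grid-search oracle. Classical tests
(Friedman, Kruskal–Wallis, Mann–Whitney/Wilcoxon, ANOVA, the optional
Pillai MANOVA) are delegated to the standard `stats` routines with their
default tie handling.

## What the synthetic generator does and does not emulate

`generate_contact_stream()` draws dyadic encounters from a Poisson rate
model, $\lambda_{ab} = \lambda_0 \exp(\beta_f \cdot \mathrm{fam}_{ab} +
\beta_t \cdot \mathrm{same\ treatment})$, with lognormal durations
(heavy-tailed contact bouts, typical of proximity data), merges
encounters closer than the 120 s logger separation time, emits each
encounter as two directed records scaled by per-logger multiplicative
bias, and injects spurious 1-s records. Defaults: baseline 0.2
encounters/h/dyad and 120 s mean duration (≈4000 s per dyad-week,
consistent with a dense barn network), familiarity effect 0.02 per day
(penmates associate ≈4–5× baseline, matching the ~11% ex-penmate
pair-time the method is designed to detect), treatment effect 0 (the
emulated study found no treatment assortment), logger bias log-SD 0.05,
spurious-record rate 0.02.

`generate_rearing_data()` draws entry weights N(37.39, 5.55²) kg,
per-calf SGR N(1.06, 0.14²) %/day, ~5% impaired-health days,
per-pen vocalisation rates around the period-by-treatment means of the
emulated cohort (gamma across pens, e.g. post-weaning 109.38 / 26.08 /
45.42 calls/h for *I*/*P5*/*P28*), intake ramping to a 448 g/day
whole-trial mean, and one individually housed calf removed on day 12.

The generator reproduces the *statistical structure* the analysis
assumes — familiarity-graded rates, multiplicative logger bias, pen-level
treatment effects — but not everything real data contain: no diurnal or
spatial structure in contacts, no transitivity beyond what the rate
model induces, independent dyads given the rates, and no drift in logger
performance over time. Passing tests therefore demonstrate that the
estimators recover what they claim under their own assumptions, not that
those assumptions hold on any particular farm.

## Numerical choices and problem sizes

* Seeds: every stochastic function takes a `seed`; given one, runs are
  bit-reproducible. The pipeline derives fixed per-stage substreams from
  its top-level seed.
* Degenerate inputs: all-identical ANOVA groups return F = 0, p = 1;
  all-zero association rows make CV/pair-time `NA` with a warning;
  both-zero dyads are skipped in bias estimation; undefined classical
  test p-values (all-tied data) propagate as `NA` through the FDR step.
* Ties: reference-logger ties break lexicographically; DIC ties report a
  tie and return the first fit.
* Test problem sizes: oracle batteries use 1000 random 3–6 node
  matrices (exact equality), exhaustive enumeration at N = 5 (120 node
  relabels) and 3+3 ANOVA labels (20 assignments); calibration uses 500
  replicates at 199 permutations; end-to-end recovery uses 20 runs of a
  one-week, 0.05 encounters/h cohort with 3000-iteration chains. These
  sizes give Monte-Carlo error comfortably below the margins asserted
  while keeping the default suite quick.

## Known limitations

* The bias correction assumes a *constant multiplicative* per-logger
  bias; drifting or duration-dependent bias is not modelled.
* The differentiation null fixes only the total association time, not
  individual gregariousness; a degree-preserving null would be stricter.
* DIC is reported with conditional focus; marginal-likelihood criteria
  could rank multi-membership models differently.
* `pMCMC` is a posterior tail summary, not a frequentist p-value.
* Week windows are fixed 7-day blocks from the grouping day; encounters
  spanning a boundary count wholly toward the week they start in.
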