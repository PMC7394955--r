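---
title: "Methods: randomized natural effects by the parametric mediational g-formula"
author: "medgf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomized natural effects by the parametric mediational g-formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medgf)
```

## The causal structure

The package targets a longitudinal setting with one distal binary outcome
and three repeated processes measured at waves $t = 1, \dots, T$ ($T$ = 3 or
4): binary time-varying confounders $L_t$ (smoking, depression, optionally
self-rated health), a binary mediator $M_t$ (physical inactivity) and a
binary exposure $A_t$ (obesity, BMI $\ge$ 30 kg/m²). Baseline covariates $V$
(gender, social class, early-adult smoking and mental health in the shipped
presets) precede everything. Within each wave the causal order is fixed as

$$L_t \rightarrow M_t \rightarrow A_t,$$

i.e. inactivity is taken to be measured (and to occur) before obesity at the
same age. Two consequences follow. First, $A_t$ may influence $M_{t+1}$ but
never the concurrent $M_t$; the exposure–mediator feedback loop is handled
by g-methods rather than by a single regression. Second, there is no
mediator between final-wave obesity onset and the outcome, so for an
exposure trajectory that differs from the reference only at the final wave
the total effect is structurally unmediated: the package reports rTE alone
for such regimes and the oracle shows $\psi(\bar a, \bar a) =
\psi(\bar a, \bar a^*)$ exactly.

Exposure trajectories are deterministic regimes $\bar a$ — never obese,
incident at wave $k$, persistent — reflecting that observed obesity is
effectively absorbing (reversion is rare), which is also why subjects are
classified by wave of first onset only.

## Estimand: randomized interventional analogues

For regimes $\bar a$ (outcome stream) and $\bar a'$ (mediator stream),

$$\psi(\bar a, \bar a') = \mathbb{E}_V\!\left[\;\sum_{\bar m}
P(\bar M = \bar m \mid \bar A = \bar a', V)\;
\mathbb{E}\{Y \mid \bar A = \bar a, \bar M = \bar m, V\}\;\right],$$

where the mediator law is *interventional*: it conditions on baseline
covariates only, marginalizing over the confounder paths that would arise
under $\bar a'$. With reference $\bar a^*$ (never obese),
rTE $= \psi(\bar a,\bar a)/\psi(\bar a^*,\bar a^*)$,
rNDE $= \psi(\bar a,\bar a^*)/\psi(\bar a^*,\bar a^*)$,
rNIE $= \psi(\bar a,\bar a)/\psi(\bar a,\bar a^*)$, and
rTE $=$ rNDE $\times$ rNIE holds exactly because the three ratios share the
same $\psi$ evaluations. Randomized-interventional analogues were chosen
over natural effects because they remain identified under exposure-induced
mediator–outcome confounding, which is intrinsic here ($A_t$ affects
$L_{t+1}$ and $M_{t+1}$).

Identification additionally assumes no unmeasured confounding of the
exposure–outcome, mediator–outcome and exposure–mediator relations given
measured history, correct parametric model specification, consistency and
no interference. None of these is testable from the data.

Whether the mediator draw should condition on $V$ only or on richer history
is a genuinely open design point; $V$-only is the standard
randomized-interventional construction and is what the enumeration oracle
implements, so the two routes are directly comparable.

## Estimation

**Models.** One maximum-likelihood logistic regression per time-varying
confounder per wave, per mediator per wave, and for the outcome, each with
main effects of the full measured history permitted by the ordering (no
interactions, no pooling across waves). This is the smallest specification
consistent with a "parametric" g-formula; richer specifications would trade
bias for variance at the cohort sizes involved (~2 400–8 700). Fits use
IRLS (`stats::glm.fit`) with score tolerance $10^{-8}$ and an iteration cap
of 100; zero-variance responses, rank deficiency, non-convergence and
likely separation (any $|\hat\beta| > 20$) raise errors naming the model —
nothing is silently penalized.

**Monte Carlo g-computation.** `simulate_psi()` draws `n_mc` *total*
trajectories, recycling the observed baseline rows in a balanced cycle so
every subject's $V$ enters equally often (with `n_mc` a multiple of $n$,
each subject is used exactly `n_mc`$/n$ times; no resampling within a point
estimate). Each trajectory runs two independent streams: stream 1 simulates
$L'_t, M'_t$ forward under $\bar a'$ and records $\bar m$; stream 2
re-simulates $L_t$ under $\bar a$ with $\bar M$ fixed at $\bar m$ and
evaluates the fitted outcome probability (the Bernoulli draw of $Y$ itself
is integrated out, a standard variance-reduction step). The estimate is the
grand mean; its Monte Carlo standard error is attached as an attribute.

**Uncertainty.** `bootstrap_effects()` resamples subjects with replacement,
refits all models and recomputes all effects per replicate on an
independent RNG substream; SE = sd of replicate estimates and the 95% CI is
the symmetric normal interval (matching how such intervals are
conventionally reported). Replicates that fail to fit are dropped and
counted; more than 10% failures aborts with the count, since silent
dropping at higher rates would bias the SE.

**Reproducibility.** All randomness derives from one user seed through
named substreams (`derive_seed(seed, key)`): one per $\psi$ evaluation
(keyed by the regime pair), one per bootstrap replicate index. Results are
therefore invariant to the order in which regimes are evaluated, and
identical configuration + seed gives byte-identical pipeline outputs.

## Tunable parameters

| Parameter | Default | Meaning / guidance |
|---|---|---|
| `threshold` | 30 kg/m² | obesity cutoff, boundary inclusive |
| `centile` | 10 (%) | gender-specific poor-functioning cutoff; the threshold is the smallest observed score whose cumulative proportion reaches the centile, so flags are $\ge$ 10% and ties inflate, never deflate |
| `n_mc` | 10 000 | total simulated trajectories per $\psi$; MC SE on a risk of 0.1–0.3 is $\approx \sqrt{\psi(1-\psi)/n_{mc}}$ — 20 000 halves it relative to 5 000 |
| `n_boot` | 500 | bootstrap replicates; 200 is adequate for 95% normal CIs when time-constrained |
| `waves_used` | all | prefix $1..K$ of analysis waves; $K = T-1$ reproduces the omit-last-wave sensitivity analysis without changing the algorithm |
| `stratify_by` | none | per-gender runs (gender removed from the covariate set in strata) |

## The exact oracle

For all-binary structural models, `exact_psi()` evaluates the mediational
g-formula by full enumeration: per baseline configuration it sums the
mediator-trajectory law under $\bar a'$ over all confounder paths
(asserting the law sums to 1 within $10^{-10}$), then the expected outcome
under $\bar a$ over a second, independent confounder stream. Enumeration
order matches the simulator (waves outer, $L \rightarrow M \rightarrow A$
within wave) so the two code paths cross-check each other. Configurations
are indexed by the bits of an integer vector, keeping memory at a few
numeric vectors; a guard rejects state spaces beyond $2^{22}$
configurations. Baseline covariates are independent Bernoulli in the oracle;
dependence among observed baselines is handled empirically by the estimator
(which conditions on observed rows), not by the oracle.

## The synthetic generator and its presets

`generate_cohort()` simulates complete cohorts from a structural model in
the declared ordering and emits, besides the binary history, a binary
structural outcome `y`, per-wave BMI consistent with the obesity flags, and
an integer-rounded 0–100 functioning score (linear in final-wave history
plus Gaussian noise, sd 8, lower = worse) so the centile dichotomizer is
exercised with realistic ties. Presets are version-controlled YAML files,
inspectable and editable without touching code:

* `nshd-like` (4 waves) and `ncds-like` (3 waves) were calibrated by exact
  enumeration so that gender-specific obesity marginals rise from ~6% to
  ~30% (4-wave) / ~11% to ~23% (3-wave) with persistence
  $P(A_t = 1 \mid A_{t-1} = 1) \ge 0.95$, inactivity sits in the 30–65%
  band and is higher among the obese at every wave, and both a direct and a
  mediated positive pathway to poor functioning exist. Baseline confounder
  prevalences are round documented values (e.g. 48% male, 30% low social
  class), since the source descriptive detail for those variables is not
  reproduced here.
* `null-mediation`, `no-direct-effect` and `toy-mediation` are two-wave,
  one-confounder fixtures for null recovery, pathway isolation and
  oracle-equivalence/coverage checks.

What the presets emulate is *marginal structure only*. They do not attempt
the restricted cohorts' joint distributions, item-level SF-36 scoring,
missing data, attrition, or measurement error; passing tests therefore
demonstrate that the estimator recovers known truths under a correctly
specified, complete-data generating process — not that any particular
published effect size is reproduced.

## Numerical and testing choices

* Ties at the outcome centile follow the $\le$-threshold rule on observed
  scores (integer thresholds arise naturally); the alternative
  software-quantile convention is not used because observed-score
  thresholds are what descriptive tables report.
* Categorical association-stage covariates use their most frequent level as
  reference (stable under resampling); constant covariates are dropped from
  adjustment sets, which leaves estimates invariant.
* Test problem sizes are the package's own choices balancing resolution
  against runtime: oracle equivalence uses $n_{mc} = 10^5$ (3-binomial-SE
  tolerance), null recovery averages 32 independent cohorts of $n = 5000$
  (a single run has effect-sd $\approx 0.046$, so the $\pm 0.03$ check is
  powered on the mean; the pathway check's $\pm 0.05$ band needs only 12),
  and bootstrap coverage uses 100 cohorts of $n = 1000$ with
  $n_{boot} = 200$, $n_{mc} = 5000$ against the exact rTE.

## Known limitations

* Complete-data contract: rows with missing analysis values are rejected;
  multiple imputation is upstream of this package.
* Binary variables throughout the causal machinery; continuous mediators or
  survival outcomes are out of scope, as are natural (non-randomized)
  effects and exposure–mediator-interaction decompositions.
* Main-effects logistic models; misspecification bias is not diagnosed
  internally.
* The oracle is limited to state spaces $\le 2^{22}$, so the 4-wave presets
  are validated via exact marginal enumeration and scaled-down exact-effect
  models rather than direct 4-wave enumeration.
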