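---
title: "Methods: strategies, displays, synthetic cohorts and the statistical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strategies, displays, synthetic cohorts and the statistical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopsignal)
```

## The setting

Two players repeatedly face a prisoner's dilemma with payoffs
$T > R > P > S$ (here $7 > 5 > 3 > 2$): mutual cooperation pays $R$ each,
mutual defection $P$, and unilateral defection $T$ against $S$. A
*memory-one* strategy is a vector $p = (p_{CC}, p_{CD}, p_{DC}, p_{DD})$ of
cooperation probabilities conditioned on the previous round's outcome
(own move first), plus a first-round move. Everywhere in this package,
4-vectors indexed by outcome use the fixed order $CC, CD, DC, DD$.

`coopsignal` models a behavioral experiment in which human participants
play 20 rounds against computer counterparts that (i) follow one of two
zero-determinant strategies — extortion or generosity — and (ii) display
outcome-contingent facial expressions under a cooperative or competitive
orientation. The package provides the strategy algebra, the match engine,
the display policy, a synthetic-cohort generator, and the complete
statistical pipeline such an experiment's analyses require, so the whole
chain is testable end to end without human data.

## Zero-determinant algebra

Following Press and Dyson, write $\tilde p = (p_{CC}-1,\, p_{CD}-1,\,
p_{DC},\, p_{DD})$, and let $S_X = (R, S, T, P)$ and $S_Y = (R, T, S, P)$
be the two players' payoff vectors over outcomes. A strategy is
zero-determinant (ZD) when

$$\tilde p = \alpha S_X + \beta S_Y + \gamma \mathbf{1},$$

in which case it unilaterally enforces $\alpha s_X + \beta s_Y + \gamma = 0$
between the long-run per-round payoffs, i.e.
$s_X - \ell = \chi\,(s_Y - \ell)$ with baseline
$\ell = -\gamma/(\alpha+\beta)$ and slope $\chi = -\beta/\alpha$.

* `make_zd(ell, chi, phi)` constructs
  $\tilde p = \phi\big[(S_X - \ell) - \chi (S_Y - \ell)\big]$ and rejects
  parameter sets that push any probability outside $[0,1]$ (closed
  interval, no epsilon slack).
* `zd_certificate()` solves the 4-equation, 3-unknown system by least
  squares and reports the maximum absolute residual. We certify via the
  residual rather than the determinant identity because it is numerically
  transparent and quantitative; the determinant form
  $\det[\tilde p \mid S_X \mid S_Y \mid \mathbf 1] = 0$ is kept as an
  independent oracle in the test suite. The default tolerance $10^{-6}$
  suits exactly specified vectors. When $\alpha + \beta = 0$ (e.g.
  tit-for-tat, $\chi = 1$) the baseline is undefined and reported `NA`.
* `zd_complete()` treats one missing entry as a fourth unknown, making the
  system square; the three known outcomes pin $(\alpha, \beta, \gamma)$ and
  the remaining row determines the entry uniquely (a singular 3×3 block
  raises a no-unique-completion error).

The two task strategies under $(T,R,P,S) = (7,5,3,2)$ are

* **extortion** $(9/13,\, 0,\, 7/13,\, 0)$, first move D, enforcing
  $s_X - P = 3 (s_Y - P)$, and
* **generosity** $(1,\, 2/11,\, 1,\, 4/11)$, first move C, enforcing
  $s_X - R = 3 (s_Y - R)$.

Probabilities printed to three decimals (0.692, 0.538, 0.182, 0.364) are
decimal roundings of these rationals; `paper_strategy()` snaps inputs
within $5 \times 10^{-4}$ of such a rational to the exact value so that
downstream identities hold at machine precision.

### Long-run outcome distributions

Two memory-one strategies induce a 4-state Markov chain over outcomes.
`stationary_distribution()` returns the unique stationary vector when the
chain has a single recurrent class (rank test on $M^\top - I$). With
deterministic entries the chain can be reducible; the function then
returns the Cesàro (long-run average) distribution from the state given by
the two initial moves, computed *exactly*: closed communicating classes of
the support graph, each class's stationary vector, and the absorption
probabilities from the start state. This keeps results exact for cases
like tit-for-tat against itself, where the initial moves decide the
long-run outcome. `expected_payoffs()` contracts the distribution with
$S_X$ and $S_Y$; `simulate_outcome_freq()` is the Monte-Carlo counterpart
with batch-means standard errors (batching absorbs the chain's
autocorrelation) and backs the oracle-equivalence tests.

## Emotion display policy

The counterpart reacts to each outcome (encoded from its own perspective,
so $DC$ = "I exploited the participant") with one of four expressions.
The cooperative orientation signals joy after mutual cooperation and
regret after exploiting; the competitive orientation swaps exactly those
two cells; both show anger after being exploited and neutral after mutual
defection. The two orientations are therefore distinguishable only after
$CC$ or $DC$ outcomes — a property test generates matches containing only
$CD$/$DD$ outcomes and asserts identical display streams. No expression
precedes round 1.

## The synthetic cohort generator

`generate_cohort()` emulates the experiment's data structure: a
2 (strategy) × 2 (display orientation) between-participants design with
`n_per_cell` = 85 participants per cell (the study-scale recruitment
target) and 20 rounds each. The counterpart side is exact: moves follow the
cell's ZD strategy (initial move included) and expressions follow the
cell's orientation policy. The participant side is a logistic
memory-one-with-covariates choice model,

$$\Pr(C_{it}) = \mathrm{logit}^{-1}\big(b_0 + b_{strat}\,[\mathrm{gen}]
 + b_{emoG}\,[\mathrm{gen,coop}] + b_{emoE}\,[\mathrm{ext,coop}]
 + b_{recip}\,[\text{co-player C at } t{-}1]
 + b_{expect}\,\tfrac{e_{i,t-1}-50}{50}
 + b_{first}\,[t{=}1] + b_{last}\,[t{=}k] + u_i\big),$$

with participant random intercept $u_i \sim N(0, \sigma_u^2)$. No
participant model is claimed to be *the* true human model; its only
contract is to reproduce the qualitative structure the analyses test:

* a strategy effect much larger than the emotion effect, and an emotion
  effect confined to generosity ($b_{emoE} = 0$ by default);
* cooperation starting high in round 1, stabilizing lower, and dropping
  again in the final round;
* reciprocity toward a counterpart that cooperated last round;
* condition effects that run through expectations.

Mediators: after each round the participant reports an expectation of
counterpart cooperation on a 0–100 scale (the response format is not fixed
by the experimental literature we model; a 0–100 slider is assumed),

$$e_{it} = \mathrm{clip}\big(a_0 + a_{exp}\,\bar q_{it} + a_{emo}\,
[\text{cooperative display}] + v_i + \varepsilon_{it},\ 0,\ 100\big),$$

where $\bar q_{it}$ is the counterpart's cooperation frequency so far,
$v_i \sim N(0, \sigma_{between}^2)$ is a stable rater bias (some people
are persistently more optimistic), and $\varepsilon_{it}$ is round-level
noise. The self-reported emotion is a softmax draw over joy, sadness,
anger, regret and neutral whose joy log-odds increase with the
participant's own round payoff. Post-task 1–7 ratings (mental demand,
display genuineness) come from condition-dependent latent normals, rounded
and clamped; defaults have genuineness higher under generosity, and higher
for cooperative displays only there.

The $b_{expect}$ term matters beyond realism. The mediation analyses
presuppose a causal path from expectations to choices; without it, any
condition effect reaches cooperation around the measured mediator and no
generator configuration can make the direct effect vanish. The term also
exposes a structural subtlety: when expectations load on the counterpart's
*realized* cooperation ($a_{exp} > 0$) against a responsive memory-one
counterpart, the mediator is endogenous — the participant's own random
moves shift the counterpart's behavior and hence the mediator, inflating
the mediator-outcome slope and biasing the OLS direct effect negative.
This is a genuine property of such designs, not an implementation
artifact. The test suite therefore checks *exact* recovery (indirect
effect detected, direct effect's CI covering zero) on a configuration
whose mediator path is exogenous (the display-orientation loading
$a_{emo}$, with $a_{exp} = 0$ and an $a_0$ offset keeping ratings off the
scale bounds), and checks the $a_{exp} > 0$ configuration for indirect
detection only.

**Calibration.** Defaults were calibrated once, by simulation, so that the
strategy effect on cooperation rate has partial $\eta^2 \approx 0.2$ at
study scale (the benchmark the design targets), with the emotion effect an
order of magnitude smaller ($\approx 0.025$); the shipped
`inst/extdata/default_cohort.yml` records this configuration, and a test
asserts the calibration within $\pm 0.08$ over 20 seeds.

**What passing tests do not show.** The generator reproduces the moment
structure the statistical pipeline consumes — cell means, round profiles,
mediator correlations — under clean parametric noise. Real participants
bring heavy-tailed heterogeneity, inattention, comprehension failures and
drop-out (the study excluded 19 of 340 recruits), none of which are
modeled. Passing tests validate the *pipeline*, not any claim about human
behavior.

## The statistical pipeline

All procedures are implemented from first principles on base-R numerical
primitives, with established implementations used as independent oracles
in the tests (`car::Anova` for Type III sums of squares and sphericity
epsilons, `stats::t.test` for the pooled t test, direct noncentral-F
simulation for power).

* **Two-way ANOVA** (`anova_two_way`): Type III sums of squares via model
  comparison on a sum-to-zero-coded design matrix. The study's cells are
  unbalanced (74/80/82/85); Type III matches the convention of the
  commercial packages standard in this literature. Partial
  $\eta^2 = F\,df_1 / (F\,df_1 + df_2)$ is emitted per row and its
  identity with $SS_{eff}/(SS_{eff}+SS_{err})$ is asserted on every table.
  Pairwise cell comparisons use the pooled MSE with Bonferroni adjustment
  by multiplication, capped at 1.
* **Planned synergistic contrast** (`planned_contrast`): the triangular
  pattern "one cell above the other three" with default weights
  $(+3, -1, -1, -1)$ and $t = \sum w_j \bar y_j \big/ \sqrt{MSE \sum
  w_j^2/n_j}$. The error term defaults to the pooled within-cell MSE with
  $N - 4$ df, but both are caller-overridable: published contrast dfs in
  this literature are not always derivable from the omnibus error term, so
  the df policy is exposed rather than guessed.
* **Mixed ANOVA** (`mixed_anova`): split-plot decomposition with the
  between-subject tests on round means and the within-subject tests on an
  orthonormal contrast transformation (Type III throughout, so unbalanced
  cells are handled). Sphericity: Greenhouse–Geisser
  $\hat\varepsilon = (\mathrm{tr}\,S)^2 / \big((k-1)\,\mathrm{tr}\,S^2\big)$
  from the residual covariance of the transformed responses, then the
  Huynh–Feldt small-sample adjustment (Lecoutre-corrected form, as in
  base R and car), capped at 1. Corrected dfs are
  $\varepsilon \times$ the uncorrected dfs; a two-level within factor
  forces $\varepsilon = 1$. Missing rounds are an error — no imputation.
* **Multiple mediation** (`multiple_mediation`): OLS paths
  ($a_j$: condition → mediator; $b_j, c'$: mediators + condition →
  outcome; $c$: condition → outcome), indirect effects $a_j b_j$, and the
  exact decomposition $c = c' + \sum_j a_j b_j$. Confidence intervals are
  percentile bootstrap over participants (5,000 resamples by default,
  seeded and reproducible); percentile rather than BCa because the
  procedure we mirror specifies only bootstrap intervals, and percentile
  is the transparent default. Condition coding is explicit
  (`code_one`), since reported mediation signs depend on it. Mediators
  enter as per-participant aggregates: the mean expectation rating and the
  proportion of rounds each emotion was reported — the natural unit for a
  between-subjects analysis of 20-round blocks.
* **Power analysis** (`power_sample_size`): smallest total $N$ such that
  the fixed-effects F test with numerator df 1, denominator df $N - 4$,
  and noncentrality $\lambda = f^2 N$ (Cohen's convention) reaches the
  target power; an upward scan, exact noncentral-F tails, no
  approximations. The planning scenario $f = 0.20$, $\alpha = 0.05$,
  power $0.95$ returns $N = 327$.

P-values everywhere come from exact F/t distributions.

## Numerical choices and degenerate inputs

* Probabilities live in the closed interval $[0,1]$; validation has no
  epsilon slack.
* ZD certification tolerance defaults to $10^{-6}$; `is_zd` is a verdict,
  not an error — inconsistent systems simply report their residual.
* Zero error variance (constant responses within cells) and zero pooled
  variance are errors, as the corresponding tests are undefined.
* Collinear mediators are rejected by name (QR rank check) before any
  bootstrap work.
* One seeded generator drives each simulated match; draws are consumed in
  round order, focal player first, so equal seeds give bitwise-equal
  records. The cohort generator draws round-by-round across the
  participant vector under a single seed; the same config is byte-identical
  across runs.

## Problem sizes used in the tests

The suite runs study-scale cohorts (340 participants × 20 rounds) for the
calibration and pipeline checks, $10^6$-round chains for the 20
stationary-vs-simulation oracle comparisons, 200 seeds for null bootstrap
CI coverage (300 resamples each at n = 120), and 100 seeds of an 800
participant zero-effect generator for type-I calibration of the ANOVA
(α = 0.01) and planned contrast (α = 0.05). These sizes give Monte-Carlo
standard errors small enough that each assertion's band (3 SE, or
α + 2·MCSE) is meaningful while the full suite stays in the minutes range.

## Known limitations

* The generator's participant model is a convenience: logistic, memory-one,
  homogeneous coefficients. It is not fit to any human dataset.
* OLS mediation on designs with responsive counterparts inherits the
  endogeneity discussed above; the package reports what OLS reports.
* The planned contrast's error-term policy is exposed but the package
  takes no position on which published convention is "right".
* Strategies with memory greater than one, evolutionary dynamics, and
  population tournaments are out of scope.
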