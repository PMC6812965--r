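---
title: "Modeling feedback-contingent choice in competitive matching-pennies play"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling feedback-contingent choice in competitive matching-pennies play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxrabbit)
```

## The scientific problem

In a zero-sum competitive game, a player profits from two conflicting
abilities: exploiting any predictability in the opponent, which requires an
internal *model* of the opponent's behaviour, and remaining unpredictable,
which favours *memory-free, stochastic* choice. `foxrabbit` implements the
analysis pipeline for a rule-selection variant of matching pennies (the
"fox/rabbit" game): on every trial each player picks one of two response
rules; the fox wins when both picked the same rule, the rabbit when they
differed. Opponents are either simulated agents that switch rules from one
trial to the next with a fixed probability (e.g. 20/35/50/65/80%), or a
second model-governed player (dyad mode).

The player's *switch rate* — the probability of choosing a different rule
than on the previous trial — is the behavioural lens: a model-based player
tracks the opponent's switch rate (switching along with a frequent switcher
after wins, holding after losses, and vice versa for rare switchers), a
memory-free player sits at 0.5 regardless of the opponent, and lower-level
biases (perseveration, win-stay/lose-shift) push the rate around
unconditionally.

## The choice model

The switch probability is a logistic function of four parameters. With
$os = \ln(p_{os}/(1-p_{os}))$ the log-odds of the opponent's switch rate and
$wl \in \{+1, -1\}$ the previous trial's feedback (action errors count as
losses), the switch log-odds are

$$\mathrm{logit}\, P(\text{switch}) =
  wl \cdot os \cdot \left(ms + sm\,\frac{1 - wl}{2}\right) - pe - wl \cdot ss.$$

* **ms** (model strength) is the post-win slope on the opponent log-odds
  axis; $ms = 1$ is exact probability matching, $ms > 1$ a maximizing
  tendency.
* **sm** (strategy mix) shifts the slope on post-loss trials: on the
  *reversed-label* axis (post-loss opponent rates relabelled $p \to 1-p$)
  the post-loss slope is $ms + sm$, so $sm < 0$ means the opponent model is
  suppressed after losses and $sm = -ms$ wipes it out, leaving the flat
  post-loss probability $\mathrm{logis}(-pe + ss)$.
* **pe** (perseveration) is an unconditional repeat bias.
* **ss** (win-stay/lose-shift) biases towards repeating after wins and
  abandoning after losses.

The published rendering of this equation is typographically garbled; the
form above is the package's reconstruction, chosen so that (i) probability
matching corresponds literally to $ms = 1$, (ii) the post-loss
reversed-label slope is $ms + sm$ with $sm \approx -ms$ eliminating the
model after losses, and (iii) the perseveration and win-stay/lose-shift
terms enter with the conventional signs. All three anchors are asserted in
the test suite.

```{r}
th <- choice_params(ms = 0.48, sm = -0.38, pe = 0.21, ss = 0.20)
predict_condition_grid(th, c(0.2, 0.5, 0.8))
```

## Estimation

Two estimators are provided, mirroring the two ways the data are summarised:

* `fit_condition_averages()` fits the model to the mean switch rate per
  (opponent rate × post-win/post-loss) cell by least squares. The optimiser
  is a Nelder–Mead simplex started at $(0.5, -0.3, 0.1, 0.2)$ with five
  seeded jittered restarts (best objective wins), followed by a BFGS
  polish; on noise-free grids this inverts the model to better than
  $10^{-4}$ per parameter. Cells are unweighted by default because the
  design balances trial counts; weighting by cell $n$ is available. $R^2$
  is computed about the grand mean of the observed cells.
* `fit_trialwise()` maximises the Bernoulli likelihood of the observed
  switch/repeat sequence. Because the model is linear in its four
  parameters on the logit scale, the likelihood is maximised exactly by a
  binomial GLM on the design columns $wl \cdot os$,
  $wl \cdot os (1-wl)/2$, $-1$, $-wl$; standard errors come from the
  observed information. First trials of each block carry no feedback or
  switch indicator and are excluded everywhere. Degenerate sequences
  (all-switch/all-repeat) and rank-deficient designs (e.g. constant
  feedback, or $p_{os} = 0.5$ making $os = 0$) are flagged, not hidden.

For dyads there is no programmed opponent rate, so
`running_opponent_switch_rate()` supplies the per-trial estimate: within a
block, the running mean of the partner's observed switches using only
trials before the current one; each block starts from the previous block's
final value (0.5 for the first), carried over as a single
pseudo-observation. A symmetric smoothing count of 0.5 successes and 0.5
failures keeps the estimate strictly inside $(0,1)$ — its log-odds must
stay finite. Whether the carried-over value should weigh more than one
pseudo-observation is not determinable from the source material; the
smoothing weight is exposed as an argument and one pseudo-observation is
the default.

### Uncertainty

Condition-average fits report residual-bootstrap 95% intervals (199
resamples, seeded). Residuals are centred and scaled by
$\sqrt{n/(n-p)}$ before resampling: raw residuals from a 4-parameter fit to
ten cells under-disperse, which makes naive intervals anti-conservative.
Even so, two caveats are inherent and documented rather than patched over:
with only ten cells the interval is a small-sample bootstrap and covers
slightly below nominal rate, and the *group-average* fit of a heterogeneous
cohort carries an aggregation bias (the mean of logistic curves is not the
logistic curve of the mean parameters — visible in the recovery audit of
`analysis/05_recovery.R`, most strongly for `sm`). Trialwise fits report
Wald intervals. The published "±" intervals are produced by an unspecified
procedure; the package makes no claim to match them numerically.

## The simulator

`simulate_session()` is a closed-loop generator: opponents switch with a
fixed per-block probability, independent of the player; the player's switch
probability on each trial is the model evaluated at the block's opponent
rate and the previous trial's feedback; the first trial of every block is a
uniform draw. Defaults emulate the baseline design — ten 80-trial blocks
crossing five opponent switch rates (20/35/50/65/80%) with fox/rabbit
roles, randomly ordered. An EEG-style design uses three rates
(25/50/75%); a simple-choice mode relabels rules up/down and forces the
error rate to zero; a random-feedback mode replaces outcomes with a fair
coin.

Action errors are an independent Bernoulli process (default rate 0.05, a
typical value for speeded rule-selection tasks); an error trial always ends
in a loss. Error trials keep the *intended* rule on record and switch
indicators are computed from intended rules, so the error process adds
outcome noise without corrupting the choice sequence; how errors should
enter switch sequences is not specified by the source material, and this
choice is the package's own. RTs are lognormal (median 600 ms, sdlog 0.3)
and play no causal role; they exist so the stochasticity-vs-noise control
has something to control for.

`simulate_cohort()` draws per-subject parameters from independent
Gaussians, by default centred on the group estimates typical for the
baseline design (0.48, −0.38, 0.21, 0.20) with SDs (0.15, 0.12, 0.08,
0.08) — spreads chosen once to produce the kind of between-subject
variability the individual-fit columns of the source study imply, including
occasional sign reversals of the bias terms. Per-subject seeds derive
deterministically from the master seed, so cohorts are byte-reproducible.

`simulate_dyad()` couples two model-governed players; each treats the
running estimate of the partner's switch rate as its opponent rate, making
the loop fully closed. Outcomes are strictly zero-sum. If both players
would commit an action error on the same trial, one of the two flags is
kept at random: this preserves both invariants exactly (zero-sum, error ⇒
loss) at the cost of a marginal error rate of $e - e^2/2$, negligible at
realistic $e$. Note that a dyad log records the partner's error in
`opponent_action_error`, since a partner's error hands the player a win
that the rule-match bookkeeping alone cannot explain.

### Synthetic feedback-locked epochs

`simulate_neural_epochs()` generates one signal time course per trial on a
−200…1050 ms grid (50 ms step), aligned to feedback onset:

$$y(t) = \mathrm{ERP}_{wl}(t) + \sum_k \beta_k(wl, t)\, x_k + b_{subj} +
  \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$

where the context variables $x_k$ are the opponent's overall switch rate
(standardized), the opponent's and player's current-trial switch
(effect-coded ±1), and the rate × switch product. Coefficient time courses
ramp up by 300 ms, hold to 700 ms, and decay; after losses they are
additionally ramped to zero starting at a configurable latency (default
400 ms) — information initially present, then suppressed. The default
noise SD of 4 (signal units, against embedded amplitudes of order 1)
reflects single-trial signal-to-noise typical of feedback-locked scalp
potentials. The generator emulates exactly the linear structure the
analyses assume: no sensor geometry, no artifacts, no autocorrelated noise,
no nonlinear coupling. Passing recovery tests therefore validates the
estimators, not the realism of scalp electrophysiology.

## Behavioural analyses

* `condition_switch_rates()` tabulates the empirical condition grid.
* `reversed_label_slopes()` is the core contrast. Comparing raw post-win
  and post-loss slopes conflates a sign flip (model-based in both states)
  with flattening (stochastic after losses), so post-loss opponent rates
  are relabelled $p \to 1-p$ first; then equal slopes mean an intact model
  and a shallower post-loss slope means suppression. Slopes are computed
  per subject on the proportion scale over condition means (least
  squares), and the win/loss × rate interaction is tested in a mixed model
  over subject-condition cells. The full random-slope structure is
  attempted first and simplified stepwise on singular or non-converged
  fits, with the final structure logged — full structures routinely fail
  at realistic cohort sizes.
* `history_regression()` fits the 15-predictor multilevel logistic model:
  opponent overall rate, opponent and player switch history at lags 1–3,
  the win/loss contrast, and contrast × predictor interactions, with
  continuous predictors z-scored and binary ones effect-coded within the
  fitted subset. With label reversal, opponent predictors are sign-flipped
  on post-loss rows; player predictors only where separate post-win and
  post-loss fits show an empirical sign flip. Dyad data add a third level
  (players within dyads).
* `stochasticity_vs_noise()` asks whether loss-induced flattening is mere
  noise: absolute slopes are regressed on the win/loss contrast with
  subject-centred RT and error rate as within-subject covariates. If
  stochastic choice were general processing noise, the contrast should
  vanish under these controls.
* `success_regression()` regresses each player's win proportion on
  $ms, sm, |pe|, |ss|$ with a random intercept per experiment or dyad.
  Absolute values for the bias terms, because a bias in either direction is
  exploitable.

## Signal analyses

`timepoint_context_regression()` fits, per time point and feedback
condition, a two-level regression (trials within subjects, random
intercept) of the baselined signal on the four context variables;
standardized coefficients z-score signal and predictors within the
feedback subset. Whether the original analyses used random slopes per
subject is unknowable from the text; random intercepts are the default and
escalation is a one-argument change. `window_average()` reduces epochs to
the a-priori 300–700 ms feedback window.

`ppi_analysis()` is the two-step interaction test: step 1 regresses the
window signal on the context variables and keeps the residuals — finally
projected onto the orthogonal complement of the step-1 design, so the
residual is *exactly* uncorrelated with the context variables rather than
approximately so under the mixed model; step 2 predicts the next trial's
switch from context, residual, and residual × context terms in a
multilevel logistic model. A significant residual × context term means
trial-to-trial fluctuations of context information in the signal modulate
how context drives the upcoming choice.

`individual_difference_correlations()` correlates per-subject window
coefficients with per-subject slopes and win rates, and contrasts post-win
against post-loss correlations with the Meng–Rosenthal–Rubin z test for
dependent correlations sharing one variable — the "Steiger-family" test;
the original analyses name none, so the choice is documented in the
output.

Label reversal in the signal analyses flips the opponent-related
predictors (A, B) on post-loss rows; their product A×B is invariant under
the double flip. Whether the player predictor C should also flip is
knowable only from empirical sign flips, so both signed
(`reverse_labels = FALSE`) and reversed variants are available.

## Numerical choices and degenerate inputs

* Opponent rates at exactly 0 or 1 are a domain error for the model (their
  log-odds are infinite) but legal for the opponent generator, where they
  mean a constant or strictly alternating opponent.
* Condition fits refuse grids with fewer than four cells; duplicated
  (rate × feedback) cells are an error; empty cells are dropped with a
  warning.
* The mixed-model fallback ladder never fails silently: the structure
  actually used is part of every result object.
* The PPI drops residual-interaction terms with a notice when the step-1
  residual variance is ~0.
* Correlations over zero-variance inputs are reported as `NA`, not 0.

## Problem sizes

The test suite and the acceptance script run cohorts of 3–40 subjects with
6–12 blocks of 40–80 trials and 10–50 seeded replicates per experiment —
sizes chosen so every distributional claim is checked against its own
Monte-Carlo error at desk scale. The analysis scripts under `analysis/`
default to the 40-player / 20-dyad study scale.

## Known limitations

* The synthetic epoch generator shares its linear structure with the
  analysis model; it cannot reveal misspecification of that structure.
* Group-average condition fits of heterogeneous cohorts are mildly biased
  (aggregation); per-subject fits averaged afterwards are the cleaner
  cohort summary, and the recovery audit quantifies the difference.
* The dyad generator's players are stationary model-followers; real dyads
  adapt their parameters over time.
* No reinforcement-learning competitor models, no Bayesian estimation, and
  no model-selection criteria beyond $R^2$ and log-likelihood are
  provided.
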