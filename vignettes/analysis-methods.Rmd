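---
title: "Models and methods behind probepref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind probepref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

probepref analyses two behavioural paradigms used to probe cognitive biases
in great apes: a **dot-probe task**, where two face stimuli appear briefly
and a probe replaces one of them — faster responses to the probe indicate
which stimulus was being attended — and a **two-alternative preference
task**, where a subject repeatedly chooses between two colour-coded options
that stand for two stimulus categories (flanged vs unflanged male faces).
This vignette explains the statistical models, the choices that were open,
and what the simulation-based tests do and do not establish.

## Reaction-time filtering

Two exclusion rules are applied per subject (and per task):

* **Anticipatory responses**: RT < 200 ms. These are faster than a
  plausible perception–action loop and are treated as guesses.
* **Slow outliers**: RT above `median + 2.5 × MAD`, with the MAD scaled by
  the normal-consistency constant 1.4826. The threshold is robust: a single
  slow trial cannot drag it upward the way a mean ± SD rule would.

Two details are genuinely open and are fixed as follows. First, the MAD
convention: `mad_upper_threshold()` defaults to the scaled MAD (the
`stats::mad()` default and the convention of the robust-outlier literature
this rule comes from), and exposes `constant = 1` for the raw MAD. Second,
the ordering of the two rules: thresholds are computed on the subject's
full submitted batch *before* removing sub-200 ms trials (the conservative
reading), with `fast_first = TRUE` available to compute them after.

Excluded trials are re-run once in subject-specific repetition sessions and
the same criteria are applied again (`merge_repetitions()`); trials excluded
in both rounds are lost. The accounting (`filter_report`,
`combine_filter_reports`) always satisfies
`collected = fast + slow + retained`, which the test suite property-checks
on random tables.

## Per-subject robust dot-probe regression

With three subjects, pooling would hide individual differences, so one model
is fitted per subject and task. The response is the subject's mean-centred
RT in ms; predictors are Congruence (probe behind the hypothesised
attention-grabbing stimulus) and Probe location, both sum-coded ±1
(congruent = +1, left = +1), with a session-varying intercept:

$$\mathrm{rt}^c_i \sim \mathrm{Student}\text{-}t\!\left(\nu,\;
  \beta_0 + \beta_c C_i + \beta_l L_i + u_{s(i)},\; \sigma\right),
  \qquad u_s \sim \mathcal N(0, \sigma_s^2).$$

Under ±1 coding a coefficient is the deviation from the grand mean, so the
congruent-minus-incongruent difference on the condition scale is $2\beta_c$
(`contrast_draws()` implements exactly this algebra).

Priors: $\beta_0 \sim \mathcal N(0, 5)$ (the response is centred, so the
intercept is a small deviation), $\beta \sim \mathcal N(0, 10)$ (weakly
regularising on the ms scale), $\nu \sim \mathrm{Gamma}(\text{shape } 2,
\text{rate } 0.1)$, and half Student-t(3) priors on all scale parameters.
Two prior readings deserve a note:

* The Gamma prior on $\nu$ is read as shape 2 / **rate** 0.1, giving a
  prior mean of 20 degrees of freedom — heavy tails allowed, Gaussian
  recoverable. The alternative (scale 0.1, mean 0.2) would confine $\nu$
  below 1 and is untenable for a degrees-of-freedom parameter.
* A half-t(3) scale of 2.5 is far too narrow for millisecond-scale
  residuals. `fit_dotprobe_subject()` therefore uses
  `max(2.5, sd(response))` as the half-t scale — the data-dependent default
  behaviour of mainstream Bayesian regression interfaces — and records the
  value used in the fit object.

The Student-t family is the point of the model: a 10 SD outlier that
survives filtering moves the posterior median of $\beta_c$ far less than a
Gaussian-family fit does, which the test suite demonstrates by fitting both
families (`family = "gaussian"` exists for exactly this comparison).

Centring uses the subject's final filtered dataset (after the repetition
merge); repetition sessions enter as their own session levels; a
single-session subject drops the group term with a logged message. With
`moderator = TRUE`, the centred absolute width difference of the stimulus
pair and its interaction with Congruence are added — the sensitivity
analysis asking whether the congruence effect is confined to large width
differences.

## Pooled preference model

All subjects' choice-phase trials enter one Bernoulli logistic mixed model
(forced-phase trials teach the colour mapping and are not choices — they are
excluded from the likelihood):

$$\mathrm{logit}\, P(\text{choice}_i = \text{flanged}) =
  \beta_0 + \beta_g G_i + \beta_o O_i + \beta_h H_i
  + a_{j(i)} + b_{j(i)} G_i + v_{js(i)},$$

with Colour Flanged $G$ (green = +1) and Order $O$ (red-block-first = +1)
sum-coded, the optional height covariate $H$ in screen-fraction units
(zero-centred by construction, range −0.35 to 0.35, negative = higher on
screen), random intercepts $a_j$ by subject and $v_{js}$ by session within
subject, and a by-subject colour slope $b_j$ correlated with $a_j$.
Priors: $\mathcal N(0, 0.5)$ on the logit scale for intercept and
coefficients, half Student-t(3, 2.5) on all SDs, and a uniform prior on the
intercept–slope correlation (for a 2×2 correlation matrix this equals the
LKJ(1) prior that mainstream interfaces default to).

Reporting is on the odds-ratio scale. The draws are exponentiated first and
then summarised, so the median commutes exactly with the transform while
the MAD and HDI are computed where they belong, on the OR scale. The
probability of direction for an OR is computed from the logit-scale draws
(an OR is positive by construction, so a pd of its own draws would be
vacuously 1): pd here answers "which side of OR = 1". Note the height OR is
per +1 unit of height while the observable range spans only 0.7 units, so a
large-looking OR corresponds to a moderate probability swing across the
screen. Per-subject summaries combine the fixed intercept with the
subject's deviation draws, mapped through the logistic function for
probability-scale reporting against the 0.5 chance line.

## Effect-size indices

Every effect is reported as: posterior **median**, scaled **MAD** of the
draws (same 1.4826 convention as the RT filter), the **89% HDI** (89%
rather than 95% to discourage reading the interval as a hypothesis test),
and the **probability of direction** (pd, in [0.5, 1]). The HDI is the
shortest window of `ceiling(mass·n)` sorted draws; its realised inside-mass
is between `mass` and `mass + 2/n` (property-tested). For a multimodal
posterior this still returns one contiguous interval — a documented
simplification. Draws exactly at zero count toward neither direction and pd
renormalises over non-zero draws (measure-zero for continuous posteriors).

## Sampling and diagnostics

All models run through JAGS (4 chains × 6000 iterations, 1000 warmup by
default, i.e. 20 000 retained draws), with per-chain RNG seeds derived from
one integer seed, so every fit is bit-reproducible given the seed and
backend version. Diagnostics report split-R-hat (each chain halved before
the potential-scale-reduction computation), effective sample size, and the
maximum lag-1 autocorrelation; fits with any split-R-hat above 1.05 are
flagged. JAGS uses Gibbs/slice updates, which have no divergence
diagnostic; `n_divergences` is reported as 0 with a note rather than
silently omitted.

## Switch-count test for temporal structure

Within one session's binary choice series, the statistic $T$ counts
adjacent unequal pairs. The test asks whether $T$ is consistent with
*independent* choices at that subject-session's own choice rate:

1. update a Beta(10, 10) prior on the flanged-choice probability θ with the
   session's choices (the strong prior encodes an expectation of roughly
   50/50 choice);
2. simulate 10 000 series of the session's length, each with
   θ\* ~ Beta(a, b) and independent Bernoulli(θ\*) trials;
3. compare the observed $T$ with the 95% HDI of the simulated null and
   report both overlapping tail shares $P(T_{null} \ge T_{obs})$ and
   $P(T_{null} \le T_{obs})$.

Below the interval means temporal clustering (runs), above means temporal
dispersion (alternation). The null has the closed-form mean
$(n-1)\,2ab/\big((a+b)(a+b+1)\big)$, and `exact_null_T()` computes the whole
pmf by $2^n$ enumeration (n ≤ 12) — the independent oracle against which
the Monte-Carlo null is verified bin by bin. The 95% HDI on a *discrete*
empirical distribution is not uniquely defined; it is built by greedy
accumulation of the highest-probability counts (ties broken toward the
mode) and reported as the [min, max] of the selected support. Because the
accumulated mass overshoots 95% by the last bin added, the realised
flagging rate on truly independent 16-trial series is materially below the
nominal 5%: exact enumeration over all 2^16 series puts it at 2.6%. Any
HDI definition on an integer-valued statistic shares this conservatism —
the boundary bins carry several percent of mass each — so "consistent"
verdicts are more common than the nominal rate suggests. Sessions are
analysed independently; series length follows the actual session (16, or
fewer when trials are missing).

## The synthetic-data generator

The generator is the package's testbed and mirrors both designs exactly:
72 pairs × 6 sessions × 24 trials (flange) and 80 × 8 × 20 (symmetry), each
pair probed once congruently and once incongruently, probe sides balanced
within session up to rounding; 6 subjects × 6 preference sessions in two
contiguous colour-association blocks of 3 (order groups split 3/3), each
session 8 forced then 16 choice trials. The dot height follows the circular
opposite-placement geometry, `0.35·cos(U(0, 2π))`, matching the stated
range and the zero mean of the covariate. RT noise is Student-t
location-scale with session-level intercept variation; contamination adds
anticipatory responses (Uniform(50, 199) ms, all below the 200 ms floor by
construction) and slow outliers (+600 ms), 5% each by default — values
chosen so the filtering stage has realistic work to do; the two events are
mutually exclusive per trial. Negative simulated RTs are clipped at 50 ms
and flagged. Choice-trial stimulus identity carries no effect in the
generator because the analysis model ignores it.

What the generator does **not** emulate: learning or fatigue across
sessions, stimulus-identity effects, response-side motor biases that
interact with congruence, or any dependence between consecutive choices.
Passing recovery tests therefore shows the pipeline is correct and
well-calibrated *under the assumed data-generating process*, not that the
models are correct for any particular real dataset.

## Simulation sizes and numerical choices

The recovery/coverage studies use 50 replicates per model with a reduced
sampler (2 chains, 500 warmup + 1000 retained draws per chain): enough
draws that an 89% HDI is stable to within a couple of percent, and enough
replicates that the binomial uncertainty on a coverage proportion
(±4.4 percentage points SD at 89%) is well inside the ±8-point band the
checks use. The coverage studies follow the simulation-based-calibration
design: each replicate's generating effect is drawn from the model's own
prior (Normal(0, 10) ms for the congruence effect, Normal(0, 0.5) logit for
the colour effect), under which credible-interval coverage is nominal by
construction whenever the implementation is correct. A fixed truth far in
the prior's tail would instead measure prior shrinkage — e.g. at a true
effect of −25 ms (2.5 prior SDs), the Normal(0, 10) prior pulls the
posterior toward zero by ~12% and the 89% interval's frequentist coverage
drops to ~78% even for a perfect sampler. The directional *recovery*
examples in the unit tests do use fixed, detectable truths (−25 ms;
odds ratio 0.67), because there the question is power, not calibration.
Degenerate inputs are handled explicitly rather than by crashing: subjects
with fewer than 2 trials are reported unfilterable, single-session subjects
lose the session term with a message, all-identical-choice subjects are
flagged and left to the priors to regularise.

## Known limitations

* The Monte-Carlo switch-test HDI is conservative on short series (discrete
  overshoot), so "consistent" verdicts are slightly more common than the
  nominal 95% suggests.
* The per-subject dot-probe models assume exchangeable sessions; slow
  drifts within a session are absorbed by the residual, not modelled.
* The repetition-session machinery assumes one round of repetitions;
  a second round would require chaining `merge_repetitions()` manually.
* External datasets are ingested via `read_trials(rename_map = ...)`;
  semantic mismatches (e.g. a height covariate on a different scale) are
  the caller's responsibility beyond the range checks.
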