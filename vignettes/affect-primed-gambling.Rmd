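---
title: "Modelling affect-primed gambling: task, agents, hierarchical fits and ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling affect-primed gambling: task, agents, hierarchical fits and ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(affectbandit)
```

## The problem this package addresses

Reward-based decision making is commonly probed with two-choice
probabilistic gambling tasks: on every trial the participant picks one of
two decks, receives binary feedback, and must track which deck is currently
"rich" (higher reward probability) as the deck pair's probabilities shift
between blocks. In affect-priming variants, a task-irrelevant facial
expression (neutral, angry or happy) precedes each choice, and the question
is how the induced affective state modulates choice strategy, learning, and
the brain's reward-prediction-error signalling — and how all of this
differs between patients with schizophrenia and healthy controls.

The package implements the full analysis chain for such a study:

1. **Task simulation** — block schedules, deck probabilities, feedback.
2. **Generative agents** — delta-rule learning with softmax choice.
3. **Behavioral strategy metrics** — win-stay/lose-shift split by deck
   class, total scores, PANAS affect-shift scores.
4. **Hierarchical Bayesian model fitting** — per-subject learning rate and
   choice consistency with group-level means and SDs, by MCMC.
5. **ERP extraction** — N170, P200 and the FRN difference wave from
   continuous multichannel EEG.
6. **A synthetic cohort generator** — so that every stage is testable
   without access to participant data.
7. **Correlation statistics** — Pearson correlations between subject-level
   measures and PANSS symptom factors with Holm–Bonferroni correction.

## Task model

A session's experimental phase has 480 trials divided pseudorandomly into
six blocks of 70–90 trials (`task_config()` defaults). Each block assigns
the deck pair a rich:poor reward-probability ratio whose two probabilities
sum to a fixed total of 60%; a 6:1 block therefore has deck probabilities
(0.514, 0.086). Block lengths are drawn as a uniform composition of the
480 trials into six parts constrained to [70, 90] via rejection sampling —
unbiased over the feasible set and trivially correct. Which deck is rich is
re-randomized independently per block, and consecutive blocks may repeat
the same rich side (the task description does not forbid it).

Two choices the task text leaves open, decided here once:

* **Ratio set.** Only the extreme ratios (6:1, 1:6) are stated explicitly;
  the block figure shows four ratios whose intermediate values are not
  legible. The default set is {6:1, 1:6, 3:1, 1:3} and is fully
  configurable (`ratio_set`).
* **Reward scheduling.** Rewards are independent Bernoulli draws on the
  chosen deck per trial, and the unchosen deck's outcome is never
  materialized. "Scheduled" rewards could alternatively imply baiting
  (outcomes persisting until collected); independence is the simplest
  reading consistent with the learning model's outcome variable. A
  `baited` flag is reserved in the configuration but not implemented.

The training phase plays blocks of 20 trials on a fixed pair and probes the
participant to name the rich deck after each block until the answer is
correct (`run_training_phase()`); the probe policy is pluggable so both
ideal and erring participants can be emulated.

## Learning model

Deck expectations follow the delta rule: after choosing a deck and
receiving reward $R_t \in \{0, 1\}$,

$$Q(t) = Q(t-1) + \alpha\,[R_t - Q(t-1)],$$

with learning rate $\alpha \in [0,1]$; the unchosen deck's expectation is
carried forward unchanged. Choice follows a softmax (logistic) rule with
choice consistency $\beta \ge 0$:

$$P_A(t) = \frac{e^{\beta Q_A(t)}}{e^{\beta Q_A(t)} + e^{\beta Q_B(t)}},$$

computed overflow-safely by subtracting the larger exponent. Initial
expectations are $q_0 = 0.5$ for both decks — the midpoint of the outcome
range — and are *not* reset at block boundaries, since participants are
never told where boundaries fall; both choices are configurable. The model
updates only the chosen deck, as written; no decay of the unchosen deck's
expectation is applied.

## Hierarchical Bayesian estimation

`fit_rlhb()` estimates each subject's $(\alpha_i, \beta_i)$ jointly with
group-level hyperparameters. Subject parameters are modelled as normals
with means $\mu_\alpha, \mu_\beta$ and SDs $\sigma_\alpha, \sigma_\beta$;
hyperpriors are uniform: $\mu_\alpha, \sigma_\alpha \sim U(0,1)$,
$\mu_\beta \sim U(0,10)$, $\sigma_\beta \sim U(0,5)$. Because a normal has
unbounded support while $\alpha$ and $\beta$ do not, the subject-level
normals are truncated to $[0,1]$ and $[0,10]$ respectively — the supports
of the corresponding hyperpriors. (Logit/log transformation would be an
alternative support-handling scheme; truncation was chosen because it
keeps the subject-level parameters on their natural scales and the
group-level normal interpretation direct.)

The sampler is an adaptive random-walk Metropolis-within-Gibbs scheme
written in C++: per iteration each subject's $\alpha_i$ and $\beta_i$ and
the four hyperparameters get Gaussian random-walk proposals, with proposal
SDs adapted toward 44% acceptance during burn-in only (so detailed balance
holds for retained draws). Truncated-normal normalizing constants are
included in the hyperparameter acceptance ratios, where they do not cancel.
Any general-purpose MCMC family is statistically acceptable for this model;
what the package treats as non-negotiable is the draw-accounting contract:
per chain, `n_iterations` total, `burn_in` discarded, every `thin`-th
retained, so the standard protocol (3 chains × 16,000 iterations, 6,000
burn-in, thin 5 — `mcmc_config("paper")`) retains exactly 6,000 draws. A
lighter `"fast"` preset (3 × 4,000, 1,000 burn-in, thin 2) is used for
simulation studies and tests. Each group × prime-condition dataset is fit
independently (the pooling structure across conditions is not specified in
the protocol this follows; independent fits are the conservative choice).

Convergence is monitored with a split-chain potential scale reduction
factor (`rhat()`); fits warn — never silently pass — when any parameter
exceeds 1.1. Point estimates are posterior means (medians are also
reported); `use_likelihood = FALSE` samples the prior alone, which is used
in tests to confirm that hyperparameter posteriors then reproduce their
uniform priors. An independent cross-check in the test suite fits the same
model in JAGS and compares posterior means.

At the sizes used in the package's checks — 20 subjects × 480 trials,
fast preset — the fit takes on the order of ten seconds and recovers
$\mu_\alpha$ within ±0.10, $\mu_\beta$ within ±1.0, and per-subject
learning rates at $r \ge 0.6$ against truth.

## Win-stay / lose-shift strategy metrics

`classify_strategy_events()` labels every trial that has a successor with
its feedback (win/lose), the following action (stay/shift), and the deck
class (rich/poor) of the *feedback* trial under its own block's
assignment. Rates are per subject × condition: matching (feedback, action)
events over matching feedback events, split by deck class and also pooled
by event weighting (both pooled and per-class rates are reported since the
pooling convention is a genuine ambiguity). Three deliberate rules:

* Events are evaluated **across block boundaries** — the decks persist,
  only their probabilities shift, and participants are unaware of
  boundaries.
* Empty denominators yield `NA`, never 0, and drop out of group means;
  imputing zeros would bias rates downward.
* Rates are computed per subject and then aggregated, never pooled across
  subjects before division.

## ERP pipeline

The extraction chain reproduces a conventional ERP workflow, in µV and ms
throughout:

1. **Bandpass 0.1–40 Hz**, zero-phase. Implemented as cascaded Butterworth
   stages — 2nd-order high-pass at 0.1 Hz plus 4th-order low-pass at
   40 Hz, each applied forward–backward (`signal::filtfilt`). A single
   direct bandpass design at a 0.0002 normalized corner is numerically
   unstable in double precision, which is why the cascade is used; its
   measured response passes 10 Hz within 5%, attenuates DC below 5 µV per
   100 µV input, and attenuates 60 Hz by more than 20 dB.
2. **Epoching**: −100..500 ms around facial-prime onsets, −100..900 ms
   around feedback onsets. All windows are half-open `[start, end)` at
   sample resolution, with 0 ms the first poststimulus sample; events
   whose window leaves the record are skipped and counted.
3. **Baseline correction** against the mean of [−100, 0) ms, per epoch and
   channel.
4. **Artifact rejection**: an epoch is rejected iff any sample on an
   analysis channel (P7, P8, Fz, FCz, Cz, Pz) exceeds ±50 µV *strictly* —
   exactly ±50.0 is retained. The mask depends only on the samples and the
   threshold, never on condition labels, and rejecting-then-averaging is
   identical to averaging the retained subset.
5. **Averaging and measurement**: component amplitudes are means over
   fixed windows and channel sets — N170: 150–210 ms at {P7, P8}; P200:
   170–230 ms at {Fz, Cz, Pz}; FRN: 300–600 ms at {Fz, FCz, Cz} — with
   channels weighted equally (a single amplitude per component is
   reported, and the aggregation rule across channels is the package's
   choice). The P200 is *displayed* at FCz in some reports but quantified
   at Fz/Cz/Pz; the quantification set is what `component_windows()`
   encodes, and every window/channel set is overridable.

The FRN is quantified from the difference wave *unexpected loss −
unexpected win*, where expectancy comes from the deck class × reward cell:
poor deck + reward = unexpected win, rich deck + no reward = unexpected
loss. Eyeblink correction is not implemented — synthetic data exercise the
threshold-rejection stage instead (`blink_rate` injects 80 µV frontal
transients); re-referencing is likewise omitted because the synthetic
scalp signals are generated reference-free.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` builds a full study: 38 patients and 26 controls, each
with three prime-condition sessions of 480 trials, model parameters drawn
from group × condition truncated normals, continuous EEG with injected
components, PANAS pre/post item ratings, and PANSS five-factor scores for
patients.

**Group × condition defaults.** The configured contrasts are directional,
matching the qualitative pattern reported for this paradigm: patients have
a *higher* group-mean learning rate and *lower* choice consistency than
controls (most extreme in the happy condition), an attenuated N170 in all
conditions, a P200 that fails to respond to angry primes, and an FRN that
is comparable to controls in the neutral condition but attenuated in the
emotional ones (defaults: controls −3.3/−4.2/−4.1 µV for
neutral/angry/happy against patients −3.1/−2.0/−2.2 µV, consistent with
reported overall means near −3.9 vs −2.4 µV). Where the source protocol
prints a number it is used directly (group sizes, PANSS factor means and
SDs such as positive 8.39 ± 3.53, N170 lateralization P7/P8 =
3.7/4.54); where it prints none, the default is a single fixed choice a
practitioner would call plausible, never tuned afterwards. Effect-size
parameterization for condition differences is deliberately configurable
because no quantitative parameterization is published.

**Planted correlations.** Symptom factors and the angry-condition
subject-level measures (learning rate, choice consistency, P200 template
amplitude, FRN template amplitude) are realized through a Gaussian copula:
a joint latent normal whose cross-correlation block defaults to the
significant/marginal reported cells (e.g. FRN × positive −0.436, FRN ×
cognitive −0.447, consistency × positive −0.334). The configuration
rejects any planted matrix whose implied joint correlation matrix is not
positive semi-definite. Note that correlations are planted on the
*template* (truth) amplitudes; pipeline-measured amplitudes add
measurement noise, so measured correlations are attenuated toward zero
relative to the planted values — the recovery tests therefore check the
truth-side correlations, and the attenuation is a known property, not a
defect.

**EEG synthesis.** Sessions are generated as epoch-aligned 2.2 s stretches
per trial (prime at 0.2 s, feedback 0.7 s later) rather than a continuous
session timeline with inter-stimulus jitter: epoching is exercised
identically and records stay small. Components are Gaussian bumps (N170:
peak 180 ms, SD 20 ms, right-lateralized; P200: 200 ms, SD 25 ms,
frontocentral; FRN effect: 450 ms, SD 60 ms on unexpected-loss feedbacks
only). Template amplitudes are specified as *window-mean targets*: the
generator converts them to peak heights using the analytic Gaussian window
average (`gauss_window_mean()`), so an injected −3 µV FRN is recovered as
approximately −3 µV by the measurement pipeline. Noise is white by default
(SD 10 µV) with an optional 1/f spectral exponent. The generator does not
emulate volume conduction, reference effects, alpha rhythms, drifts, or
muscle artifacts — passing tests therefore show the pipeline arithmetic is
correct on well-behaved signals, not that the pipeline is robust to every
pathology of real recordings.

**Storage.** Raw EEG is not stored in the study object (a full cohort
would be tens of gigabytes); each session stores a seed and truth
amplitudes, and `cohort_eeg()` re-synthesizes the identical record on
demand. Everything any recovery test needs — true $(\alpha_i, \beta_i)$,
template amplitudes, planted correlations, per-session seeds — is kept.

## Statistics

`pearson_r()` wraps the product-moment correlation with the exact
t-transform p value; `holm_bonferroni()` applies the step-down adjustment
$\tilde p_{(k)} = \max_{j \le k}(m - j + 1)\,p_{(j)}$ capped at 1.
`correlation_table()` builds the measure × condition × factor grid for the
patient group with pairwise deletion (counts always reported) and applies
Holm within configurable families; the default family is the 15 tests
(3 conditions × 5 factors) of one measurement type, mirroring how such
tables group rows, since the exact family convention is not stated
anywhere and materially affects the correction. Two-sided p values are
used throughout.

`run_study()` chains all stages — generate, summarize behavior, fit each
group × condition, extract ERPs, correlate — with per-stage timing on
standard error and full determinism per seed.

## Numerical choices and degenerate inputs

* Softmax and log-likelihood subtract the maximum exponent; $\beta = 0$
  yields exact indifference, and saturated $\beta$ values do not overflow.
* Block composition uses rejection sampling; an infeasible
  trials/blocks/range combination raises a configuration error naming the
  bound rather than looping forever.
* Deck-pair identities (sum, ratio) hold to 1e-12 relative tolerance.
* Empty strategy denominators are `NA` markers; zero retained epochs, zero
  usable events, missing channels, and windows outside epochs are all
  hard errors with counts, never silent `NaN`s.
* Constant MCMC chains give an `NA` R-hat rather than a spurious 1.0;
  single-chain fits report the diagnostic as unavailable.
* Trial indices are 0-based and block bounds half-open, matching the
  half-open time windows of the ERP code.

## Problem sizes used in the checks

The package's own verification runs at sizes chosen to keep the whole
suite comfortably interactive: parameter recovery at 20 subjects × 480
trials under the fast MCMC preset; the paper-protocol draw-accounting run
on a 2-subject toy; ERP injection-recovery at 480 trials, 250 Hz and noise
SD 10 µV (SEM-derived tolerance ±0.5 µV); behavioral direction checks at
the full 38 + 26 cohort over 10 seeds; the FRN direction arm on a reduced
cohort (8 + 8 subjects, 240-trial sessions, 250 Hz); and the family-wise
error simulation at 15 tests × 1,000 replicates. Each of these sizes is a
package choice, stated here so results are interpreted at the scale they
were computed.

## Known limitations

* The sampler is random-walk Metropolis; it is exact but less efficient
  than gradient-based samplers for large cohorts. The draw-accounting
  contract, not sampler family, is what downstream code relies on.
* The synthetic EEG omits most real-world artifact structure (see above).
* Win-stay/lose-shift pooling across deck classes is event-weighted;
  per-class rates are always available for the alternative convention.
* The generator's condition effect sizes are directional placeholders
  wherever the source prints no number; conclusions from synthetic runs
  are about pipeline correctness, not about patients.
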