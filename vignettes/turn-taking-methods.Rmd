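---
title: "Latency, counter calls and latency-ratio matching: the models behind antiphony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency, counter calls and latency-ratio matching: the models behind antiphony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiphony)
```

## The problem

An interactive acoustic playback trial pits a live animal against an operator
who broadcasts a recorded conspecific call (the *exemplar*) and times each
broadcast off the animal's own responses. The scientific questions are about
*timing*: does the subject answer the exemplar faster than it calls on its
own; does its response latency entrain to the playback's latency (the
coupled-oscillator reading of turn-taking); and do these signatures weaken as
the subject's behavioral state moves from engagement through agitation to
disengagement? antiphony implements the analysis pipeline for such trials,
starting from annotated event tables (not audio) and ending in fitted
contrasts with randomization-based significance.

All user-facing functions take and return data frames (tibbles), so the
pipeline composes with dplyr and the pipe.

## Event model and latency definition

A session is a time-ordered set of call events (source: `exemplar` or
`subject`; onset and offset in seconds; optional relative amplitude in dB),
behavior events (neutral or wheezy surface blows, surfacings), and
behaviorally defined phase intervals. Phase intervals are half-open
`[start, end)`, which makes phase assignment total and unique at boundaries;
the convention is ours, chosen so that no event can sit in two phases.

The *inter-call latency* is the time from the preceding call's offset to the
subsequent call's onset, computed within one source. The phase of a latency
record is the phase at the *terminating* call's onset, because the response
is the event being explained. Overlapping same-source calls would produce
negative latencies; we treat them as annotation errors and exclude them with
a warning rather than clamping to zero. Calls outside every phase interval
are kept in whole-series analyses (e.g. the counter-call contrast) but
dropped from phase-stratified ones.

A subject call is a *counter call* when the most recent prior call on the
merged timeline is an exemplar and no blow or surfacing falls strictly
between that exemplar's offset and the subject call's onset — breathing at
the surface disrupts calling, so a blow breaks the exchange chain. An
intervening exemplar between two subject calls never removes the latency
record itself; `classify_counter_calls(strict = TRUE)` additionally drops
the mixed case (an exemplar intervened, yet a blow stripped counter status),
for users who want the non-counter class to contain only clean successions.

## Latency-ratio matching

A response pair compares the latency *into* a call with the latency *out of*
it: for an exemplar answered by the subject, the first latency runs from the
preceding subject call's offset to the exemplar's onset (the operator's
response time) and the second from the exemplar's offset to the answering
call's onset (the subject's response time). The mirrored construction
anchors on a subject call flanked by exemplars. All three events must be
consecutive on the merged call timeline. This is the only construction we
found that compares *response times* and yields distinct pair sets for the
two directions; an alternative pairing of successive same-source intervals
is available behind `strategy = "same_source_interval"` but is exploratory.

To compare pairs across absolute durations, the two latencies are
standardized to percentage shares of their sum. We summarize a pair by its
smaller share $s = 100\,\min(L_1,L_2)/(L_1+L_2) \in [0,50]$, its
*discrepancy* $d = 100 - 2s$ (percentage points between the two shares;
$0$ is a perfect 50:50 match), and a binary *match* flag, true when the
ratio lies between 41:59 and 50:50, i.e. $s \ge 41$ with the band edge
included. The three formulations are equivalent ($s \ge 41
\Leftrightarrow d \le 18$), and all metrics are symmetric in the pair and
invariant to common scaling. The band-edge comparison carries a $10^{-9}$
tolerance: a pair like 4.1 s / 5.9 s has an exact share of 41 but a floating
point one a few ulps below it. Discrepancies are additionally rounded to
integer percentage points (`discrepancy_int`) where a count-family model
needs them; the exact value is always retained alongside.

Phases represented by fewer than two pairs are flagged `insufficient` and
excluded from proportion contrasts — one pair cannot inform a proportion.

## Regression families

Latency and discrepancy outcomes are fitted with negative binomial
regression (log link) on values rounded to whole seconds or percentage
points; binary match outcomes with logistic regression; amplitudes with a
Gaussian identity-link model. Latencies are continuous, so rounding to
seconds is the minimal reconciliation with a count family; a Gamma log-link
alternative on the raw seconds is available via `family = "gamma"` and gives
practically identical contrasts. The negative binomial dispersion is
estimated by maximum likelihood (`MASS::glm.nb`), with a quiet fall back to
Poisson when the dispersion vanishes — in that regime the coefficients
coincide. For a single categorical predictor the log-link coefficient of a
level equals the log of its outcome-mean ratio to the reference level
exactly, whatever the dispersion, and the logistic coefficient equals the
2×2 log odds ratio; both identities serve as closed-form oracles in the test
suite. Complete separation in the match model (a phase with 0% or 100%
matched) leaves the logistic MLE unbounded; the fit is then flagged and
Haldane–Anscombe corrected contingency-table odds ratios (0.5 per cell) are
substituted, without p-values.

## Randomization tests

With a single 20-minute encounter there is no replication across subjects,
so model significance is backed by randomization: the group labels are
permuted uniformly without replacement, the coefficient of interest is
recomputed on each permuted dataset, and the empirical p-value is the
two-sided add-one tail $(1 + \#\{|\beta^*| \ge |\beta_{obs}|\})/(N+1)$,
which can never return zero. Permuted-data coefficients use the closed-form
single-predictor identities above, which are exactly the GLM point
estimates; permutations with a degenerate group (e.g. zero mean under a log
link) are excluded from the denominator, and more than 10% failures aborts
the procedure. The default is $N = 1000$ permutations. Everything is driven
by one integer seed: the same seed reproduces the null coefficient sequence
bit for bit.

## What the generator emulates

`simulate_playback_session()` produces sessions with the statistical
structure the analysis assumes, with known ground truth:

* an alternating timeline — three initial broadcasts before the subject's
  first response, then an operator who either mirrors the subject's last
  response latency (plus Gaussian noise, SD 1 s) or broadcasts at a fixed
  mean; the operator never waits longer than the 20 s rebroadcast timeout,
  as a human operator would not;
* phase-dependent response latencies — uncoupled draws are Gamma with means
  8 / 14 / 25 s across engagement, agitation and disengagement and shape 2
  (strongly right-skewed, coefficient of variation ≈ 0.7, typical of
  behavioral response times);
* latency coupling — with per-phase probability 0.8 / 0.3 / 0.1 a response
  mimics the latency into the exemplar it answers, times $(1+\varepsilon)$
  with $\varepsilon \sim N(0, 0.1)$; this operationalizes the coupled
  oscillator with one recoverable parameter per phase, and the operator
  latency cap keeps the resulting copy-chain from drifting without bound;
* a deterministic schedule of seven blows (two neutral ones interspersed
  with the initial broadcasts, three wheezy in agitation, two neutral in
  disengagement): blows are landmark events that define phases, so a fixed
  schedule keeps boundary tests simple. A blow scheduled inside a response
  window — or within the 15 s lookahead after an exemplar, a subject about
  to surface holds its call — delays the response to 30 s past the blow and
  strips the next call's counter status;
* a broadcast stop 60 s into disengagement followed by three solo subject
  calls whose gaps continue the subject's current calling rate (twice the
  last response latency plus a call duration) — calls in succession, hence
  non-counter;
* amplitudes — baseline −27 dB with additive phase effects 0 / −2 / −6 dB
  and 3 dB noise, spanning roughly −21 to −43 dB;
* a control day — six subject calls whose gaps are Normal(60, 15²) s
  truncated at zero, much sparser than any playback phase.

The phase boundaries default to 0 / 420 / 900 / 1200 s of a 20-minute
session. Under these defaults a session settles around 34 subject calls and
35 exemplars, with roughly 29 exemplar-to-subject and 30 subject-to-exemplar
response pairs — the scale of a real 20-minute exchange — without any of
those counts being enforced.

Ground truth records every draw (coupling indicator, drawn vs realized
latency, blow interruption, per-phase means), so parameter-recovery tests
can compare estimates against what generated the data. Three presets cover
the regimes used in testing: `paper_like` (the defaults above), `null`
(identical phases, zero coupling, fixed-mean operator, no blows — the
type-I-error reference; a fixed-mean operator matters here because a
mirroring operator induces serial dependence that breaks the exchangeability
a permutation null requires), and `perfect_oscillator` (deterministic
mimicry: every pair is exactly 50:50).

What the generator does *not* emulate: acoustic waveforms, spectral call
features, propagation or orientation effects on amplitude, multiple
subjects, or stochastic surfacing behavior. Passing parameter-recovery tests
therefore shows the pipeline recovers the timing structure it models, not
that real recordings satisfy those assumptions.

## Numerical and design choices

* Times are seconds from session start with at least millisecond
  resolution, as selection tables export them.
* Latency records with negative latency are excluded, not clamped; the
  excluded count is kept on the result.
* The match-band edge is inclusive and compared with a $10^{-9}$ tie
  tolerance (above).
* Reference levels default to the scientifically natural baseline: the
  control day when present, otherwise engagement; the non-counter class for
  the counter contrast.
* Predictor levels with fewer than two observations are dropped from fits
  and reported as inestimable rather than silently extrapolated.
* Zero latencies are nudged to 1 ms for the Gamma alternative family only.
* All randomness funnels through explicit integer seeds; simulation and
  randomization results are bit-reproducible given the seed.

Test-suite problem sizes were chosen to make the statistical checks sharp at
desk scale: 10,000 random pairs for the ratio-metric properties, 1,000
random small sessions against the brute-force counter-call oracle, and 200
replicate sessions for randomization calibration (1,000 permutations each)
and parameter recovery.

## Known limitations

The pipeline analyzes one subject per session and fits plain GLMs: no
mixed effects, no autocorrelation structure, although consecutive latencies
in a coupled exchange are serially dependent by construction. The
counter-call rule and pair construction assume non-overlapping, pre-labeled
calls of exactly two sources. Printed coefficients from other software on
the original field data are not reproducible here because raw event times
for that encounter are not available; what the package can and does verify
is that its own estimators recover known ground truth and match closed-form
oracles.
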