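# antiphony

Turn-taking and latency-matching analysis for interactive acoustic playback
trials.

When a recorded conspecific call (an *exemplar*) is broadcast interactively
to a wild animal — each broadcast timed off the animal's own responses — the
evidence that a genuine exchange took place lives in the timing of the
events: inter-call latencies, direct counter-calling, and the matching of
response times between the two parties. `antiphony` implements that
analysis for annotated acoustic-event tables (Raven selection-table dialect
or plain TSV), plus a fully parameterized session simulator with known
ground truth so every estimator can be checked against what generated the
data.

## The statistics at its core

For consecutive same-source calls, the **inter-call latency** is
`onset(next) − offset(previous)`. A subject call is a **counter call** when
the most recent prior call is an exemplar and no surface blow or surfacing
falls between that exemplar's offset and the call's onset.

A **response pair** compares the latency into a call with the latency out of
it (operator response time vs subject response time). Its two latencies
L₁, L₂ are standardized to shares of their sum:

    share_small = 100 · min(L₁, L₂) / (L₁ + L₂)      ∈ [0, 50]
    discrepancy = 100 − 2 · share_small               (pp; 0 = perfect match)
    matched     ⇔ share_small ≥ 41                    (ratio in 41:59 … 50:50)

Latency and discrepancy contrasts are fitted with negative binomial
regression (log link, outcomes rounded to whole units), match proportions
with logistic regression (exp(β) is an odds ratio), amplitude trends with a
Gaussian model. Significance is backed by seeded randomization tests: labels
permuted N times, empirical p = (1 + #{|β*| ≥ |β_obs|}) / (N + 1).

## Worked example

Simulate a 20-minute playback exchange plus a sparse control-day sequence,
run the full analysis, and read the fitted contrasts:

```r
library(antiphony)

cfg    <- sim_config(seed = 42)
sim    <- simulate_playback_session(cfg)
ctrl   <- simulate_control_session(cfg)
report <- analyze_exchange(sim$session, ctrl, n_randomizations = 1000, seed = 42)
report
#> <playback_report> antiphony 0.1.0
#>   inputs: 38 exemplar / 37 subject calls; 7 behaviors; 6 control calls
#>   latency records: 41
#>   pairs: E_T 31 / T_E 33
#>   models: latency_phase, counter, match, discrepancy, amplitude
#>   randomization p: 0.01399

tidy(report$models$latency_phase)
#> # A tibble: 3 × 5
#>   term          estimate std.error statistic  p.value
#> 1 agitation       -0.559     0.189    -2.96  3.07e- 3
#> 2 disengagement   -0.131     0.219    -0.600 5.49e- 1
#> 3 engagement      -1.35      0.178    -7.54  4.81e-14
```

The reference level is the control day, so every playback phase shows
shorter latencies than passive calling (engagement most strongly:
exp(−1.35) ≈ 0.26, about a quarter of the control-day inter-call interval).
Counter calls come back faster than non-counter calls, and the permutation
test says that contrast is unlikely under label exchange:

```r
tidy(report$models$counter)
#> 1 counter   -0.763     0.264     -2.90 0.00379
report$randomization
#> <randomization_result>
#>   coefficient: counter  ( nb )
#>   beta observed: -0.7634
#>   permutations: 1000
#>   empirical p: 0.01399
```

Matching concentrates in engagement (17/20 pairs matched vs 5/10 in
agitation; the single disengagement pair is flagged insufficient and
excluded), and call amplitude drops by ~8 dB once the subject disengages:

```r
report$match_counts
#> 1 agitation          10         5           5 FALSE
#> 2 disengagement       1         0           1 TRUE
#> 3 engagement         20        17           3 FALSE
tidy(report$models$amplitude)
#> 1 agitation       -0.925      1.19    -0.781 0.440
#> 2 disengagement   -8.47       1.58    -5.35  0.00000606
```

`plot_latency_series()`, `plot_latency_by_phase()`, `plot_match_rate()`,
`plot_discrepancy()` and `autoplot()` on a randomization result give the
matching ggplot views. A thin command-line front end is shipped at
`inst/cli/antiphony.R` (`simulate` / `analyze` subcommands writing TSV
tables and a JSON report).

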