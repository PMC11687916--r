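---
title: "The momentum chain model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The momentum chain model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmchain)
```

## The model

Psychological momentum — the "hot hand" — is modelled as a per-player
scalar state updated after every point of a tennis match by a first-order
difference equation with exponential forgetting:

$$M_i = f(\Delta t_i)\, M_{i-1} + \Delta M_i, \qquad M_0 = 0,$$
$$f(\Delta t) = 0.6 + 0.4\, e^{-\lambda \Delta t},$$
$$\Delta M = \alpha \sum_{k=1}^{3} w_{pk}\, flag_{pk}
           \;-\; \beta \sum_{j=1}^{3} w_{nj}\, flag_{nj}.$$

The six binary flags are the events most associated with scoring swings:
winning serves ($p1$), winning shots ($p2$) and three consecutive points
won ($p3$) on the positive side; double faults ($n1$), unforced errors
($n2$) and three consecutive points lost ($n3$) on the negative side. The
server modifiers encode the serving side's structural advantage (the
server holds about 84% of games): $\alpha = 1.2$ when serving and $1$
otherwise, $\beta = 1$ when serving and $1.2$ otherwise — a gain event on
serve counts more, a loss event on return hurts more. The shipped weights
are $w_p = (0.30, 0.32, 0.38)$ and $w_n = (0.32, 0.26, 0.42)$: three-point
runs/slumps carry the largest weight on each side.

**Sign convention.** The increment's negative-event term carries an
explicit minus while the weights stay nonnegative. The model's narrative
requires negative events to *lower* momentum; a literal reading of the
published formula (both terms added with positive sign) would make double
faults raise it. We treat that as a typographical artefact and encode the
decline explicitly.

**Forgetting.** $f$ is bounded in $(0.6, 1]$: the previous point's
momentum is never fully remembered after a pause nor ever fully forgotten
within a match. $f(0) = 1$ exactly because the floor (0.6) and the
transient scale (0.4) sum to 1. The decay rate $\lambda$ is *not* part of
the published constants. The package default is $\lambda = \ln 2 / 40
\approx 0.0173\ \mathrm{s}^{-1}$, chosen so the transient component halves
over a typical 40-second inter-point gap; every acceptance-level check
either uses the $\lambda$-free limit or fixes $\lambda$ explicitly, and the
value is a single config field.

**Gaps.** $\Delta t_i$ is the difference of the cumulative match clock.
Missing or non-positive gaps (clock resets, data gaps) fall back to
`default_dt_seconds = 40`.

## Event extraction

Flags are derived from the raw per-point indicator columns of the public
Grand Slam point-by-point schema:

* **p1 (winning serve)** — an ace, or an ace/untouched serve winner
  (`p1_definition` config; the wider reading is the default since both are
  points won directly by the serve). A winning serve suppresses the
  generic winner flag for the same point so that one point contributes one
  gain event.
* **p2 (winning shot)** — a winner struck by the point winner. An
  opponent's unforced error sets *no* positive flag: only active winning
  situations count, since the opponent's mistakes say little about the
  scorer's own ability.
* **n1/n2** — a double fault (server only, and the server loses the
  point) suppresses the generic unforced-error flag for the same point.
* **p3/n3 (streaks)** — the flag fires on the third and every subsequent
  point of a run, so a five-point run yields three flags. This per-point
  firing keeps the recursion local and is consistent with streak counts
  that are large relative to match length in the reference tallies. In a
  two-player match, A's three-wins stream is *identically* B's
  three-losses stream — a structural symmetry the tests assert exactly.
  Streaks deliberately run across set boundaries (the pure point sequence
  is used); a reset-at-set-boundary variant was considered and rejected as
  an extra rule the event definitions do not state.
* **Break points** — trusted from the raw columns when present, otherwise
  reconstructed by replaying the game score from the point-victor
  sequence (receiver at 3+ points with at least a one-point lead, outside
  tiebreaks).

Indicator columns *absent* from a file are tri-state-absent, not zero:
they contribute zero flags but raise a warning, because silently treating
missing data as "no events" would bias momentum toward zero without
telling the analyst.

## Per-set scores, prediction

Each set is summarised by the mean momentum over its points plus a
break-point bonus: `w_bp_created = 0.05` per break point created and
`w_bp_converted = 0.10` per conversion. The published description
motivates a break-point adjustment "at the end of each match ... in a
set" but states neither weights nor locus; both weights and the per-set
locus are package extrapolations, configurable, and switching them off
reduces scores to plain means.

The match winner is predicted from the sign of the momentum differential.
Three match-level scores are implemented (`prediction_mode`): the final
point's momentum, the match mean (default), and the cumulative sum, each
plus the summed break-point adjustments. The mean is the default because
the literal final value is dominated by the last handful of points through
forgetting, while the description of the procedure emphasises overall
performance. Ties break deterministically (more points won, then player
1).

**What prediction accuracy means here.** The differential is computed
from the *realized* match's own events — an in-sample readout, exactly as
in the published evaluation procedure. Consequently even a corpus with
zero skill gap yields accuracy far above 0.5 (about 0.85 on simulated
best-of-3 corpora): in a coin-flip match the player who happened to win
also accumulated more positive events. A green accuracy figure therefore
establishes that the momentum score coherently summarises within-match
dominance, *not* that it forecasts matches from pre-match information.
The one acceptance check that expected chance-level accuracy on zero-skill
corpora is left failing, with this analysis, rather than widened.

## The synthetic generator

The simulator exists so every operation has a ground-truth oracle without
external data. It emulates the Grand Slam point-by-point schema:

* **Scoring machine** — standard rules: games to 4 win-by-2 with deuce,
  sets to 6 games win-by-2, 7-point win-by-2 tiebreak at 6–6 (configurable
  in the deciding set), serve alternating by game with the 1-2-2 tiebreak
  pattern. The source material's prose summary of the rules conflates
  games and sets; the canonical rules of the sport are implemented since
  the data being emulated are Grand Slam matches.
* **Points** — i.i.d. Bernoulli per serve: the server wins with
  probability `p_serve[server]`. The default is calibrated by bisection so
  the closed-form game-hold probability equals the empirical 0.84
  (`calibrate_point_prob(0.84)` ≈ 0.656 per point).
* **Attribution** — each point's end is explained by exactly one of ace,
  untouched serve winner, rally winner, unforced error or double fault,
  drawn conditionally on who won and whether the server won, so the raw
  columns are mutually consistent by construction.
* **Net play** — approaches are biased toward the point winner so the
  success rate among approaches converges to the observed 0.82 while the
  mean approach rate stays at its configured value.
* **Court effects** — only serve speed, rally length and ace probability
  shift with the surface (slow high-bouncing clay: longer rallies, fewer
  aces, slower serves; grass slower serves than hard courts), matching
  the indicators that vary across surfaces in the reference variance
  table; double-fault and unforced-error rates are court-invariant.
* **Gaps** — Exponential(mean 40 s) truncated to [15, 180] s via inverse
  CDF (one uniform per point, keeping the RNG stream deterministic).

What the generator does **not** model: fatigue, weather, crowd, serve
order strategy, and — deliberately — any feedback of momentum into
point-win probabilities, which would presuppose the model's conclusion.
A green end-to-end test therefore establishes correctness of the
computational pipeline on schema-faithful data, not the psychological
reality of momentum.

## Statistics

* `chi_square()` implements the Pearson statistic with expected counts
  from marginals, no continuity correction by default (the reference
  values are consistent with uncorrected Pearson on large samples; Yates
  is a flag). p-values come from the upper tail and are floored at
  1e-300 — "significance 0.00" is read as below working precision, never
  literal zero.
* `court_type_summary()` normalizes each court-level indicator value by
  the pooled observation-level min-max range of that indicator, then takes
  the population variance across courts. A per-indicator min-max across
  the court values themselves was considered and rejected: with three
  courts it forces every variance into [1/6, 2/9] regardless of the data,
  which contradicts the reference table's span (0.0003–0.19).
* `event_correlation()` is Pearson (phi) on the stacked binary flag
  streams; zero-variance streams yield NA with a warning rather than a
  silent drop.

## Numerical notes

* The recursion accumulates in double precision with no intermediate
  rounding; tests verify it against an independently coded unrolled
  product–sum oracle to 1e-9 on 1,000 random 100-point matches.
* `calibrate_point_prob()` bisects to interval width 1e-12, giving
  residuals below 1e-10 across targets 0.2–0.95.
* Degenerate inputs: empty series and zero service points yield errors or
  absent rates (never silent zeros); a finished match cannot be advanced;
  validation reports violations as data so flagged matches still flow
  through the engine — the reference procedure never drops points.

## Known limitations

* $\lambda$, the break-point weights and the prediction locus are
  principled defaults, not published constants; headline corpus accuracies
  depend on them and on the external match corpus, so they are computed by
  the harness only when users supply the public CSVs.
* The generator's i.i.d. point model contains no true momentum; it can
  validate machinery and calibrations but cannot measure hot-hand effect
  sizes.
* Only singles scoring is implemented; no-ad scoring and 10-point
  match tiebreaks are out of scope.
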