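---
title: "Order-pattern networks: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-pattern networks: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opnet)
```

## The model

Given a multichannel recording $u_i(t)$, $i = 1..N$, $t = 1..T$, each
channel is encoded into a sequence of *order patterns*: the symbol at
anchor $t$ is the permutation describing the relative ranks of the $d$
values $u_i(t), u_i(t+\tau), \dots, u_i(t+(d-1)\tau)$. For $d = 2$ the
pattern is simply "up" (encoded 0) or "down" (encoded 1); in general there
are $d!$ possible patterns. Encoding every anchor yields a symbol series of
length $T - (d-1)\tau$ per channel.

Two channels are functionally connected at $t$ exactly when their symbols
at $t$ are identical:

$$A_{ij}(t) = \begin{cases} 1 & \pi_i(t) = \pi_j(t),\ i \neq j \\ 0 & \text{otherwise.} \end{cases}$$

Symbol identity is an equivalence relation, so every network in the
resulting sequence is a disjoint union of cliques — one clique per symbol
present — and the component count equals the number of distinct symbols.
Two structural consequences are worth keeping in mind when reading the
metric curves:

- All *defined* local clusterings (degree $\ge 2$) are exactly 1.
- The component structure, the density and the clustering are all
  functions of the symbol-class sizes alone; `metric_time_series()`
  exploits this (and the package tests verify the shortcut against the
  generic adjacency-matrix implementations and against igraph).

The appeal of the identity criterion is that it needs **no similarity
threshold** — the usual arbitrary step between a real-valued association
matrix and a binary graph disappears — and that the encoding is exactly
invariant under any strictly increasing amplitude transformation, hence
robust to gains, slow drifts and monotone sensor nonlinearities. The price
is that connectivity is all-or-nothing at each time point; graded
similarity (e.g. by pattern edit distance) is deliberately out of scope.

### Assumptions

- Channels are sampled simultaneously on one clock; the method compares
  symbols at equal $t$, so desynchronized channels are meaningless.
- Values are real-valued with ties being rare events (see tie handling
  below).
- The same $(d, \tau)$ is appropriate for all channels — supported by the
  aggregation step, and by over-embedding.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $d$ | samples per pattern | estimated | smallest dimension with FNN fraction $\le$ 1% |
| $\hat d$ | over-embedded dimension | $2d + 2$ | copes with non-stationarity and suppresses chance matches |
| $\tau$ | delay between pattern samples (samples) | estimated | first local minimum of auto-MI |
| `n_bins` | MI histogram bins per marginal | 100 | estimates stabilize near 100 bins; too few bins inflate the delay |
| `max_lag` | MI scan range (samples) | 100 | generous upper bound for physiological sampling rates |
| `rtol`, `atol` | FNN criteria | 10, 2 | the standard published constants for the false-nearest-neighbour test |
| `threshold` | acceptable FNN fraction | 0.01 | conventional convergence level |
| `n_perm` | permutations per time point | 2000 | standard choice for a sliding test |

**Dimension.** `fnn_fraction()` embeds the series in dimension $d$,
finds each point's Euclidean nearest neighbour while excluding temporal
neighbours within one delay (a Theiler window, so trajectory segments do
not masquerade as geometric neighbours), and flags the pair as false when
the added $(d\!+\!1)$-th coordinate grows their distance by more than
`rtol` relatively or beyond `atol` standard deviations absolutely.
`estimate_dimension()` returns the smallest $d$ whose fraction drops to
`threshold`; if none does by `max_d` (white noise behaves this way) it
returns `max_d` with a non-convergence flag. On noise-free Lorenz data the
FNN profile at $d = 2$ sits at a few percent — above the 1% default, so
the estimate is 2 or 3 depending on the threshold; since the dimension is
subsequently over-embedded ($\hat d = 2d+2$), this ambiguity has little
practical consequence.

**Delay.** `mutual_information()` uses equal-width bins over each
marginal's range (not equiprobable bins), a joint histogram of the lagged
pairs, zero-count cells contributing zero, and reports bits. At lag 0 it
equals the binned Shannon entropy — a closed-form check in the tests.
`estimate_delay()` takes the first lag $\ell \ge 2$ with
$MI(\ell) < MI(\ell-1)$ and $MI(\ell) \le MI(\ell+1)$; a profile with no
local minimum in range falls back to the global arg-min with a warning.
The bin count matters: coarse histograms blur the profile and push the
first minimum outward, which is why the default is 100 and why a
convergence check (comparing estimates at two bin counts) is worth doing
on new data.

**Aggregation.** With many channels, per-channel estimates are combined as
the *mode* of the dimensions (ties broken toward the smaller — cheaper,
and over-embedding absorbs the difference — with a message) and the
*mean* of the delays rounded to the nearest integer, half away from zero.
The aggregated $\tau$ is rounded once, and the span $\Delta t = (\hat d -
1)\tau$ is derived from the rounded value.

**Time realignment.** A pattern anchored at $t$ summarizes the next
$\Delta t = (d_\text{used}-1)\tau$ samples, so for display the timestamp is
moved to the window centre, $t^* = t + \Delta t/2$, kept fractional, and
converted to milliseconds when a sampling rate is known. Anchors and
realigned times are kept distinct throughout (`start_index` vs `times`).

## Numerical conventions

- **Ties.** Tied values within a window are ranked by position (the
  earlier sample gets the lower rank) via a stable comparison, and the
  symbolization warns with a count of affected windows. This makes
  integer-valued or quantized inputs deterministic instead of undefined.
- **Symbol encoding.** Patterns are serialized as their lexicographic rank
  among all $d!$ permutations (Lehmer code), with `pattern_unrank()` as the
  exact inverse (tested exhaustively for $d \le 6$). Any bijection would
  produce identical networks; one must simply be pinned for file exchange.
- **Non-finite samples** are rejected with the offending channel and
  sample index, never skipped — silently dropping samples would
  desynchronize channels.
- **Degenerate metrics.** Nodes of degree $< 2$ have clustering 0 *and
  stay in the network average*. Averaging only over defined nodes would
  force $C(t) \equiv 1$ on clique unions; with the zero convention $C(t)$
  grows with link density while the normalized clustering
  $C'(t) = C(t)/\rho(t)$ falls — the two curves separate exactly as
  observed in practice. $C'$ is reported as missing where $\rho = 0$, and
  infinite graph distances are returned as `Inf`, serialized as missing,
  never as a large number.
- **Density convention.** $\rho = \sum_{i \ne j} A_{ij} / (N(N-1))$,
  i.e. ordered pairs over ordered pairs, so $\rho \in [0, 1]$ with the
  complete graph at exactly 1.
- **Edge-list serialization** stores `t, time, from, to` plus a JSON
  sidecar with labels, times and parameters, so the full adjacency
  sequence round-trips exactly — including empty networks, which a bare
  edge list could not represent.

## The Lorenz benchmark

Two identical Lorenz systems ($\sigma = 10$, $r = 28$, $b = 8/3$) are
coupled diffusively through their first components with strength $g$; the
coupling enters both equations symmetrically ($g[y_1 - x_1]$ and
$g[x_1 - y_1]$). Initial states $(-1, 3, 4)$ and $(-8, 8, 27)$ are
perturbed independently by uniform jitter on $[-0.5, 0.5]$. Integration
uses the adaptive Dormand–Prince RK4(5) pair (`deSolve::ode45`) with dense
output at step 0.001; the trajectory is then down-sampled by keeping every
5th point, the first 10000 down-sampled points are discarded as transient,
and the next 1000 points of $x_1$ and $y_1$ are analysed. The transient is
counted *after* down-sampling, giving a long (50 time-unit) settling
period so the coupled pair is completely synchronized — in practice down
to the solver's local error scale — and the uncoupled pair fully
decorrelated.

Detection works per realization: the order-pattern rate is the fraction of
time points with identical symbols ($\tau = 30$; $d = 2$ and the
over-embedded $\hat d = 6$), and the correlation baseline is the mean of
$|r|$ over consecutive non-overlapping windows of $w = (d-1)\tau$ samples
(30 and 150). The absolute value is deliberate: over short windows two
smooth independent oscillators produce strong correlations of *either*
sign, and a signed average would cancel to zero and hide the
false-positive problem the comparison is meant to expose. A zero-variance
window contributes $r = 0$ with a warning.

At $d = 2$ two independent channels agree whenever both happen to move in
the same direction — roughly half the time — so the uncoupled
order-pattern rate sits near 0.5; at $\hat d = 6$ a chance agreement
requires an identical permutation of six values and the rate collapses to
the percent level. This directional effect (false positives at $\hat d = 6$
below those at $d = 2$ in every batch) is asserted as a property test.
`scripts/acceptance.R` reruns the full grid at 100 seeded realizations per
coupling; the test suite uses the same size once and smaller batches
elsewhere.

## The synthetic multichannel generator

`generate_synthetic_ensemble()` emulates the percolation behaviour the
method is designed to resolve: channels are independent smooth noise
(an AR(1) process, coefficient 0.9) except that, within a planted group's
epoch, every member shows the *same* waveform through a channel-specific
strictly increasing distortion $f_c(u) = a_c u + c_c \tanh(u) + b_c$ with
$a_c > 0$, $c_c \ge 0$. Because the distortions are monotone, the members'
symbols are *exactly* identical at every anchor whose window lies fully
inside the epoch — the ground truth is deterministic, not approximate —
while their amplitudes differ channel by channel.
`expected_component_schedule()` translates the planted design into the
expected component count per anchor.

What the generator does **not** emulate: volume conduction (a single
source mixing linearly into many channels), oscillatory rhythms with
phase relationships, heavy-tailed artifacts, or slowly varying coupling
strength. Passing tests on this generator therefore demonstrate the
mechanics of the pipeline — symbol identity under monotone distortion,
component bookkeeping, epoch localization after realignment — not that
the method resolves any particular physiological effect. Two caveats seen
in the tests: anchors whose windows straddle an epoch boundary share only
part of the waveform and may or may not merge (the dip's edges are soft at
the scale of one pattern span), and independent channels collide by chance
with probability bounded by $\binom{N}{2}/d!$ per time point, so component
counts outside epochs hover just below $N$ unless $d! \gg N^2$.

## The sliding permutation test

Condition comparisons use a two-sided paired sign-flip permutation test:
within each subject the two condition values at a time point are
exchangeable under the null, so the sign of each subject's difference is
flipped at random; the statistic is the absolute mean difference and the
add-one estimator $p = (1 + \#\{|\bar d^{perm}| \ge |\bar d|\})/(n_{perm}+1)$
keeps $p \ge 1/(n_{perm}+1)$. The paired scheme matches a within-subject
design; the two-sided statistic is the conservative reading when the
direction of an effect is not prespecified. One seeded stream drives
independent draws per time point, so a whole result is reproducible from
one seed. No multiple-testing correction is applied across time — the
0.05/0.01 levels in `autoplot()` are reference lines, and readers should
treat isolated sub-threshold excursions accordingly. Calibration is tested
by exhaustive enumeration for small $n$ and by the uniformity of null
p-values (KS check over 1000 simulated nulls).

## Problem sizes used by the test suite

The suite runs the benchmark once at 100 realizations per coupling (the
same size the acceptance script uses), four directional batches of 8
uncoupled realizations, property loops of 1000 random symbol vectors, 100
random graphs against igraph, 1000 simulated null tests at 199
permutations, and synthetic ensembles of 6–10 channels and 300–700
samples. These sizes keep every Monte-Carlo tolerance in the tests at the
3-sigma level or better while the whole suite completes in minutes.

## Known limitations

- Binary, threshold-free links mean no notion of connection strength;
  relaxing identity to graded symbolic similarity would reintroduce a
  threshold and is deliberately not implemented.
- The identity criterion makes component structure (cliques) rigid; the
  interesting temporal signal is *which* channels merge and when, not
  within-component topology.
- FNN and MI estimators need a few thousand points for stable estimates;
  on short segments the delay estimate is noisy (the aggregation across
  channels exists precisely to stabilize this).
- The pipeline compares symbols at equal times only; lagged coupling
  between channels is invisible unless it happens to align patterns.
- EEG-specific preprocessing (filtering, artifact rejection, re-referencing,
  trial averaging) is out of scope; the package expects cleaned,
  channel-major numeric matrices.
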