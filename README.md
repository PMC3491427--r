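# opnet

Time-evolving functional connectivity from order patterns.

Multichannel physiological recordings (EEG above all) are short, noisy and
non-stationary, which defeats most connectivity measures that need long
stationary windows and a thresholding step. `opnet` takes a different route:
each channel is encoded into a sequence of **order patterns** — the
permutation describing the relative ranks of `d` samples spaced `τ` apart —
and two channels are declared functionally connected at time *t* exactly
when their patterns at *t* are identical:

```
A_ij(t) = 1  iff  π_i(t) = π_j(t),   i ≠ j
```

Because only ranks enter the encoding, the links are invariant under any
strictly increasing amplitude transformation (gains, drifts, monotone sensor
nonlinearities) and no similarity threshold is ever chosen: the result is
directly a **temporal sequence of binary networks**, one per time point,
each a disjoint union of cliques (channels sharing a symbol). From an
`N × T` recording with parameters `(d, τ)` you get `T − (d−1)τ` networks.

The package covers the full workflow:

- **Symbolization** — `symbolize_set()`, with the lexicographic
  (Lehmer-code) integer encoding of patterns (`pattern_index()` /
  `pattern_unrank()`).
- **Parameter estimation** — embedding dimension by false nearest
  neighbours (`estimate_dimension()`), delay by the first minimum of the
  auto-mutual-information (`estimate_delay()`), aggregation across channels
  (mode of dimensions, mean of delays) and over-embedding `d̂ = 2d + 2`
  (`aggregate_params()`), window-centre time realignment
  (`realign_times()`).
- **Networks and metrics** — `build_network_sequence()`, link density
  ρ(t), clustering C(t) and normalized clustering C′(t) = C/ρ, connected
  components, graph distances (`metric_time_series()` returns a tidy
  tibble).
- **Statistics** — a sliding paired sign-flip permutation test between two
  conditions (`sliding_permutation_test()`, 2000 permutations by default).
- **Benchmark & synthetic data** — two coupled/uncoupled Lorenz
  oscillators integrated with Dormand–Prince RK4(5)
  (`simulate_coupled_lorenz()`), the link-detection benchmark against a
  windowed-correlation baseline (`run_lorenz_benchmark()`), and a seeded
  generator that plants epochs of shared (monotonically distorted)
  waveforms across channel groups (`generate_synthetic_ensemble()`).

Results are tibbles or small S3 objects with `tidy()`/`glance()` methods
and `autoplot()`/`plot_metric_series()` graphics, so everything chains with
the pipe.

## Worked example

Plant a synchronized epoch across four of eight channels, then watch the
component count dip while it lasts:

```r
library(opnet)
library(dplyr)

sim <- generate_synthetic_ensemble(
  8, 600, groups = list(list(channels = 1:4, epoch = c(201, 400))), seed = 42)
sim$data
#> <ts_set> 8 channel(s) x 600 samples

sy <- symbolize_set(sim$data, d = 5, tau = 4)
sy
#> <op_symbols> 8 channel(s) x 584 symbols (d = 5, tau = 4, alphabet size 120)

nets <- build_network_sequence(sy)
nets
#> <op_networks> 584 networks on 8 nodes (d = 5, tau = 4); times in samples

metric_time_series(nets, c("density", "n_components")) |>
  mutate(phase = ifelse(t >= 201 & t <= 400 - 16, "epoch interior", "outside")) |>
  group_by(metric, phase) |>
  summarise(mean = round(mean(value), 3), .groups = "drop")
#>         metric          phase  mean
#> 1      density epoch interior 0.223
#> 2      density        outside 0.014
#> 3 n_components epoch interior 4.886
#> 4 n_components        outside 7.648
```

Inside the epoch the four planted channels always share one symbol — their
windows see the same waveform through channel-specific increasing
distortions — so the component count drops from ≈8 to ≈5 and the link
density rises accordingly. `plot_metric_series()` draws the curves;
`sliding_permutation_test()` compares two such panels across subjects.

The Lorenz benchmark contrasts the order-pattern detector with windowed
correlation (window = pattern span `(d−1)τ`):

```r
run_lorenz_benchmark(n_realizations = 5, seed = 7)
#>    coupling        method dimension window     rate       sd
#>  1  coupled order_pattern         2     30 1.000000 0.00e+00
#>  2  coupled order_pattern         6    150 1.000000 0.00e+00
#>  3  coupled   correlation         2     30 1.000000 9.00e-10
#>  4  coupled   correlation         6    150 1.000000 5.67e-10
#>  5 uncoupled order_pattern         2     30 0.448454 1.02e-01
#>  6 uncoupled order_pattern         6    150 0.000235 5.26e-04
#>  7 uncoupled   correlation         2     30 0.859793 1.87e-02
#>  8 uncoupled   correlation         6    150 0.520264 1.22e-01
```

Both detectors find the synchronized (coupled, g = 5) pair. On the
*uncoupled* pair, correlation reports ≈0.86 spurious association at short
windows and ≈0.52 even at long ones, while the order-pattern rate falls
from ≈0.45 at the estimated dimension `d = 2` to essentially zero at the
over-embedded `d̂ = 6` — over-embedding is what suppresses false positives.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/opnet run-all --input recording.csv --outdir out/
Rscript inst/cli/opnet lorenz-benchmark --n 100 --seed 1
Rscript inst/cli/opnet --help
```

## Vignette

`vignettes/order-pattern-networks.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, the
numerical conventions (tie handling, binning, rounding, degenerate cases)
and the known limitations.
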