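# spikete

Effective (directed) connectivity between spiking neurons from binned
spike trains, using extensions of transfer entropy, with a
known-ground-truth spiking network simulator and an ROC evaluation
framework for benchmarking.

## The problem

Synaptic influences between cortical neurons arrive with conduction
delays of one to tens of milliseconds, and presynaptic "messages" can
span several bins (bursts). Classical single-delay transfer entropy
(D1TE) looks only one bin back and misses most of this structure.
`spikete` implements:

* **D1TE** — transfer entropy at a single one-bin delay,
  `TE = Σ p(i_{t+1}, i_t, j_t) log2 [ p(i_{t+1} | i_t, j_t) /
  p(i_{t+1} | i_t) ]` (bits);
* **delayed TE** — the same quantity with the source bin shifted `d`
  bins into the past (`d` = 1…30), giving a delay profile per ordered
  pair whose peak sits at the putative conduction delay;
* **HOTE** — higher-order TE with `k`-bin target histories and `l`-bin
  source messages (`k, l` = 1…5), tallied with a sparse pattern-counting
  algorithm whose cost scales with spikes, not bins;
* **NCC / NCCH** — normalized cross-correlation (standardized, and
  spike-count normalized) on the same delay grid, for comparison.

Profiles are collapsed to a single connection score by their peak (Pk)
or by the coincidence index (CI; area within a ~5 ms window around the
peak over total area). Scores are benchmarked against known wiring by
ROC analysis: TPR at a fixed false positive rate of 0.01, purity, the
fraction of synaptic weight identified, inhibitory/excitatory breakdown,
and sweeps over recording length, bin width and message-length order.

Ground truth comes from the bundled Izhikevich spiking cortical network:
800 regular-spiking + 200 fast-spiking neurons, 100 delayed synapses
each, STDP on excitatory weights for one simulated hour, frozen weights
for a second hour, final 30 minutes recorded and 80 + 20 neurons
sub-sampled — a compiled implementation that runs the full two-hour
protocol in under a minute.

The package is aimed at methodologists validating connectivity measures
and at experimentalists who want delay-resolved TE on their own rasters.

## Worked example

A source neuron drives a target with a 7-ms delay; delayed TE finds the
lag, while D1TE sees almost nothing:

```r
library(spikete)
set.seed(42)
D <- 60000                      # one minute of 1-ms bins
j <- rbinom(D, 1, 0.02)         # source neuron, ~20 Hz
i <- integer(D)                 # target responds 7 ms later, p = 0.6
at <- which(j == 1) + 7
at <- at[at <= D]
i[at[runif(length(at)) < 0.6]] <- 1L
i[sample.int(D, 150)] <- 1L     # plus background spikes

prof <- delayed_te(i, j, delays = 1:30)
peak_score(prof)
#> $value
#> [1] 0.06506446
#> $delay
#> [1] 7
coincidence_index(prof, tau_ms = 5, T_ms = 30)
#> [1] 0.9903199
d1te(i, j)
#> [1] 4.3e-05
```

The peak sits exactly at the 7-ms lag and the profile is sharply peaked
(CI ≈ 0.99); the single-delay value is four orders of magnitude smaller
because the signal is not at a one-bin lag.

End to end on a short simulation (15 min of STDP, 15 min frozen, last
10 min analyzed; about a minute of compute):

```r
cfg <- sim_config(stdp_duration_s = 900, frozen_duration_s = 900,
                  record_last_s = 600, seed = 7)
res <- run_pipeline(cfg, seeds = 7,
                    measures = c("HOTECI", "TECI", "NCCCI", "D1TE"))
res
#> <spk_pipeline_result> 1 seed(s)
#>  measure  tpr_mean tpr_sd weight_fraction_mean weight_fraction_sd
#>     D1TE 0.0000000      0            0.0000000                  0
#>   HOTECI 0.5105485      0            0.6520376                  0
#>    NCCCI 0.5021097      0            0.6435748                  0
#>     TECI 0.4908579      0            0.6288774                  0
```

Half of the true synapses are recovered at a 1% false positive rate from
only 10 minutes of data by the delay-resolved measures, and the weight
fraction exceeds the TPR because strong synapses are found first; D1TE
at 1-ms bins is blind here, since the post-synaptic response lags the
synaptic delay by a few milliseconds of integration time.

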