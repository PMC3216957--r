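# Independent brute-force oracles used to validate the sparse kernels.

# dense full-scan pattern counter: visits every valid t
dense_counts <- function(i, j, k, l, d) {
  D <- length(i)
  tmin <- max(k - 1, d + l - 2)  # 0-based
  tmax <- D - 2
  stopifnot(tmax >= tmin)
  cnt <- array(0, c(2, 2^k, 2^l))
  for (t in tmin:tmax) {
    inext <- i[t + 2]
    iw <- sum(i[(t + 1) - 0:(k - 1)] * 2^((k - 1):0))
    jw <- sum(j[(t + 2 - d) - 0:(l - 1)] * 2^((l - 1):0))
    cnt[inext + 1, iw + 1, jw + 1] <- cnt[inext + 1, iw + 1, jw + 1] + 1
  }
  cnt
}

# direct evaluation of the transfer entropy sum over all patterns
naive_te <- function(cnt) {
  n <- sum(cnt)
  te <- 0
  for (a in 1:2) for (b in seq_len(dim(cnt)[2])) for (g in seq_len(dim(cnt)[3])) {
    pj <- cnt[a, b, g] / n
    if (pj == 0) next
    p_cond_full <- cnt[a, b, g] / sum(cnt[, b, g])
    p_cond_hist <- sum(cnt[a, b, ]) / sum(cnt[, b, ])
    te <- te + pj * log2(p_cond_full / p_cond_hist)
  }
  te
}

# a random binary series of given density
rbin <- function(D, p) stats::rbinom(D, 1, p)

# two-row raster from binary vectors
pair_raster <- function(i, j, bin_ms = 1) {
  spike_raster(rbind(i, j), bin_ms = bin_ms)
}

# small, fast network config for simulator tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_excitatory = 40, n_inhibitory = 10, synapses_per_neuron = 10,
         stdp_duration_s = 2, frozen_duration_s = 2, record_last_s = 2),
    list(...))
  do.call(sim_config, args)
}
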