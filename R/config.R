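#' Izhikevich neuron parameter presets
#'
#' Parameters `(a, b, c, d)` of the Izhikevich model: `a` sets the time
#' scale of the recovery variable (1/ms), `b` its sensitivity to
#' subthreshold voltage, `c` the post-spike reset voltage (mV) and `d` the
#' post-spike recovery increment.  `"RS"` is the regular-spiking excitatory
#' preset `(0.02, 0.2, -65, 8)`; `"FS"` the fast-spiking inhibitory preset
#' `(0.1, 0.2, -65, 2)`.
#'
#' @param type `"RS"` or `"FS"`.
#' @return A list with numeric fields `a`, `b`, `c`, `d`.
#' @examples
#' neuron_params("RS")
#' @export
neuron_params <- function(type = c("RS", "FS")) {
  type <- match.arg(type)
  switch(type,
    RS = list(a = 0.02, b = 0.2, c = -65, d = 8),
    FS = list(a = 0.1, b = 0.2, c = -65, d = 2)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the spiking cortical
#' network simulation.  Defaults describe the standard protocol: 800
#' regular-spiking excitatory and 200 fast-spiking inhibitory neurons, 100
#' outgoing synapses per neuron, excitatory conduction delays uniform on
#' 1--20 ms, inhibitory delays fixed at 1 ms, initial excitatory weights of
#' 6 mV (plastic under STDP, clipped to \[0, 10\] mV), inhibitory weights of
#' -5 mV (fixed), 20-mV thalamic inputs at a mean rate of 1 Hz per neuron,
#' one hour of STDP followed by one hour with frozen weights, of which the
#' final 30 minutes are recorded in 1-ms bins.
#'
#' @param n_excitatory,n_inhibitory Neuron counts per type.
#' @param synapses_per_neuron Out-degree of every neuron.
#' @param exc_delay_range_ms Integer delay interval for excitatory synapses.
#' @param inh_delay_ms Fixed delay of inhibitory synapses (ms).
#' @param init_exc_weight_mV,inh_weight_mV,max_exc_weight_mV,thalamic_weight_mV
#'   Synaptic weights in mV; `inh_weight_mV` is a magnitude, stored with a
#'   negative sign.
#' @param thalamic_rate_hz Mean thalamic input rate per neuron (Hz).
#' @param thalamic_scheme `"one-per-ms"` delivers one input to a uniformly
#'   chosen neuron each millisecond (equivalent to 1 Hz/neuron for 1000
#'   neurons); `"bernoulli"` gives each neuron an independent input with the
#'   per-ms probability implied by `thalamic_rate_hz`.
#' @param stdp_duration_s Seconds of simulation with STDP active.
#' @param frozen_duration_s Seconds with weights frozen afterwards.
#' @param record_last_s Length of the recorded window at the end of the
#'   frozen phase (seconds).
#' @param bin_ms Width of the spike-time bins (ms).
#' @param seed Master seed; wiring, dynamics and sub-sampling use
#'   deterministic streams derived from it.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(stdp_duration_s = 10, frozen_duration_s = 10,
#'                   record_last_s = 10)
#' @export
sim_config <- function(n_excitatory = 800L,
                       n_inhibitory = 200L,
                       synapses_per_neuron = 100L,
                       exc_delay_range_ms = c(1L, 20L),
                       inh_delay_ms = 1L,
                       init_exc_weight_mV = 6,
                       inh_weight_mV = 5,
                       max_exc_weight_mV = 10,
                       thalamic_weight_mV = 20,
                       thalamic_rate_hz = 1,
                       thalamic_scheme = c("one-per-ms", "bernoulli"),
                       stdp_duration_s = 3600,
                       frozen_duration_s = 3600,
                       record_last_s = 1800,
                       bin_ms = 1,
                       seed = 1L) {
  cfg <- list(
    n_excitatory = as.integer(n_excitatory),
    n_inhibitory = as.integer(n_inhibitory),
    synapses_per_neuron = as.integer(synapses_per_neuron),
    exc_delay_range_ms = as.integer(exc_delay_range_ms),
    inh_delay_ms = as.integer(inh_delay_ms),
    init_exc_weight_mV = init_exc_weight_mV,
    inh_weight_mV = inh_weight_mV,
    max_exc_weight_mV = max_exc_weight_mV,
    thalamic_weight_mV = thalamic_weight_mV,
    thalamic_rate_hz = thalamic_rate_hz,
    thalamic_scheme = match.arg(thalamic_scheme),
    stdp_duration_s = stdp_duration_s,
    frozen_duration_s = frozen_duration_s,
    record_last_s = record_last_s,
    bin_ms = bin_ms,
    seed = as.integer(seed)
  )
  n <- cfg$n_excitatory + cfg$n_inhibitory
  stopifnot(
    cfg$n_excitatory >= 0, cfg$n_inhibitory >= 0, n > 0,
    cfg$synapses_per_neuron >= 0,
    length(cfg$exc_delay_range_ms) == 2,
    cfg$exc_delay_range_ms[1] >= 1,
    diff(cfg$exc_delay_range_ms) >= 0,
    cfg$inh_delay_ms >= 1,
    is.finite(cfg$init_exc_weight_mV), is.finite(cfg$inh_weight_mV),
    is.finite(cfg$max_exc_weight_mV), is.finite(cfg$thalamic_weight_mV),
    cfg$thalamic_rate_hz >= 0,
    cfg$stdp_duration_s >= 0, cfg$frozen_duration_s >= 0,
    cfg$record_last_s > 0,
    cfg$record_last_s <= cfg$frozen_duration_s + cfg$stdp_duration_s,
    cfg$bin_ms >= 1
  )
  if (cfg$record_last_s > cfg$frozen_duration_s && cfg$stdp_duration_s > 0)
    warning("recorded window extends into the plastic (STDP) phase")
  if (cfg$synapses_per_neuron >= n)
    stop("synapses_per_neuron must be smaller than the network size")
  structure(cfg, class = "sim_config")
}

# run code with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic sub-seed for a named stream, kept within the 32-bit
# integer range R requires of set.seed()
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
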