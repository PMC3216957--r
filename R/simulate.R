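#' Simulate the spiking cortical network
#'
#' Runs the Izhikevich network defined by `config`: Euler integration of
#' the membrane equations in 0.5-ms half-steps, spike reset at 30 mV,
#' delayed synaptic delivery, Poisson thalamic drive, and additive STDP on
#' excitatory synapses during the first `stdp_duration_s` seconds (weights
#' clipped to \[0, `max_exc_weight_mV`\]), after which weights are frozen.
#' Spikes from the final `record_last_s` seconds are returned in 1-ms bins.
#'
#' @param config A [sim_config()].
#' @param network Optionally a pre-built [build_network()] result (must
#'   match `config`); by default the wiring is drawn from the config's
#'   wiring stream.
#' @return A list with elements
#'   \describe{
#'     \item{spikes}{a [spike_trains()] object for all neurons, times in ms
#'       relative to the start of the recorded window;}
#'     \item{network}{the `"spk_network"` with post-STDP (frozen) weights.}
#'   }
#' @examples
#' cfg <- sim_config(n_excitatory = 80, n_inhibitory = 20,
#'                   synapses_per_neuron = 10, stdp_duration_s = 2,
#'                   frozen_duration_s = 2, record_last_s = 2)
#' sim <- simulate_network(cfg)
#' @export
simulate_network <- function(config, network = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(network)) network <- build_network(config)
  stopifnot(inherits(network, "spk_network"))

  n <- network$n_neurons
  type <- network$neuron_type
  rs <- neuron_params("RS")
  fs <- neuron_params("FS")
  pick <- function(f) ifelse(type == "exc", rs[[f]], fs[[f]])

  total_ms <- as.integer(round(
    (config$stdp_duration_s + config$frozen_duration_s) * 1000))
  record_ms <- as.integer(round(config$record_last_s * 1000))
  stdp_ms <- as.integer(round(config$stdp_duration_s * 1000))

  res <- sim_network_cpp(
    post = network$post,
    delay = network$delay_ms,
    weight = network$weight_mV,
    is_exc = type == "exc",
    a = pick("a"), b = pick("b"), c = pick("c"), d = pick("d"),
    stdp_ms = stdp_ms, total_ms = total_ms, record_ms = record_ms,
    s_max = config$max_exc_weight_mV,
    thal_w = config$thalamic_weight_mV,
    thal_scheme = if (config$thalamic_scheme == "one-per-ms") 0L else 1L,
    thal_p = config$thalamic_rate_hz / 1000,
    seed = as.numeric(derive_seed(config$seed, "dynamics"))
  )
  network$weight_mV <- res$weights
  spikes <- spike_trains(res$spikes, duration_ms = record_ms,
                         neuron_ids = seq_len(n))
  list(spikes = spikes, network = network)
}

#' Sub-sample recorded neurons
#'
#' Mimics an electrode array that records only part of the population:
#' randomly keeps `n_exc` excitatory and `n_inh` inhibitory neurons and
#' restricts the ground truth to the sampled set.
#'
#' @param spikes A [spike_trains()] object covering the full network.
#' @param net The matching `"spk_network"`.
#' @param n_exc,n_inh Neurons of each type to keep.
#' @param seed Seed of the sub-sampling stream; `NULL` derives one from the
#'   network's config.
#' @return A list with `spikes` (restricted, `neuron_ids` giving original
#'   indices) and `truth` (a [ground_truth()] over the sampled neurons).
#' @export
subsample_recording <- function(spikes, net, n_exc = 80, n_inh = 20,
                                seed = NULL) {
  stopifnot(inherits(spikes, "spk_spike_trains"),
            inherits(net, "spk_network"))
  if (is.null(seed)) seed <- derive_seed(net$config$seed, "subsample")
  exc_ids <- which(net$neuron_type == "exc")
  inh_ids <- which(net$neuron_type == "inh")
  stopifnot(n_exc <= length(exc_ids), n_inh <= length(inh_ids))
  ids <- with_seed(seed, sort(c(
    if (n_exc > 0) sample(exc_ids, n_exc) else integer(),
    if (n_inh > 0) sample(inh_ids, n_inh) else integer()
  )))
  sub <- spike_trains(spikes$times[ids], duration_ms = spikes$duration_ms,
                      neuron_ids = spikes$neuron_ids[ids])
  list(spikes = sub, truth = ground_truth(net, ids))
}

#' Mean firing rates per neuron type
#'
#' @param spikes A [spike_trains()] object.
#' @param neuron_type Character vector (`"exc"`/`"inh"`) aligned with the
#'   trains.
#' @return Named numeric vector of mean rates in Hz per type.
#' @export
firing_rates <- function(spikes, neuron_type) {
  stopifnot(inherits(spikes, "spk_spike_trains"),
            length(neuron_type) == length(spikes$times))
  counts <- lengths(spikes$times)
  rate <- counts / (spikes$duration_ms / 1000)
  vapply(split(rate, neuron_type), mean, numeric(1))
}
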