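#' Run the full simulate / measure / evaluate pipeline
#'
#' For each seed: simulate the network, sub-sample the recorded neurons,
#' bin the spikes, compute the requested connectivity measures, and
#' evaluate them against the ground truth at the operating FPR.  Results
#' are deterministic given the seeds.
#'
#' @param config A [sim_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of master seeds (one simulated data set
#'   each).
#' @param n_exc,n_inh Recorded neurons per type (sub-sampling).
#' @param measures,delays,hote_pk_order,hote_ci_order,tau_ms,T_ms Passed to
#'   [connectivity_scores()].
#' @param fpr_readout,weak_mV Passed to [evaluate_scores()].
#' @return A list of class `"spk_pipeline_result"`:
#'   \describe{
#'     \item{per_seed}{data.frame `seed`, `measure`, `tpr`, `purity`,
#'       `weight_fraction`, `inhibitory_fraction`, `exc_tp`, `inh_tp`,
#'       `fp`;}
#'     \item{aggregate}{mean and s.d. of `tpr` and `weight_fraction` per
#'       measure across seeds;}
#'     \item{sim_stats}{per-seed firing rates and weight statistics of the
#'       full network.}
#'   }
#' @export
run_pipeline <- function(config = sim_config(),
                         seeds = config$seed,
                         n_exc = 80, n_inh = 20,
                         measures = c("HOTEPk", "HOTECI", "TEPk", "TECI",
                                      "NCCPk", "NCCCI", "D1TE"),
                         delays = 1:30,
                         hote_pk_order = c(1, 3),
                         hote_ci_order = c(3, 2),
                         tau_ms = 5, T_ms = 30,
                         fpr_readout = 0.01, weak_mV = 1) {
  stopifnot(inherits(config, "sim_config"), length(seeds) >= 1)
  per_seed <- list()
  sim_stats <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    sim <- simulate_network(cfg)
    sim_stats[[length(sim_stats) + 1]] <-
      cbind(seed = seed, as.data.frame(simulation_stats(sim, weak_mV)))
    sub <- subsample_recording(sim$spikes, sim$network, n_exc, n_inh)
    raster <- bin_spikes(sub$spikes, cfg$bin_ms)
    sc <- connectivity_scores(raster, measures, delays = delays,
                              hote_pk_order = hote_pk_order,
                              hote_ci_order = hote_ci_order,
                              tau_ms = tau_ms, T_ms = T_ms)
    for (m in names(sc)) {
      ev <- evaluate_scores(sc[[m]], sub$truth, fpr_readout, weak_mV)
      per_seed[[length(per_seed) + 1]] <- data.frame(
        seed = seed, measure = m, tpr = ev$tpr, purity = ev$purity,
        weight_fraction = ev$weight_fraction,
        inhibitory_fraction = ev$breakdown$inhibitory_fraction,
        exc_tp = ev$breakdown$exc_tp, inh_tp = ev$breakdown$inh_tp,
        fp = ev$breakdown$fp)
    }
  }
  per_seed <- do.call(rbind, per_seed)
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$measure),
    function(d) data.frame(
      measure = d$measure[1],
      tpr_mean = mean(d$tpr), tpr_sd = sd_or_zero(d$tpr),
      weight_fraction_mean = mean(d$weight_fraction),
      weight_fraction_sd = sd_or_zero(d$weight_fraction))))
  rownames(agg) <- NULL
  structure(list(per_seed = per_seed, aggregate = agg,
                 sim_stats = do.call(rbind, sim_stats)),
            class = "spk_pipeline_result")
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' @export
print.spk_pipeline_result <- function(x, ...) {
  cat(sprintf("<spk_pipeline_result> %d seed(s)\n",
              length(unique(x$per_seed$seed))))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Summary statistics of a simulated data set
#'
#' Firing rates per neuron type over the recorded window and the weight
#' statistics used to characterize the post-STDP network: the percentage
#' of excitatory synapses below the weak threshold, the connectivity
#' density after excluding weak synapses, and the fraction of total
#' synaptic weight carried by the excluded synapses.
#'
#' @param sim A [simulate_network()] result.
#' @param weak_mV Weak-weight threshold (mV).
#' @return A list with `rate_exc_hz`, `rate_inh_hz`, `pct_weak_exc`,
#'   `density_pct`, `excluded_weight_pct`.
#' @export
simulation_stats <- function(sim, weak_mV = 1) {
  net <- sim$network
  rates <- firing_rates(sim$spikes, net$neuron_type)
  exc <- net$neuron_type == "exc"
  w_exc <- net$weight_mV[exc, , drop = FALSE]
  w_all_abs <- abs(net$weight_mV)
  n <- net$n_neurons
  strong <- sum(w_all_abs > weak_mV)
  list(
    rate_exc_hz = unname(rates["exc"]),
    rate_inh_hz = if ("inh" %in% names(rates))
      unname(rates["inh"]) else NA_real_,
    pct_weak_exc = 100 * mean(w_exc < weak_mV),
    density_pct = 100 * strong / (n * (n - 1)),
    excluded_weight_pct = 100 * sum(w_exc[w_exc <= weak_mV]) /
      sum(w_all_abs)
  )
}
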