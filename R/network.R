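#' Build the ground-truth synaptic wiring
#'
#' Draws the random connectivity of the simulated cortical network: every
#' neuron receives `synapses_per_neuron` outgoing synapses to distinct
#' targets (no self-connections).  Excitatory synapses get conduction
#' delays spread uniformly over `exc_delay_range_ms` (balanced -- an equal
#' number of synapses per delay value -- when the out-degree is a multiple
#' of the number of delay values, independently sampled otherwise) and the
#' initial weight `init_exc_weight_mV`.  Inhibitory neurons project only
#' onto excitatory neurons, with fixed delay `inh_delay_ms` and weight
#' `-inh_weight_mV`.
#'
#' @param config A [sim_config()].
#' @param seed Seed of the wiring stream; `NULL` uses the stream derived
#'   from `config$seed`.
#' @return An object of class `"spk_network"`: a synapse table with
#'   `post`, `delay_ms` and `weight_mV` matrices (neurons x out-degree),
#'   a `neuron_type` vector (`"exc"`/`"inh"`), and the originating config.
#' @seealso [weight_matrix()], [ground_truth()], [simulate_network()]
#' @examples
#' net <- build_network(sim_config(n_excitatory = 40, n_inhibitory = 10,
#'                                 synapses_per_neuron = 20))
#' table(rowSums(net$post > 0))  # out-degree 20 for all 50 neurons
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- derive_seed(config$seed, "wiring")
  ne <- config$n_excitatory
  ni <- config$n_inhibitory
  n <- ne + ni
  m <- config$synapses_per_neuron
  type <- rep(c("exc", "inh"), c(ne, ni))

  dlo <- config$exc_delay_range_ms[1]
  dhi <- config$exc_delay_range_ms[2]
  nd <- dhi - dlo + 1

  post <- matrix(0L, n, m)
  delay <- matrix(0L, n, m)
  weight <- matrix(0, n, m)
  if (m > 0) {
    with_seed(seed, {
      for (i in seq_len(n)) {
        if (type[i] == "exc") {
          cand <- setdiff(seq_len(n), i)
          if (m %% nd == 0) {
            dl <- rep(dlo:dhi, each = m %/% nd)
          } else {
            dl <- sort(sample(dlo:dhi, m, replace = TRUE))
          }
          w <- config$init_exc_weight_mV
        } else {
          # inhibitory neurons target excitatory neurons only; if the
          # network has none, fall back to any other neuron
          cand <- if (ne > 0) seq_len(ne) else setdiff(seq_len(n), i)
          dl <- rep(config$inh_delay_ms, m)
          w <- -config$inh_weight_mV
        }
        if (m > length(cand))
          stop("not enough distinct targets for neuron ", i)
        post[i, ] <- sample(cand, m)
        delay[i, ] <- dl
        weight[i, ] <- w
      }
    })
  }
  structure(
    list(post = post, delay_ms = delay, weight_mV = weight,
         neuron_type = type, n_neurons = n, config = config),
    class = "spk_network"
  )
}

#' @export
print.spk_network <- function(x, ...) {
  cat(sprintf(
    "<spk_network> %d neurons (%d exc, %d inh), out-degree %d\n",
    x$n_neurons, sum(x$neuron_type == "exc"), sum(x$neuron_type == "inh"),
    ncol(x$post)))
  invisible(x)
}

#' Signed weight and delay matrices of a network
#'
#' @param net A `"spk_network"`.
#' @return `weight_matrix()`: a dense pre x post matrix of signed synaptic
#'   weights (mV), 0 where no synapse exists. `delay_matrix()`: the matching
#'   integer delay matrix (ms), 0 where no synapse exists.
#' @export
weight_matrix <- function(net) {
  stopifnot(inherits(net, "spk_network"))
  w <- matrix(0, net$n_neurons, net$n_neurons)
  idx <- cbind(rep(seq_len(nrow(net$post)), ncol(net$post)),
               as.vector(net$post))
  w[idx] <- as.vector(net$weight_mV)
  w
}

#' @rdname weight_matrix
#' @export
delay_matrix <- function(net) {
  stopifnot(inherits(net, "spk_network"))
  d <- matrix(0L, net$n_neurons, net$n_neurons)
  idx <- cbind(rep(seq_len(nrow(net$post)), ncol(net$post)),
               as.vector(net$post))
  d[idx] <- as.vector(net$delay_ms)
  d
}

#' Ground truth restricted to a set of recorded neurons
#'
#' Collapses a synapse-table network to the dense representation used by
#' the evaluation module: signed weight and delay matrices over the
#' recorded neurons, plus their types and original ids.
#'
#' @param net A `"spk_network"`.
#' @param ids Neuron ids to keep (default: all).
#' @return An object of class `"spk_truth"` with fields `weight_mV`
#'   (signed, pre x post), `delay_ms`, `adjacency` (logical: a synapse
#'   exists, regardless of weight), `neuron_type`, `neuron_ids`.
#' @export
ground_truth <- function(net, ids = seq_len(net$n_neurons)) {
  w <- weight_matrix(net)[ids, ids, drop = FALSE]
  d <- delay_matrix(net)[ids, ids, drop = FALSE]
  structure(
    list(weight_mV = w, delay_ms = d, adjacency = d > 0,
         neuron_type = net$neuron_type[ids], neuron_ids = ids),
    class = "spk_truth"
  )
}

#' @export
print.spk_truth <- function(x, ...) {
  cat(sprintf("<spk_truth> %d neurons, %d synapses\n",
              length(x$neuron_ids), sum(x$adjacency)))
  invisible(x)
}

#' @export
as.data.frame.spk_truth <- function(x, ...) {
  idx <- which(x$adjacency, arr.ind = TRUE)
  data.frame(
    pre = x$neuron_ids[idx[, 1]],
    post = x$neuron_ids[idx[, 2]],
    weight_mV = x$weight_mV[idx],
    delay_ms = x$delay_ms[idx]
  )
}
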