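test_that("no drive and no initial weights means no spikes", {
  cfg <- sim_config(n_excitatory = 20, n_inhibitory = 5,
                    synapses_per_neuron = 5,
                    init_exc_weight_mV = 0, inh_weight_mV = 0,
                    thalamic_rate_hz = 0,
                    stdp_duration_s = 0, frozen_duration_s = 2,
                    record_last_s = 2)
  sim <- simulate_network(cfg)
  expect_equal(sum(lengths(sim$spikes$times)), 0)
})

test_that("with STDP disabled excitatory weights stay exactly at 6 mV", {
  cfg <- tiny_config(stdp_duration_s = 0, frozen_duration_s = 3,
                     record_last_s = 3)
  sim <- simulate_network(cfg)
  exc <- sim$network$neuron_type == "exc"
  expect_true(all(sim$network$weight_mV[exc, ] == 6))
})

test_that("STDP changes only excitatory weights, within bounds", {
  cfg <- tiny_config(stdp_duration_s = 4, frozen_duration_s = 1,
                     record_last_s = 1)
  sim <- simulate_network(cfg)
  exc <- sim$network$neuron_type == "exc"
  w_exc <- sim$network$weight_mV[exc, ]
  expect_true(all(w_exc >= 0 & w_exc <= cfg$max_exc_weight_mV))
  expect_gt(stats::sd(w_exc), 0)  # plasticity actually moved weights
  expect_true(all(sim$network$weight_mV[!exc, ] == -5))
})

test_that("simulation is reproducible from the master seed", {
  cfg <- tiny_config(seed = 123)
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(a$spikes$times, b$spikes$times)
  expect_identical(a$network$weight_mV, b$network$weight_mV)
  cfg2 <- tiny_config(seed = 124)
  c <- simulate_network(cfg2)
  expect_false(identical(a$spikes$times, c$spikes$times))
})

test_that("recorded spikes lie within the recording window, 1-ms bins", {
  cfg <- tiny_config()
  sim <- simulate_network(cfg)
  all_t <- unlist(sim$spikes$times)
  expect_true(all(all_t >= 0 & all_t < cfg$record_last_s * 1000))
  expect_true(all(all_t == floor(all_t)))
})

test_that("subsampling keeps consistent indices and pair counts", {
  cfg <- tiny_config()
  sim <- simulate_network(cfg)
  sub <- subsample_recording(sim$spikes, sim$network, n_exc = 8,
                             n_inh = 2, seed = 77)
  expect_length(sub$spikes$times, 10)
  expect_equal(length(sub$truth$neuron_ids), 10)
  expect_equal(sum(sub$truth$neuron_type == "inh"), 2)
  # spikes carried over unchanged for the sampled ids
  for (q in seq_along(sub$spikes$neuron_ids)) {
    id <- sub$spikes$neuron_ids[q]
    expect_identical(sub$spikes$times[[q]], sim$spikes$times[[id]])
  }
  # identity restriction
  full <- subsample_recording(sim$spikes, sim$network, n_exc = 40,
                              n_inh = 10, seed = 1)
  expect_equal(full$truth$neuron_ids, 1:50)
})

test_that("both thalamic schemes sustain comparable activity", {
  cfg1 <- sim_config(stdp_duration_s = 0, frozen_duration_s = 20,
                     record_last_s = 20, seed = 5)
  cfg2 <- sim_config(stdp_duration_s = 0, frozen_duration_s = 20,
                     record_last_s = 20, seed = 5,
                     thalamic_scheme = "bernoulli")
  r1 <- firing_rates(simulate_network(cfg1)$spikes,
                     rep(c("exc", "inh"), c(800, 200)))
  r2 <- firing_rates(simulate_network(cfg2)$spikes,
                     rep(c("exc", "inh"), c(800, 200)))
  expect_gt(r1[["exc"]], 0.5)
  expect_gt(r2[["exc"]], 0.5)
  expect_lt(abs(log(r1[["exc"]] / r2[["exc"]])), log(3))
})

test_that("firing rates are computed per neuron type", {
  st <- spike_trains(list(c(0, 500), c(100), numeric(0)), duration_ms = 1000)
  r <- firing_rates(st, c("exc", "exc", "inh"))
  expect_equal(r[["exc"]], 1.5)
  expect_equal(r[["inh"]], 0)
})
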