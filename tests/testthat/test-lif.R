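# A silent input set with n afferents.
empty_inputs <- function(n, duration) {
  structure(list(trains = rep(list(numeric(0)), n), n = n,
                 duration = duration, meta = list(kind = "empty")),
            class = "spike_input_set")
}

one_spike_input <- function(times, duration) {
  structure(list(trains = list(times), n = 1, duration = duration,
                 meta = list(kind = "manual")),
            class = "spike_input_set")
}

test_that("the membrane relaxes to rest without input", {
  pop <- synapse_population(0.003, plastic = FALSE)
  sim <- simulate_neuron(lif_params(), list(empty_inputs(1, 500)),
                         list(pop), 500, record_v = TRUE)
  expect_length(sim$post_times, 0)
  expect_equal(tail(sim$v, 1), -70, tolerance = 1e-6)
  expect_true(all(sim$v <= -54))
})

test_that("a clamped conductance gives the closed-form steady state", {
  # one spike raises g to 0.1; with an (effectively) infinite synaptic
  # time constant the conductance stays clamped and the subthreshold
  # steady state is (v_rest + g * e_syn) / (1 + g)
  params <- lif_params(tau_syn = 1e15)
  pop <- synapse_population(0.1, plastic = FALSE, g_max = 0.1)
  sim <- simulate_neuron(params, list(one_spike_input(0.05, 2000)),
                         list(pop), 2000, record_v = TRUE)
  expect_equal(tail(sim$v, 1), -70 / 1.1, tolerance = 1e-4)
})

test_that("output rate is positive and monotone in the weights", {
  for (seed in 1:5) {
    inp <- poisson_trains(400, 10, 4000, seed = seed)
    w <- init_bimodal_weights(400, 0.015, seed = seed)
    r1 <- length(simulate_neuron(lif_params(), list(inp),
                                 list(synapse_population(w, FALSE,
                                                         g_max = 0.015)),
                                 4000)$post_times)
    r2 <- length(simulate_neuron(lif_params(), list(inp),
                                 list(synapse_population(pmin(2 * w, 0.03),
                                                         FALSE,
                                                         g_max = 0.03)),
                                 4000)$post_times)
    expect_gt(r2, 0)
    expect_gte(r2, r1)
  }
})

test_that("bimodal initialization matches its contract", {
  g_max <- 0.006
  w <- init_bimodal_weights(1e5, g_max, seed = 1)
  expect_true(all(w >= 0 & w <= g_max))
  low <- w[w < g_max / 2]
  se <- sd(low) / sqrt(length(low))
  expect_lt(abs(mean(low) - 0.05 * g_max), 3 * se)
  expect_identical(w, init_bimodal_weights(1e5, g_max, seed = 1))
  # odd n: the larger half gets the low mode
  w_odd <- init_bimodal_weights(11, g_max, seed = 2)
  expect_length(w_odd, 11)
  expect_gte(sum(w_odd < g_max / 2), 6)
})

test_that("weights stay within bounds under heavy plasticity", {
  # high rates and a large learning rate to stress the clipping
  inp <- poisson_trains(100, 40, 3000, seed = 13)
  w0 <- runif(100, 0, 0.06)
  pop <- synapse_population(w0, plastic = TRUE, g_max = 0.06, eta = 0.2)
  sim <- simulate_neuron(lif_params(), list(inp), list(pop), 3000,
                         record_v = TRUE)
  expect_gt(length(sim$post_times), 0)
  expect_true(all(sim$weights[[1]] >= 0))
  expect_true(all(sim$weights[[1]] <= 0.06 + 1e-12))
  # recorded membrane samples never exceed threshold (reset applied)
  expect_true(all(sim$v <= -54 + 1e-9))
})

test_that("trace-based STDP equals the all-pairs double sum", {
  # deterministic short trains; amplitudes tiny so bounds never bind,
  # and a long refractory period so each driver pulse gives one spike
  set.seed(21)
  pre <- sort(runif(40, 0, 400))
  driver <- seq(10, 390, by = 25)      # strong non-plastic afferent
  params <- lif_params(t_ref = 20)
  plastic <- synapse_population(0.5, plastic = TRUE, g_max = 1,
                                eta = 1e-7, ltd_ratio = 1.05)
  strong <- synapse_population(5, plastic = FALSE, g_max = 5)
  sim <- simulate_neuron(params,
                         list(one_spike_input(pre, 400),
                              one_spike_input(driver, 400)),
                         list(plastic, strong), 400)
  posts <- sim$post_times
  expect_gt(length(posts), 3)
  dw_expected <- all_pairs_stdp(pre, posts,
                                a_plus = plastic$a_plus,
                                a_minus = plastic$a_minus, tau_stdp = 20)
  # 1e-10 tolerance in absolute weight units
  expect_lt(abs((sim$weights[[1]][1] - 0.5) - dw_expected), 1e-10)
})

test_that("exact pre/post coincidences fall on the depression branch", {
  # drive a single post spike (long refractory prevents a burst), then
  # place a plastic pre spike exactly at the recorded post time
  params <- lif_params(t_ref = 200)
  strong <- synapse_population(5, plastic = FALSE, g_max = 5)
  probe <- simulate_neuron(params, list(one_spike_input(10, 100),
                                        empty_inputs(1, 100)),
                           list(strong,
                                synapse_population(0.5, TRUE, g_max = 1,
                                                   eta = 1e-7)), 100)
  expect_length(probe$post_times, 1)
  t_post <- probe$post_times[1]
  plastic <- synapse_population(0.5, plastic = TRUE, g_max = 1, eta = 1e-7)
  sim <- simulate_neuron(params,
                         list(one_spike_input(10, 100),
                              one_spike_input(t_post, 100)),
                         list(strong, plastic), 100)
  expect_equal(sim$post_times[1], t_post)
  dw <- sim$weights[[2]][1] - 0.5
  # the tied pair must contribute exactly -a_minus, not +a_plus
  expect_lt(abs(dw - all_pairs_stdp(t_post, sim$post_times,
                                    plastic$a_plus, plastic$a_minus, 20)),
            1e-10)
  expect_lt(abs(dw + plastic$a_minus *
                  sum(exp(-(sim$post_times - t_post) / 20))), 1e-10)
})

test_that("copy experiment shows the directional asymmetry", {
  cfg <- copy_experiment_config(duration = 4e5)
  gains <- sapply(1:2, function(s) {
    fwd <- run_copy_experiment("indirect_to_direct", seed = s, config = cfg)
    rev <- run_copy_experiment("direct_to_indirect", seed = s, config = cfg)
    expect_true(all(abs(fwd$correlation) <= 1 + 1e-12))
    c(fwd = tail(fwd$correlation, 1) - fwd$correlation[1],
      rev = tail(rev$correlation, 1) - rev$correlation[1])
  })
  expect_true(all(gains["fwd", ] > 0))
  expect_true(all(gains["fwd", ] > gains["rev", ]))
  expect_true(all(gains["rev", ] < 0.05))
})

test_that("zero learning rate freezes the weight correlation", {
  cfg <- copy_experiment_config(duration = 3e4, eta = 0)
  r <- run_copy_experiment("indirect_to_direct", seed = 3, config = cfg)
  expect_equal(diff(range(r$correlation)), 0)
})

test_that("replay without plasticity gives a flat tuning trajectory", {
  cfg <- replay_experiment_config(duration = 6e3, eta = 0)
  r <- run_spatial_replay_experiment(speed_factor = 20, seed = 2,
                                     config = cfg)
  expect_equal(diff(range(r$correlation)), 0)
})
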