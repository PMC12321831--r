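test_that("optimized engine matches the brute-force per-synapse oracle exactly", {
  net <- make_tiny_net()
  n_steps <- 200
  drive <- tiny_input_steps(n_steps)

  oracle <- oracle_simulate(net, n_steps, drive)
  sim <- simulate_network(net, duration = n_steps * 0.1 / 1000,
                          scripted_input = steps_to_times(drive, 0.1),
                          snapshot_interval = 10, log_min_request = 0)

  expect_gt(nrow(oracle$raster), 0) # the fixture does spike
  expect_gt(sum(oracle$events$direction == "potentiation"), 0)
  expect_gt(sum(oracle$events$direction == "depression"), 0)

  expect_identical(sim$raster$time_ms, oracle$raster$time_ms)
  expect_identical(sim$raster$neuron, oracle$raster$neuron)
  expect_identical(sim$weights, oracle$weights)
  expect_identical(sim$pools, oracle$pools)
  # membrane trajectories agree to numerical precision (the engine tracks
  # per-neuron current aggregates; summation order differs from the oracle)
  expect_equal(sim$final_state$v, oracle$v, tolerance = 1e-12)
  expect_equal(sim$final_state$r, oracle$r, tolerance = 1e-12)

  # same pairings, same grants, event by event
  ev_e <- sim$events
  ev_o <- oracle$events
  expect_equal(nrow(ev_e), nrow(ev_o))
  expect_identical(ev_e$time_ms, ev_o$time_ms)
  expect_identical(as.integer(ev_e$synapse), ev_o$synapse)
  expect_identical(ev_e$tau, ev_o$tau)
  expect_identical(ev_e$granted, ev_o$granted)
})

test_that("oracle equivalence holds under a depression-heavy drive", {
  net <- make_tiny_net()
  net$rec$weight <- c(1.2, 1.0, 1.1, 0.9, 1.3)
  net$pools <- c(0.05, 0.0, 0.1) # scarce pools: partial grants exercised
  n_steps <- 200
  drive <- matrix(FALSE, n_steps, 2)
  drive[c(1, 31, 61, 101, 141), 1] <- TRUE
  drive[c(11, 71, 131), 2] <- TRUE

  oracle <- oracle_simulate(net, n_steps, drive)
  sim <- simulate_network(net, duration = 0.02,
                          scripted_input = steps_to_times(drive, 0.1),
                          log_min_request = 0)
  expect_identical(sim$weights, oracle$weights)
  expect_identical(sim$pools, oracle$pools)
  expect_identical(sim$raster$time_ms, oracle$raster$time_ms)
})

test_that("total resources obey the pool-decay budget over a full run", {
  net <- build_network(network_params(n_exc = 50, n_in = 20), seed = 4)
  sim <- simulate_network(net, duration = 2, input_rate = 50,
                          input_duration = 2, seed = 5)
  total0 <- sum(net$rec$weight) + sum(net$pools)
  total_end <- sum(sim$weights) + sum(sim$pools)
  # conservation: what is gone is exactly the integrated pool decay
  expect_equal(total_end + sim$cum_pool_decay, total0, tolerance = 1e-8)
  expect_true(all(sim$weights >= 0))
  expect_true(all(sim$pools >= 0))
  # the same holds at every snapshot along the trace
  tr <- sim$trace
  expect_true(all(abs(tr$weight_sum + tr$pool_sum + tr$cum_pool_decay - total0)
                  < 1e-6 * total0))
})

test_that("partial potentiation appears once pools run low", {
  net <- build_network(network_params(n_exc = 50, n_in = 20), seed = 4)
  sim <- simulate_network(net, duration = 2, input_rate = 50,
                          input_duration = 2, seed = 5)
  expect_gt(sim$n_partial_pot_events, 0)
  eff <- potentiation_efficacy(sim$events)
  expect_true(all(eff >= 0 & eff <= 100))
  expect_true(any(eff < 100))
  expect_true(any(eff == 100))
})

test_that("deletion schedule is deterministic and resources are accounted", {
  net <- build_network(network_params(n_exc = 30, n_in = 10), seed = 9)
  order <- seq_len(nrow(net$rec))
  run <- function(repl) simulate_network(
    net, duration = 3, input_rate = 50, input_duration = 1, seed = 6,
    degeneration = list(start = 1, interval = 2, order = order,
                        replenish = repl),
    log_events = FALSE)
  a <- run(TRUE)
  b <- run(TRUE)
  expect_identical(a$deletions, b$deletions)
  expect_false(any(duplicated(a$deletions$synapse)))
  # all scheduled deletions happened ((3 s - 1 s) / 2 ms >= n_syn)
  expect_equal(nrow(a$deletions), nrow(net$rec))
  expect_true(all(!a$alive))

  total0 <- sum(net$pools)
  # replenish on: losses only through pool decay
  expect_equal(sum(a$weights) + sum(a$pools) + a$cum_pool_decay, total0,
               tolerance = 1e-8)
  # replenish off: additionally the discarded deleted weights
  c <- run(FALSE)
  expect_equal(sum(c$weights) + sum(c$pools) + c$cum_pool_decay +
                 c$cum_discarded, total0, tolerance = 1e-8)
  expect_gt(c$cum_discarded, 0)
})

test_that("a silent network is detected and stops at cessation", {
  net <- build_network(network_params(n_exc = 20, n_in = 5), seed = 1)
  sim <- simulate_network(net, duration = 5, input_rate = 0,
                          input_duration = 0, stop_at_cessation = TRUE,
                          quiet_window = 500, log_events = FALSE)
  expect_equal(nrow(sim$raster), 0)
  expect_true(all(sim$weights == 0))
  expect_equal(sim$cessation_ms, 500)
  expect_lt(sim$end_time_ms, 5000)
})
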