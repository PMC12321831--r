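test_that("STDP window matches its closed form", {
  expect_equal(stdp_window(0, 0), 1)
  expect_equal(stdp_window(0, 5), 1)
  expect_equal(stdp_window(20, 1), exp(-1))
  expect_equal(stdp_window(-20, 1), 0.18 * exp(-1))
  expect_equal(stdp_window(-20, 0), 0)   # silent synapses are never depressed
  expect_equal(stdp_window(-10, 2), 2 * stdp_window(-10, 1)) # linear in w
  expect_true(all(stdp_window(seq(-100, 100, by = 7), 0.5) >= 0))
})

test_that("neighbor kernel is exponential in distance and sums to one", {
  norm <- 2 * (exp(-1) + exp(-2) + exp(-3))
  expect_equal(neighbor_share(1), exp(-1) / norm)
  expect_equal(neighbor_share(1), 0.33265, tolerance = 1e-4)
  expect_equal(sum(2 * neighbor_share(1:3)), 1)
  expect_equal(neighbor_share(4), 0)
  expect_gt(neighbor_share(1), neighbor_share(2))
})

test_that("potentiation draws neighbors-first with pool fallback, conserving resources", {
  params <- stdp_params()
  fx <- make_fixture("dendrite6")
  net <- fx$network
  j <- 4 # center synapse, pos 3, all six neighbors present
  total0 <- sum(net$rec$weight) + net$pools[8]

  # (i) ample neighbors: each loses its share, pool untouched
  res <- potentiate(net, j, 0.5)
  ev <- res$event
  expect_equal(ev$granted, 0.5)
  expect_equal(ev$from_pool, 0)
  shares <- neighbor_share(abs(res$network$rec$pos[-j] - 3))
  expect_equal(res$network$rec$weight[-j], 1 - 0.5 * shares)
  expect_equal(sum(res$network$rec$weight) + res$network$pools[8], total0)

  # (ii) silent neighbors, ample pool: everything from the pool
  net2 <- net
  net2$rec$weight[] <- 0
  net2$pools[8] <- 2
  res2 <- potentiate(net2, j, 0.7)
  expect_equal(res2$event$granted, 0.7)
  expect_equal(res2$event$from_neighbors, 0)
  expect_equal(res2$network$pools[8], 2 - 0.7)
  expect_equal(res2$network$rec$weight[j], 0.7)

  # (iii) pool holds only half the request: granted is capped, pool emptied
  net3 <- net2
  net3$pools[8] <- 0.35
  res3 <- potentiate(net3, j, 0.7)
  expect_equal(res3$event$granted, 0.35)
  expect_equal(res3$network$pools[8], 0)

  # (iv) neighbors supply part, pool the rest
  net4 <- net
  net4$rec$weight[] <- 0.05 # six neighbors cap at 0.3 total
  net4$rec$weight[j] <- 0
  net4$pools[8] <- 5
  res4 <- potentiate(net4, j, 1)
  expect_equal(res4$event$from_neighbors + res4$event$from_pool, 1)
  expect_gt(res4$event$from_pool, 0)
  expect_equal(res4$event$granted, 1)
  expect_equal(sum(res4$network$rec$weight) + res4$network$pools[8],
               sum(net4$rec$weight) + net4$pools[8])

  # (v) nothing anywhere: potentiation impossible
  net5 <- net2
  net5$pools[8] <- 0
  res5 <- potentiate(net5, j, 1)
  expect_equal(res5$event$granted, 0)
  expect_equal(res5$network$rec$weight, net5$rec$weight)

  expect_error(potentiate(net, 99, 0.1), "unknown synapse")
})

test_that("edge synapses renormalize the kernel over existing neighbors", {
  fx <- make_fixture("dendrite6")
  net <- fx$network
  res <- potentiate(net, 1, 0.6) # pos 0: neighbors only at +1,+2,+3
  expect_equal(res$event$from_neighbors, 0.6) # still fully neighbor-funded
  e <- exp(-(1:3))
  expect_equal(res$network$rec$weight[2:4], 1 - 0.6 * e / sum(e))
  expect_equal(res$network$rec$weight[5:7], rep(1, 3)) # beyond max distance
})

test_that("depression relocates weight into the pool", {
  fx <- make_fixture("dendrite6")
  net <- fx$network
  net$rec$weight[2] <- 0.5
  res <- depress(net, 2, 0.2)
  expect_equal(res$network$rec$weight[2], 0.3)
  expect_equal(res$network$pools[8], 0.2)

  net$rec$weight[2] <- 0.1
  res2 <- depress(net, 2, 0.2)
  expect_equal(res2$network$rec$weight[2], 0)
  expect_equal(res2$network$pools[8], 0.1)
  expect_equal(res2$event$granted, 0.1)

  net$rec$weight[2] <- 0
  res3 <- depress(net, 2, 0.2)
  expect_equal(res3$network$rec$weight, net$rec$weight)
  expect_equal(res3$network$pools, net$pools)
})

test_that("pool decay follows its exponential within Euler error", {
  p <- decay_pools(2, dt = 0.1, tau_pool = 10, n_steps = 1e5) # 10 s
  expect_equal(p, 2 * exp(-1), tolerance = 1e-4)
  expect_equal(decay_pools(0, 0.1, 10, 1000), 0)
  expect_lt(decay_pools(5, 0.1, 10, 1e7), 1e-40) # -> 0 as t -> Inf
})

test_that("nearest-spike pairing on the pair fixture matches pair enumeration", {
  params <- stdp_params()
  fx <- make_fixture("pair")
  net <- fx$network
  st <- plasticity_state(net)

  # scripted: pre arrival at 10 ms, post spike at 30 ms -> tau = +20 ms
  res <- on_pre_arrival(net, st, 1, fx$pre_arrivals$time_ms[1])
  expect_null(res$event) # nothing to pair with yet
  expect_equal(res$state$last_pre[1], 10)

  res2 <- on_post_spike(res$network, res$state, 2, fx$post_spikes$time_ms[1])
  expect_equal(nrow(res2$events), 1)
  expect_equal(res2$events$requested, exp(-1))
  expect_equal(res2$events$tau, 20)
  expect_equal(res2$network$rec$weight[1], exp(-1)) # pool-funded (pool = 2)

  # a second arrival after the post spike pairs acausally: tau = 30 - 35 = -5
  res3 <- on_pre_arrival(res2$network, res2$state, 1, 35)
  expect_equal(res3$event$tau, -5)
  expect_equal(res3$event$requested,
               0.18 * exp(-5 / 20) * exp(-1))

  # two arrivals after one post spike both pair with that same post spike
  res4 <- on_pre_arrival(res3$network, res3$state, 1, 45)
  expect_equal(res4$event$tau, 30 - 45)
  w45 <- res3$network$rec$weight[1]
  expect_equal(res4$event$requested, 0.18 * exp(-15 / 20) * w45)

  # explicit pair enumeration over the scripted sequence: each event pairs
  # with the most recent opposite spike, never an older one
  pres <- c(10, 35, 45); posts <- 30
  expected_pairs <- data.frame(
    t = c(30, 35, 45),
    tau = c(30 - 10, 30 - 35, 30 - 45))
  got <- rbind(
    data.frame(t = 30, tau = res2$events$tau),
    data.frame(t = 35, tau = res3$event$tau),
    data.frame(t = 45, tau = res4$event$tau))
  expect_equal(got, expected_pairs)
})

test_that("simultaneous-tau afferents are processed in dendritic order under scarcity", {
  fx <- make_fixture("dendrite6")
  net <- fx$network
  net$rec$weight[] <- 0
  net$pools[8] <- 0.5 # not enough for two full requests
  st <- plasticity_state(net)
  st$last_pre[c(2, 6)] <- 0 # two afferents, equal tau
  res <- on_post_spike(net, st, 8, 0)
  expect_equal(nrow(res$events), 2)
  expect_equal(res$events$synapse, c(2, 6)) # ascending dendritic position
  total_before <- 0.5
  expect_equal(sum(res$events$granted), total_before, tolerance = 1e-12)
  # first in dendritic order got the full request (1.0 > pool): pool-capped
  expect_equal(res$events$granted[1], 0.5)
  expect_equal(res$events$granted[2], 0)

  # no recorded arrivals -> no events
  res0 <- on_post_spike(net, plasticity_state(net), 8, 0)
  expect_equal(nrow(res0$events), 0)
})

test_that("random event sequences conserve neuron resources exactly", {
  fx <- make_fixture("dendrite6")
  net <- fx$network
  net$pools[8] <- 1.3
  set.seed(7)
  total <- sum(net$rec$weight) + net$pools[8]
  for (i in 1:300) {
    j <- sample(7, 1)
    amt <- runif(1, 0, 1.5)
    if (runif(1) < 0.5) {
      net <- potentiate(net, j, amt)$network
    } else {
      net <- depress(net, j, amt)$network
    }
    expect_true(all(net$rec$weight >= 0))
    expect_gte(net$pools[8], 0)
    expect_lt(abs(sum(net$rec$weight) + net$pools[8] - total), 1e-12)
  }
})
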