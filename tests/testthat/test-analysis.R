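test_that("firing rates are spike counts over the window", {
  r <- firing_rates(data.frame(time_ms = c(5, 20, 40, 60, 99), neuron = 1L),
                    window = 100, n_neurons = 2, t_max = 100)
  expect_equal(r[1, 1], 50) # 5 spikes in 100 ms
  expect_equal(r[2, 1], 0)

  empty <- firing_rates(data.frame(time_ms = numeric(), neuron = integer()),
                        window = 100, n_neurons = 3, t_max = 500)
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(3, 5))

  # regular 100 Hz train: every interior window reads 100 Hz
  train <- data.frame(time_ms = seq(0, 999.9, by = 10), neuron = 2L)
  r100 <- firing_rates(train, window = 100, n_neurons = 2, t_max = 1000)
  expect_true(all(r100[2, ] == 100))
  expect_true(all(r100[1, ] == 0))
})

test_that("potentiation efficacy is granted over requested in percent", {
  ev <- data.frame(direction = c("potentiation", "potentiation",
                                 "potentiation", "depression",
                                 "potentiation"),
                   requested = c(0.5, 0.5, 0.8, 0.3, 0),
                   granted = c(0.5, 0.25, 0, 0.3, 0))
  eff <- potentiation_efficacy(ev)
  expect_equal(eff, c(100, 50, 0)) # depression and requested-0 rows excluded
})

test_that("nonfilopodia spacing is the mean nearest-neighbor dendritic distance", {
  mknet <- function(pos, w, target = 1L) {
    params <- network_params(n_exc = 2, n_in = 1, p_rec = 1, p_in = 1)
    rec <- data.frame(source = 2L, target = target, pos = as.integer(pos),
                      delay_steps = 10L, weight = w)
    structure(list(rec = rec, input = data.frame(source = integer(),
                                                 target = integer(),
                                                 delay_steps = integer(),
                                                 weight = numeric()),
                   pools = c(0, 0), params = params),
              class = "stdp_network")
  }
  expect_equal(nonfilopodia_spacing(
    mknet(0:5, c(1, 0, 0, 1, 0, 0))), 3) # symmetric pair {0,3}
  expect_equal(nonfilopodia_spacing(mknet(0:5, rep(1, 6))), 1) # contiguous
  expect_equal(nonfilopodia_spacing(
    mknet(0:5, c(1, 1, 0, 0, 1, 0))), 5 / 3) # {0,1,4} -> 1,1,3
  expect_true(is.na(nonfilopodia_spacing(
    mknet(0:5, c(1, 0, 0, 0, 0, 0))))) # a single spine: undefined
  # silencing an interior spine weakly increases spacing
  dense <- nonfilopodia_spacing(mknet(0:5, rep(1, 6)))
  holey <- nonfilopodia_spacing(mknet(0:5, c(1, 1, 0, 1, 1, 1)))
  expect_gte(holey, dense)
  expect_gte(dense, 1)
})

test_that("graph metrics use delay-weighted closeness over reachable nodes", {
  fx <- make_fixture("chain3") # A -> B -> C, 2 ms delays
  gm <- graph_metrics(fx$network)
  expect_equal(gm$n_edges, 2)
  expect_equal(gm$mean_in_degree, 2 / 3)
  expect_equal(gm$mean_out_degree, gm$mean_in_degree)
  # out-closeness: A reaches B (2 ms) and C (4 ms) -> 2/6; B -> 1/2; C -> 0
  expect_equal(gm$mean_out_closeness, mean(c(2 / 6, 1 / 2, 0)))
  expect_equal(gm$mean_in_closeness, mean(c(0, 1 / 2, 2 / 6)))

  # empty graph: all zero
  empty <- fx$network
  empty$rec$weight[] <- 0
  gm0 <- graph_metrics(empty)
  expect_equal(gm0$mean_out_closeness, 0)
  expect_equal(gm0$mean_in_degree, 0)

  # increasing a used edge's delay can only decrease closeness
  slower <- fx$network
  slower$rec$delay_steps[1] <- 40L
  expect_lt(graph_metrics(slower)$mean_out_closeness, gm$mean_out_closeness)
})

test_that("closeness agrees with a brute-force shortest-path oracle", {
  set.seed(12)
  for (trial in 1:5) {
    n <- 6
    net <- build_network(network_params(n_exc = n, n_in = 1, p_rec = 0.5),
                         seed = trial)
    net$rec$weight <- runif(nrow(net$rec))
    net$rec$weight[runif(nrow(net$rec)) < 0.3] <- 0
    gm <- graph_metrics(net)
    e <- net$rec[net$rec$weight > 0, ]
    d <- floyd_distances(n, e$source, e$target, e$delay_steps * 0.1)
    diag(d) <- Inf
    cl_row <- function(dr) {
      reach <- is.finite(dr)
      if (!any(reach)) 0 else sum(reach) / sum(dr[reach])
    }
    expect_equal(gm$mean_out_closeness, mean(apply(d, 1, cl_row)))
    expect_equal(gm$mean_in_closeness, mean(apply(d, 2, cl_row)))
    expect_equal(gm$mean_in_degree, nrow(e) / n)
  }
})

test_that("memory_alive uses a half-open quiet window", {
  raster <- data.frame(time_ms = c(100, 400, 700), neuron = 1L)
  expect_true(memory_alive(raster, 1000, 500))   # spike at 700 in (500,1000]
  expect_false(memory_alive(raster, 1200, 500))  # last spike exactly at t - qw
  expect_true(memory_alive(raster, 1199.9, 500))
  expect_false(memory_alive(data.frame(time_ms = numeric(),
                                       neuron = integer()), 1000, 500))
})

test_that("survival curves normalize each trace to its own maximum", {
  fake <- structure(list(trace = data.frame(
    time_ms = c(0, 100, 200, 300),
    weight_sum_pct = c(50, 100, 75, 0),
    active_neurons_pct = c(100, 80, 40, 0))), class = "stdp_degeneration")
  sc <- survival_curves(fake)
  expect_equal(max(sc$weight_sum_pct), 100)
  expect_true(all(sc$weight_sum_pct >= 0 & sc$weight_sum_pct <= 100))
  expect_true(all(diff(sc$active_neurons_pct) <= 0)) # monotone decay here
})
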