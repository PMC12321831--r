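#' Deterministic test fixtures
#'
#' Tiny handcrafted networks with scripted spike sequences, used to exercise
#' single operations in isolation:
#' * `"pair"`: one presynaptic and one postsynaptic neuron joined by a single
#'   silent synapse, with a scripted presynaptic arrival 20 ms before a
#'   scripted postsynaptic spike — one potentiation pairing with requested
#'   change `exp(-1)`.
#' * `"dendrite6"`: seven afferent synapses of unit weight on one dendrite
#'   (positions 0..6); potentiating the center synapse draws from all six
#'   neighbors according to the exponential-distance shares.
#' * `"chain3"`: three neurons in a directed chain with 2 ms delays, for
#'   closeness checks against hand-computed shortest paths.
#'
#' @param name One of `"pair"`, `"dendrite6"`, `"chain3"`.
#' @return A list with elements `network` (an `stdp_network`),
#'   `pre_arrivals` (data.frame `synapse`, `time_ms`), and `post_spikes`
#'   (data.frame `neuron`, `time_ms`); the spike tables may be empty.
#' @examples
#' fx <- make_fixture("pair")
#' fx$network$rec
#' @export
make_fixture <- function(name = c("pair", "dendrite6", "chain3")) {
  name <- match.arg(name)
  params <- network_params(n_exc = 2, n_in = 1, p_rec = 1, p_in = 1)
  fx <- switch(
    name,
    pair = {
      rec <- data.frame(source = 1L, target = 2L, pos = 0L,
                        delay_steps = 10L, weight = 0)
      inp <- data.frame(source = 1L, target = 1L, delay_steps = 10L,
                        weight = 0.8)
      net <- structure(list(rec = rec, input = inp, pools = c(0, 2),
                            params = params),
                       class = "stdp_network")
      list(network = net,
           pre_arrivals = data.frame(synapse = 1L, time_ms = 10),
           post_spikes = data.frame(neuron = 2L, time_ms = 30))
    },
    dendrite6 = {
      params <- network_params(n_exc = 8, n_in = 1, p_rec = 1, p_in = 1)
      rec <- data.frame(source = 1:7, target = 8L, pos = 0:6,
                        delay_steps = 10L, weight = 1)
      inp <- data.frame(source = 1L, target = 8L, delay_steps = 10L,
                        weight = 0.5)
      net <- structure(list(rec = rec, input = inp, pools = rep(0, 8),
                            params = params),
                       class = "stdp_network")
      list(network = net,
           pre_arrivals = data.frame(synapse = 4L, time_ms = 10),
           post_spikes = data.frame(neuron = 8L, time_ms = 10))
    },
    chain3 = {
      params <- network_params(n_exc = 3, n_in = 1, p_rec = 1, p_in = 1)
      rec <- data.frame(source = c(1L, 2L), target = c(2L, 3L),
                        pos = c(0L, 0L), delay_steps = c(20L, 20L),
                        weight = 1)
      inp <- data.frame(source = 1L, target = 1L, delay_steps = 10L,
                        weight = 0.5)
      net <- structure(list(rec = rec, input = inp, pools = rep(1, 3),
                            params = params),
                       class = "stdp_network")
      list(network = net,
           pre_arrivals = data.frame(synapse = integer(), time_ms = numeric()),
           post_spikes = data.frame(neuron = integer(), time_ms = numeric()))
    })
  fx
}
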