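#' STDP window
#'
#' The requested weight change for a pre/post spike pair with timing
#' difference `tau = post - pre` (ms). Causal pairs (`tau >= 0`) request a
#' potentiation of `exp(-tau/tau_stdp)`; acausal pairs request a depression of
#' `depression_multiple * exp(tau/tau_stdp) * w` — depression is weight
#' dependent, so silent synapses (w = 0) are never depressed. The returned
#' value is the magnitude of the requested change; whether it is granted in
#' full depends on available resources (see [potentiate()]).
#'
#' @param tau Spike-timing difference(s) in ms, `post - pre`.
#' @param w Current synaptic weight(s), `>= 0`.
#' @param params A [stdp_params()] object.
#' @return Non-negative requested change magnitude(s), vectorized over `tau`/`w`.
#' @examples
#' stdp_window(0, 1)            # 1
#' stdp_window(20, 1)           # exp(-1)
#' stdp_window(-20, 1)          # 0.18 * exp(-1)
#' @export
stdp_window <- function(tau, w, params = stdp_params()) {
  stopifnot(all(is.finite(tau)), all(w >= 0))
  ifelse(tau >= 0,
         exp(-tau / params$tau_stdp),
         params$depression_multiple * exp(tau / params$tau_stdp) * w)
}

#' Heterosynaptic neighbor share
#'
#' Fraction of a requested potentiation drawn from the dendritic neighbor at
#' position offset `+-k` when the full neighborhood (both sides, up to
#' `max_distance`) exists. Shares fall exponentially with distance and are
#' normalized so that all `2 * max_distance` neighbor shares sum to exactly 1,
#' making fully neighbor-funded potentiation resource conserving. Offsets
#' beyond `max_distance` have share 0. When some neighbor positions are
#' missing (dendrite ends, deleted synapses) the engine renormalizes over the
#' neighbors that exist.
#'
#' @param k Absolute position offset(s) (1, 2, ...).
#' @param max_distance Neighborhood radius in synapse positions (default 3).
#' @return Share(s) in `[0, 1]`.
#' @examples
#' neighbor_share(1)                      # ~0.33265
#' sum(2 * neighbor_share(1:3))           # 1
#' neighbor_share(4)                      # 0
#' @export
neighbor_share <- function(k, max_distance = 3L) {
  stopifnot(all(k >= 1))
  norm <- 2 * sum(exp(-seq_len(max_distance)))
  ifelse(k <= max_distance, exp(-k) / norm, 0)
}

# shares renormalized over an existing set of neighbor distances,
# in the caller's order; returns numeric(0) for no neighbors
neighbor_shares_existing <- function(dists) {
  if (length(dists) == 0) return(numeric(0))
  e <- exp(-dists)
  e / sum(e)
}

#' Resource-dependent potentiation
#'
#' Grants a requested potentiation to recurrent synapse `j` using only locally
#' available resources on the target neuron. Resources are drawn
#' neighbors-first: every existing synapse within `max_neighbor_distance`
#' dendritic positions of `j` is depressed by its exponential-distance share
#' of the request, capped at its current weight (heterosynaptic depression).
#' Any shortfall is drawn from the neuron's resource pool, capped at the pool
#' level. The granted amount — what was actually collected — is added to
#' `w_j`, so the neuron's total resources (sum of afferent weights + pool) are
#' unchanged: if pool and neighbors are depleted, potentiation is not
#' possible.
#'
#' @param net An `stdp_network`.
#' @param j Synapse id (row of `net$rec`).
#' @param requested Requested weight increase (>= 0), typically from
#'   [stdp_window()].
#' @param params A [stdp_params()] object.
#' @param time Event time in ms (metadata only).
#' @param tau Pairing timing difference in ms (metadata only).
#' @return A list with elements `network` (updated) and `event`, a one-row
#'   data.frame `(time, synapse, tau, direction, requested, granted,
#'   from_neighbors, from_pool)`.
#' @export
potentiate <- function(net, j, requested, params = stdp_params(),
                       time = NA_real_, tau = NA_real_) {
  stopifnot(inherits(net, "stdp_network"), requested >= 0)
  if (length(j) != 1 || is.na(j) || j < 1 || j > nrow(net$rec)) {
    stop("unknown synapse id: ", j)
  }
  tgt <- net$rec$target[j]
  pos_j <- net$rec$pos[j]
  nb <- which(net$rec$target == tgt &
                abs(net$rec$pos - pos_j) <= params$max_neighbor_distance &
                seq_len(nrow(net$rec)) != j)
  nb <- nb[order(net$rec$pos[nb])]
  shares <- neighbor_shares_existing(abs(net$rec$pos[nb] - pos_j))

  from_neighbors <- 0
  for (i in seq_along(nb)) {
    take <- min(net$rec$weight[nb[i]], requested * shares[i])
    net$rec$weight[nb[i]] <- net$rec$weight[nb[i]] - take
    from_neighbors <- from_neighbors + take
  }
  shortfall <- requested - from_neighbors
  from_pool <- min(net$pools[tgt], shortfall)
  net$pools[tgt] <- net$pools[tgt] - from_pool
  granted <- from_neighbors + from_pool
  net$rec$weight[j] <- net$rec$weight[j] + granted

  event <- data.frame(time = time, synapse = j, tau = tau,
                      direction = "potentiation", requested = requested,
                      granted = granted, from_neighbors = from_neighbors,
                      from_pool = from_pool)
  list(network = net, event = event)
}

#' Depression with resource relocation
#'
#' Depresses recurrent synapse `j` by the requested amount, capped at its
#' current weight, and relocates the removed resources into the target
#' neuron's pool for reuse — depression never destroys resources.
#'
#' @inheritParams potentiate
#' @param requested Requested weight decrease (>= 0).
#' @return As [potentiate()]: list of `network` and `event` (with
#'   `from_pool` recording the amount moved into the pool, negative sign
#'   convention not used: the event's `granted` is the amount removed).
#' @export
depress <- function(net, j, requested, params = stdp_params(),
                    time = NA_real_, tau = NA_real_) {
  stopifnot(inherits(net, "stdp_network"), requested >= 0)
  if (length(j) != 1 || is.na(j) || j < 1 || j > nrow(net$rec)) {
    stop("unknown synapse id: ", j)
  }
  tgt <- net$rec$target[j]
  moved <- min(requested, net$rec$weight[j])
  net$rec$weight[j] <- net$rec$weight[j] - moved
  net$pools[tgt] <- net$pools[tgt] + moved
  event <- data.frame(time = time, synapse = j, tau = tau,
                      direction = "depression", requested = requested,
                      granted = moved, from_neighbors = 0, from_pool = moved)
  list(network = net, event = event)
}

#' Exponential decay of resource pools
#'
#' Forward-Euler decay of the per-neuron pools, `tau_pool dp/dt = -p`:
#' resources in the pool degrade like recycled receptors/proteins if unused.
#'
#' @param pools Numeric vector of pool values (>= 0).
#' @param dt Step in ms.
#' @param tau_pool Pool time constant in seconds (default 10).
#' @param n_steps Number of Euler steps to apply (default 1).
#' @return Decayed pools.
#' @examples
#' decay_pools(2, dt = 0.1, n_steps = 1e5)   # ~ 2 * exp(-1) after 10 s
#' @export
decay_pools <- function(pools, dt, tau_pool = 10, n_steps = 1L) {
  stopifnot(all(pools >= 0), dt > 0, tau_pool > 0,
            dt < tau_pool * 1000)
  pools * (1 - dt / (tau_pool * 1000))^n_steps
}

#' Pairing state for event-level plasticity
#'
#' Tracks, per neuron, the time of the most recent postsynaptic spike and,
#' per recurrent synapse, the time of the most recent presynaptic arrival —
#' the bookkeeping needed for nearest-spike STDP pairing.
#'
#' @param net An `stdp_network`.
#' @return A list with `last_post` (length `n_exc`, `-Inf` = never) and
#'   `last_pre` (one per recurrent synapse, `-Inf` = never).
#' @export
plasticity_state <- function(net) {
  list(last_post = rep(-Inf, net$params$n_exc),
       last_pre = rep(-Inf, nrow(net$rec)))
}

#' Handle a presynaptic arrival at a synapse
#'
#' Under nearest-spike pairing, a presynaptic spike arriving at synapse `j` at
#' time `t` pairs with the target neuron's most recent postsynaptic spike (if
#' any), giving `tau = t_post - t < 0` and a weight-dependent depression via
#' [stdp_window()] and [depress()]. The arrival time is then recorded as the
#' synapse's most recent presynaptic arrival. Timing is measured at arrival
#' (after the axonal delay), not at emission: plasticity is local to the
#' synapse. Exact coincidences (`tau = 0`) are routed to potentiation, not
#' depression.
#'
#' @param net An `stdp_network`.
#' @param state A [plasticity_state()].
#' @param j Synapse id.
#' @param t Arrival time, ms.
#' @param params A [stdp_params()] object.
#' @return List of `network`, `state`, and `event` (`NULL` if the neuron has
#'   never fired).
#' @export
on_pre_arrival <- function(net, state, j, t, params = stdp_params()) {
  tgt <- net$rec$target[j]
  event <- NULL
  t_post <- state$last_post[tgt]
  if (is.finite(t_post) && t_post - t < 0) {
    tau <- t_post - t
    res <- depress(net, j, stdp_window(tau, net$rec$weight[j], params),
                   params, time = t, tau = tau)
    net <- res$network
    event <- res$event
  }
  state$last_pre[j] <- t
  list(network = net, state = state, event = event)
}

#' Handle a postsynaptic spike
#'
#' When neuron `n` fires at time `t`, every afferent recurrent synapse that
#' has ever received a presynaptic arrival pairs with its most recent arrival
#' (`tau = t - t_pre >= 0`) and requests a potentiation of
#' `exp(-tau/tau_stdp)`, granted resource-dependently by [potentiate()].
#' Synapses are processed in ascending dendritic-position order; when
#' resources are scarce the order matters and is therefore fixed. The spike
#' time is then recorded as the neuron's most recent postsynaptic spike.
#'
#' @param net An `stdp_network`.
#' @param state A [plasticity_state()].
#' @param n Neuron index.
#' @param t Spike time, ms.
#' @param params A [stdp_params()] object.
#' @return List of `network`, `state`, and `events` (a data.frame, possibly
#'   empty).
#' @export
on_post_spike <- function(net, state, n, t, params = stdp_params()) {
  aff <- which(net$rec$target == n & is.finite(state$last_pre))
  aff <- aff[order(net$rec$pos[aff])]
  events <- list()
  for (j in aff) {
    tau <- t - state$last_pre[j]
    res <- potentiate(net, j, stdp_window(tau, net$rec$weight[j], params),
                      params, time = t, tau = tau)
    net <- res$network
    events[[length(events) + 1L]] <- res$event
  }
  state$last_post[n] <- t
  list(network = net, state = state,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(time = numeric(), synapse = integer(), tau = numeric(),
                    direction = character(), requested = numeric(),
                    granted = numeric(), from_neighbors = numeric(),
                    from_pool = numeric()))
}
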