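# Brute-force reference simulator: explicit per-synapse state and per-event
# resource bookkeeping, all in plain R. Used as the independent oracle for
# the optimized engine. Every plasticity event is checked for exact local
# resource conservation as it happens.
#
# Phase order per step t (time t_ms = t*dt), matching the documented engine
# semantics:
#   A deliver arrivals (impulse, acausal pairing -> depression, record t_pre)
#   B enqueue this step's input spikes
#   C Euler update v, r, s, s' (v clamped while absolutely refractory)
#   D threshold: reset, causal pairing -> potentiation (ascending dendritic
#     position), enqueue efferents
#   E pool decay

oracle_simulate <- function(net, n_steps, input_spikes,
                            neuron = neuron_params(), stdp = stdp_params(),
                            v0 = NULL, record_traces = FALSE,
                            conservation_tol = 1e-12) {
  dt <- net$params$dt
  rec <- net$rec
  inp <- net$input
  n <- net$params$n_exc
  ns <- nrow(rec)
  ni <- nrow(inp)
  w <- rec$weight
  pool <- net$pools
  gain <- neuron$syn_gain
  tau_p_ms <- stdp$tau_pool * 1000
  n_abs <- round(neuron$t_abs / dt)

  v <- if (is.null(v0)) rep(0, n) else v0
  r <- rep(1, n)
  refrac <- rep(0L, n)
  sp_r <- ss_r <- rep(0, ns)
  sp_i <- ss_i <- rep(0, ni)
  last_post <- rep(-Inf, n)
  last_pre <- rep(-Inf, ns)

  max_delay <- max(c(rec$delay_steps, inp$delay_steps, 1))
  queue <- vector("list", n_steps + max_delay + 1)
  spikes_t <- numeric()
  spikes_n <- integer()
  events <- list()
  if (record_traces) {
    v_tr <- matrix(NA_real_, n_steps, n)
    r_tr <- matrix(NA_real_, n_steps, n)
    s_tr <- matrix(NA_real_, n_steps, n)
  }

  neuron_resources <- function(nn) sum(w[rec$target == nn]) + pool[nn]

  depress_at <- function(j, t_ms, tau) {
    before <- neuron_resources(rec$target[j])
    req <- stdp$depression_multiple * exp(tau / stdp$tau_stdp) * w[j]
    moved <- min(req, w[j])
    w[j] <<- w[j] - moved
    pool[rec$target[j]] <<- pool[rec$target[j]] + moved
    stopifnot(abs(neuron_resources(rec$target[j]) - before) <= conservation_tol)
    events[[length(events) + 1L]] <<- data.frame(
      time_ms = t_ms, synapse = j, tau = tau, direction = "depression",
      requested = req, granted = moved, from_neighbors = 0, from_pool = moved)
  }

  potentiate_at <- function(j, t_ms, tau) {
    tgt <- rec$target[j]
    before <- neuron_resources(tgt)
    req <- exp(-tau / stdp$tau_stdp)
    nb <- which(rec$target == tgt &
                  abs(rec$pos - rec$pos[j]) <= stdp$max_neighbor_distance)
    nb <- setdiff(nb, j)
    nb <- nb[order(rec$pos[nb])]
    from_nb <- 0
    if (length(nb)) {
      e <- exp(-abs(rec$pos[nb] - rec$pos[j]))
      shares <- e / sum(e)
      for (i in seq_along(nb)) {
        take <- min(w[nb[i]], req * shares[i])
        w[nb[i]] <<- w[nb[i]] - take
        from_nb <- from_nb + take
      }
    }
    from_pool <- min(pool[tgt], req - from_nb)
    pool[tgt] <<- pool[tgt] - from_pool
    granted <- from_nb + from_pool
    w[j] <<- w[j] + granted
    stopifnot(abs(neuron_resources(tgt) - before) <= conservation_tol,
              granted <= req * (1 + 1e-12), all(w >= 0), pool[tgt] >= 0)
    events[[length(events) + 1L]] <<- data.frame(
      time_ms = t_ms, synapse = j, tau = tau, direction = "potentiation",
      requested = req, granted = granted, from_neighbors = from_nb,
      from_pool = from_pool)
  }

  for (t in seq_len(n_steps) - 1L) {
    t_ms <- t * dt
    # A: deliveries (ids > ns encode input synapses)
    for (id in queue[[t + 1L]]) {
      if (id > ns) {
        jj <- id - ns
        sp_i[jj] <- sp_i[jj] + gain * inp$weight[jj]
      } else {
        sp_r[id] <- sp_r[id] + gain * w[id]
        tp <- last_post[rec$target[id]]
        if (is.finite(tp) && tp - t_ms < 0) depress_at(id, t_ms, tp - t_ms)
        last_pre[id] <- t_ms
      }
    }
    queue[t + 1L] <- list(NULL)
    # B: input spikes emitted this step
    if (t + 1L <= nrow(input_spikes)) {
      for (k in which(input_spikes[t + 1L, ])) {
        for (jj in which(inp$source == k)) {
          at <- t + inp$delay_steps[jj] + 1L
          queue[[at]] <- c(queue[[at]], ns + jj)
        }
      }
    }
    # C: Euler updates
    s_sum <- rep(0, n)
    for (jj in seq_len(ni)) {
      s_sum[inp$target[jj]] <- s_sum[inp$target[jj]] + ss_i[jj]
    }
    for (j in seq_len(ns)) {
      s_sum[rec$target[j]] <- s_sum[rec$target[j]] + ss_r[j]
    }
    for (nn in seq_len(n)) {
      if (refrac[nn] > 0) {
        refrac[nn] <- refrac[nn] - 1L
        v[nn] <- 0
      } else {
        v[nn] <- v[nn] + dt / neuron$tau_v * (-v[nn] + r[nn] * s_sum[nn])
      }
      r[nn] <- r[nn] + dt / neuron$tau_r * (1 - r[nn])
    }
    ss_i <- ss_i + dt / neuron$tau_sf * (-ss_i + sp_i)
    sp_i <- sp_i * (1 - dt / neuron$tau_sr)
    ss_r <- ss_r + dt / neuron$tau_sf * (-ss_r + sp_r)
    sp_r <- sp_r * (1 - dt / neuron$tau_sr)
    # D: threshold
    for (nn in seq_len(n)) {
      if (refrac[nn] == 0L && v[nn] >= neuron$theta) {
        spikes_t <- c(spikes_t, t_ms)
        spikes_n <- c(spikes_n, nn)
        v[nn] <- 0
        refrac[nn] <- n_abs
        r[nn] <- neuron$r_reset
        aff <- which(rec$target == nn & is.finite(last_pre))
        aff <- aff[order(rec$pos[aff])]
        for (j in aff) potentiate_at(j, t_ms, t_ms - last_pre[j])
        last_post[nn] <- t_ms
        for (j in which(rec$source == nn)) {
          at <- t + rec$delay_steps[j] + 1L
          queue[[at]] <- c(queue[[at]], j)
        }
      }
    }
    # E: pool decay
    d <- pool * (dt / tau_p_ms)
    pool <- pool - d
    if (record_traces) {
      v_tr[t + 1L, ] <- v
      r_tr[t + 1L, ] <- r
      s_tr[t + 1L, ] <- s_sum
    }
  }

  out <- list(weights = w, pools = pool,
              raster = data.frame(time_ms = spikes_t, neuron = spikes_n),
              v = v, r = r,
              events = if (length(events)) do.call(rbind, events) else NULL)
  if (record_traces) {
    out$v_trace <- v_tr
    out$r_trace <- r_tr
    out$s_trace <- s_tr
  }
  out
}

# hand-built 3-neuron, 5-synapse network driven by two scripted input trains;
# synapse table sorted by (target, pos) as the engine requires
make_tiny_net <- function() {
  params <- network_params(n_exc = 3, n_in = 2, p_rec = 1, p_in = 1)
  rec <- data.frame(
    source = c(2L, 3L, 1L, 3L, 1L),
    target = c(1L, 1L, 2L, 2L, 3L),
    pos = c(0L, 1L, 0L, 1L, 0L),
    delay_steps = c(12L, 25L, 10L, 17L, 30L),
    weight = c(0.8, 0.5, 0.6, 0.9, 0.7))
  inp <- data.frame(source = c(1L, 1L, 2L),
                    target = c(1L, 2L, 3L),
                    delay_steps = c(10L, 15L, 12L),
                    weight = c(2.5, 2.0, 2.8))
  structure(list(rec = rec, input = inp, pools = c(1.5, 0.3, 2.0),
                 params = params),
            class = "stdp_network")
}

# scripted spike-step matrix for the tiny net's two trains
tiny_input_steps <- function(n_steps) {
  m <- matrix(FALSE, n_steps, 2)
  m[seq(1, n_steps, by = 80), 1] <- TRUE
  m[seq(6, n_steps, by = 57), 2] <- TRUE
  m
}

# steps -> per-train spike-time list (ms) for simulate_network(scripted_input=)
steps_to_times <- function(spike_mat, dt) {
  lapply(seq_len(ncol(spike_mat)), function(k) (which(spike_mat[, k]) - 1) * dt)
}

# Floyd-Warshall all-pairs shortest paths, for closeness cross-checks
floyd_distances <- function(n, edges_from, edges_to, edges_len) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_along(edges_from)) {
    d[edges_from[i], edges_to[i]] <- min(d[edges_from[i], edges_to[i]],
                                         edges_len[i])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}
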