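#' Network construction parameters
#'
#' Parameters of the random recurrent network: an excitatory pool of
#' `n_exc` neurons recurrently connected with probability `p_rec`, driven by
#' `n_in` independent Poisson spike trains each contacting a neuron with
#' probability `p_in`. All connections carry an axonal delay drawn uniformly
#' from `[delay_min, delay_max]` ms and rounded to the integration grid.
#'
#' @param n_exc Number of excitatory neurons (default 200).
#' @param n_in Number of input spike trains (default 50).
#' @param p_rec Recurrent connection probability per ordered neuron pair,
#'   in (0, 1] (default 0.25). Self-connections are never made.
#' @param p_in Input connection probability per (train, neuron) pair (default 0.10).
#' @param delay_min,delay_max Axonal delay bounds in ms (defaults 1 and 5).
#' @param pool_scale Scale of the log-normal per-neuron resource pool
#'   initialization `p = pool_scale * exp(xi)`, `xi ~ N(0,1)` (default 2).
#' @param dt Integration time step in ms (default 0.1).
#' @param dendrite_order How synapses are laid out along each target neuron's
#'   dendrite: `"source"` assigns dendritic positions in ascending presynaptic
#'   source order; `"random"` uses a seeded random permutation.
#' @return An object of class `network_params` (a validated list).
#' @examples
#' p <- network_params(n_exc = 10, n_in = 5)
#' p$p_rec
#' @export
network_params <- function(n_exc = 200L, n_in = 50L, p_rec = 0.25, p_in = 0.10,
                           delay_min = 1, delay_max = 5, pool_scale = 2,
                           dt = 0.1, dendrite_order = c("source", "random")) {
  dendrite_order <- match.arg(dendrite_order)
  n_exc <- as.integer(n_exc)
  n_in <- as.integer(n_in)
  stopifnot(
    "n_exc must be a positive count" = length(n_exc) == 1 && !is.na(n_exc) && n_exc >= 1,
    "n_in must be a positive count" = length(n_in) == 1 && !is.na(n_in) && n_in >= 1,
    "dt must be positive" = is.numeric(dt) && length(dt) == 1 && dt > 0,
    "pool_scale must be positive" = is.numeric(pool_scale) && pool_scale > 0,
    "delay bounds must satisfy dt <= delay_min <= delay_max" =
      delay_min >= dt && delay_max >= delay_min
  )
  if (!is.numeric(p_rec) || p_rec <= 0 || p_rec > 1) {
    stop("p_rec must lie in (0, 1], got ", p_rec)
  }
  if (!is.numeric(p_in) || p_in <= 0 || p_in > 1) {
    stop("p_in must lie in (0, 1], got ", p_in)
  }
  structure(
    list(n_exc = n_exc, n_in = n_in, p_rec = p_rec, p_in = p_in,
         delay_min = delay_min, delay_max = delay_max,
         pool_scale = pool_scale, dt = dt, dendrite_order = dendrite_order),
    class = "network_params"
  )
}

#' Neuron and synaptic-current parameters
#'
#' Constants of the refractory leaky integrate-and-fire neuron and the
#' double-exponential synaptic current. The membrane potential `v` relaxes with
#' time constant `tau_v` toward the refractoriness-gated synaptic drive and is
#' reset to 0 on crossing the threshold `theta`; an absolute refractory period
#' `t_abs` is followed by relative refractoriness recovering with `tau_r`.
#' Each presynaptic arrival feeds a current pair `s' -> s` with rise constant
#' `tau_sr` and fall constant `tau_sf`.
#'
#' `syn_gain` sets the amplitude convention of the unitary postsynaptic
#' current: an arrival increments `s'` by `syn_gain * w`. The default
#' normalizes the peak of the double-exponential so that a single spike through
#' a weight-`w` synapse produces `max_t s = w` (see [psc_peak_gain()]).
#'
#' @param tau_v Membrane time constant, ms (default 25).
#' @param tau_r Relative-refractoriness recovery time constant, ms (default 5).
#' @param tau_sr Synaptic current rise time constant, ms (default 2.6).
#' @param tau_sf Synaptic current fall time constant, ms (default 31.3).
#' @param theta Firing threshold in membrane units (default 1).
#' @param t_abs Absolute refractory period, ms (default 3).
#' @param syn_gain Increment applied to `s'` per unit weight on a presynaptic
#'   arrival. Default: peak normalization `psc_peak_gain(tau_sr, tau_sf)`.
#' @param r_reset Value the refractory gain `r` takes at a spike (default 0).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_v = 25, tau_r = 5, tau_sr = 2.6, tau_sf = 31.3,
                          theta = 1, t_abs = 3,
                          syn_gain = psc_peak_gain(tau_sr, tau_sf),
                          r_reset = 0) {
  stopifnot(
    tau_v > 0, tau_r > 0, tau_sr > 0, tau_sf > tau_sr,
    theta > 0, t_abs >= 0, syn_gain > 0, r_reset >= 0, r_reset <= 1
  )
  structure(
    list(tau_v = tau_v, tau_r = tau_r, tau_sr = tau_sr, tau_sf = tau_sf,
         theta = theta, t_abs = t_abs, syn_gain = syn_gain, r_reset = r_reset),
    class = "neuron_params"
  )
}

#' Plasticity parameters
#'
#' Parameters of the resource-dependent STDP rule: the STDP window time
#' constant, the depression multiple balancing potentiation against the extra
#' depression contributed heterosynaptically, the dendritic neighborhood radius
#' over which potentiation draws resources from neighboring spines, and the
#' resource-pool decay time constant.
#'
#' @param tau_stdp STDP window time constant, ms (default 20).
#' @param depression_multiple Dimensionless multiple scaling the depression
#'   branch of the window (default 0.18).
#' @param max_neighbor_distance Maximum dendritic distance, in synapse
#'   positions, from which a potentiating synapse draws resources (default 3).
#' @param tau_pool Resource pool decay time constant, in seconds (default 10).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(tau_stdp = 20, depression_multiple = 0.18,
                        max_neighbor_distance = 3L, tau_pool = 10) {
  max_neighbor_distance <- as.integer(max_neighbor_distance)
  stopifnot(
    tau_stdp > 0, depression_multiple > 0,
    max_neighbor_distance >= 1, tau_pool > 0
  )
  structure(
    list(tau_stdp = tau_stdp, depression_multiple = depression_multiple,
         max_neighbor_distance = max_neighbor_distance, tau_pool = tau_pool),
    class = "stdp_params"
  )
}

#' Stimulation and degeneration protocol configuration
#'
#' Defines the experimental timeline. Learning: independent Poisson input at
#' `input_rate` Hz for the first `input_duration` seconds, then free running
#' until `total_duration`. Degeneration: from `degeneration_start` seconds,
#' surviving recurrent synapses are deleted one at a time at a constant
#' interval; with `replenish_on_delete = TRUE` a deleted synapse's resources
#' are returned to its target neuron's pool, otherwise they are discarded.
#'
#' @param input_rate Poisson input rate in Hz (default 50).
#' @param input_duration Stimulation duration in seconds (default 20).
#' @param total_duration Total simulated duration in seconds. Default 40 for
#'   the learning protocol; the degeneration protocol uses 140 unless given,
#'   so that the default deletion interval spaces all deletions over 100 s.
#' @param degeneration_start Start of progressive deletion, seconds (default 40).
#' @param deletion_interval Time between single-synapse deletions, ms. Default
#'   `NULL` derives `(total_duration - degeneration_start)/n_synapses`.
#' @param replenish_on_delete Should a deleted synapse's weight be returned to
#'   the target neuron's resource pool? (default `TRUE`)
#' @param snapshot_interval Interval between scalar trace snapshots, ms
#'   (default 100).
#' @param checkpoint_interval Interval between full weight/pool checkpoints,
#'   seconds (default 2).
#' @param quiet_window Window with no spike anywhere in the pool after which
#'   network activity is declared to have ceased, ms (default 500).
#' @param rng_seed Optional integer master seed stored with the config.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(input_rate = 50, input_duration = 20,
                            total_duration = 40, degeneration_start = 40,
                            deletion_interval = NULL,
                            replenish_on_delete = TRUE,
                            snapshot_interval = 100,
                            checkpoint_interval = 2,
                            quiet_window = 500,
                            rng_seed = NULL) {
  stopifnot(
    input_rate >= 0, input_duration >= 0,
    total_duration > 0,
    "degeneration_start must be >= input_duration" =
      degeneration_start >= input_duration,
    snapshot_interval > 0, checkpoint_interval > 0, quiet_window > 0
  )
  if (!is.null(deletion_interval) && deletion_interval <= 0) {
    stop("deletion_interval must be positive")
  }
  structure(
    list(input_rate = input_rate, input_duration = input_duration,
         total_duration = total_duration,
         degeneration_start = degeneration_start,
         deletion_interval = deletion_interval,
         replenish_on_delete = isTRUE(replenish_on_delete),
         snapshot_interval = snapshot_interval,
         checkpoint_interval = checkpoint_interval,
         quiet_window = quiet_window,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "protocol_config"
  )
}

#' Full run configuration
#'
#' Bundles network, neuron, plasticity and protocol parameters with a master
#' seed. The master seed deterministically spawns independent sub-seeds for
#' topology, pool initialization, input spikes and the deletion order, so one
#' source of randomness can be varied at a time.
#'
#' @param network A [network_params()] object.
#' @param neuron A [neuron_params()] object.
#' @param stdp A [stdp_params()] object.
#' @param protocol A [protocol_config()] object.
#' @param seed Integer master seed (default 1).
#' @return An object of class `run_config`.
#' @export
run_config <- function(network = network_params(), neuron = neuron_params(),
                       stdp = stdp_params(), protocol = protocol_config(),
                       seed = 1L) {
  stopifnot(
    inherits(network, "network_params"), inherits(neuron, "neuron_params"),
    inherits(stdp, "stdp_params"), inherits(protocol, "protocol_config")
  )
  structure(
    list(network = network, neuron = neuron, stdp = stdp, protocol = protocol,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Derive independent sub-seeds from a master seed
#'
#' @param seed Integer master seed.
#' @return Named integer vector with elements `topology`, `pools`, `input`,
#'   `deletion`, each below 2^31.
#' @export
derive_seeds <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("topology", "pools", "input", "deletion")
  s
}

#' @export
print.run_config <- function(x, ...) {
  cat("restdp run configuration\n")
  cat(sprintf("  network : %d neurons, %d input trains (p_rec=%.2f, p_in=%.2f)\n",
              x$network$n_exc, x$network$n_in, x$network$p_rec, x$network$p_in))
  cat(sprintf("  protocol: %g Hz input for %g s, total %g s\n",
              x$protocol$input_rate, x$protocol$input_duration,
              x$protocol$total_duration))
  cat(sprintf("  seed    : %d\n", x$seed))
  invisible(x)
}
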