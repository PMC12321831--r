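#' Build the network prescribed by a run configuration
#'
#' Uses the master seed's `topology` sub-seed for connectivity, delays and
#' input weights, and the `pools` sub-seed for the resource pools, so the two
#' can be varied independently.
#'
#' @param config A [run_config()].
#' @return An `stdp_network`.
#' @export
build_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed)
  net <- build_network(config$network, seed = seeds[["topology"]])
  set.seed(seeds[["pools"]])
  net$pools <- init_resource_pools(config$network$n_exc,
                                   config$network$pool_scale)
  net
}

#' Learning protocol: stimulate, then free-run
#'
#' Runs the standard learning experiment: independent Poisson input at
#' `input_rate` Hz for the first `input_duration` seconds drives the network
#' while resource-dependent STDP shapes the recurrent weights; the network
#' then runs without input until `total_duration`. A memory has been learned
#' when a subset of neurons keeps firing after the input stops.
#'
#' @param config A [run_config()].
#' @return An `stdp_sim` (see [simulate_network()]) with the `run_config`
#'   attached as `$config` and a checkpoint recorded at the end of
#'   stimulation.
#' @export
run_learning <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  net <- build_from_config(config)
  seeds <- derive_seeds(config$seed)
  pr <- config$protocol
  sim <- simulate_network(
    net, duration = pr$total_duration, neuron = config$neuron,
    stdp = config$stdp, input_rate = pr$input_rate,
    input_duration = pr$input_duration,
    quiet_window = pr$quiet_window, stop_at_cessation = FALSE,
    snapshot_interval = pr$snapshot_interval,
    checkpoint_interval = pr$checkpoint_interval,
    checkpoint_times = pr$input_duration,
    seed = seeds[["input"]]
  )
  sim$config <- config
  sim
}

#' Degeneration protocol: learn, then progressively delete synapses
#'
#' Runs the learning protocol through `degeneration_start` seconds, then
#' deletes one uniformly-random surviving recurrent synapse every
#' `deletion_interval` ms. With `replenish_on_delete = TRUE` each deleted
#' synapse's resources return to its target neuron's pool, enabling
#' compensatory potentiation of surviving synapses; without replenishment the
#' resources are lost. The run ends when network activity ceases (no spike
#' anywhere for `quiet_window` ms) or when no synapses remain.
#'
#' If the configured `total_duration` does not extend past
#' `degeneration_start`, a deletion phase of 100 s is appended. The default
#' deletion interval spreads all deletions uniformly over the deletion phase.
#'
#' @param config A [run_config()].
#' @return An object of class `stdp_degeneration`: the underlying `stdp_sim`
#'   as `$sim`, plus
#'   * `deletions`: deletion timeline (time, synapse id),
#'   * `trace`: the scalar trace with `weight_sum_pct` and
#'     `active_neurons_pct` columns (each normalized to its own maximum),
#'   * `cessation_ms`: when all neurons stopped firing (`NA` if never),
#'   * `remaining_fraction`: fraction of original recurrent synapses
#'     surviving at the end of the run,
#'   * `time_to_weight_zero_ms`: duration from deletion onset to the end of
#'     the weight-sum decay (the trace reaching 0, or activity ceasing),
#'   * `mean_nonfil_weight`: trace of the mean nonfilopodia (w > 0) weight.
#' @export
run_degeneration <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  net <- build_from_config(config)
  seeds <- derive_seeds(config$seed)
  pr <- config$protocol
  n_syn <- nrow(net$rec)
  total <- pr$total_duration
  if (total <= pr$degeneration_start) total <- pr$degeneration_start + 100
  interval <- pr$deletion_interval
  if (is.null(interval)) {
    interval <- (total - pr$degeneration_start) * 1000 / n_syn
  }
  set.seed(seeds[["deletion"]])
  order <- sample.int(n_syn)

  sim <- simulate_network(
    net, duration = total, neuron = config$neuron, stdp = config$stdp,
    input_rate = pr$input_rate, input_duration = pr$input_duration,
    degeneration = list(start = pr$degeneration_start, interval = interval,
                        order = order,
                        replenish = pr$replenish_on_delete),
    quiet_window = pr$quiet_window, stop_at_cessation = TRUE,
    snapshot_interval = pr$snapshot_interval,
    checkpoint_interval = pr$checkpoint_interval,
    checkpoint_times = c(pr$input_duration, pr$degeneration_start),
    log_events = FALSE,
    seed = seeds[["input"]]
  )
  sim$config <- config

  trace <- sim$trace
  wmax <- max(trace$weight_sum)
  trace$weight_sum_pct <- if (wmax > 0) 100 * (trace$weight_sum / wmax) else 0
  act <- active_neuron_counts(sim$raster, trace$time_ms, pr$quiet_window)
  amax <- max(act)
  trace$active_neurons_pct <- if (amax > 0) 100 * (act / amax) else 0

  deg_start_ms <- pr$degeneration_start * 1000
  zero_idx <- which(trace$weight_sum == 0 & trace$time_ms > deg_start_ms)
  zero_ms <- if (length(zero_idx)) trace$time_ms[zero_idx[1]] else NA_real_
  decay_end_ms <- min(zero_ms, sim$cessation_ms, na.rm = TRUE)
  if (!is.finite(decay_end_ms)) decay_end_ms <- NA_real_

  structure(
    list(
      sim = sim,
      deletions = sim$deletions,
      trace = trace,
      cessation_ms = sim$cessation_ms,
      remaining_fraction = sum(sim$alive) / n_syn,
      time_to_weight_zero_ms = decay_end_ms - deg_start_ms,
      deletion_interval_ms = interval,
      replenish = pr$replenish_on_delete,
      config = config
    ),
    class = "stdp_degeneration"
  )
}

# number of distinct neurons with >= 1 spike in (t - window, t], per t
active_neuron_counts <- function(raster, times, window) {
  vapply(times, function(t) {
    sel <- raster$time_ms > t - window & raster$time_ms <= t
    length(unique(raster$neuron[sel]))
  }, numeric(1))
}

#' @export
print.stdp_degeneration <- function(x, ...) {
  cat(sprintf("stdp_degeneration (replenish %s): %.1f%% of synapses remained when activity ceased\n",
              if (x$replenish) "on" else "off", 100 * x$remaining_fraction))
  if (!is.na(x$cessation_ms)) {
    cat(sprintf("  activity ceased at %.1f s; weight-sum decay lasted %.1f s\n",
                x$cessation_ms / 1000, x$time_to_weight_zero_ms / 1000))
  }
  invisible(x)
}

#' Reconstruct the network at a recorded checkpoint
#'
#' @param sim An `stdp_sim`.
#' @param which Checkpoint index, or a time in seconds (matched to the nearest
#'   recorded checkpoint) if `time = TRUE`.
#' @param time Interpret `which` as a time in seconds?
#' @return An `stdp_network` with the checkpoint's weights and pools; deleted
#'   synapses are dropped from the table (their dendritic positions remain
#'   with the survivors unchanged).
#' @export
checkpoint_network <- function(sim, which, time = FALSE) {
  stopifnot(inherits(sim, "stdp_sim"))
  if (time) {
    tt <- vapply(sim$checkpoints, function(c) c$time_ms, numeric(1))
    which <- which.min(abs(tt - which * 1000))
  }
  ck <- sim$checkpoints[[which]]
  net <- sim$network
  net$rec$weight <- ck$weights
  net$rec <- net$rec[ck$alive, ]
  net$pools <- ck$pools
  net
}
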