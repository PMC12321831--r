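#' Peak time and peak normalization of the double-exponential PSC
#'
#' A single presynaptic spike drives the current pair
#' `tau_sr ds'/dt = -s' + input`, `tau_sf ds/dt = -s + s'`. The output current
#' `s` peaks at `t* = tau_sr*tau_sf/(tau_sf - tau_sr) * log(tau_sf/tau_sr)`
#' after arrival. `psc_peak_gain` returns the increment to `s'` per unit
#' weight that normalizes this peak to 1, so a weight-`w` synapse produces a
#' unitary current of amplitude `w` (in threshold units).
#'
#' @param tau_sr Rise time constant, ms.
#' @param tau_sf Fall time constant, ms.
#' @return Peak time in ms (`psc_peak_time`) or the dimensionless gain
#'   (`psc_peak_gain`).
#' @examples
#' psc_peak_time()   # ~7.05 ms
#' @export
psc_peak_time <- function(tau_sr = 2.6, tau_sf = 31.3) {
  tau_sr * tau_sf / (tau_sf - tau_sr) * log(tau_sf / tau_sr)
}

#' @rdname psc_peak_time
#' @export
psc_peak_gain <- function(tau_sr = 2.6, tau_sf = 31.3) {
  tstar <- psc_peak_time(tau_sr, tau_sf)
  peak <- tau_sr / (tau_sf - tau_sr) * (exp(-tstar / tau_sf) - exp(-tstar / tau_sr))
  1 / peak
}

#' Poisson input spike trains
#'
#' Each train emits a spike in each time step independently with probability
#' `rate * dt` (with `dt` converted to seconds), the Bernoulli approximation
#' of a Poisson process on the integration grid.
#'
#' @param rate Firing rate in Hz (>= 0).
#' @param dt Time step in ms.
#' @param n_steps Number of steps.
#' @param n_trains Number of independent trains.
#' @return Logical matrix `n_steps x n_trains`; `TRUE` marks a spike.
#' @examples
#' set.seed(1)
#' sp <- poisson_input(50, dt = 0.1, n_steps = 1000, n_trains = 2)
#' @export
poisson_input <- function(rate, dt, n_steps, n_trains = 1L) {
  stopifnot(rate >= 0, dt > 0, n_steps >= 0, n_trains >= 1)
  p <- rate * dt * 1e-3
  if (p >= 1) stop("rate * dt >= 1: time step too coarse for a Bernoulli step")
  matrix(stats::runif(n_steps * n_trains) < p, nrow = n_steps)
}

#' Run the spiking-network simulation engine
#'
#' Integrates the full closed loop — Poisson input, delayed spike delivery,
#' refractory leaky integrate-and-fire dynamics, resource-dependent STDP, and
#' pool decay — with forward Euler at the network's `dt`. This is the
#' low-level engine; [run_learning()] and [run_degeneration()] wrap it with
#' the standard protocols.
#'
#' @param net An `stdp_network` from [build_network()] (recurrent table sorted
#'   by target then dendritic position, as built).
#' @param duration Simulated duration in seconds.
#' @param neuron A [neuron_params()] object.
#' @param stdp A [stdp_params()] object, or `NULL` to disable plasticity.
#' @param input_rate Poisson input rate, Hz.
#' @param input_duration Stimulation duration in seconds (input is silent
#'   afterwards).
#' @param scripted_input Optional list with one numeric vector of spike times
#'   (ms) per input train; overrides the Poisson generator and consumes no
#'   randomness.
#' @param degeneration Optional list with fields `start` (s), `interval` (ms),
#'   `order` (integer vector: synapse ids in deletion order) and `replenish`
#'   (logical): progressive single-synapse deletion.
#' @param quiet_window Silence (ms) after which network activity counts as
#'   ceased.
#' @param stop_at_cessation Stop the run once activity has ceased?
#' @param snapshot_interval Scalar-trace snapshot interval, ms.
#' @param checkpoint_interval Full weight/pool checkpoint interval, s.
#' @param checkpoint_times Extra checkpoint times (s), e.g. the end of
#'   stimulation.
#' @param log_events Keep a per-pairing plasticity event log?
#' @param log_min_request Smallest requested change that is logged (smaller
#'   pairings are still applied).
#' @param log_max_events Cap on logged events (counters keep running).
#' @param seed Optional seed for the input spike stream.
#' @return An object of class `stdp_sim`: list with `raster` (data.frame
#'   `time_ms`, `neuron`), `weights`, `pools`, `alive` (final synapse state),
#'   `trace` (data.frame of scalar snapshots), `checkpoints`, `events`
#'   (data.frame), event counters, `deletions`, `cessation_ms`, conservation
#'   accumulators (`cum_pool_decay`, `cum_discarded`), and the input `network`.
#' @export
simulate_network <- function(net, duration,
                             neuron = neuron_params(), stdp = stdp_params(),
                             input_rate = 50, input_duration = duration,
                             scripted_input = NULL,
                             degeneration = NULL,
                             quiet_window = 500, stop_at_cessation = FALSE,
                             snapshot_interval = 100,
                             checkpoint_interval = 2,
                             checkpoint_times = numeric(),
                             log_events = TRUE, log_min_request = 1e-8,
                             log_max_events = 5e5, seed = NULL) {
  stopifnot(inherits(net, "stdp_network"), duration > 0)
  dt <- net$params$dt
  n_steps <- round(duration * 1000 / dt)
  stdp_on <- !is.null(stdp)
  if (!stdp_on) stdp <- stdp_params()

  if (!is.null(scripted_input)) {
    if (length(scripted_input) != net$params$n_in) {
      stop("scripted_input must have one spike-time vector per input train")
    }
    scripted_input <- lapply(scripted_input, function(tt)
      as.integer(sort(round(tt / dt))))
  }
  deg <- list(start_ms = Inf, interval_ms = 1, order = integer(), replenish = TRUE)
  if (!is.null(degeneration)) {
    stopifnot(degeneration$interval > 0)
    deg <- list(start_ms = degeneration$start * 1000,
                interval_ms = degeneration$interval,
                order = as.integer(degeneration$order),
                replenish = isTRUE(degeneration$replenish))
  }

  ctrl <- list(
    dt = dt, n_steps = as.double(n_steps), input_rate = input_rate,
    input_end_step = as.double(round(input_duration * 1000 / dt)),
    scripted_input = scripted_input, stdp_on = stdp_on,
    deg_start_ms = deg$start_ms, deletion_interval_ms = deg$interval_ms,
    deletion_order = deg$order, replenish = deg$replenish,
    quiet_window_ms = quiet_window, stop_at_cessation = stop_at_cessation,
    snapshot_every = as.double(max(1, round(snapshot_interval / dt))),
    checkpoint_every = as.double(max(1, round(checkpoint_interval * 1000 / dt))),
    checkpoint_extra = as.integer(sort(unique(round(checkpoint_times * 1000 / dt)))),
    log_events = log_events, log_min_request = log_min_request,
    log_max_events = as.double(log_max_events)
  )

  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- .sim_core(
    net$rec$source, net$rec$target, net$rec$pos, net$rec$delay_steps,
    net$rec$weight,
    net$input$source, net$input$target, net$input$delay_steps,
    net$input$weight,
    net$pools, net$params$n_exc, net$params$n_in,
    unclass(neuron), unclass(stdp), ctrl
  )

  events <- as.data.frame(res$events)
  events$direction <- ifelse(events$direction > 0, "potentiation", "depression")
  structure(
    list(
      raster = data.frame(time_ms = res$spike_t, neuron = res$spike_n),
      weights = res$weights, pools = res$pools, alive = res$alive,
      trace = as.data.frame(res$trace),
      checkpoints = res$checkpoints,
      events = events,
      n_pot_events = res$n_pot_events,
      n_dep_events = res$n_dep_events,
      n_partial_pot_events = res$n_partial_pot_events,
      deletions = data.frame(time_ms = res$deletion_t,
                             synapse = res$deletion_syn),
      cessation_ms = res$cessation_ms,
      end_time_ms = res$end_step * dt,
      cum_pool_decay = res$cum_pool_decay,
      cum_discarded = res$cum_discarded,
      final_state = list(v = res$v, r = res$r, s = res$s, s_rise = res$s_rise),
      network = net, neuron = neuron,
      stdp = if (stdp_on) stdp else NULL,
      duration = duration
    ),
    class = "stdp_sim"
  )
}

#' @export
print.stdp_sim <- function(x, ...) {
  cat(sprintf("stdp_sim: %.1f s simulated, %d spikes from %d neurons\n",
              x$end_time_ms / 1000, nrow(x$raster),
              length(unique(x$raster$neuron))))
  cat(sprintf("  final weight sum %.3f over %d nonzero synapses; pool sum %.3f\n",
              sum(x$weights[x$alive]), sum(x$weights[x$alive] > 0),
              sum(x$pools)))
  if (!is.na(x$cessation_ms)) {
    cat(sprintf("  activity ceased at %.1f s\n", x$cessation_ms / 1000))
  }
  invisible(x)
}
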