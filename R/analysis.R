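#' Per-neuron firing-rate series
#'
#' Spike counts in consecutive windows divided by the window length, in Hz.
#'
#' @param raster Data.frame with columns `time_ms`, `neuron`.
#' @param window Window length, ms (default 100: resolves 10 Hz increments).
#' @param n_neurons Number of neurons (rows of the result).
#' @param t_max End of the analyzed interval, ms (default: last window edge
#'   covering the raster; must be given for an empty raster).
#' @return Matrix `n_neurons x n_windows` of rates in Hz, with the window
#'   midpoints (ms) as an attribute `"time_ms"`.
#' @export
firing_rates <- function(raster, window = 100, n_neurons, t_max = NULL) {
  stopifnot(window > 0, n_neurons >= 1)
  if (is.null(t_max)) {
    t_max <- if (nrow(raster)) ceiling(max(raster$time_ms) / window) * window
             else stop("t_max required for an empty raster")
  }
  breaks <- seq(0, t_max, by = window)
  if (length(breaks) < 2) breaks <- c(0, window)
  nb <- length(breaks) - 1
  rates <- matrix(0, n_neurons, nb)
  if (nrow(raster)) {
    keep <- raster$time_ms >= 0 & raster$time_ms < breaks[nb + 1]
    bin <- findInterval(raster$time_ms[keep], breaks, rightmost.closed = FALSE)
    tab <- table(factor(raster$neuron[keep], levels = seq_len(n_neurons)),
                 factor(bin, levels = seq_len(nb)))
    rates <- unclass(tab) * 1000 / window
    dimnames(rates) <- NULL
  }
  attr(rates, "time_ms") <- breaks[-1] - window / 2
  rates
}

#' Potentiation efficacy
#'
#' For each potentiation event, the granted weight change as a percentage of
#' the change requested by the STDP window. Values below 100% mark events
#' where neighboring spines and the pool could not fully fund the request;
#' 0% marks a nonpotentiable instance.
#'
#' @param events Event log data.frame (columns `direction`, `requested`,
#'   `granted`), as returned in `stdp_sim$events`.
#' @return Numeric vector of efficacies in `[0, 100]`, one per potentiation
#'   event with `requested > 0`.
#' @export
potentiation_efficacy <- function(events) {
  pot <- events[events$direction == "potentiation" & events$requested > 0, ]
  pmin(100, 100 * pot$granted / pot$requested)
}

#' Mean nearest-neighbor distance between nonfilopodia spines
#'
#' A nonfilopodia spine is a synapse with strictly positive weight. Per
#' neuron, each such spine's distance (in dendritic position units) to its
#' closest nonfilopodia neighbor is averaged; the result is the mean over all
#' neurons carrying at least two nonfilopodia spines. Increasing spacing
#' during learning reflects competition for resources spreading functional
#' spines along the dendrite.
#'
#' @param net An `stdp_network`.
#' @return Mean distance (>= 1), or `NA` if no neuron has two nonfilopodia
#'   spines.
#' @export
nonfilopodia_spacing <- function(net) {
  stopifnot(inherits(net, "stdp_network"))
  r <- net$rec[net$rec$weight > 0, ]
  per_neuron <- vapply(split(r$pos, r$target), function(p) {
    if (length(p) < 2) return(NA_real_)
    p <- sort(p)
    gaps_l <- c(Inf, diff(p))
    gaps_r <- c(diff(p), Inf)
    mean(pmin(gaps_l, gaps_r))
  }, numeric(1))
  per_neuron <- per_neuron[!is.na(per_neuron)]
  if (!length(per_neuron)) return(NA_real_)
  mean(per_neuron)
}

#' Degree and delay-weighted closeness of the learned graph
#'
#' Builds the directed graph whose edges are recurrent synapses with weight
#' above `weight_threshold` and computes mean in/out degree and mean in/out
#' closeness, where path length is the summed axonal delay (ms). Closeness of
#' a node is `(number of reachable nodes) / (sum of shortest-path delays to
#' them)`, and 0 for nodes that reach (or are reached by) nothing — the graph
#' may be disconnected, especially early in learning.
#'
#' @param net An `stdp_network`.
#' @param weight_threshold Edges require `weight > weight_threshold`
#'   (default 0: any nonzero weight).
#' @return List with `mean_in_degree`, `mean_out_degree`,
#'   `mean_in_closeness`, `mean_out_closeness` (ms^-1), and `n_edges`.
#' @export
graph_metrics <- function(net, weight_threshold = 0) {
  stopifnot(inherits(net, "stdp_network"))
  n <- net$params$n_exc
  e <- net$rec[net$rec$weight > weight_threshold, ]
  if (nrow(e) == 0) {
    return(list(mean_in_degree = 0, mean_out_degree = 0,
                mean_in_closeness = 0, mean_out_closeness = 0, n_edges = 0L))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target,
               weight = e$delay_steps * net$params$dt),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  d <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  diag(d) <- Inf # exclude self
  out_cl <- apply(d, 1, .closeness_row)
  in_cl <- apply(d, 2, .closeness_row)
  list(mean_in_degree = nrow(e) / n,
       mean_out_degree = nrow(e) / n,
       mean_in_closeness = mean(in_cl),
       mean_out_closeness = mean(out_cl),
       n_edges = nrow(e))
}

.closeness_row <- function(dr) {
  reach <- is.finite(dr)
  if (!any(reach)) return(0)
  sum(reach) / sum(dr[reach])
}

#' Graph-metric series over a simulation's checkpoints
#'
#' @param sim An `stdp_sim`.
#' @param weight_threshold Passed to [graph_metrics()].
#' @return Data.frame with one row per checkpoint: `time_ms`, degrees and
#'   closeness values.
#' @export
graph_metrics_series <- function(sim, weight_threshold = 0) {
  stopifnot(inherits(sim, "stdp_sim"))
  rows <- lapply(seq_along(sim$checkpoints), function(i) {
    gm <- graph_metrics(checkpoint_network(sim, i), weight_threshold)
    data.frame(time_ms = sim$checkpoints[[i]]$time_ms,
               mean_in_degree = gm$mean_in_degree,
               mean_out_degree = gm$mean_out_degree,
               mean_in_closeness = gm$mean_in_closeness,
               mean_out_closeness = gm$mean_out_closeness,
               n_edges = gm$n_edges)
  })
  do.call(rbind, rows)
}

#' Survival curves of a degeneration run
#'
#' The weight-sum and active-neuron traces, each normalized to its own
#' maximum (in percent).
#'
#' @param degen An `stdp_degeneration` from [run_degeneration()].
#' @return Data.frame `time_ms`, `weight_sum_pct`, `active_neurons_pct`.
#' @export
survival_curves <- function(degen) {
  stopifnot(inherits(degen, "stdp_degeneration"))
  degen$trace[, c("time_ms", "weight_sum_pct", "active_neurons_pct")]
}

#' Is the network still active at time t?
#'
#' `TRUE` iff at least one pool neuron spiked in the half-open window
#' `(t - quiet_window, t]`.
#'
#' @param raster Spike raster data.frame (`time_ms`, `neuron`).
#' @param t Evaluation time, ms.
#' @param quiet_window Window length, ms.
#' @return Logical flag.
#' @export
memory_alive <- function(raster, t, quiet_window = 500) {
  stopifnot(t >= quiet_window)
  any(raster$time_ms > t - quiet_window & raster$time_ms <= t)
}

#' Summary metric report for a simulation
#'
#' Convenience bundle of the standard analysis metrics for a learning run.
#'
#' @param sim An `stdp_sim`.
#' @param rate_window Firing-rate window, ms.
#' @return List with `rates` (matrix), `weight_histogram` (a [hist()]
#'   object, not plotted), `efficacy` (vector), `spacing_start`/`spacing_end`
#'   (from the first and last checkpoints), `graph` (final
#'   [graph_metrics()]), and `memory_persists` (activity alive at the end of
#'   the run).
#' @export
metric_report <- function(sim, rate_window = 100) {
  stopifnot(inherits(sim, "stdp_sim"))
  n <- sim$network$params$n_exc
  end_ms <- sim$end_time_ms
  list(
    rates = firing_rates(sim$raster, rate_window, n, t_max = end_ms),
    weight_histogram = graphics::hist(sim$weights[sim$alive], breaks = 50,
                                      plot = FALSE),
    efficacy = potentiation_efficacy(sim$events),
    spacing_start = nonfilopodia_spacing(checkpoint_network(sim, 1)),
    spacing_end = nonfilopodia_spacing(
      checkpoint_network(sim, length(sim$checkpoints))),
    graph = graph_metrics(checkpoint_network(sim, length(sim$checkpoints))),
    memory_persists = memory_alive(sim$raster, end_ms,
                                   min(500, end_ms))
  )
}
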