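#' Initialize per-neuron resource pools
#'
#' Pools are drawn log-normally, `p = scale * exp(xi)` with `xi` standard
#' normal, reflecting the skewed distributions typical of synaptic and
#' neuronal quantities. Draws come from the current R random stream.
#'
#' @param n Number of neurons.
#' @param scale Multiplicative scale (the distribution median); default 2.
#' @return Numeric vector of `n` strictly positive pool values.
#' @examples
#' set.seed(1)
#' p <- init_resource_pools(5)
#' all(p > 0)
#' @export
init_resource_pools <- function(n, scale = 2) {
  stopifnot(n >= 1, scale > 0)
  scale * exp(stats::rnorm(n))
}

#' Build a random recurrent network
#'
#' Constructs the synapse tables and resource pools. Each ordered pair of
#' distinct excitatory neurons is connected independently with probability
#' `p_rec`; each (input train, neuron) pair with probability `p_in`. Recurrent
#' weights start at 0 (a newly formed network: all spines silent); input
#' weights are drawn uniformly on (0, 1) and are fixed. Delays are drawn
#' uniformly on `[delay_min, delay_max]` ms and rounded to integer multiples
#' of `dt`. On each target neuron the recurrent synapses occupy contiguous
#' dendritic positions `0..(m-1)`, ordered by presynaptic source index (or a
#' seeded random permutation, see [network_params()]).
#'
#' @param params A [network_params()] object.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `stdp_network`: a list with elements
#'   * `rec`: data.frame `(source, target, pos, delay_steps, weight)`, one row
#'     per recurrent synapse, sorted by `(target, pos)`; row order is the
#'     synapse id.
#'   * `input`: data.frame `(source, target, delay_steps, weight)` for the
#'     fixed input projection.
#'   * `pools`: numeric vector of per-neuron resource pools.
#'   * `params`: the `network_params` used.
#' @examples
#' net <- build_network(network_params(n_exc = 20, n_in = 5), seed = 1)
#' nrow(net$rec)
#' @export
build_network <- function(params = network_params(), seed = NULL) {
  stopifnot(inherits(params, "network_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- params$n_exc
  dt <- params$dt

  # recurrent topology: all ordered pairs i != j, independent Bernoulli
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < params$p_rec
  rec <- pairs[keep, ]
  m <- nrow(rec)
  rec$delay_steps <- as.integer(round(
    stats::runif(m, params$delay_min, params$delay_max) / dt))
  rec$weight <- 0

  # dendritic layout: contiguous positions per target neuron
  rec <- rec[order(rec$target, rec$source), ]
  rec$pos <- stats::ave(seq_len(m), rec$target, FUN = seq_along) - 1L
  if (params$dendrite_order == "random" && m > 0) {
    rec$pos <- as.integer(unlist(lapply(split(rec$pos, rec$target), sample),
                                 use.names = FALSE))
    rec <- rec[order(rec$target, rec$pos), ]
  }
  rec <- rec[, c("source", "target", "pos", "delay_steps", "weight")]
  rownames(rec) <- NULL
  attr(rec, "out.attrs") <- NULL

  ipairs <- expand.grid(source = seq_len(params$n_in), target = seq_len(n))
  ikeep <- stats::runif(nrow(ipairs)) < params$p_in
  inp <- ipairs[ikeep, ]
  mi <- nrow(inp)
  inp$delay_steps <- as.integer(round(
    stats::runif(mi, params$delay_min, params$delay_max) / dt))
  inp$weight <- stats::runif(mi)
  inp <- inp[order(inp$source, inp$target), ]
  rownames(inp) <- NULL
  attr(inp, "out.attrs") <- NULL

  pools <- init_resource_pools(n, params$pool_scale)

  structure(
    list(rec = rec, input = inp, pools = pools, params = params),
    class = "stdp_network"
  )
}

#' @export
print.stdp_network <- function(x, ...) {
  cat(sprintf("stdp_network: %d neurons, %d recurrent synapses (%d silent), %d input synapses\n",
              x$params$n_exc, nrow(x$rec), sum(x$rec$weight == 0), nrow(x$input)))
  cat(sprintf("  pools: total %.3f (median %.3f)\n",
              sum(x$pools), stats::median(x$pools)))
  invisible(x)
}

validate_network <- function(net) {
  stopifnot(inherits(net, "stdp_network"))
  r <- net$rec
  if (any(r$source == r$target)) stop("self-connections present")
  if (any(r$weight < 0)) stop("negative recurrent weight")
  if (any(net$pools < 0)) stop("negative resource pool")
  dmin <- net$params$delay_min / net$params$dt
  dmax <- net$params$delay_max / net$params$dt
  if (nrow(r) && (min(r$delay_steps) < floor(dmin) || max(r$delay_steps) > ceiling(dmax))) {
    stop("delay outside bounds")
  }
  invisible(net)
}

#' Remove a recurrent synapse
#'
#' Deletes synapse `j` (a row index of `net$rec`) from the synapse table. With
#' `replenish = TRUE` the synapse's weight is returned to the target neuron's
#' resource pool (modeling resorption of the spine's resources); otherwise the
#' weight is discarded and the neuron's total resources drop. The dendritic
#' positions of the remaining synapses are unchanged, so a gap remains and
#' neighbor distances grow.
#'
#' @param net An `stdp_network`.
#' @param j Synapse id (row index into `net$rec`).
#' @param replenish Return the deleted weight to the pool?
#' @return The modified network.
#' @export
delete_synapse <- function(net, j, replenish = TRUE) {
  stopifnot(inherits(net, "stdp_network"))
  if (length(j) != 1 || is.na(j) || j < 1 || j > nrow(net$rec)) {
    stop("unknown synapse id: ", j)
  }
  if (replenish) {
    tgt <- net$rec$target[j]
    net$pools[tgt] <- net$pools[tgt] + net$rec$weight[j]
  }
  net$rec <- net$rec[-j, ]
  net
}

#' Write / read a network as columnar text
#'
#' Serializes the synapse tables and pool vector to plain-text files
#' (`<prefix>_recurrent.tsv`, `<prefix>_input.tsv`, `<prefix>_pools.tsv`)
#' that round-trip losslessly.
#'
#' @param net An `stdp_network`.
#' @param prefix Path prefix for the three files.
#' @return `write_network` returns `prefix` invisibly; `read_network` returns
#'   the reconstructed `stdp_network`.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "stdp_network"))
  utils::write.table(format(net$rec, digits = 17, trim = TRUE, scientific = FALSE),
                     paste0(prefix, "_recurrent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(net$input, digits = 17, trim = TRUE, scientific = FALSE),
                     paste0(prefix, "_input.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(net$pools, digits = 17, trim = TRUE, scientific = FALSE),
             paste0(prefix, "_pools.tsv"))
  invisible(prefix)
}

#' @param params The `network_params` the network was built with (stored
#'   alongside when reading back).
#' @rdname write_network
#' @export
read_network <- function(prefix, params = network_params()) {
  rec <- utils::read.table(paste0(prefix, "_recurrent.tsv"), header = TRUE)
  rec$pos <- as.integer(rec$pos)
  rec$delay_steps <- as.integer(rec$delay_steps)
  inp <- utils::read.table(paste0(prefix, "_input.tsv"), header = TRUE)
  inp$delay_steps <- as.integer(inp$delay_steps)
  pools <- as.numeric(readLines(paste0(prefix, "_pools.tsv")))
  structure(list(rec = rec, input = inp, pools = pools, params = params),
            class = "stdp_network")
}
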