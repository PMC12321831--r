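#' Load / save a run configuration as YAML
#'
#' The YAML file holds (any subset of) the sections `network`, `neuron`,
#' `stdp`, `protocol`, and a top-level `seed`; omitted fields take the model's
#' default values, so an empty file yields the full default configuration
#' (200 neurons, 25% recurrent connectivity, 50 Hz input for 20 s, and so
#' on). Unknown sections or keys are rejected, as are out-of-range values.
#'
#' @param path Path to a YAML file.
#' @return `load_config` returns a [run_config()]; `save_config` writes
#'   `config` to `path` and returns it invisibly. A save/load round trip is
#'   lossless.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("malformed config file: ", path)
  known <- c("network", "neuron", "stdp", "protocol", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  take <- function(section, fun) {
    given <- raw[[section]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(formals(fun)))
    if (length(bad)) {
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    }
    do.call(fun, given)
  }
  run_config(
    network = take("network", network_params),
    neuron = take("neuron", neuron_params),
    stdp = take("stdp", stdp_params),
    protocol = take("protocol", protocol_config),
    seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}

#' @param config A [run_config()].
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(network = unclass(config$network),
              neuron = unclass(config$neuron),
              stdp = unclass(config$stdp),
              protocol = Filter(Negate(is.null), unclass(config$protocol)),
              seed = config$seed)
  yaml::write_yaml(out, path, precision = 17)
  invisible(config)
}

#' Write / read a spike raster as two-column text
#'
#' Format: a `#`-prefixed metadata header line, then one `time_ms neuron`
#' pair per line.
#'
#' @param raster Data.frame (`time_ms`, `neuron`).
#' @param path Output path.
#' @param meta Optional metadata string for the header.
#' @return `write_raster` returns `path` invisibly; `read_raster` the
#'   data.frame.
#' @export
write_raster <- function(raster, path, meta = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# restdp spike raster (time_ms neuron) ", meta), con)
  utils::write.table(raster, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("time_ms", "neuron"))
  df$neuron <- as.integer(df$neuron)
  df
}

#' Write a plasticity event log as CSV
#'
#' @param events Event data.frame (`stdp_sim$events`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the full configuration, the master seed and the package version —
#' sufficient to reproduce a run's outputs bit-identically.
#'
#' @param config A [run_config()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.yaml")
  save_config(config, path)
  cat(sprintf("# restdp %s\n", as.character(utils::packageVersion("restdp"))),
      file = path, append = TRUE)
  invisible(path)
}
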