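#' Presynaptic spike train
#'
#' @param node_id Integer identifier of the presynaptic node.
#' @param times Numeric vector of event times (ms), strictly increasing.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(node_id, times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(node_id = as.integer(node_id), times = times),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> node %d, %d spikes\n", x$node_id, length(x$times)))
  invisible(x)
}

#' Partition presynaptic nodes into functional groups
#'
#' Presynaptic excitatory nodes are organised into functional groups -- cell
#' assemblies whose members share a common slow rate modulator. The node
#' count is the synapse budget divided by the mean divergence (floored), then
#' rounded down to a whole number of groups. With the study's numbers,
#' 26112 synapses at a mean divergence of 5 give 5222 nodes, trimmed to 5200
#' so that 52 groups of 100 can be formed.
#'
#' @param n_synapses Total number of excitatory synapses (> 0).
#' @param mean_divergence Mean synapses per presynaptic node (> 0).
#' @param group_size Nodes per functional group (default 100).
#' @return A list of `functional_group` objects, each a list with fields
#'   `group_id` and `node_ids`; the groups partition `1:n_nodes_retained`.
#' @examples
#' g <- build_functional_groups(26112, 5, 100)
#' length(g) # 52
#' @export
build_functional_groups <- function(n_synapses, mean_divergence,
                                    group_size = 100) {
  if (!is.finite(n_synapses) || n_synapses <= 0) stop("n_synapses must be > 0")
  if (!is.finite(mean_divergence) || mean_divergence <= 0) {
    stop("mean_divergence must be > 0")
  }
  if (!is.finite(group_size) || group_size <= 0) stop("group_size must be > 0")
  n_nodes <- floor(n_synapses / mean_divergence)
  if (group_size > n_nodes) {
    stop("group_size exceeds the available node count (", n_nodes, ")")
  }
  n_groups <- floor(n_nodes / group_size)
  n_keep <- n_groups * group_size
  ids <- seq_len(n_keep)
  lapply(seq_len(n_groups), function(g) {
    structure(
      list(group_id = g,
           node_ids = ids[((g - 1) * group_size + 1):(g * group_size)]),
      class = "functional_group"
    )
  })
}

#' Sample an inhomogeneous Poisson spike train from a rate trace
#'
#' Bernoulli-per-bin thinning at the trace's own grid: a uniform variate is
#' drawn for each bin and a spike emitted when it falls below `r[t] * dt`
#' (with `dt` in seconds; the default 1 ms grid gives `dt = 1/1000`). Valid
#' only while every per-bin probability is below 1.
#'
#' @param rate A `rate_trace` in Hz.
#' @param seed Optional integer seed.
#' @param node_id Node id stored on the result.
#' @return A `spike_train`; spike times sit on bin starts, so they are
#'   strictly increasing and duplicate-free.
#' @export
sample_poisson <- function(rate, seed = NULL, node_id = 1L) {
  stopifnot(inherits(rate, "rate_trace"))
  p <- rate$values * rate$dt / 1000
  if (any(p >= 1)) {
    stop("rate * dt reaches 1 in at least one bin; use a finer grid")
  }
  if (!is.null(seed)) set.seed(seed)
  hit <- stats::runif(length(p)) <= p
  spike_train(node_id, rate$t0 + (which(hit) - 1) * rate$dt)
}

#' Sample correlated spike trains for a whole functional group
#'
#' Equivalent to applying [modulate_node_rates()] followed by
#' [sample_poisson()] for every member node, without materialising one rate
#' trace per node. All members share `modulator`, so their spike trains are
#' statistically correlated.
#'
#' @param base_rates Mean rate (Hz) per node.
#' @param modulator Shared `rate_trace` multiplier.
#' @param seed Optional integer seed.
#' @param node_ids Node ids (default `seq_along(base_rates)`).
#' @return List of `spike_train` objects.
#' @export
sample_poisson_group <- function(base_rates, modulator, seed = NULL,
                                 node_ids = seq_along(base_rates)) {
  stopifnot(inherits(modulator, "rate_trace"))
  if (any(base_rates < 0)) stop("base rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(modulator$values)
  scale <- modulator$dt / 1000
  pmax_all <- max(base_rates) * max(modulator$values) * scale
  if (pmax_all >= 1) stop("rate * dt reaches 1; use a finer grid")
  u <- matrix(stats::runif(n * length(base_rates)), nrow = n)
  t_grid <- modulator$t0 + (seq_len(n) - 1) * modulator$dt
  out <- vector("list", length(base_rates))
  for (i in seq_along(base_rates)) {
    hit <- u[, i] <= base_rates[i] * modulator$values * scale
    out[[i]] <- spike_train(node_ids[i], t_grid[hit])
  }
  out
}

#' Jittered copies of a base spike train (clustered coactive input)
#'
#' Clustered synaptic drive is emulated by taking one Poisson process and
#' jittering each spike independently and uniformly within +/- `jitter` ms
#' per output train (the study uses 40 trains, +/- 2 ms). Jittered times are
#' reflected at the window edges and re-sorted; spike counts are preserved.
#'
#' @param base A `spike_train`.
#' @param n_trains Number of jittered copies.
#' @param jitter Maximum absolute jitter in ms (>= 0).
#' @param seed Optional integer seed.
#' @param window Length-2 numeric, the simulation window in ms used for edge
#'   reflection.
#' @return List of `spike_train` objects with node ids continuing after
#'   `base$node_id`.
#' @export
gen_cluster_trains <- function(base, n_trains, jitter = 2, seed = NULL,
                               window = NULL) {
  stopifnot(inherits(base, "spike_train"))
  if (!is.finite(jitter) || jitter < 0) stop("jitter must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(window)) {
    window <- c(min(0, base$times[1] - jitter), max(base$times, 0) + jitter)
  }
  lapply(seq_len(n_trains), function(k) {
    t <- base$times
    if (jitter > 0 && length(t)) {
      t <- t + stats::runif(length(t), -jitter, jitter)
      t[t < window[1]] <- 2 * window[1] - t[t < window[1]]
      t[t > window[2]] <- 2 * window[2] - t[t > window[2]]
      t <- sort(t)
      # ties have probability zero but guard against them anyway
      while (any(duplicated(t))) t[duplicated(t)] <- t[duplicated(t)] + 1e-9
    }
    spike_train(base$node_id + k, t)
  })
}

#' Write/read spike trains as two-column delimited text
#'
#' Format: header `node_id<TAB>time_ms`, one row per spike.
#'
#' @param trains List of `spike_train` objects.
#' @param path File path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a list of `spike_train` objects.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(node_id = tr$node_id, time_ms = tr$times)
  }))
  if (is.null(df)) df <- data.frame(node_id = integer(), time_ms = numeric())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ids <- sort(unique(df$node_id))
  lapply(ids, function(id) spike_train(id, sort(df$time_ms[df$node_id == id])))
}

#' Write/read a rate trace as single-column delimited text
#'
#' The first line is a header `# t0=<ms> dt=<ms>`, followed by one value per
#' line.
#'
#' @param trace A `rate_trace`.
#' @param path File path.
#' @export
write_rate_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rate_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t0=%.17g dt=%.17g", trace$t0, trace$dt), con)
  writeLines(format(trace$values, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_rate_trace
#' @export
read_rate_trace <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("t0=([-0-9.eE+]+) dt=([-0-9.eE+]+)", header))[[1]]
  if (length(m) != 3) stop("malformed rate-trace header")
  values <- utils::read.table(path, skip = 1)[[1]]
  rate_trace(values, dt = as.numeric(m[3]), t0 = as.numeric(m[2]))
}
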