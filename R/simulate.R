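# Discrete-time simulation of an IAF network. A step integrates leak and
# synaptic input first, then tests the firing window, then resets: a spike
# emitted at step t is seen by the other neurons at step t + 1.

#' Internal state from a binary network state
#'
#' A '1' entry means the neuron has just fired: its membrane potential starts
#' at rest and its spike is delivered to its targets on the next step. A '0'
#' entry is a neuron at rest.
#'
#' @param network An [iaf_network()].
#' @param state Binary vector of length `n` (or a string like `"100"`).
#' @return A list with components `v` (membrane potentials, mV) and `spikes`
#'   (binary outputs).
#' @export
init_from_binary_state <- function(network, state) {
  stopifnot(inherits(network, "iaf_network"))
  state <- parse_state(state)
  if (length(state) != network$n)
    stop(sprintf("`state` must have length %d", network$n))
  list(v = network$neurons$v_rest, spikes = state)
}

#' Advance an IAF network by one time step
#'
#' @param network An [iaf_network()].
#' @param state A list `(v, spikes)` as returned by
#'   [init_from_binary_state()] or a previous `iaf_step()`.
#' @param external_input Optional per-neuron additive increment, mV.
#' @param source_spikes Optional 0/1 values for the network's source nodes
#'   (in the order of `network$sources`), overriding their dynamics.
#' @return The updated `(v, spikes)` list.
#' @export
iaf_step <- function(network, state, external_input = NULL,
                     source_spikes = NULL) {
  nn <- network$neurons
  v <- state$v + (network$dt / (nn$tau * network$dt)) * (nn$v_rest - state$v) +
    as.vector(network$weights %*% state$spikes)
  if (!is.null(external_input)) v <- v + external_input
  fired <- as.integer(v >= nn$threshold_low & v < nn$threshold_high)
  if (length(network$sources)) {
    if (is.null(source_spikes)) source_spikes <- rep(0L, length(network$sources))
    fired[network$sources] <- as.integer(source_spikes)
    v[network$sources] <- nn$v_rest[network$sources]
  }
  v[fired == 1L] <- nn$v_rest[fired == 1L]
  list(v = v, spikes = fired)
}

#' Simulate an IAF network from a binary initial state
#'
#' Runs `steps` applications of [iaf_step()] starting from
#' [init_from_binary_state()]. Deterministic unless external inputs or source
#' schedules are supplied.
#'
#' @inheritParams init_from_binary_state
#' @param steps Number of steps (`>= 1`).
#' @param external_input Optional `steps x n` matrix of additive mV
#'   increments; row t is applied during step t.
#' @param source_schedule Optional `steps x length(sources)` 0/1 matrix of
#'   prescribed spike trains for the network's source nodes.
#' @return An `iaf_trace`: list with `v` and `spikes` (`steps x n` matrices),
#'   the initial state and the network. Use [generics::tidy()] for a long
#'   tibble or [ggplot2::autoplot()] to plot.
#' @export
#' @examples
#' tr <- simulate_iaf(gate_network(), c(1, 0, 0), steps = 8)
#' tr$spikes
simulate_iaf <- function(network, init, steps, external_input = NULL,
                         source_schedule = NULL) {
  stopifnot(inherits(network, "iaf_network"), steps >= 1)
  init <- parse_state(init)
  st <- init_from_binary_state(network, init)
  n <- network$n
  if (!is.null(external_input)) {
    external_input <- as.matrix(external_input)
    stopifnot(nrow(external_input) >= steps, ncol(external_input) == n)
  }
  if (!is.null(source_schedule)) {
    source_schedule <- as.matrix(source_schedule)
    stopifnot(nrow(source_schedule) >= steps,
              ncol(source_schedule) == length(network$sources))
  }
  v_hist <- matrix(NA_real_, steps, n)
  s_hist <- matrix(NA_integer_, steps, n)
  for (t in seq_len(steps)) {
    st <- iaf_step(
      network, st,
      external_input = if (!is.null(external_input)) external_input[t, ],
      source_spikes = if (!is.null(source_schedule)) source_schedule[t, ]
    )
    v_hist[t, ] <- st$v
    s_hist[t, ] <- st$spikes
  }
  colnames(v_hist) <- colnames(s_hist) <- network$neurons$label
  structure(
    list(v = v_hist, spikes = s_hist, init = init, network = network),
    class = "iaf_trace"
  )
}

#' Coarse-grain a trace to binary states
#'
#' State '1' is spike firing at that step; every other membrane potential
#' value (resting or subthreshold) maps to '0'. Equals the trace's spike
#' raster.
#'
#' @param trace An `iaf_trace`.
#' @return A `steps x n` 0/1 integer matrix.
#' @export
binarize <- function(trace) {
  stopifnot(inherits(trace, "iaf_trace"))
  trace$spikes
}

# Full binary state sequence including the initial state as row 1.
state_sequence <- function(trace) {
  rbind(trace$init, trace$spikes)
}

#' @export
print.iaf_trace <- function(x, ...) {
  cat(sprintf("<iaf_trace> %d steps x %d neurons (init %s)\n",
              nrow(x$v), ncol(x$v), state_label(x$init)))
  invisible(x)
}

#' Tidy a simulation trace
#'
#' @param x An `iaf_trace`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `neuron`, `v` (mV) and `spike`.
#' @export
tidy.iaf_trace <- function(x, ...) {
  steps <- nrow(x$v)
  labs <- colnames(x$v)
  tibble::tibble(
    step = rep(seq_len(steps), times = length(labs)),
    neuron = rep(labs, each = steps),
    v = as.vector(x$v),
    spike = as.integer(as.vector(x$spikes))
  )
}

#' Write a trace as delimited text
#'
#' One row per step; per-neuron membrane potential columns (`v_<label>`)
#' followed by per-neuron spike flags (`spike_<label>`).
#'
#' @param trace An `iaf_trace`.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "iaf_trace"))
  df <- data.frame(step = seq_len(nrow(trace$v)), trace$v, trace$spikes,
                   check.names = FALSE)
  names(df) <- c("step", paste0("v_", colnames(trace$v)),
                 paste0("spike_", colnames(trace$spikes)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
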