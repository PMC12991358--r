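# Network specification for small discrete-time leaky integrate-and-fire
# (LIF/IAF) circuits. Units: potentials and weights in mV, the time step dt in
# ms, membrane time constants in multiples of dt.

#' Define a network of leaky integrate-and-fire neurons
#'
#' The membrane potential of neuron `i` evolves in discrete time as
#' \deqn{V_i(t) = V_i(t-1) + \frac{\Delta t}{\tau_i}\,(V_{rest} - V_i(t-1)) +
#'   \sum_j w_{ij}\, s_j(t-1) + I_i(t),}
#' where \eqn{s_j(t-1)} is the binary spike output of neuron `j` on the
#' previous step and \eqn{I_i} an optional external increment in mV. A neuron
#' fires when its updated potential falls inside its firing window
#' `threshold_low <= V < threshold_high`, in which case the potential is reset
#' to `v_rest`; a potential driven at or above a finite `threshold_high`
#' saturates silently and is not reset.
#'
#' @param weights `n x n` numeric matrix; `weights[i, j]` is the synaptic
#'   weight (mV) of the connection from neuron `j` into neuron `i`. Zero means
#'   no connection. The diagonal must be zero (no self-connections).
#' @param tau Membrane time constants in multiples of `dt`; scalar or length
#'   `n`. Must be `>= 1`.
#' @param threshold_low Lower firing bound(s), mV.
#' @param threshold_high Upper firing bound(s), mV; `Inf` for ordinary
#'   threshold neurons, finite only for window (XOR-like) neurons.
#' @param v_rest Resting potential(s), mV.
#' @param labels Neuron labels.
#' @param dt Simulation step, ms.
#' @param sources Integer indices of source nodes whose spike train is
#'   prescribed externally (e.g. a Poisson input treated as a network
#'   element); their membrane dynamics are ignored.
#' @return An object of class `iaf_network`.
#' @seealso [gate_network()] for the OR-AND-XOR logic-gate preset.
#' @export
iaf_network <- function(weights, tau, threshold_low, threshold_high = Inf,
                        v_rest = 0, labels = NULL, dt = 1, sources = integer()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("`weights` must be square")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be finite and non-negative")
  if (any(diag(weights) != 0)) stop("self-connections are not allowed")
  if (dt <= 0) stop("`dt` must be positive")
  rec <- function(x, what) {
    x <- rep_len(x, n)
    x
  }
  tau <- rec(tau); threshold_low <- rec(threshold_low)
  threshold_high <- rec(threshold_high); v_rest <- rec(v_rest)
  if (any(tau < 1)) stop("`tau` must be >= 1 (in units of dt)")
  if (any(threshold_low >= threshold_high))
    stop("`threshold_low` must be below `threshold_high`")
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  sources <- as.integer(sources)
  if (length(sources) && (any(sources < 1) || any(sources > n)))
    stop("`sources` out of range")
  structure(
    list(
      n = n, weights = weights, dt = dt,
      neurons = tibble::tibble(
        label = labels, tau = tau, v_rest = v_rest,
        threshold_low = threshold_low, threshold_high = threshold_high
      ),
      sources = sources
    ),
    class = "iaf_network"
  )
}

#' OR-AND-XOR logic-gate network of integrate-and-fire neurons
#'
#' Three mutually connected neurons (no self-connections) with uniform weight
#' `w` and resting potential 0 mV, whose firing windows emulate logic gates:
#' OR fires at `V >= 50` mV, AND at `V >= 100` mV (two inputs) or `V >= 150`
#' mV (three inputs), and XOR inside `50 <= V < 100` mV. With `tau = 1` and
#' `w = 50` the network reproduces the classic fully connected ABC gate
#' system: A = OR(B, C), B = AND(A, C), C = XOR(A, B).
#'
#' @param w Uniform synaptic weight, mV.
#' @param tau Membrane time constant, multiples of `dt` (applied to all
#'   neurons).
#' @param extra_input If `TRUE`, thresholds are taken from the 3-input column
#'   (AND fires at 150 mV), for use when each neuron receives one additional
#'   external input.
#' @return An `iaf_network` with neurons labelled OR, AND, XOR.
#' @export
#' @examples
#' net <- gate_network(w = 50, tau = 1)
#' net$neurons
gate_network <- function(w = 50, tau = 1, extra_input = FALSE) {
  stopifnot(w >= 0, tau >= 1)
  W <- matrix(w, 3, 3); diag(W) <- 0
  and_lo <- if (extra_input) 150 else 100
  iaf_network(
    weights = W, tau = tau,
    threshold_low = c(50, and_lo, 50),
    threshold_high = c(Inf, Inf, 100),
    v_rest = 0, labels = c("OR", "AND", "XOR"), dt = 1
  )
}

#' Extend a network with a feedforward source node
#'
#' Appends one node with no incoming connections whose spike train is
#' prescribed during simulation (see `sources` in [simulate_iaf()]), feeding
#' the `target` neuron with weight `weight`. Used for the 4-element
#' external-noise configuration, where a Poisson input is treated as a
#' network element.
#'
#' @param network An `iaf_network`.
#' @param target Index of the neuron receiving the source input.
#' @param weight Connection weight, mV.
#' @param label Label for the new node.
#' @return An `iaf_network` with `n + 1` nodes; the last node is a source.
#' @export
add_source_node <- function(network, target, weight = 50, label = "NOISE") {
  stopifnot(inherits(network, "iaf_network"))
  n <- network$n
  stopifnot(target >= 1, target <= n)
  W <- rbind(cbind(network$weights, 0), 0)
  W[target, n + 1] <- weight
  nn <- network$neurons
  iaf_network(
    weights = W,
    tau = c(nn$tau, 1),
    threshold_low = c(nn$threshold_low, 50),
    threshold_high = c(nn$threshold_high, Inf),
    v_rest = c(nn$v_rest, 0),
    labels = c(nn$label, label),
    dt = network$dt,
    sources = c(network$sources, n + 1L)
  )
}

#' Binary connectivity matrix of a network
#'
#' @param network An `iaf_network`.
#' @return An `n x n` 0/1 matrix in source-by-target orientation:
#'   `cm[i, j] = 1` iff node `i` feeds node `j` (i.e. `weights[j, i] != 0`).
#' @export
#' @examples
#' connectivity_matrix(gate_network())
connectivity_matrix <- function(network) {
  stopifnot(inherits(network, "iaf_network"))
  cm <- t(network$weights != 0) * 1L
  dimnames(cm) <- list(network$neurons$label, network$neurons$label)
  cm
}

#' @export
print.iaf_network <- function(x, ...) {
  cat(sprintf("<iaf_network> %d neurons, dt = %g ms\n", x$n, x$dt))
  print(x$neurons)
  cat("weights (mV, row = target, col = source):\n")
  print(x$weights)
  if (length(x$sources))
    cat("source nodes (prescribed spike trains):",
        paste(x$neurons$label[x$sources], collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a network specification as JSON
#'
#' @param network An `iaf_network`.
#' @param path File path.
#' @return `read_network()` returns an `iaf_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "iaf_network"))
  obj <- list(
    n = network$n, dt = network$dt,
    weights = network$weights,
    neurons = as.data.frame(network$neurons),
    sources = network$sources
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nn <- obj$neurons
  iaf_network(
    weights = matrix(unlist(obj$weights), nrow = obj$n, byrow = FALSE),
    tau = nn$tau, threshold_low = nn$threshold_low,
    threshold_high = ifelse(is.na(nn$threshold_high), Inf, nn$threshold_high),
    v_rest = nn$v_rest, labels = nn$label, dt = obj$dt,
    sources = if (length(obj$sources)) obj$sources else integer()
  )
}
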