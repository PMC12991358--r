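# Empirical estimation of the state-by-state transition probability matrix
# (TPM) from simulated runs, one restart per possible binary network state.

#' Construct a transition model from a TPM and connectivity matrix
#'
#' The state-by-state TPM is kept as estimated; no factorisation into
#' per-node probabilities is stored (coarse-grained leaky dynamics need not
#' be conditionally independent). Rows and columns follow the package state
#' ordering (node 1 = least-significant bit, see [all_states()]).
#'
#' @param tpm `2^n x 2^n` row-stochastic matrix; entry (s, s') is
#'   P(next = s' | current = s).
#' @param cm `n x n` binary connectivity matrix, source-by-target
#'   (`cm[i, j] = 1` iff node `i` feeds node `j`).
#' @param labels Node labels.
#' @param meta Optional list of provenance fields (steps_per_run, seed, ...).
#' @return A `transition_model` object.
#' @export
transition_model <- function(tpm, cm, labels = NULL, meta = list()) {
  tpm <- as.matrix(tpm)
  cm <- as.matrix(cm) * 1L
  n <- nrow(cm)
  if (ncol(cm) != n) stop("`cm` must be square")
  if (nrow(tpm) != 2^n || ncol(tpm) != 2^n)
    stop("`tpm` must be 2^n x 2^n for the n of `cm`")
  if (any(tpm < 0) || any(tpm > 1))
    stop("TPM entries must be probabilities in [0, 1]")
  rs <- rowSums(tpm)
  if (any(abs(rs - 1) > 1e-9))
    stop("every TPM row must sum to 1 (non-stochastic row found)")
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  dimnames(tpm) <- list(state_labels(n), state_labels(n))
  dimnames(cm) <- list(labels, labels)
  structure(
    list(tpm = tpm, cm = cm, n = n, labels = labels,
         ordering = "little-endian (node 1 = least-significant bit)",
         meta = meta),
    class = "transition_model"
  )
}

#' Estimate the empirical TPM of an IAF network
#'
#' Simulates the network once from each of the `2^n` binary initial states
#' for `steps_per_run` steps, records every consecutive state transition
#' (including the initial-state to first-step transition), pools the counts
#' over all restarts and normalizes each row by its total. Every state is a
#' source at least once, so every row is defined.
#'
#' For a deterministic gate network (`tau = 1`) the result contains only 0s
#' and 1s; leaky networks (`tau > 1`) generally yield fractional
#' probabilities even though the underlying dynamics are deterministic,
#' because identical binary states can hide different membrane potentials.
#'
#' @param network An [iaf_network()].
#' @param steps_per_run Steps simulated from each initial state (8 suffices
#'   for the `tau = 1` gate network; 200 is the deterministic default, 1000
#'   recommended with noise).
#' @param noise Optional [poisson_input()] describing a stochastic spike
#'   train. If the network contains source nodes the train drives them;
#'   otherwise it is injected as an additive `weight * spike` mV term into
#'   the target neuron's input sum.
#' @param seed Integer seed making noisy estimates reproducible; required
#'   when `noise` is given.
#' @return A `transition_model` with `meta` recording the protocol; `counts`
#'   holds the pooled transition counts.
#' @export
#' @examples
#' m <- empirical_tpm(gate_network(), steps_per_run = 8)
#' all(m$tpm %in% c(0, 1))
empirical_tpm <- function(network, steps_per_run = 200, noise = NULL,
                          seed = NULL) {
  stopifnot(inherits(network, "iaf_network"), steps_per_run >= 1)
  n <- network$n
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "poisson_input"))
    if (is.null(seed)) stop("`seed` is required for noisy TPM estimation")
  }
  if (!is.null(seed)) set.seed(seed)
  states <- all_states(n)
  nstate <- 2^n
  counts <- matrix(0, nstate, nstate)
  has_sources <- length(network$sources) > 0
  for (k in seq_len(nstate)) {
    ext <- NULL; sched <- NULL
    if (!is.null(noise)) {
      train <- poisson_train(noise$mean_interval, steps_per_run)
      if (has_sources) {
        sched <- matrix(train, ncol = length(network$sources))
      } else {
        ext <- matrix(0, steps_per_run, n)
        ext[, noise$target] <- noise$weight * train
      }
    }
    tr <- simulate_iaf(network, states[k, ], steps_per_run,
                       external_input = ext, source_schedule = sched)
    seq_idx <- apply(state_sequence(tr), 1, function(s) state_index(s))
    for (t in seq_len(steps_per_run)) {
      counts[seq_idx[t], seq_idx[t + 1]] <- counts[seq_idx[t], seq_idx[t + 1]] + 1
    }
  }
  tpm <- counts / rowSums(counts)
  model <- transition_model(
    tpm, connectivity_matrix(network), labels = network$neurons$label,
    meta = list(steps_per_run = steps_per_run, seed = seed,
                noise = if (!is.null(noise)) unclass(noise))
  )
  model$counts <- counts
  model
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d nodes, %d states; ordering: %s\n",
              x$n, 2^x$n, x$ordering))
  if (!is.null(x$meta$steps_per_run))
    cat(sprintf("  estimated with %d steps per restart\n",
                x$meta$steps_per_run))
  invisible(x)
}

#' Tidy a transition model into transition records
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to` and `prob` (zero-probability
#'   transitions omitted).
#' @export
tidy.transition_model <- function(x, ...) {
  labs <- state_labels(x$n)
  idx <- which(x$tpm > 0, arr.ind = TRUE)
  tibble::tibble(
    from = labs[idx[, 1]], to = labs[idx[, 2]],
    prob = x$tpm[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' Write / read a transition model
#'
#' `write_transition_model()` writes a JSON document carrying the TPM, CM,
#' node labels, state-ordering convention and estimation metadata;
#' `write_tpm_table()` writes the TPM alone as delimited text with a header
#' line recording the conventions.
#'
#' @param model A `transition_model`.
#' @param path File path.
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  obj <- list(
    n = model$n, labels = model$labels, ordering = model$ordering,
    tpm = model$tpm, cm = model$cm, meta = model$meta
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transition_model(obj$tpm, obj$cm, labels = obj$labels,
                   meta = if (is.null(obj$meta)) list() else obj$meta)
}

#' @rdname write_transition_model
#' @param sep Field separator.
#' @export
write_tpm_table <- function(model, path, sep = "\t") {
  stopifnot(inherits(model, "transition_model"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- model$meta
  writeLines(sprintf(
    "# n=%d ordering=%s steps_per_run=%s seed=%s", model$n, model$ordering,
    if (is.null(meta$steps_per_run)) "NA" else meta$steps_per_run,
    if (is.null(meta$seed)) "NA" else meta$seed
  ), con)
  utils::write.table(model$tpm, con, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}
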