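# Poisson noise experiments: a stochastic spike train delivered to the OR
# neuron, analysed either as intrinsic noise of a 3-element system or as a
# fourth, feedforward network element.

#' Describe a Poisson spike input
#'
#' A homogeneous Poisson process at rate `1/mean_interval` per step,
#' approximated as independent per-step Bernoulli draws (at most one spike
#' per time step, the resolution at which network states are defined).
#'
#' @param mean_interval Mean spike interval `1/lambda`, in multiples of the
#'   simulation step (`>= 1`; `Inf` gives the noise-free limit).
#' @param weight mV delivered per noise spike (default 50, one full
#'   gate-strength input).
#' @param target Index of the neuron receiving the noise (the OR neuron in
#'   the gate network).
#' @return A `poisson_input` specification.
#' @export
poisson_input <- function(mean_interval, weight = 50, target = 1) {
  stopifnot(mean_interval >= 1, weight >= 0)
  structure(list(mean_interval = mean_interval, weight = weight,
                 target = as.integer(target)),
            class = "poisson_input")
}

#' Draw a Poisson spike train
#'
#' Independent per-step draws with spike probability `1/mean_interval`.
#'
#' @inheritParams poisson_input
#' @param steps Number of steps.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [empirical_tpm()], which seeds once per estimation).
#' @return Integer 0/1 vector of length `steps`.
#' @export
#' @examples
#' mean(poisson_train(3, 1000, seed = 1))  # about 1/3
poisson_train <- function(mean_interval, steps, seed = NULL) {
  stopifnot(mean_interval >= 1, steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.infinite(mean_interval)) 0 else 1 / mean_interval
  rbinom(steps, 1L, p)
}

# Phi of every binary state of a model, as a tibble.
phi_per_state <- function(model) {
  n <- model$n
  states <- all_states(n)
  purrr::map_dfr(seq_len(2^n), function(k) {
    res <- tryCatch(big_phi(model, states[k, ]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(state = paste0(states[k, ], collapse = ""),
                     phi = NA_real_, status = "error",
                     n_concepts = NA_integer_)
    } else {
      tibble::tibble(state = state_label(res$state), phi = res$phi,
                     status = res$status, n_concepts = res$n_concepts)
    }
  })
}

#' Phi under intrinsic noise (3-element analysis)
#'
#' The Poisson train is injected as an additive `weight * spike` term into
#' the target neuron's input sum; the network keeps its `n` elements and its
#' `n x n` connectivity. The TPM becomes genuinely stochastic, so the run
#' length is raised to 1000 steps by default.
#'
#' @param network An [iaf_network()] (typically [gate_network()]).
#' @param mean_interval Mean Poisson spike interval, multiples of dt.
#' @param noise_weight mV per noise spike.
#' @param target Neuron receiving the noise.
#' @param steps_per_run Steps per restart for TPM estimation.
#' @param seed Integer seed (required; the pipeline is reproducible for a
#'   fixed seed).
#' @return A tibble with one row per binary state: `state`, `phi`, `status`
#'   (`ok`/`unreachable`), `n_concepts`.
#' @export
phi_internal_noise <- function(network, mean_interval, noise_weight = 50,
                               target = 1, steps_per_run = 1000, seed) {
  noise <- poisson_input(mean_interval, noise_weight, target)
  model <- if (is.infinite(mean_interval)) {
    empirical_tpm(network, steps_per_run)
  } else {
    empirical_tpm(network, steps_per_run, noise = noise, seed = seed)
  }
  phi_per_state(model)
}

#' Phi with the noise source as a fourth, feedforward element
#'
#' The Poisson train is treated as an additional network element with a
#' feedforward connection onto the target neuron and no incoming
#' connections. The TPM then has `2^(n+1)` states and is estimated with one
#' restart per state. Because the source has no causes within the system,
#' the system is reducible and Phi is zero for every state, for any
#' parameter values.
#'
#' @inheritParams phi_internal_noise
#' @param source_label Label for the appended source node.
#' @return A tibble with one row per `2^(n+1)` state.
#' @export
phi_external_noise <- function(network, mean_interval, noise_weight = 50,
                               target = 1, steps_per_run = 1000, seed,
                               source_label = "NOISE") {
  net4 <- add_source_node(network, target, noise_weight, source_label)
  noise <- poisson_input(mean_interval, noise_weight, target)
  model <- empirical_tpm(net4, steps_per_run, noise = noise, seed = seed)
  phi_per_state(model)
}

#' Relative change in Phi between a baseline and a noisy condition
#'
#' Joins two Phi tables on their shared descriptor columns (`state`, and
#' `tau`/`w` when present) and computes
#' `100 * (phi_noise - phi_base) / phi_base`. Cells with a zero baseline get
#' the sentinel `"x"` in `rel_label` (the relative difference diverges);
#' cells undefined in either condition (unreachable states) get `NA`.
#'
#' @param base,noisy Tibbles with a `phi` column (and optionally `status`),
#'   as returned by [phi_internal_noise()] or [run_sweep()].
#' @return A tibble with `phi_base`, `phi_noise`, `rel_change` (percent) and
#'   `rel_label` (formatted value or `"x"`).
#' @export
relative_change <- function(base, noisy) {
  keys <- intersect(intersect(names(base), names(noisy)),
                    c("tau", "w", "state"))
  if (!length(keys)) stop("no shared descriptor columns to join on")
  b <- dplyr::select(base, dplyr::all_of(keys), phi_base = "phi",
                     dplyr::any_of(c(status_base = "status")))
  nz <- dplyr::select(noisy, dplyr::all_of(keys), phi_noise = "phi",
                      dplyr::any_of(c(status_noise = "status")))
  out <- dplyr::inner_join(b, nz, by = keys)
  if (nrow(out) != nrow(b) || nrow(out) != nrow(nz))
    stop("tables are not aligned: descriptor sets differ")
  out |>
    dplyr::mutate(
      defined = !is.na(.data$phi_base) & !is.na(.data$phi_noise),
      rel_change = dplyr::if_else(
        .data$defined & .data$phi_base != 0,
        100 * (.data$phi_noise - .data$phi_base) / .data$phi_base,
        NA_real_),
      rel_label = dplyr::case_when(
        !.data$defined ~ NA_character_,
        .data$phi_base == 0 ~ "x",
        TRUE ~ sprintf("%.1f", .data$rel_change)
      )
    ) |>
    dplyr::select(-"defined")
}

#' Mean Phi as a function of the Poisson spike interval
#'
#' For each mean interval, estimates the noisy TPM for every `(tau, w)`
#' combination of the grid, computes Phi for every reachable state, and
#' averages across parameters and states; `Inf` gives the noise-free
#' (deterministic) point. The standard error of the mean is taken across
#' all defined `(tau, w, state)` cells (and replicates, if any).
#'
#' @param intervals Mean spike intervals in multiples of dt (may include
#'   `Inf`).
#' @param taus,weights Parameter grid (defaults: the full sweep grid).
#' @param steps_per_run Steps per restart (1000 for noisy estimates).
#' @param seed Base seed; replicate r of interval i uses
#'   `seed + 1000 * i + r`.
#' @param reps Independent seeds per interval.
#' @param noise_weight,target Noise hookup, as in [phi_internal_noise()].
#' @return A tibble with `interval`, `mean_phi`, `sem` and `n_cells`.
#' @export
mean_phi_vs_interval <- function(intervals, taus = 1:8,
                                 weights = seq(0, 100, by = 12.5),
                                 steps_per_run = 1000, seed = 1, reps = 1,
                                 noise_weight = 50, target = 1) {
  purrr::map_dfr(seq_along(intervals), function(ii) {
    interval <- intervals[ii]
    phis <- purrr::map_dfr(seq_len(reps), function(r) {
      purrr::map_dfr(taus, function(tau) {
        purrr::map_dfr(weights, function(w) {
          net <- gate_network(w = w, tau = tau)
          tab <- phi_internal_noise(
            net, interval, noise_weight = noise_weight, target = target,
            steps_per_run = steps_per_run,
            seed = seed + 1000L * ii + r)
          dplyr::mutate(tab, tau = tau, w = w, rep = r)
        })
      })
    })
    ok <- phis$phi[phis$status == "ok" & !is.na(phis$phi)]
    tibble::tibble(
      interval = interval, mean_phi = mean(ok),
      sem = stats::sd(ok) / sqrt(length(ok)), n_cells = length(ok)
    )
  })
}
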