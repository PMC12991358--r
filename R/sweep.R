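# Parameter sweep over membrane time constant and synaptic weight, and the
# plotting layer (trace rendering, Phi heatmaps).

#' Define a tau-by-weight sweep grid
#'
#' Defaults are the full study grid: tau from 1 to 8 dt, weights from 0 to
#' 100 mV in 12.5 mV steps, 200 simulation steps per restart.
#'
#' @param taus Membrane time constants, multiples of dt.
#' @param weights Uniform synaptic weights, mV.
#' @param steps_per_run Steps per restart for TPM estimation.
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(taus = 1:8, weights = seq(0, 100, by = 12.5),
                       steps_per_run = 200) {
  stopifnot(all(taus >= 1), all(weights >= 0), steps_per_run >= 1)
  structure(list(taus = taus, weights = weights,
                 steps_per_run = steps_per_run),
            class = "sweep_grid")
}

#' Run the tau-by-weight Phi sweep
#'
#' For every grid cell, builds the gate network, estimates the empirical TPM
#' with one 200-step restart per binary state, and computes Phi for each of
#' the `2^n` current states. Cells are independent; a failure in one cell is
#' recorded (`status = "error"`) without aborting the sweep. Unreachable
#' states are kept as a distinct status, never as Phi = 0.
#'
#' @param grid A [sweep_grid()].
#' @param extra_input Use the 3-input threshold column (see
#'   [gate_network()]).
#' @return A `phi_sweep` tibble with columns `tau`, `w`, `state`, `phi`,
#'   `status`, `n_concepts`; the grid is attached as an attribute.
#' @export
#' @examples
#' \donttest{
#' sw <- run_sweep(sweep_grid(taus = 1, weights = 50, steps_per_run = 8))
#' sw
#' }
run_sweep <- function(grid = sweep_grid(), extra_input = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  out <- purrr::map_dfr(grid$taus, function(tau) {
    purrr::map_dfr(grid$weights, function(w) {
      net <- gate_network(w = w, tau = tau, extra_input = extra_input)
      model <- empirical_tpm(net, steps_per_run = grid$steps_per_run)
      dplyr::mutate(phi_per_state(model), tau = tau, w = w,
                    .before = "state")
    })
  })
  attr(out, "grid") <- grid
  class(out) <- c("phi_sweep", class(out))
  out
}

#' Mean Phi across states, per grid cell
#'
#' Cell-wise arithmetic mean over the states with a defined Phi (unreachable
#' and errored states are excluded, not counted as zero).
#'
#' @param sweep A `phi_sweep` tibble from [run_sweep()].
#' @return A tibble with `tau`, `w`, `mean_phi` and `n_defined`.
#' @export
mean_across_states <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$tau, .data$w) |>
    dplyr::summarise(
      mean_phi = mean(.data$phi[.data$status == "ok"]),
      n_defined = sum(.data$status == "ok"),
      .groups = "drop"
    )
}

#' Plot a membrane-potential trace
#'
#' Draws the per-neuron membrane potential curves. Because the simulated
#' potential jumps straight back to rest on firing, an action potential is
#' hard to see; at each firing step a purely cosmetic spike overshoot
#' followed by an afterhyperpolarisation dip is drawn. These marks are added
#' at the plotting stage only and never touch the stored trace. Gate-network
#' neurons use the conventional colours (OR red, AND green, XOR blue).
#'
#' @param object An `iaf_trace`.
#' @param spike_height Cosmetic overshoot height above the firing threshold,
#'   mV (non-physical, display only).
#' @param dip_depth Cosmetic afterhyperpolarisation depth below rest, mV
#'   (non-physical, display only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iaf_trace <- function(object, spike_height = 30, dip_depth = 15,
                               ...) {
  net <- object$network
  df <- tidy(object)
  # Insert cosmetic spike/dip vertices at firing steps.
  pieces <- lapply(seq_len(net$n), function(i) {
    lab <- net$neurons$label[i]
    v <- object$v[, i]; sp <- object$spikes[, i]
    steps <- seq_along(v)
    x <- as.numeric(steps); y <- v
    fired <- which(sp == 1L)
    if (length(fired)) {
      thr <- net$neurons$threshold_low[i]
      rest <- net$neurons$v_rest[i]
      extra_x <- c(fired - 0.25, fired - 0.15, fired)
      extra_y <- c(rep(thr + spike_height, length(fired)),
                   rep(rest - dip_depth, length(fired)),
                   v[fired])
      x <- c(x, extra_x); y <- c(y, extra_y)
      o <- order(x)
      x <- x[o]; y <- y[o]
    }
    tibble::tibble(neuron = lab, step = x, v = y)
  })
  plotdf <- dplyr::bind_rows(pieces)
  plotdf$neuron <- factor(plotdf$neuron, levels = net$neurons$label)
  p <- ggplot2::ggplot(plotdf,
                       ggplot2::aes(x = .data$step, y = .data$v,
                                    colour = .data$neuron)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation step", y = "membrane potential (mV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (setequal(net$neurons$label[1:min(3, net$n)], c("OR", "AND", "XOR"))) {
    p <- p + ggplot2::scale_colour_manual(
      values = c(OR = "red", AND = "green3", XOR = "blue"),
      breaks = net$neurons$label
    )
  }
  p
}

#' Heatmaps of Phi over the parameter grid
#'
#' `autoplot()` on a `phi_sweep` draws tau-by-weight heatmaps, one facet per
#' network state (`type = "state"`) or a single mean-across-states panel
#' (`type = "mean"`). Unreachable cells are marked with an x rather than
#' coloured as zero. The colour scale is shared across facets by default.
#'
#' @param object A `phi_sweep` from [run_sweep()].
#' @param type `"state"` or `"mean"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phi_sweep <- function(object, type = c("state", "mean"), ...) {
  type <- match.arg(type)
  if (type == "mean") {
    df <- mean_across_states(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$w),
                                       y = factor(.data$tau),
                                       fill = .data$mean_phi)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c(name = expression(bar(Phi))) +
        ggplot2::labs(x = "weight (mV)", y = expression(tau ~ "(dt)")) +
        ggplot2::theme_minimal()
    )
  }
  df <- object
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$w),
                                   y = factor(.data$tau),
                                   fill = .data$phi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$status != "ok"),
      shape = 4, size = 2, colour = "grey30",
      ggplot2::aes(x = factor(.data$w), y = factor(.data$tau)),
      inherit.aes = FALSE
    ) +
    ggplot2::facet_wrap(~ state) +
    ggplot2::scale_fill_viridis_c(name = expression(Phi), na.value = "white") +
    ggplot2::labs(x = "weight (mV)", y = expression(tau ~ "(dt)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of relative Phi change under noise
#'
#' Draws the [relative_change()] table as a tau-by-weight heatmap (facetted
#' by state when present); cells whose baseline Phi is zero — where the
#' relative difference diverges — are marked with an x.
#'
#' @param comparison A tibble from [relative_change()] containing `tau`,
#'   `w`, `rel_change` and `rel_label`.
#' @return A ggplot object.
#' @export
plot_relative_change <- function(comparison) {
  stopifnot(all(c("tau", "w", "rel_change") %in% names(comparison)))
  p <- ggplot2::ggplot(comparison,
                       ggplot2::aes(x = factor(.data$w),
                                    y = factor(.data$tau),
                                    fill = .data$rel_change)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = dplyr::filter(comparison, .data$rel_label == "x"),
      shape = 4, size = 2, colour = "grey30",
      ggplot2::aes(x = factor(.data$w), y = factor(.data$tau)),
      inherit.aes = FALSE
    ) +
    ggplot2::scale_fill_gradient2(name = "rel. change (%)") +
    ggplot2::labs(x = "weight (mV)", y = expression(tau ~ "(dt)")) +
    ggplot2::theme_minimal()
  if ("state" %in% names(comparison)) p <- p + ggplot2::facet_wrap(~ state)
  p
}

#' Glance at a sweep
#'
#' @param x A `phi_sweep`.
#' @param ... Unused.
#' @return One-row tibble summarising the sweep.
#' @export
glance.phi_sweep <- function(x, ...) {
  tibble::tibble(
    n_cells = dplyr::n_distinct(x$tau, x$w),
    n_states = dplyr::n_distinct(x$state),
    n_unreachable = sum(x$status == "unreachable"),
    max_phi = max(x$phi, na.rm = TRUE),
    mean_phi = mean(x$phi[x$status == "ok"])
  )
}
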