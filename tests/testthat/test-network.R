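test_that("gate presets carry the published thresholds and wiring", {
  net2 <- gate_network(w = 50, tau = 1, extra_input = FALSE)
  net3 <- gate_network(w = 50, tau = 1, extra_input = TRUE)
  expect_equal(net2$neurons$threshold_low, c(50, 100, 50))
  expect_equal(net3$neurons$threshold_low, c(50, 150, 50))
  expect_equal(net2$neurons$threshold_high, c(Inf, Inf, 100))
  for (w in c(0, 12.5, 87.5)) {
    expect_equal(diag(gate_network(w = w, tau = 3)$weights), rep(0, 3))
  }
  expect_error(iaf_network(matrix(c(1, 0, 0, 0), 2, 2), tau = 1,
                           threshold_low = 50),
               "self-connections")
  expect_error(iaf_network(matrix(0, 2, 2), tau = 0.5, threshold_low = 50),
               "tau")
})

test_that("binary initialisation puts voltages at rest and spikes on the wire", {
  net <- gate_network()
  st <- init_from_binary_state(net, c(1, 0, 0))
  expect_equal(st$v, c(0, 0, 0))
  expect_equal(st$spikes, c(1L, 0L, 0L))
  expect_equal(init_from_binary_state(net, c(1, 1, 1))$spikes, c(1L, 1L, 1L))
  expect_error(init_from_binary_state(net, c(1, 0)), "length")
})

test_that("single-step dynamics follow the leaky integration equation", {
  # leak halves the distance to rest for tau = 2
  net <- iaf_network(matrix(0, 2, 2), tau = 2, threshold_low = 1000)
  st <- list(v = c(50, 0), spikes = c(0L, 0L))
  expect_equal(iaf_step(net, st)$v, c(25, 0))
  # tau = 1 collapses to V_rest + summed input regardless of history
  net1 <- iaf_network(matrix(0, 2, 2), tau = 1, threshold_low = 1000)
  st1 <- list(v = c(77.3, -4), spikes = c(0L, 0L))
  expect_equal(iaf_step(net1, st1)$v, c(0, 0))
  # gate network from (1,0,0): only XOR's 50 mV falls in its window
  g <- gate_network()
  out <- iaf_step(g, init_from_binary_state(g, c(1, 0, 0)))
  expect_equal(out$spikes, c(0L, 0L, 1L))
  expect_equal(oracle_gate_next(c(1, 0, 0)), c(0L, 0L, 1L))
})

test_that("tau = 1 traces equal the memoryless closed form at every step", {
  net <- gate_network(w = 62.5, tau = 1)
  for (k in 1:8) {
    init <- all_states(3)[k, ]
    tr <- simulate_iaf(net, init, steps = 20)
    spikes <- rbind(init, tr$spikes)
    for (t in 1:20) {
      v_closed <- as.vector(net$weights %*% spikes[t, ])
      fired <- as.integer(v_closed >= net$neurons$threshold_low &
                            v_closed < net$neurons$threshold_high)
      expect_equal(tr$spikes[t, ], fired, ignore_attr = TRUE)
      expect_equal(tr$v[t, ], ifelse(fired == 1, 0, v_closed),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the leak pulls an input-free potential monotonically to rest", {
  net <- iaf_network(matrix(0, 1, 1), tau = 4, threshold_low = 1000)
  st <- list(v = 80, spikes = 0L)
  vs <- numeric(30)
  for (t in 1:30) { st <- iaf_step(net, st); vs[t] <- st$v }
  expect_true(all(diff(c(80, vs)) < 0))
  expect_true(all(vs > 0))
  # a huge time constant conserves the potential almost exactly
  slow <- iaf_network(matrix(0, 1, 1), tau = 1e9, threshold_low = 1000)
  expect_equal(iaf_step(slow, list(v = 80, spikes = 0L))$v, 80,
               tolerance = 1e-6)
})

test_that("simulation is deterministic and (0,0,0) stays silent", {
  net <- gate_network(w = 75, tau = 5)
  a <- simulate_iaf(net, c(1, 1, 0), 100)
  b <- simulate_iaf(net, c(1, 1, 0), 100)
  expect_identical(a$v, b$v)
  expect_identical(a$spikes, b$spikes)
  for (tau in c(1, 4, 8)) for (w in c(12.5, 50, 100)) {
    tr <- simulate_iaf(gate_network(w = w, tau = tau), c(0, 0, 0), 50)
    expect_true(all(tr$spikes == 0L))
    expect_true(all(tr$v == 0))
  }
})

test_that("binary activity reaches a stationary (eventually periodic) state", {
  is_periodic_suffix <- function(spikes, max_period = 64) {
    n_steps <- nrow(spikes)
    for (p in seq_len(max_period)) {
      a <- spikes[seq(n_steps - 2 * p + 1, n_steps - p), , drop = FALSE]
      b <- spikes[seq(n_steps - p + 1, n_steps), , drop = FALSE]
      if (identical(a, b)) return(TRUE)
    }
    FALSE
  }
  states <- all_states(3)
  for (tau in 1:8) for (w in seq(0, 100, by = 12.5)) {
    net <- gate_network(w = w, tau = tau)
    for (k in 1:8) {
      tr <- simulate_iaf(net, states[k, ], 200)
      expect_true(is_periodic_suffix(tr$spikes),
                  info = sprintf("tau=%g w=%g state=%s", tau, w,
                                 paste(states[k, ], collapse = "")))
    }
  }
})

test_that("traces tidy and export cleanly", {
  tr <- simulate_iaf(gate_network(), c(1, 0, 0), 8)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8 * 3)
  expect_setequal(unique(td$neuron), c("OR", "AND", "XOR"))
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  got <- utils::read.delim(f)
  expect_equal(nrow(got), 8)
  expect_equal(got$spike_XOR, tr$spikes[, "XOR"], ignore_attr = TRUE)
})
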